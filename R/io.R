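# CSV readers/writers for the toolkit's tabular interchange formats.

#' Read and write vital-rate tables
#'
#' CSV with header `species, s0, s1, s2, s3, b, e, h, f, AFR`, one row per
#' species.
#'
#' @param path File path.
#' @return `read_vital_rates()`: a named list of [vital_rates()] objects.
#' @export
read_vital_rates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    with(df[i, ], vital_rates(s0, s1, s2, s3, b, e, h, f, AFR))
  })
  names(out) <- df$species
  out
}

#' @rdname read_vital_rates
#' @param vitals Named list of [vital_rates()] objects.
#' @export
write_vital_rates <- function(vitals, path) {
  df <- do.call(rbind, lapply(names(vitals), function(sp) {
    v <- vitals[[sp]]
    data.frame(species = sp, s0 = v$s0, s1 = v$s1, s2 = v$s2, s3 = v$s3,
               b = v$b, e = v$e, h = v$h, f = v$f, AFR = v$AFR)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write colony tables
#'
#' CSV with columns `island_id, lon, lat, area_km2` (and optionally `K`).
#'
#' @param path File path.
#' @return `read_colonies()`: the colony data frame, with a
#'   [colony_geometry()] in attribute `"geometry"`.
#' @export
read_colonies <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  geom <- colony_geometry(lon = df$lon, lat = df$lat, ids = df$island_id)
  attr(df, "geometry") <- geom
  df
}

#' @rdname read_colonies
#' @param colonies Colony data frame.
#' @export
write_colonies <- function(colonies, path) {
  write.csv(as.data.frame(colonies), path, row.names = FALSE)
  invisible(path)
}

#' Read and write literature vital-rate records
#'
#' CSV with columns `parameter, value, se, species, genus, family`.
#'
#' @param path File path.
#' @return `read_literature_records()`: the record data frame.
#' @export
read_literature_records <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_literature_records
#' @param records Record data frame.
#' @export
write_literature_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read and write invasive assemblage tables
#'
#' CSV with columns `island_id, invasive_category, zeta_override` (the
#' override may be blank to use the category default).
#'
#' @param path File path.
#' @param colonies Colony data frame (for island areas).
#' @return `read_invasives()`: named list of [invasive_assemblage()]
#'   objects keyed by island id (islands with no invasives are absent).
#' @export
read_invasives <- function(path, colonies) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(list())
  out <- list()
  for (id in unique(df$island_id)) {
    rows <- df[df$island_id == id, , drop = FALSE]
    area <- colonies$area_km2[match(id, colonies$island_id)]
    zeta <- rows$zeta_override
    if (is.null(zeta)) zeta <- rep(NA, nrow(rows))
    zdef <- unname(default_zeta()[rows$invasive_category])
    zeta <- ifelse(is.na(zeta), zdef, zeta)
    out[[as.character(id)]] <- invasive_assemblage(
      rows$invasive_category, area = area, zeta = zeta)
  }
  out
}

#' @rdname read_invasives
#' @param assemblages Named list of assemblages keyed by island id.
#' @export
write_invasives <- function(assemblages, path) {
  rows <- do.call(rbind, lapply(names(assemblages), function(id) {
    a <- assemblages[[id]]
    data.frame(island_id = id, invasive_category = a$members$category,
               zeta_override = a$members$zeta)
  }))
  if (is.null(rows)) {
    rows <- data.frame(island_id = character(),
                       invasive_category = character(),
                       zeta_override = integer())
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read and write count time series
#'
#' CSV with columns `island_id, year, count, invasives_present` (a
#' semicolon-separated category list, blank when none). The per-island
#' assemblage is taken from the first survey year; the removal year is the
#' first year at which a previously invaded island shows no invasives.
#'
#' @param path File path.
#' @param colonies Colony data frame supplying island areas.
#' @return `read_count_series()`: a list of [count_series()] objects.
#' @export
read_count_series <- function(path, colonies) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$invasives_present[is.na(df$invasives_present)] <- ""
  lapply(split(df, df$island_id), function(rows) {
    rows <- rows[order(rows$year), ]
    first_inv <- strsplit(rows$invasives_present[1], ";")[[1]]
    first_inv <- first_inv[nzchar(first_inv)]
    area <- colonies$area_km2[match(rows$island_id[1], colonies$island_id)]
    assemblage <- if (length(first_inv)) {
      invasive_assemblage(first_inv, area = area)
    }
    removal_year <- NA
    if (length(first_inv)) {
      empty <- !nzchar(rows$invasives_present)
      if (any(empty)) removal_year <- min(rows$year[empty])
    }
    count_series(rows$island_id[1], rows$year, rows$count,
                 assemblage = assemblage, removal_year = removal_year)
  })
}

#' @rdname read_count_series
#' @param series List of [count_series()] objects.
#' @export
write_count_series <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(s) {
    cats <- if (is.null(s$assemblage)) character()
            else s$assemblage$members$category
    inv <- vapply(s$years, function(y) {
      present <- length(cats) > 0 &&
        (is.na(s$removal_year) || y < s$removal_year)
      if (present) paste(cats, collapse = ";") else ""
    }, character(1))
    data.frame(island_id = s$island_id, year = s$years, count = s$counts,
               invasives_present = inv)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write posterior draws and diagnostics
#'
#' Draws go to a samples CSV (one row per draw, one column per parameter)
#' and the diagnostics (split R-hat and acceptance rates) to a companion
#' `*_diagnostics.csv`.
#'
#' @param posterior A `posterior_draws` object.
#' @param path Samples CSV path.
#' @export
write_posterior <- function(posterior, path) {
  write.csv(as.data.frame(posterior$samples), path, row.names = FALSE)
  diag_path <- sub("\\.csv$", "_diagnostics.csv", path)
  d <- posterior$diagnostics
  write.csv(data.frame(parameter = names(d$rhat), rhat = unname(d$rhat)),
            diag_path, row.names = FALSE)
  invisible(path)
}
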