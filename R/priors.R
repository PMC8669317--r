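#' Taxonomic weighting of literature vital-rate records
#'
#' Literature estimates are weighted by taxonomic relatedness to the focal
#' species: records from the same species are replicated 20x, same genus
#' (different species) 5x, and different genus within the same family 1x.
#' Records from outside the focal family are dropped.
#'
#' @param records Data frame of literature records with columns `parameter`,
#'   `value`, `se` (optional, may be `NA`), `species`, `genus`, `family`.
#' @param focal Named list or character vector with the focal `species`,
#'   `genus` and `family`.
#' @return The expanded data frame (one row per replicate) with a
#'   `relation` column (`species`/`genus`/`family`).
#' @examples
#' recs <- data.frame(parameter = "s2", value = c(0.9, 0.85), se = NA,
#'                    species = c("A x", "A y"), genus = "A", family = "F")
#' nrow(weight_records(recs, list(species = "A x", genus = "A",
#'                                family = "F")))  # 20 + 5
#' @export
weight_records <- function(records, focal) {
  needed <- c("parameter", "value", "species", "genus", "family")
  if (!all(needed %in% names(records))) {
    stop_invalid("records must have columns: ", paste(needed, collapse = ", "))
  }
  focal <- as.list(focal)
  in_family <- records$family == focal$family
  records <- records[in_family, , drop = FALSE]
  if (!nrow(records)) {
    stop_invalid("data deficient: no records within family '", focal$family,
                 "'; supply family-level defaults")
  }
  relation <- ifelse(records$species == focal$species, "species",
                     ifelse(records$genus == focal$genus, "genus", "family"))
  w <- c(species = 20L, genus = 5L, family = 1L)[relation]
  idx <- rep(seq_len(nrow(records)), times = w)
  out <- records[idx, , drop = FALSE]
  out$relation <- rep(relation, times = w)
  rownames(out) <- NULL
  out
}

#' Distribution family used for each vital-rate parameter
#'
#' Rates (`s0`-`s3`, `b`, `h`, `f`, `d1`-`d3`) get logit-normal priors,
#' integer-valued parameters (`e`, `AFR`) Poisson, and positive continuous
#' parameters (dispersal distance `delta`, nest density `eta`) log-normal.
#'
#' @param parameter Parameter name.
#' @return One of `"logit-normal"`, `"poisson"`, `"log-normal"`.
#' @export
prior_family_for <- function(parameter) {
  rates <- c("s0", "s1", "s2", "s3", "sa", "b", "h", "f", "d1", "d2", "d3", "da")
  if (parameter %in% rates) return("logit-normal")
  if (parameter %in% c("e", "AFR")) return("poisson")
  if (parameter %in% c("delta", "eta")) return("log-normal")
  stop_invalid("unknown parameter: ", parameter)
}

#' Fit a prior distribution to weighted literature values
#'
#' Maximum-likelihood fit (via [MASS::fitdistr()]) of the family implied by
#' the parameter kind: normal on logit-transformed values for rates (values
#' clipped to `[0.001, 0.999]` first), Poisson for integer parameters, and
#' log-normal for positive continuous parameters. `AFR` is fitted as
#' `Poisson(AFR - 1)` and shifted back, so the prior never admits an age of
#' first reproduction below one year. Degenerate samples (all values equal)
#' get their scale floored at `sigma_floor` so the prior stays proper.
#'
#' @param values Numeric vector of (already weighted/replicated) values.
#' @param parameter Parameter name (see [prior_family_for()]).
#' @param sigma_floor Minimum location-scale SD (logit or log scale).
#' @return Object of class `prior_distribution` with `family`, `params`
#'   (named vector), `parameter`, `n_effective` and `shift`.
#' @export
fit_prior <- function(values, parameter, sigma_floor = 0.05) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_invalid("no values to fit")
  fam <- prior_family_for(parameter)
  n_eff <- length(values)
  if (fam == "logit-normal") {
    if (any(values <= 0 | values >= 1)) {
      bad <- values[values <= 0 | values >= 1]
      if (any(bad < 0 | bad > 1)) {
        stop_invalid("rate values outside [0,1] rejected: ",
                     paste(utils::head(bad, 5), collapse = ", "))
      }
    }
    x <- logit(clip_rate(values))
    if (length(unique(x)) < 2) {
      pars <- c(mean = mean(x), sd = sigma_floor)
    } else {
      fit <- MASS::fitdistr(x, "normal")
      pars <- c(mean = unname(fit$estimate["mean"]),
                sd = max(unname(fit$estimate["sd"]), sigma_floor))
    }
  } else if (fam == "poisson") {
    shift <- if (parameter == "AFR") 1 else 0
    v <- values - shift
    if (any(v < 0)) stop_invalid(parameter, " values below ", shift, " rejected")
    fit <- MASS::fitdistr(round(v), "Poisson")
    pars <- c(lambda = unname(fit$estimate["lambda"]))
  } else {
    if (any(values <= 0)) stop_invalid(parameter, " values must be positive")
    x <- log(values)
    if (length(unique(x)) < 2) {
      pars <- c(meanlog = mean(x), sdlog = sigma_floor)
    } else {
      fit <- MASS::fitdistr(values, "lognormal")
      pars <- c(meanlog = unname(fit$estimate["meanlog"]),
                sdlog = max(unname(fit$estimate["sdlog"]), sigma_floor))
    }
  }
  structure(list(family = fam, params = pars, parameter = parameter,
                 n_effective = n_eff,
                 shift = if (fam == "poisson" && parameter == "AFR") 1 else 0),
            class = "prior_distribution")
}

#' @export
print.prior_distribution <- function(x, ...) {
  cat(sprintf("%s prior for %s (n_eff = %d): %s\n", x$family, x$parameter,
              x$n_effective,
              paste(names(x$params), round(x$params, 4), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Sample from a fitted prior on the natural scale
#'
#' Logit-normal priors are sampled as `plogis(rnorm(...))`, Poisson priors
#' as shifted Poisson counts (zero-truncated for egg counts so `e >= 1`),
#' log-normal priors as `rlnorm(...)`.
#'
#' @param dist A `prior_distribution`.
#' @param n Number of draws.
#' @param seed Optional seed for reproducibility.
#' @return Numeric vector of draws on the natural scale.
#' @export
sample_prior <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "prior_distribution"), n >= 1)
  with_seed(seed, {
    switch(dist$family,
      "logit-normal" = inv_logit(rnorm(n, dist$params["mean"],
                                       dist$params["sd"])),
      "poisson" = {
        x <- rpois(n, dist$params["lambda"]) + dist$shift
        if (dist$parameter == "e") {
          while (any(x == 0)) {
            x[x == 0] <- rpois(sum(x == 0), dist$params["lambda"])
          }
        }
        x
      },
      "log-normal" = rlnorm(n, dist$params["meanlog"], dist$params["sdlog"])
    )
  })
}

#' Prior mean on the natural scale (approximate for logit-normal)
#' @param dist A `prior_distribution`.
#' @return Scalar mean.
#' @export
prior_mean <- function(dist) {
  switch(dist$family,
    "logit-normal" = {
      # Gauss-Hermite-free approximation by fine quadrature
      z <- seq(-6, 6, length.out = 401)
      w <- dnorm(z)
      sum(inv_logit(dist$params["mean"] + dist$params["sd"] * z) * w) / sum(w)
    },
    "poisson" = unname(dist$params["lambda"]) + dist$shift,
    "log-normal" = unname(exp(dist$params["meanlog"] +
                                dist$params["sdlog"]^2 / 2))
  )
}

#' Build all vital-rate priors for a focal species
#'
#' Applies [weight_records()] then [fit_prior()] per parameter present in
#' the record table.
#'
#' @param records Literature record data frame (see [weight_records()]).
#' @param focal Focal taxon list (`species`, `genus`, `family`).
#' @param sigma_floor Passed to [fit_prior()].
#' @return Named list of `prior_distribution` objects.
#' @export
build_species_priors <- function(records, focal, sigma_floor = 0.05) {
  expanded <- weight_records(records, focal)
  params <- unique(expanded$parameter)
  out <- lapply(params, function(p) {
    fit_prior(expanded$value[expanded$parameter == p], p,
              sigma_floor = sigma_floor)
  })
  names(out) <- params
  out
}
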