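#' Colony geometry from pairwise distances or coordinates
#'
#' Holds the pairwise great-circle distances (km) between breeding
#' colonies. Either an explicit symmetric distance matrix or colony
#' longitude/latitude may be supplied; coordinates are converted with the
#' haversine great-circle distance since the colonies are oceanic islands.
#'
#' @param distances Optional `k x k` symmetric, zero-diagonal matrix of
#'   pairwise distances in km.
#' @param lon,lat Optional colony coordinates in decimal degrees (used when
#'   `distances` is not given).
#' @param ids Optional colony identifiers.
#' @return Object of class `colony_geometry` with elements `k`, `distances`
#'   and `ids`.
#' @examples
#' colony_geometry(lon = c(-91.1, -90.3, -89.6), lat = c(-0.4, -0.7, -1.4))
#' @export
colony_geometry <- function(distances = NULL, lon = NULL, lat = NULL,
                            ids = NULL) {
  if (is.null(distances)) {
    if (is.null(lon) || is.null(lat) || length(lon) != length(lat)) {
      stop_invalid("supply either a distance matrix or matching lon/lat")
    }
    distances <- geosphere::distm(cbind(lon, lat)) / 1000
  }
  distances <- as.matrix(distances)
  k <- nrow(distances)
  if (ncol(distances) != k) stop_invalid("distance matrix must be square")
  if (any(distances < 0)) stop_invalid("distances must be non-negative")
  if (any(abs(diag(distances)) > 1e-9)) stop_invalid("diagonal must be zero")
  if (max(abs(distances - t(distances))) > 1e-6 * max(1, max(distances))) {
    stop_invalid("distance matrix must be symmetric")
  }
  distances <- (distances + t(distances)) / 2
  ids <- ids %||% paste0("island_", seq_len(k))
  dimnames(distances) <- list(ids, ids)
  structure(list(k = k, distances = distances, ids = ids),
            class = "colony_geometry")
}

#' Stage-specific dispersal specification
#'
#' @param d1,d2,d3 Annual emigration probabilities for sub-adults, breeding
#'   adults and non-breeding adults, each in `[0, 1]`. These give only the
#'   probability of leaving the natal/resident colony; the destination is
#'   chosen by the connectivity matrix.
#' @param delta Mean dispersal distance in km (positive); the scale of the
#'   exponential dispersal kernel.
#' @return Object of class `dispersal_spec`.
#' @export
dispersal_spec <- function(d1 = 0.1, d2 = 0.02, d3 = 0.05, delta = 200) {
  check_prob(c(d1, d2, d3), "dispersal probabilities")
  check_positive(delta, "delta")
  structure(list(d1 = d1, d2 = d2, d3 = d3, delta = delta,
                 D = diag(c(d1, d2, d3))),
            class = "dispersal_spec")
}

#' Inter-population connectivity matrix
#'
#' Builds the `k x k` connectivity matrix whose off-diagonal entry in row
#' `j`, column `i` is the probability that an emigrant from colony `i`
#' settles at colony `j`. Dispersal distances are taken as exponentially
#' distributed with mean `delta`, so relative likelihoods are
#' `exp(-distance/delta)`, rescaled so the off-diagonal entries of every
#' column sum to one. The diagonal is fixed at -1, which makes every full
#' column sum to zero and simplifies the meta-matrix algebra.
#'
#' @param geom A [colony_geometry()] (needs `k >= 2`).
#' @param delta Mean dispersal distance in km.
#' @return `k x k` connectivity matrix.
#' @examples
#' g <- colony_geometry(distances = matrix(c(0, 100, 200, 100, 0, 150,
#'                                           200, 150, 0), 3))
#' build_connectivity(g, delta = 100)
#' @export
build_connectivity <- function(geom, delta) {
  stopifnot(inherits(geom, "colony_geometry"))
  check_positive(delta, "delta")
  k <- geom$k
  if (k < 2) {
    stop_invalid("connectivity is undefined for a single colony; ",
                 "use the single-colony projection path")
  }
  W <- exp(-geom$distances / delta)
  diag(W) <- 0
  IP <- sweep(W, 2, colSums(W), "/")
  diag(IP) <- -1
  dimnames(IP) <- dimnames(geom$distances)
  IP
}

#' Assemble the metapopulation projection matrix
#'
#' Combines per-colony stage matrices, stage-specific dispersal and the
#' connectivity matrix into the `3k x 3k` meta-matrix
#' \deqn{M = (IP \otimes D) C + C}
#' where `C` is the block diagonal of the colony matrices and `D` the
#' diagonal matrix of stage emigration probabilities. Individuals first
#' survive and transition within their colony (`C`), and the emigrating
#' fraction is then redistributed among destinations; because each column
#' of `IP` sums to zero (off-diagonals to one, diagonal -1), dispersal
#' conserves individuals. With one colony, `M = C`.
#'
#' @param mats List of `projection_matrix` objects (or plain 3x3 matrices),
#'   one per colony, island-major order.
#' @param dispersal A [dispersal_spec()]; `NULL` disables dispersal.
#' @param IP Connectivity matrix from [build_connectivity()]; required when
#'   `dispersal` is given and there is more than one colony (built
#'   automatically when `geom` is supplied instead).
#' @param geom Optional [colony_geometry()] used to build `IP` with the
#'   dispersal spec's `delta`.
#' @return `3k x 3k` metapopulation matrix.
#' @export
assemble_metapopulation <- function(mats, dispersal = NULL, IP = NULL,
                                    geom = NULL) {
  blocks <- lapply(mats, function(m) {
    if (inherits(m, "projection_matrix")) m$A else as.matrix(m)
  })
  k <- length(blocks)
  if (!all(vapply(blocks, function(b) all(dim(b) == c(3, 3)), logical(1)))) {
    stop_invalid("each colony matrix must be 3x3")
  }
  C <- matrix(0, 3 * k, 3 * k)
  for (i in seq_len(k)) {
    idx <- (3 * (i - 1) + 1):(3 * i)
    C[idx, idx] <- blocks[[i]]
  }
  if (is.null(dispersal) || k == 1) return(C)
  stopifnot(inherits(dispersal, "dispersal_spec"))
  if (is.null(IP)) {
    if (is.null(geom)) stop_invalid("supply IP or geom for dispersal")
    IP <- build_connectivity(geom, dispersal$delta)
  }
  if (!all(dim(IP) == k)) stop_invalid("IP must be k x k")
  kronecker(IP, dispersal$D) %*% C + C
}

#' Project a metapopulation one year forward
#'
#' @param M Metapopulation matrix from [assemble_metapopulation()].
#' @param n Stacked stage-abundance vector of length `3k`, island-major
#'   (colony 1 stages 1-3, colony 2 stages 1-3, ...).
#' @return The abundance vector one year later.
#' @export
project_metapopulation <- function(M, n) {
  n <- as.numeric(n)
  if (any(n < 0) || anyNA(n)) stop_invalid("abundances must be >= 0")
  if (length(n) != ncol(M)) stop_invalid("length(n) must equal ncol(M)")
  as.numeric(M %*% n)
}
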