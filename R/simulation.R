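#' Stochasticity configuration for forward simulations
#'
#' @param sigma_e Named logit-scale SDs of annual environmental deviations
#'   per vital rate. Defaults: 1 for first-winter (fledgling) survival
#'   `s0`, 0.5 for all other perturbed rates. Deviations are perfectly
#'   correlated across rates within a colony-year (one standardised
#'   deviate per colony-year, scaled per rate).
#' @param sigma_log_e Log-scale SD for egg-count deviations (default 0:
#'   clutch size is not perturbed unless requested).
#' @param temporal_r First-order autocorrelation of annual deviations
#'   (default 0.67).
#' @param spatial_anchors Two (distance km, correlation) anchor points the
#'   spatial decay must pass through; default R = 0.9 at 100 km and
#'   R = 0.5 at 1000 km.
#' @param demographic_threshold Colony abundance below which survival is
#'   drawn with demographic (beta) stochasticity (default 100).
#' @return A list of class `stochasticity_config`.
#' @export
stochasticity_config <- function(sigma_e = c(s0 = 1, s1 = 0.5, s2 = 0.5,
                                             s3 = 0.5, b = 0.5, h = 0.5,
                                             f = 0.5),
                                 sigma_log_e = 0,
                                 temporal_r = 0.67,
                                 spatial_anchors = list(d = c(100, 1000),
                                                        r = c(0.9, 0.5)),
                                 demographic_threshold = 100) {
  if (any(sigma_e < 0) || sigma_log_e < 0) stop_invalid("sigma must be >= 0")
  if (abs(temporal_r) >= 1) stop_invalid("temporal_r must be in (-1, 1)")
  if (demographic_threshold < 0) stop_invalid("threshold must be >= 0")
  structure(list(sigma_e = sigma_e, sigma_log_e = sigma_log_e,
                 temporal_r = temporal_r, spatial_anchors = spatial_anchors,
                 demographic_threshold = demographic_threshold),
            class = "stochasticity_config")
}

#' Between-colony correlation of environmental deviations
#'
#' Stretched-exponential distance decay `R(d) = exp(-(d/rho)^c)` with
#' `(c, rho)` solved exactly so the curve passes through both anchor
#' points (by default R = 0.9 at 100 km and R = 0.5 at 1000 km). The
#' result has unit diagonal and is projected to the nearest positive
#' semi-definite matrix (eigenvalue clipping, diagonal re-normalised)
#' if needed.
#'
#' @param distances `k x k` distance matrix in km.
#' @param anchors List with `d` (two distances) and `r` (two correlations).
#' @return `k x k` correlation matrix.
#' @examples
#' spatial_correlation(matrix(c(0, 100, 100, 0), 2))[1, 2]  # 0.9
#' @export
spatial_correlation <- function(distances,
                                anchors = list(d = c(100, 1000),
                                               r = c(0.9, 0.5))) {
  distances <- as.matrix(distances)
  d1 <- anchors$d[1]; d2 <- anchors$d[2]
  r1 <- anchors$r[1]; r2 <- anchors$r[2]
  cc <- log(log(r2) / log(r1)) / log(d2 / d1)
  rho <- d1 / (-log(r1))^(1 / cc)
  R <- exp(-(distances / rho)^cc)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 1e-10)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    s <- sqrt(diag(R))
    R <- R / tcrossprod(s)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
        < -1e-8) {
      stop_invalid("spatial correlation matrix not positive semi-definite")
    }
  }
  R
}

#' Generate spatiotemporally correlated environmental deviates
#'
#' Draws zero-mean logit-scale deviations for every (year, colony, rate):
#' a single standardised deviate per colony-year, shared across rates and
#' scaled by the per-rate `sigma_e`. Spatially correlated innovations
#' (Cholesky factor of the [spatial_correlation()] matrix) are passed
#' through a stationary AR(1) recursion with coefficient `temporal_r`
#' (initialised from the stationary distribution and innovation-scaled by
#' `sqrt(1 - r^2)`), so marginal SDs, the lag-1 autocorrelation and the
#' cross-colony correlations are all attained exactly in expectation.
#'
#' @param n_years Number of years.
#' @param k Number of colonies.
#' @param cfg A [stochasticity_config()].
#' @param distances Optional `k x k` km distance matrix (independent
#'   colonies when omitted).
#' @param seed Optional seed.
#' @return Array `[n_years, k, rate]` of logit-scale deviations, with the
#'   standardised colony-year deviates in attribute `"z"`.
#' @export
generate_env_deviates <- function(n_years, k, cfg = stochasticity_config(),
                                  distances = NULL, seed = NULL) {
  stopifnot(n_years >= 1, k >= 1)
  with_seed(seed, {
    if (!is.null(distances) && k > 1) {
      R <- spatial_correlation(distances, cfg$spatial_anchors)
      L <- chol(R)
    } else {
      L <- diag(k)
    }
    r <- cfg$temporal_r
    innov <- matrix(rnorm(n_years * k), n_years, k) %*% L
    z <- matrix(0, n_years, k)
    z[1, ] <- innov[1, ]
    if (n_years > 1) {
      sc <- sqrt(1 - r^2)
      for (t in 2:n_years) z[t, ] <- r * z[t - 1, ] + sc * innov[t, ]
    }
    rates <- names(cfg$sigma_e)
    out <- array(0, dim = c(n_years, k, length(rates)),
                 dimnames = list(NULL, NULL, rates))
    for (j in seq_along(rates)) out[, , j] <- z * cfg$sigma_e[j]
    attr(out, "z") <- z
    out
  })
}

#' Demographic-stochasticity survival draw
#'
#' Realised survival for a small group of `n` individuals: a beta draw
#' with mean `p` and variance `p(1-p)/n` (method-of-moments shapes
#' `alpha = p(n-1)`, `beta = (1-p)(n-1)`). At `n = 1` the beta variance
#' target equals the Bernoulli variance and the shapes degenerate, so a
#' Bernoulli draw is returned instead.
#'
#' @param p Expected survival probability in (0, 1).
#' @param n Number of individuals experiencing the rate (`>= 1`).
#' @param seed Optional seed.
#' @return A realised survival probability.
#' @export
demographic_survival_draw <- function(p, n, seed = NULL) {
  check_prob(p, "p", allow_zero = FALSE, allow_one = FALSE)
  if (n < 1) stop_invalid("n must be >= 1")
  with_seed(seed, {
    if (n <= 1) return(rbinom(1, 1, p))
    rbeta(1, p * (n - 1), (1 - p) * (n - 1))
  })
}

# ---- scenarios ------------------------------------------------------------

#' Management scenarios
#'
#' Constructors for the scenarios compared by the simulator: `default`
#' (current threats unchanged), removal of invasive species from selected
#' islands at a given year, a reduction of at-sea mortality hazard on
#' sub-adult and adult survival, and reintroduction/translocation of
#' founders to a (previously empty) island already present in the
#' configuration. Translocation additionally removes the founders from the
#' source colonies in proportion to their abundance.
#'
#' @param islands Island indices (or ids) losing their invasives.
#' @param year Year the action takes effect (1 = first simulated year).
#' @param offset Log-hazard reduction applied to `s1`, `s2`, `s3`
#'   (`s' = s^exp(-offset)`, so survival increases).
#' @param island Target island index for founders.
#' @param founders Length-3 vector of founder females by stage.
#' @param K Carrying capacity assigned to the target island from `year` on
#'   (`NULL` keeps the configured value).
#' @return A list of class `scenario`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_default <- function() {
  structure(list(kind = "default"), class = "scenario")
}

#' @rdname scenarios
#' @export
scenario_invasive_removal <- function(islands, year = 1) {
  structure(list(kind = "invasive_removal", islands = islands, year = year),
            class = "scenario")
}

#' @rdname scenarios
#' @export
scenario_at_sea_mitigation <- function(offset) {
  if (offset < 0) stop_invalid("offset must be >= 0")
  structure(list(kind = "at_sea_mitigation", offset = offset),
            class = "scenario")
}

#' @rdname scenarios
#' @export
scenario_reintroduction <- function(island, founders, K = NULL, year = 1) {
  structure(list(kind = "reintroduction", island = island,
                 founders = founders, K = K, year = year),
            class = "scenario")
}

#' @rdname scenarios
#' @export
scenario_translocation <- function(island, founders, K = NULL, year = 1) {
  structure(list(kind = "translocation", island = island,
                 founders = founders, K = K, year = year),
            class = "scenario")
}

# ---- species configuration ------------------------------------------------

#' Species configuration for forward simulation
#'
#' Bundles the fixed structure of a simulated species: its islands (areas,
#' carrying capacities, invasive assemblages), geometry and dispersal,
#' density-dependence shape, and the age of first reproduction used to
#' collapse the age classes.
#'
#' @param islands List with one entry per island: a list holding `id`,
#'   `area` (km2), `K` (females) and optionally `assemblage` (an
#'   [invasive_assemblage()] or `NULL`).
#' @param AFR Age of first reproduction (years).
#' @param geometry Optional [colony_geometry()] (required for dispersal
#'   with more than one island).
#' @param dispersal Optional [dispersal_spec()].
#' @param hazards Optional [hazard_parameters()] applying to all islands
#'   with assemblages.
#' @param theta Density-dependence shape exponent.
#' @return A list of class `species_config`.
#' @export
species_config <- function(islands, AFR, geometry = NULL, dispersal = NULL,
                           hazards = NULL, theta = 7.5) {
  k <- length(islands)
  if (!is.null(dispersal) && k > 1 && is.null(geometry)) {
    stop_invalid("dispersal with multiple islands requires geometry")
  }
  structure(list(islands = islands, k = k, AFR = AFR, geometry = geometry,
                 dispersal = dispersal, hazards = hazards, theta = theta),
            class = "species_config")
}

#' Initialise the stage-structured population vector
#'
#' Three entry points, depending on what abundance information exists:
#' per-island totals of all birds (halved to females, spread over the
#' stable stage distribution), per-island breeding-pair counts (pairs set
#' the breeding-female stage directly; other stages scaled by SSD ratios),
#' or a species-wide total of birds (halved, partitioned among islands by
#' allocation proportions, then spread over the SSD).
#'
#' @param ssd Stable stage distribution (length 3, sums to 1).
#' @param totals Per-island totals of all birds.
#' @param pairs Per-island breeding-pair counts.
#' @param species_total Species-wide total of all birds.
#' @param proportions Island allocation proportions (required with
#'   `species_total`), e.g. from [allocate()].
#' @return `3 x k` matrix of female abundance by stage and island.
#' @export
initialize_population <- function(ssd, totals = NULL, pairs = NULL,
                                  species_total = NULL, proportions = NULL) {
  stopifnot(length(ssd) == 3, abs(sum(ssd) - 1) < 1e-8)
  if (!is.null(totals)) {
    females <- totals / 2
    out <- vapply(females, function(N) N * ssd, numeric(3))
  } else if (!is.null(pairs)) {
    if (ssd[2] <= 0) stop_invalid("SSD has no breeders; cannot scale pairs")
    out <- vapply(pairs, function(p) p * ssd / ssd[2], numeric(3))
  } else if (!is.null(species_total)) {
    if (is.null(proportions)) stop_invalid("species_total needs proportions")
    females <- (species_total / 2) * proportions / sum(proportions)
    out <- vapply(females, function(N) N * ssd, numeric(3))
  } else {
    stop_invalid("no abundance information supplied")
  }
  matrix(out, nrow = 3)
}

#' Quasi-extinction threshold from initial population size
#'
#' 50 females (100 individuals) for species starting above 200 breeding
#' pairs, 10 females otherwise.
#'
#' @param initial_pairs Initial breeding pairs (total over islands).
#' @return The QE threshold in females.
#' @export
choose_qe <- function(initial_pairs) {
  if (initial_pairs > 200) 50 else 10
}

# ---- inner simulation loop ------------------------------------------------

# per-island hazard log-ratios under the fixed parameters (NULL -> zeros)
island_gammas <- function(config) {
  t(vapply(config$islands, function(isl) {
    if (is.null(isl$assemblage) || is.null(config$hazards) ||
        isl$assemblage$Xi == 0) {
      return(c(0, 0))
    }
    c(chick_log_hazard(isl$assemblage, config$hazards),
      adult_cumulative_hazard(isl$assemblage, config$hazards))
  }, numeric(2)))
}

#' Run one stochastic trajectory
#'
#' Simulates `years` of metapopulation dynamics for one parameter draw.
#' Each year and island: invasive hazards (as modified by the scenario)
#' adjust fledging success and breeding-adult survival; density dependence
#' reduces fledging success as the colony approaches its `K`; environmental
#' deviates perturb the vital rates on the logit scale; survival is drawn
#' with beta demographic stochasticity when the colony is below the
#' demographic threshold; the colony matrices are re-solved and assembled
#' into the meta-matrix; and the population is projected one year. A
#' trajectory whose total female abundance falls below `qe` is absorbed at
#' zero (quasi-extinction) unless `absorbing = FALSE`.
#'
#' @param vitals A [vital_rates()] object (the parameter draw).
#' @param config A [species_config()].
#' @param init `3 x k` initial female abundance matrix.
#' @param scenario A scenario object (see [scenario_default()]).
#' @param years Number of years to simulate.
#' @param cfg A [stochasticity_config()].
#' @param qe Quasi-extinction threshold in females (0 disables).
#' @param seed Optional seed.
#' @param absorbing Treat quasi-extinction as absorbing.
#' @param deviates Optional pre-generated deviate array (from
#'   [generate_env_deviates()]); drawn internally when omitted.
#' @return List with `totals` (length `years + 1`, includes the initial
#'   year) and `trajectory` (`(years+1) x 3 x k` array).
#' @export
run_inner <- function(vitals, config, init, scenario = scenario_default(),
                      years = 100, cfg = stochasticity_config(), qe = 0,
                      seed = NULL, absorbing = TRUE, deviates = NULL) {
  stopifnot(inherits(config, "species_config"))
  k <- config$k
  init <- matrix(init, nrow = 3)
  stopifnot(ncol(init) == k)
  with_seed(seed, {
    dist_m <- if (!is.null(config$geometry)) config$geometry$distances
    if (is.null(deviates)) {
      deviates <- generate_env_deviates(years, k, cfg, dist_m)
    }
    # dispersal operator is constant across years: M_t = (IP (x) D + I) C_t,
    # so precompute E = IP (x) D + I once and apply it to the post-demography
    # abundances
    E <- if (!is.null(config$dispersal) && k > 1) {
      IP <- build_connectivity(config$geometry, config$dispersal$delta)
      kronecker(IP, config$dispersal$D) + diag(3 * k)
    }
    gam <- island_gammas(config)
    Ks <- vapply(config$islands, function(isl) isl$K, numeric(1))
    ids <- vapply(seq_len(k), function(i) {
      as.character(config$islands[[i]]$id %||% i)
    }, character(1))
    removal_set <- integer()
    if (scenario$kind == "invasive_removal") {
      removal_set <- if (is.character(scenario$islands)) {
        match(scenario$islands, ids)
      } else as.integer(scenario$islands)
    }
    atsea <- if (scenario$kind == "at_sea_mitigation") scenario$offset else 0
    founder_year <- if (scenario$kind %in%
                        c("reintroduction", "translocation")) {
      scenario$year
    } else 0
    T <- config$AFR - 1
    ri <- match(c("s0", "s1", "s2", "s3", "b", "h", "f"),
                dimnames(deviates)[[3]])
    if (anyNA(ri)) stop_invalid("deviate array lacks named rate slices")
    n <- init
    traj <- array(0, dim = c(years + 1, 3, k))
    traj[1, , ] <- n
    totals <- numeric(years + 1)
    totals[1] <- sum(n)
    extinct <- FALSE
    for (t in seq_len(years)) {
      if (extinct) break
      if (t == founder_year) {
        tgt <- as.integer(scenario$island)
        if (scenario$kind == "translocation") {
          take <- sum(scenario$founders)
          src_tot <- totals[t] - sum(n[, tgt])
          if (src_tot > 0) {
            for (i in setdiff(seq_len(k), tgt)) {
              n[, i] <- n[, i] * max(0, 1 - take / src_tot)
            }
          }
        }
        n[, tgt] <- n[, tgt] + scenario$founders
        if (!is.null(scenario$K)) Ks[tgt] <- scenario$K
      }
      # vectorized over islands: k-vectors of this year's effective rates
      removed <- (seq_len(k) %in% removal_set) &
        t >= (if (length(removal_set)) scenario$year else Inf)
      g_f <- ifelse(removed, 0, gam[, 1])
      g_s <- ifelse(removed, 0, gam[, 2])
      Ni <- .colSums(n, 3, k)
      s0 <- rep(vitals$s0, k); s1 <- rep(vitals$s1, k)
      s2 <- rep(vitals$s2, k); s3 <- rep(vitals$s3, k)
      b <- rep(vitals$b, k); e <- rep(vitals$e, k)
      h <- rep(vitals$h, k); f <- rep(vitals$f, k)
      f <- ifelse(g_f > 0 & f > 0, f^exp(g_f), f)
      s2 <- ifelse(g_s > 0 & s2 > 0, s2^exp(g_s), s2)
      if (atsea > 0) {
        sc <- exp(-atsea)
        s1 <- s1^sc; s2 <- s2^sc; s3 <- s3^sc
      }
      f <- f / (1 + (Ni / Ks)^config$theta)
      # perturbation skipped for zero deviates so that deterministic runs
      # (and boundary rates 0/1) are untouched
      dv <- matrix(deviates[t, , ], nrow = k)
      ptb <- function(p, d) ifelse(d == 0, p, inv_logit(logit(clip_rate(p)) + d))
      s0 <- ptb(s0, dv[, ri[1]]); s1 <- ptb(s1, dv[, ri[2]])
      s2 <- ptb(s2, dv[, ri[3]]); s3 <- ptb(s3, dv[, ri[4]])
      b <- ptb(b, dv[, ri[5]]); h <- ptb(h, dv[, ri[6]])
      f <- ptb(f, dv[, ri[7]])
      if (cfg$sigma_log_e > 0) {
        e <- exp(log(e) + attr(deviates, "z")[t, ] * cfg$sigma_log_e)
      }
      small <- which(Ni > 0 & Ni < cfg$demographic_threshold)
      for (i in small) {
        bdraw <- function(p, m) {
          if (m < 1) return(p)
          p <- clip_rate(p)
          if (m <= 1) rbinom(1, 1, p) else rbeta(1, p * (m - 1),
                                                 (1 - p) * (m - 1))
        }
        s0[i] <- bdraw(s0[i], n[2, i] * b[i] * (e[i] / 2) * h[i] * f[i])
        s1[i] <- bdraw(s1[i], n[1, i])
        s2[i] <- bdraw(s2[i], n[2, i])
        s3[i] <- bdraw(s3[i], n[3, i])
      }
      for (i in seq_len(k)) {
        sol <- .solve_stage_cpp(c(s0[i], s1[i], s2[i], s3[i], b[i], e[i],
                                  h[i], f[i]), T, 1e-6, 200L, 1)
        n[, i] <- sol$A %*% n[, i]
      }
      if (!is.null(E)) n <- matrix(E %*% as.numeric(n), nrow = 3)
      if (any(!is.finite(n))) {
        stop_invalid("numeric overflow in year ", t)
      }
      tot <- sum(n)
      if (qe > 0 && tot < qe && absorbing) {
        extinct <- TRUE
        n[] <- 0
        tot <- 0
      }
      totals[t + 1] <- tot
      traj[t + 1, , ] <- n
    }
    list(totals = totals, trajectory = traj)
  })
}

#' Quasi-extinction probability from a set of trajectories
#'
#' Fraction of trajectories whose total female abundance ever drops below
#' the QE threshold.
#'
#' @param totals Matrix of trajectory totals, one row per run.
#' @param qe QE threshold in females.
#' @return Proportion in `[0, 1]`.
#' @export
compute_qep <- function(totals, qe) {
  totals <- as.matrix(totals)
  mean(apply(totals, 1, function(x) any(x < qe)))
}

#' Two-loop stochastic projection
#'
#' The outer loop draws one joint parameter set per replicate from the
#' posterior (`NS1` replicates, capturing parameter uncertainty); the
#' inner loop runs `NS2` stochastic trajectories per draw (environmental
#' and demographic stochasticity). Each outer replicate yields a point
#' estimate of projected abundance (`N_proj`, the median terminal-year
#' total across inner runs) and a QEP (fraction of inner runs crossing the
#' QE threshold); medians, standard errors and interquartile ranges of
#' both are reported across outer replicates.
#'
#' @param posteriors A `posterior_draws` object (or a data frame / matrix
#'   of natural-scale samples with vital-rate columns and optionally
#'   hazard columns).
#' @param config A [species_config()].
#' @param init `3 x k` initial abundance matrix.
#' @param scenario Scenario object.
#' @param NS1,NS2 Outer and inner replicates (both default 100).
#' @param years Simulated years (default 100).
#' @param cfg A [stochasticity_config()].
#' @param qe QE threshold; when `NULL`, chosen by [choose_qe()] from the
#'   initial breeding-pair total.
#' @param seed Master seed; all replicate seeds derive from it.
#' @return A list of class `simulation_result` with `N_proj`, `QEP` (per
#'   outer replicate) and a `summary` data frame (median, se, IQR).
#' @export
run_full <- function(posteriors, config, init, scenario = scenario_default(),
                     NS1 = 100, NS2 = 100, years = 100,
                     cfg = stochasticity_config(), qe = NULL, seed = 1) {
  samples <- if (inherits(posteriors, "posterior_draws")) {
    posteriors$samples
  } else {
    as.matrix(posteriors)
  }
  init <- matrix(init, nrow = 3)
  qe <- qe %||% choose_qe(sum(init[2, ]))
  hz_cols <- c("delta_bar", "sigma_delta", "phi", "psi", "beta1", "beta2")
  have_hz <- all(hz_cols %in% colnames(samples))
  categories <- unique(unlist(lapply(config$islands, function(isl) {
    if (is.null(isl$assemblage)) character()
    else isl$assemblage$members$category
  })))
  N_proj <- QEP <- numeric(NS1)
  row_ids <- with_seed(derive_seed(seed, 999),
                       sample.int(nrow(samples), NS1, replace = TRUE))
  for (r in seq_len(NS1)) {
    draw <- samples[row_ids[r], ]
    vit <- vital_rates(s0 = draw[["s0"]], s1 = draw[["s1"]],
                       s2 = draw[["s2"]], s3 = draw[["s3"]],
                       b = draw[["b"]], e = max(draw[["e"]], 0.1),
                       h = draw[["h"]], f = draw[["f"]], AFR = config$AFR)
    cfg_r <- config
    if (have_hz && length(categories)) {
      dx <- vapply(categories, function(cc) {
        nm <- paste0("delta_", cc)
        if (nm %in% colnames(samples)) draw[[nm]]
        else max(1, draw[["delta_bar"]])
      }, numeric(1))
      names(dx) <- categories
      adsz <- if (!is.null(config$hazards)) config$hazards$adult_size else 1
      cfg_r$hazards <- hazard_parameters(
        delta_x = dx, phi = draw[["phi"]], psi = draw[["psi"]],
        beta1 = draw[["beta1"]], beta2 = draw[["beta2"]],
        delta_bar = max(draw[["delta_bar"]], 1.0001),
        sigma_delta = draw[["sigma_delta"]], adult_size = adsz)
    }
    finals <- numeric(NS2)
    crossed <- logical(NS2)
    for (j in seq_len(NS2)) {
      run <- run_inner(vit, cfg_r, init, scenario, years, cfg, qe,
                       seed = derive_seed(seed, r * 1000L + j))
      finals[j] <- run$totals[years + 1]
      crossed[j] <- any(run$totals < qe)
    }
    N_proj[r] <- median(finals)
    QEP[r] <- mean(crossed)
  }
  summarise <- function(x) {
    c(median = median(x), se = sd(x) / sqrt(length(x)),
      iqr_lo = unname(quantile(x, 0.25)), iqr_hi = unname(quantile(x, 0.75)))
  }
  structure(list(N_proj = N_proj, QEP = QEP, qe = qe,
                 scenario = scenario$kind,
                 summary = rbind(N_proj = summarise(N_proj),
                                 QEP = summarise(QEP))),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("mPVA projection (%s scenario, QE = %g females)\n",
              x$scenario, x$qe))
  print(round(x$summary, 4))
  invisible(x)
}
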