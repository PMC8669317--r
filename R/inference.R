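#' Weights defining pseudo-observed annual growth rates by trend status
#'
#' The lookup table mapping each qualitative IUCN-style trend label to a
#' weight (out of 100) for each candidate annual growth rate lambda on the
#' grid 0.90-1.10. Modal values are 1.02 (Increasing), 1.00 (Stable) and
#' 0.98 (Decreasing); the Unknown column spreads weight broadly. Every
#' column sums to 100.
#'
#' @return Data frame with columns `lambda`, `Increasing`, `Stable`,
#'   `Decreasing`, `Unknown`.
#' @export
trend_weight_table <- function() {
  data.frame(
    lambda = seq(0.90, 1.10, by = 0.01),
    Increasing = c(0, 0, 0, 0, 0, 1, 2, 3, 6, 8, 11, 12, 13, 12, 11, 8, 6,
                   4, 2, 1, 0),
    Stable     = c(0, 0, 0, 1, 2, 3, 5, 8, 11, 13, 14, 13, 11, 8, 5, 3, 2,
                   1, 0, 0, 0),
    Decreasing = c(0, 1, 2, 3, 6, 8, 11, 12, 13, 12, 11, 8, 6, 4, 2, 1, 0,
                   0, 0, 0, 0),
    Unknown    = c(1, 1, 2, 3, 3, 5, 6, 7, 9, 10, 10, 10, 9, 7, 5, 4, 3, 2,
                   1, 1, 1))
}

#' Pseudo-observations of annual growth rate for a trend label
#'
#' Expands the weight table column for a status into a vector of exactly
#' 100 "observed" lambda values (each grid value repeated by its weight),
#' used as data when updating vital-rate posteriors from a categorical
#' trend.
#'
#' @param status One of `"Increasing"`, `"Stable"`, `"Decreasing"`,
#'   `"Unknown"`.
#' @return Object of class `trend_label`: list with `status` and
#'   `pseudo_obs` (length-100 numeric vector).
#' @examples
#' tl <- build_trend_pseudo_observations("Decreasing")
#' table(tl$pseudo_obs)
#' @export
build_trend_pseudo_observations <- function(status) {
  tab <- trend_weight_table()
  valid <- setdiff(names(tab), "lambda")
  if (!is.character(status) || length(status) != 1 || !(status %in% valid)) {
    stop_invalid("unknown trend status; valid labels: ",
                 paste(valid, collapse = ", "))
  }
  obs <- rep(tab$lambda, times = tab[[status]])
  stopifnot(length(obs) == 100)
  structure(list(status = status, pseudo_obs = obs), class = "trend_label")
}

#' Count time series for one island
#'
#' @param island_id Island identifier.
#' @param years Strictly increasing integer survey years.
#' @param counts Non-negative integer survey counts (same length).
#' @param assemblage Optional [invasive_assemblage()] present at the
#'   island (NULL for invasive-free islands).
#' @param removal_year Calendar year from which the island is
#'   invasive-free (inclusive), or `NA` if invasives were never removed.
#' @return Object of class `count_series`.
#' @export
count_series <- function(island_id, years, counts, assemblage = NULL,
                         removal_year = NA) {
  years <- as.integer(years)
  if (any(diff(years) <= 0)) stop_invalid("years must be strictly increasing")
  if (length(counts) != length(years)) stop_invalid("years/counts mismatch")
  if (any(counts < 0) || anyNA(counts)) stop_invalid("counts must be >= 0")
  if (!is.null(assemblage)) stopifnot(inherits(assemblage,
                                               "invasive_assemblage"))
  structure(list(island_id = island_id, years = years,
                 counts = as.numeric(counts), assemblage = assemblage,
                 removal_year = unname(as.numeric(removal_year))),
            class = "count_series")
}

# ---- shared internals for both Bayesian fits ------------------------------

vital_par_names <- function() c("q_s0", "q_s1", "q_s2", "q_s3", "q_b",
                                "q_h", "q_f", "l_e")

# Normal prior (on the transformed scale) for each vital-rate parameter,
# taken from the priors module: rates were fitted on the logit scale
# already; the Poisson egg-count prior is approximated by a log-normal
# matching its mean and coefficient of variation so that e can move
# continuously in the sampler.
vital_prior_table <- function(priors) {
  need <- c("s0", "s1", "s2", "s3", "b", "h", "f", "e")
  missing <- setdiff(need, names(priors))
  if (length(missing)) {
    stop_invalid("missing priors for: ", paste(missing, collapse = ", "))
  }
  mu <- sdv <- numeric(8)
  for (i in 1:7) {
    p <- priors[[need[i]]]
    if (p$family != "logit-normal") {
      stop_invalid("prior for ", need[i], " must be logit-normal")
    }
    mu[i] <- p$params["mean"]; sdv[i] <- p$params["sd"]
  }
  pe <- priors$e
  if (pe$family == "poisson") {
    lam <- pe$params["lambda"]
    mu[8] <- log(lam)
    sdv[8] <- sqrt(log(1 + 1 / lam))
  } else {
    mu[8] <- pe$params["meanlog"]; sdv[8] <- pe$params["sdlog"]
  }
  list(mu = setNames(mu, vital_par_names()),
       sd = setNames(sdv, vital_par_names()))
}

vitals_from_par <- function(par) {
  c(inv_logit(par[c("q_s0", "q_s1", "q_s2", "q_s3", "q_b", "q_h", "q_f")]),
    exp(par["l_e"]))
}

# stage matrix (cpp solve) from natural-scale vitals with optional hazards
solve_matrix_hazard <- function(vnat, T, gamma_f = 0, gamma_s = 0,
                                tol = 1e-8) {
  vv <- c(vnat[["q_s0"]], vnat[["q_s1"]], vnat[["q_s2"]], vnat[["q_s3"]],
          vnat[["q_b"]], vnat[["l_e"]], vnat[["q_h"]], vnat[["q_f"]])
  if (gamma_f > 0) vv[8] <- vv[8]^exp(gamma_f)
  if (gamma_s > 0) vv[3] <- vv[3]^exp(gamma_s)
  .solve_stage_cpp(vv, T, tol, 200L, 1)
}

hazard_par_names <- function(categories) {
  c(paste0("ldx_", categories), "ldbar", "lsd", "qphi", "lpsi",
    "beta1", "beta2")
}

# log prior for the hazard block on the transformed scale
hazard_log_prior <- function(par, categories) {
  dbar <- exp(par[["ldbar"]])
  sdl <- exp(par[["lsd"]])
  phi <- inv_logit(par[["qphi"]])
  psi <- exp(par[["lpsi"]])
  lp <- dnorm(par[["ldbar"]], 0, 10, log = TRUE) +
    dnorm(sdl, 0, 10, log = TRUE) + par[["lsd"]] +          # half-N(0,10)
    log(phi) + log(1 - phi) +                               # U(0,1) Jacobian
    dnorm(psi, 0, 10, log = TRUE) + par[["lpsi"]] +         # half-N(0,10)
    dnorm(par[["beta1"]], 0, 10, log = TRUE) +
    dnorm(par[["beta2"]], 0, 10, log = TRUE)
  # hierarchical Delta_x ~ N(delta_bar, sigma) truncated below at 1
  for (cc in categories) {
    ldx <- par[[paste0("ldx_", cc)]]
    dx <- 1 + exp(ldx)
    tail_mass <- 1 - pnorm(1, dbar, sdl)
    if (tail_mass < 1e-12) return(-Inf)
    lp <- lp + dnorm(dx, dbar, sdl, log = TRUE) - log(tail_mass) + ldx
  }
  lp
}

#' Fit the invasive-impact state-space model to count time series
#'
#' Bayesian state-space fit of the invasive hazard parameters. The latent
#' true female abundance at each island follows the deterministic
#' stage-structured projection (built from the vital rates with the
#' proportional-hazards invasive adjustments; density dependence and
#' inter-island dispersal are excluded here), started from its stable
#' stage distribution at an estimated initial abundance. Survey counts are
#' Poisson-distributed around the latent abundance. Islands with a
#' `removal_year` switch from the hazard-adjusted matrix to the baseline
#' matrix in that year, which is what identifies the hazard ratios.
#'
#' Sampling is by adaptive random-walk Metropolis-within-Gibbs on log/logit
#' scales: one block for the vital rates, one for the hazard parameters
#' (`Delta_x` per invasive category, the hierarchy hyper-parameters
#' `delta_bar` and `sigma_delta`, `phi`, `psi`, `beta1`, `beta2`), and
#' scalar updates for each island's initial abundance. Vital-rate priors
#' come from the priors module; hazard parameters get weakly informative
#' priors (half-normal(0,10) for `psi` and `sigma_delta`, uniform(0,1) for
#' `phi`, normal(0,10) for `beta1`, `beta2` and `log(delta_bar)`) and
#' initial abundances a log-uniform prior on `[1, 10 max(O)]`.
#'
#' @param series List of [count_series()] objects.
#' @param species_meta List with `AFR` (years) and `adult_size` (kg).
#' @param priors Named list of `prior_distribution` objects for
#'   `s0,s1,s2,s3,b,h,f,e` (see [build_species_priors()]).
#' @param mcmc An [mcmc_config()].
#' @param seed Integer seed; chains use sub-seeds derived from it.
#' @return A `posterior_draws` object. `$samples` holds natural-scale
#'   draws (vital rates, `delta_<category>`, `delta_bar`, `sigma_delta`,
#'   `phi`, `psi`, `beta1`, `beta2`, `N1_<island>`); `$diagnostics` holds
#'   split R-hat and block acceptance rates.
#' @export
fit_state_space <- function(series, species_meta, priors,
                            mcmc = mcmc_config(), seed = 1) {
  if (!length(series)) stop_invalid("need at least one count series")
  stopifnot(all(vapply(series, inherits, logical(1), "count_series")))
  T <- species_meta$AFR - 1
  adsz <- species_meta$adult_size %||% 1
  vp <- vital_prior_table(priors)
  categories <- sort(unique(unlist(lapply(series, function(s) {
    if (is.null(s$assemblage)) character() else s$assemblage$members$category
  }))))
  if (!length(categories)) {
    stop_invalid("no invasive assemblages present: hazard parameters are ",
                 "unidentifiable from these series")
  }
  hz_names <- hazard_par_names(categories)
  isl_ids <- vapply(series, function(s) as.character(s$island_id),
                    character(1))
  n1_names <- paste0("lN1_", isl_ids)
  par_names <- c(vital_par_names(), hz_names, n1_names)
  struct_idx <- seq_len(8 + length(hz_names))

  # per-island precomputations
  info <- lapply(series, function(s) {
    first <- s$years[1]
    n_years <- s$years[length(s$years)] - first + 1L
    obs_idx <- s$years - first + 1L
    has_inv <- !is.null(s$assemblage) && s$assemblage$Xi > 0
    switch_idx <- 0L
    if (has_inv && !is.na(s$removal_year)) {
      switch_idx <- max(0L, as.integer(s$removal_year - first))
    }
    list(n_years = n_years, obs_idx = obs_idx, counts = s$counts,
         has_inv = has_inv, switch_idx = switch_idx,
         cat = if (has_inv) s$assemblage$members$category else character(),
         zeta = if (has_inv) s$assemblage$members$zeta else integer(),
         Xi = if (has_inv) s$assemblage$Xi else 0L,
         area = if (has_inv) effective_area(s$assemblage$area) else 1,
         max_obs = max(s$counts, 1))
  })

  make_log_post <- function() {
    cache_key <- NULL
    cache_mats <- NULL
    function(par) {
      vn <- vitals_from_par(par)
      names(vn) <- vital_par_names()
      lp <- sum(dnorm(par[struct_idx[1:8]], vp$mu, vp$sd, log = TRUE)) +
        hazard_log_prior(par, categories)
      if (!is.finite(lp)) return(-Inf)
      key <- par[struct_idx]
      if (is.null(cache_key) || !identical(key, cache_key)) {
        dx <- 1 + exp(par[paste0("ldx_", categories)])
        names(dx) <- categories
        phi <- inv_logit(par[["qphi"]])
        psi <- exp(par[["lpsi"]])
        b1 <- par[["beta1"]]; b2 <- par[["beta2"]]
        base <- solve_matrix_hazard(vn, T)
        if (!base$converged) return(-Inf)
        mats <- vector("list", length(info))
        for (i in seq_along(info)) {
          ii <- info[[i]]
          if (!ii$has_inv) {
            mats[[i]] <- list(pre = base$A, post = base$A)
          } else {
            ldx_m <- log(dx[ii$cat])
            scalef <- ii$Xi^(-phi) * ii$area^(-psi)
            g_f <- sum(ldx_m) * scalef
            g_s <- sum(ii$zeta * b1 * ldx_m / (1 / adsz + 1)^b2) * scalef
            pre <- solve_matrix_hazard(vn, T, g_f, g_s)
            if (!pre$converged) return(-Inf)
            mats[[i]] <- list(pre = pre$A, post = base$A)
          }
        }
        cache_key <<- key
        cache_mats <<- mats
      }
      ll <- 0
      for (i in seq_along(info)) {
        ii <- info[[i]]
        lN1 <- par[[n1_names[i]]]
        if (lN1 < 0 || lN1 > log(10 * ii$max_obs)) return(-Inf)
        traj <- .project_totals_cpp(cache_mats[[i]]$pre,
                                    cache_mats[[i]]$post,
                                    ii$switch_idx, exp(lN1), ii$n_years)
        mu <- traj[ii$obs_idx]
        if (any(mu <= 0) || any(!is.finite(mu))) return(-Inf)
        ll <- ll + sum(dpois(ii$counts, mu, log = TRUE))
      }
      lp + ll
    }
  }

  init_factory <- function(chain) {
    set.seed(derive_seed(seed, 1000 + chain))
    init <- c(vp$mu + rnorm(8, 0, 0.1 * vp$sd),
              setNames(rep(log(0.2), length(categories)),
                       paste0("ldx_", categories)),
              ldbar = log(1.2) + rnorm(1, 0, 0.05),
              lsd = log(0.15), qphi = rnorm(1, 0, 0.3),
              lpsi = log(0.1), beta1 = 0.5 + rnorm(1, 0, 0.1),
              beta2 = 1 + rnorm(1, 0, 0.1),
              setNames(vapply(info, function(ii) {
                log(max(ii$counts[1], 2)) + rnorm(1, 0, 0.05)
              }, numeric(1)), n1_names))
    names(init)[1:8] <- vital_par_names()
    init
  }

  # vitals and hazard sub-blocks, a joint structural block (the two are
  # strongly correlated through the baseline growth rate), and scalar
  # initial-abundance updates
  blocks <- c(list(struct_idx[1:8], struct_idx[-(1:8)], struct_idx),
              as.list(8 + length(hz_names) + seq_along(n1_names)))
  out <- run_chains(make_log_post, init_factory, blocks, mcmc, seed,
                    transform = function(raw) {
                      nat <- raw
                      colnames(nat) <- c("s0", "s1", "s2", "s3", "b", "h",
                                         "f", "e",
                                         paste0("delta_", categories),
                                         "delta_bar", "sigma_delta", "phi",
                                         "psi", "beta1", "beta2",
                                         paste0("N1_", isl_ids))
                      for (j in 1:7) nat[, j] <- inv_logit(raw[, j])
                      nat[, "e"] <- exp(raw[, "l_e"])
                      for (cc in categories) {
                        nat[, paste0("delta_", cc)] <-
                          1 + exp(raw[, paste0("ldx_", cc)])
                      }
                      nat[, "delta_bar"] <- exp(raw[, "ldbar"])
                      nat[, "sigma_delta"] <- exp(raw[, "lsd"])
                      nat[, "phi"] <- inv_logit(raw[, "qphi"])
                      nat[, "psi"] <- exp(raw[, "lpsi"])
                      for (nm in n1_names) {
                        nat[, sub("^lN1_", "N1_", nm)] <- exp(raw[, nm])
                      }
                      nat
                    })
  out$categories <- categories
  out
}

#' Update vital-rate posteriors from a categorical trend label
#'
#' Treats the 100 pseudo-observed growth rates implied by an IUCN-style
#' trend label as data: each is assumed log-normally distributed around
#' the deterministic growth rate `lambda_hat` implied by the current
#' vital-rate draw (with any invasive hazards applied), with fitted
#' observation SD `sigma_lambda`. The sampler explores the vital rates
#' and `sigma_lambda`; invasive hazard parameters are held fixed at the
#' values supplied in `island_config` (draw them per outer replicate when
#' propagating uncertainty).
#'
#' @param priors Named list of vital-rate priors (as in
#'   [fit_state_space()]).
#' @param trend A `trend_label` from [build_trend_pseudo_observations()].
#' @param island_config List with `AFR`, and optionally `assemblage`
#'   (an [invasive_assemblage()]) plus `hazards` (a [hazard_parameters()])
#'   describing fixed invasive impacts entering `lambda_hat`.
#' @param mcmc An [mcmc_config()] (default 5000 saved samples across
#'   chains).
#' @param seed Integer seed.
#' @return A `posterior_draws` object; `$samples` has the natural-scale
#'   vital rates, `sigma_lambda` and the implied `lambda_hat`.
#' @export
update_with_trends <- function(priors, trend, island_config,
                               mcmc = mcmc_config(n_chains = 4,
                                                  n_burn = 1000,
                                                  n_save = 1250),
                               seed = 1) {
  stopifnot(inherits(trend, "trend_label"))
  T <- island_config$AFR - 1
  vp <- vital_prior_table(priors)
  g_f <- 0; g_s <- 0
  if (!is.null(island_config$assemblage) &&
      island_config$assemblage$Xi > 0) {
    hp <- island_config$hazards
    if (is.null(hp)) stop_invalid("assemblage supplied without hazards")
    g_f <- chick_log_hazard(island_config$assemblage, hp)
    g_s <- adult_cumulative_hazard(island_config$assemblage, hp)
  }
  obs <- trend$pseudo_obs
  par_names <- c(vital_par_names(), "lsl")

  make_log_post <- function() {
    function(par) {
      lp <- sum(dnorm(par[1:8], vp$mu, vp$sd, log = TRUE))
      sl <- exp(par[["lsl"]])
      lp <- lp + dnorm(sl, 0, 1, log = TRUE) + par[["lsl"]]  # half-N(0,1)
      vn <- vitals_from_par(par)
      names(vn) <- vital_par_names()
      sol <- solve_matrix_hazard(vn, T, g_f, g_s)
      if (!sol$converged || sol$lambda <= 0) return(-Inf)
      lp + sum(dlnorm(obs, log(sol$lambda), sl, log = TRUE))
    }
  }
  init_factory <- function(chain) {
    set.seed(derive_seed(seed, 2000 + chain))
    init <- c(vp$mu + rnorm(8, 0, 0.1 * vp$sd), lsl = log(0.03))
    names(init) <- par_names
    init
  }
  blocks <- list(1:8, 9L)
  out <- run_chains(make_log_post, init_factory, blocks, mcmc, seed,
                    transform = function(raw) {
                      nat <- raw
                      colnames(nat) <- c("s0", "s1", "s2", "s3", "b", "h",
                                         "f", "e", "sigma_lambda")
                      for (j in 1:7) nat[, j] <- inv_logit(raw[, j])
                      nat[, "e"] <- exp(raw[, "l_e"])
                      nat[, "sigma_lambda"] <- exp(raw[, "lsl"])
                      lam <- apply(raw, 1, function(p) {
                        vn <- vitals_from_par(p)
                        names(vn) <- vital_par_names()
                        solve_matrix_hazard(vn, T, g_f, g_s)$lambda
                      })
                      cbind(nat, lambda_hat = lam)
                    })
  out$trend <- trend$status
  out
}
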