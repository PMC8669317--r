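#' Default adult-risk switch by invasive category
#'
#' Whether a category of invasive species poses a measurable mortality risk
#' to adult seabirds (1) or only to eggs/nestlings (0): herbivores and
#' birds default to 0; carnivores, omnivores and rats to 1.
#'
#' @return Named integer vector over the five invasive categories.
#' @export
default_zeta <- function() {
  c(bird = 0L, carnivore = 1L, herbivore = 0L, omnivore = 1L, rat = 1L)
}

invasive_categories <- function() names(default_zeta())

#' Invasive-species assemblage on an island
#'
#' @param categories Character vector of invasive categories present, each
#'   one of `bird`, `carnivore`, `herbivore`, `omnivore`, `rat`.
#' @param area Island area in km2 (positive). Areas below 0.01 km2 are
#'   floored at 0.01 km2 when hazards are computed, to keep the
#'   island-size amplification bounded.
#' @param zeta Optional 0/1 vector overriding the default adult-risk
#'   switch per member.
#' @return Object of class `invasive_assemblage` with a `members` data
#'   frame (`category`, `zeta`), the member count `Xi` and `area`.
#' @examples
#' invasive_assemblage(c("rat", "carnivore"), area = 2.5)
#' @export
invasive_assemblage <- function(categories = character(), area, zeta = NULL) {
  check_positive(area, "area")
  categories <- as.character(categories)
  bad <- setdiff(categories, invasive_categories())
  if (length(bad)) {
    stop_invalid("unknown invasive categories: ", paste(bad, collapse = ", "),
                 " (valid: ", paste(invasive_categories(), collapse = ", "), ")")
  }
  zeta <- zeta %||% unname(default_zeta()[categories])
  if (length(zeta) != length(categories) || !all(zeta %in% c(0, 1))) {
    stop_invalid("zeta must be a 0/1 vector matching categories")
  }
  structure(list(members = data.frame(category = categories,
                                      zeta = as.integer(zeta),
                                      stringsAsFactors = FALSE),
                 Xi = length(categories), area = area),
            class = "invasive_assemblage")
}

#' Invasive hazard parameters
#'
#' Parameters of the proportional-hazards model for invasive impacts.
#' `delta_x` are chick hazard ratios keyed by invasive category for the
#' focal species' nesting type (a value of 1.1 means a 10% increase in
#' egg/nestling mortality risk). `phi` controls how hazards from multiple
#' invasives combine (purely additive at 0, purely compensatory at 1),
#' `psi` how per-capita impacts shrink on larger islands. `beta1` and
#' `beta2` scale adult hazards relative to chick hazards as a function of
#' adult body size, and `delta_bar`/`sigma_delta` are the hierarchical
#' hyper-parameters from which category-level `delta_x` are drawn.
#'
#' @param delta_x Named numeric vector of chick hazard ratios (`>= 1`) by
#'   invasive category, or a single unnamed value applied to all.
#' @param phi Compensation exponent in `[0, 1]`.
#' @param psi Island-size exponent (`>= 0`).
#' @param beta1,beta2 Adult-hazard scaling parameters.
#' @param delta_bar,sigma_delta Hyper-mean and SD of the hazard-ratio
#'   hierarchy (`sigma_delta > 0`).
#' @param adult_size Adult body mass in kg (positive).
#' @return Object of class `hazard_parameters`.
#' @export
hazard_parameters <- function(delta_x, phi = 0.5, psi = 0.1,
                              beta1 = 0.5, beta2 = 1,
                              delta_bar = 1.25, sigma_delta = 0.15,
                              adult_size = 1) {
  if (any(delta_x < 1)) {
    stop_invalid("delta_x must be >= 1 (invasives cannot reduce mortality)")
  }
  check_prob(phi, "phi")
  if (psi < 0) stop_invalid("psi must be >= 0")
  check_positive(sigma_delta, "sigma_delta")
  check_positive(adult_size, "adult_size")
  structure(list(delta_x = delta_x, phi = phi, psi = psi,
                 beta1 = beta1, beta2 = beta2, delta_bar = delta_bar,
                 sigma_delta = sigma_delta, adult_size = adult_size),
            class = "hazard_parameters")
}

lookup_delta <- function(params, categories) {
  dx <- params$delta_x
  if (is.null(names(dx))) {
    if (length(dx) == 1) return(rep(dx, length(categories)))
    stop_invalid("delta_x must be named by category when length > 1")
  }
  missing <- setdiff(categories, names(dx))
  if (length(missing)) {
    stop_invalid("no delta_x for categories: ", paste(missing, collapse = ", "))
  }
  unname(dx[categories])
}

effective_area <- function(area, floor = 0.01) max(area, floor)

#' Cumulative log hazard of invasive effects on fledging success
#'
#' \deqn{\gamma_f = \Big[\sum_x \log \Delta_x\Big] (1/X_i)^\phi (1/Area_i)^\psi}
#' Summed log hazard ratios over the `Xi` invasives present, discounted for
#' compensatory mortality (`phi`) and island size (`psi`). Zero for an
#' empty assemblage.
#'
#' @param assemblage An [invasive_assemblage()].
#' @param params A [hazard_parameters()].
#' @return Non-negative cumulative log hazard ratio.
#' @examples
#' a <- invasive_assemblage("rat", area = 1)
#' p <- hazard_parameters(delta_x = c(rat = 1.1))
#' chick_log_hazard(a, p)  # log(1.1)
#' @export
chick_log_hazard <- function(assemblage, params) {
  stopifnot(inherits(assemblage, "invasive_assemblage"),
            inherits(params, "hazard_parameters"))
  if (assemblage$Xi == 0) return(0)
  dx <- lookup_delta(params, assemblage$members$category)
  sum(log(dx)) * (1 / assemblage$Xi)^params$phi *
    (1 / effective_area(assemblage$area))^params$psi
}

#' Adult log hazard ratio for a single invasive
#'
#' \deqn{\log \Omega_x = \zeta_x \beta_1 \log(\Delta_x) / (1/AdSz + 1)^{\beta_2}}
#' Adult hazards are scaled down from chick hazards, more strongly for
#' small-bodied species, and switched off entirely (`zeta = 0`) for
#' invasive categories that pose no risk to adults.
#'
#' @param delta_x Chick hazard ratio (`> 0`).
#' @param zeta 0/1 adult-risk switch.
#' @param adult_size Adult body mass in kg.
#' @param beta1,beta2 Scaling parameters.
#' @return Adult log hazard ratio.
#' @export
adult_log_hazard_single <- function(delta_x, zeta, adult_size, beta1, beta2) {
  check_positive(delta_x, "delta_x")
  check_positive(adult_size, "adult_size")
  if (!all(zeta %in% c(0, 1))) stop_invalid("zeta must be 0 or 1")
  zeta * beta1 * log(delta_x) / (1 / adult_size + 1)^beta2
}

#' Cumulative log hazard of invasive effects on adult survival
#'
#' As [chick_log_hazard()] but with the per-member adult log hazards
#' `log(Omega_x)` (see [adult_log_hazard_single()]) in place of
#' `log(Delta_x)`; the same compensation and island-size discounts apply.
#'
#' @inheritParams chick_log_hazard
#' @return Non-negative cumulative adult log hazard ratio.
#' @export
adult_cumulative_hazard <- function(assemblage, params) {
  stopifnot(inherits(assemblage, "invasive_assemblage"),
            inherits(params, "hazard_parameters"))
  if (assemblage$Xi == 0) return(0)
  dx <- lookup_delta(params, assemblage$members$category)
  lo <- adult_log_hazard_single(dx, assemblage$members$zeta,
                                params$adult_size, params$beta1, params$beta2)
  sum(lo) * (1 / assemblage$Xi)^params$phi *
    (1 / effective_area(assemblage$area))^params$psi
}

#' Apply cumulative hazards to fledging success and adult survival
#'
#' Proportional-hazards transform of survival-type rates: a cumulative log
#' hazard `gamma` multiplies the cumulative mortality hazard `-log(S)` by
#' `exp(gamma)`, i.e. `S' = S^exp(gamma)`. Rates of exactly zero pass
#' through unchanged.
#'
#' @param f Baseline fledging probability.
#' @param s2 Baseline breeding-adult survival probability.
#' @param gamma_f,gamma_s Cumulative log hazard ratios (`>= 0`).
#' @return Named list with adjusted `f` and `s2`.
#' @examples
#' apply_hazards(0.7, 0.92, gamma_f = log(1.1), gamma_s = 0)
#' @export
apply_hazards <- function(f, s2, gamma_f, gamma_s) {
  check_prob(f, "f"); check_prob(s2, "s2")
  if (any(c(gamma_f, gamma_s) < 0)) stop_invalid("gammas must be >= 0")
  list(f = ifelse(f == 0, 0, f^exp(gamma_f)),
       s2 = ifelse(s2 == 0, 0, s2^exp(gamma_s)))
}

#' Draw category-level hazard ratios from the hierarchy
#'
#' Hierarchical draws `Delta_x ~ N(delta_bar, sigma_delta)` truncated below
#' at 1: hazard ratios under 1 would mean invasive species reduce seabird
#' mortality, which the model excludes.
#'
#' @param n Number of draws.
#' @param delta_bar,sigma_delta Hyper-parameters.
#' @param log_scale If `TRUE`, the hierarchy is placed on `log(Delta_x)`
#'   instead (normal around `log(delta_bar)`, truncated at `log(1) = 0`).
#' @param seed Optional seed.
#' @return Numeric vector of hazard ratios `>= 1`.
#' @export
draw_delta_x <- function(n, delta_bar, sigma_delta, log_scale = FALSE,
                         seed = NULL) {
  with_seed(seed, {
    mu <- if (log_scale) log(delta_bar) else delta_bar
    lo <- if (log_scale) 0 else 1
    # inverse-CDF truncated normal
    plo <- pnorm(lo, mu, sigma_delta)
    u <- runif(n, plo, 1)
    x <- qnorm_safe(u, mu, sigma_delta)
    if (log_scale) exp(x) else x
  })
}

qnorm_safe <- function(u, mu, sd) {
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mu, sd)
}
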