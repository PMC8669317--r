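#' Fit the nesting-proportion model for Area of Occupancy scaling
#'
#' Only part of a species' IUCN Area of Occupancy (AoO) is usable nesting
#' habitat. This fits a linear model for the logit of the nesting
#' proportion with adult body size (log kg) and taxonomic family as
#' covariates, for use by [scale_aoo()].
#'
#' @param training Data frame with columns `proportion` (in (0,1)),
#'   `body_size` (kg) and optionally `family`.
#' @return Fitted `lm` object of class `aoo_model`.
#' @export
fit_aoo_model <- function(training) {
  stopifnot(all(c("proportion", "body_size") %in% names(training)))
  training$y <- logit(clip_rate(training$proportion))
  fml <- if ("family" %in% names(training) &&
             length(unique(training$family)) > 1) {
    y ~ log(body_size) + family
  } else {
    y ~ log(body_size)
  }
  m <- lm(fml, data = training)
  class(m) <- c("aoo_model", class(m))
  m
}

#' Scale Area of Occupancy to suitable nesting area
#'
#' `AoO* = AoO x p`, where the nesting proportion `p` is either given
#' directly or predicted from an [fit_aoo_model()] fit for the species'
#' body size and family; predictions are clamped to `(0, 1]`.
#'
#' @param AoO Area of Occupancy in km2 (positive).
#' @param proportion Nesting proportion in `(0, 1]`; alternative to `model`.
#' @param model An `aoo_model`; used with `body_size` (and `family`).
#' @param body_size Adult body mass in kg.
#' @param family Taxonomic family label (must be a level seen in training
#'   unless the model was fitted without family).
#' @return Suitable nesting area `AoO*` in km2.
#' @export
scale_aoo <- function(AoO, proportion = NULL, model = NULL,
                      body_size = NULL, family = NULL) {
  check_positive(AoO, "AoO")
  if (is.null(proportion)) {
    if (is.null(model) || is.null(body_size)) {
      stop_invalid("supply either proportion or model + body_size")
    }
    nd <- data.frame(body_size = body_size)
    if ("family" %in% all.vars(stats::formula(model))) {
      if (is.null(family)) {
        stop_invalid("model uses family but none supplied")
      }
      nd$family <- family
    }
    proportion <- inv_logit(unname(predict(model, newdata = nd)))
  }
  if (any(proportion <= 0)) stop_invalid("proportion must be positive")
  proportion <- pmin(proportion, 1)
  AoO * proportion
}

#' Range-wide carrying capacity from nesting area and nest density
#'
#' `K = AoO* x eta`, in females (one nest is one breeding female).
#' A zero nesting area gives `K = 0` with a warning, flagging a degenerate
#' configuration.
#'
#' @param AoO_star Suitable nesting area in km2 (`>= 0`).
#' @param eta Maximum nest density in nests/km2 (positive).
#' @return Range-wide `K` in females.
#' @examples
#' species_K(10, 100)  # 1000 females
#' @export
species_K <- function(AoO_star, eta) {
  if (AoO_star < 0) stop_invalid("AoO_star must be >= 0")
  check_positive(eta, "eta")
  if (AoO_star == 0) {
    warning("AoO* is zero: carrying capacity degenerate at 0")
    return(0)
  }
  AoO_star * eta
}

#' Proportional-allocation model among breeding islands
#'
#' Logit-linear model for the share of range-wide abundance held by each
#' island, with terms for log island area, the number of breeding islands
#' `NI`, the island's relative-area share, the two interactions, and an
#' optional per-family intercept offset.
#'
#' @param intercept,log_area,NI,share,log_area_NI,NI_share Model
#'   coefficients (any may be 0).
#' @param family_effects Optional named numeric vector of per-family
#'   intercept offsets.
#' @return Object of class `allocation_model`.
#' @export
allocation_model <- function(intercept = 0, log_area = 1, NI = 0, share = 0,
                             log_area_NI = 0, NI_share = 0,
                             family_effects = NULL) {
  co <- c(intercept = intercept, log_area = log_area, NI = NI, share = share,
          log_area_NI = log_area_NI, NI_share = NI_share)
  if (any(!is.finite(co))) stop_invalid("coefficients must be finite")
  structure(list(coefficients = co, family_effects = family_effects),
            class = "allocation_model")
}

#' Allocate range-wide abundance (or K) proportionally among islands
#'
#' Applies the inverse-logit linear predictor of an [allocation_model()] to
#' each island and renormalises, so the returned proportions sum to one.
#'
#' @param areas Island areas in km2 (positive).
#' @param model An `allocation_model`.
#' @param NI Number of breeding islands (defaults to `length(areas)`).
#' @param family Optional family label selecting a family intercept offset.
#' @return Proportions summing to 1, one per island.
#' @export
allocate <- function(areas, model, NI = length(areas), family = NULL) {
  check_positive(areas, "areas")
  stopifnot(inherits(model, "allocation_model"))
  co <- model$coefficients
  shr <- areas / sum(areas)
  off <- 0
  if (!is.null(family) && !is.null(model$family_effects) &&
      family %in% names(model$family_effects)) {
    off <- model$family_effects[[family]]
  }
  lp <- co["intercept"] + off + co["log_area"] * log(areas) + co["NI"] * NI +
    co["share"] * shr + co["log_area_NI"] * log(areas) * NI +
    co["NI_share"] * NI * shr
  p <- inv_logit(lp)
  unname(p / sum(p))
}

#' Fit the allocation model to observed island shares
#'
#' Fits the logit-linear allocation model to a training table of observed
#' abundance shares. When more than one family is present a linear mixed
#' model with a random family intercept (via [lme4::lmer()]) is used,
#' matching the grouping structure of multi-species training data;
#' otherwise a plain `lm`.
#'
#' @param training Data frame with columns `share` (observed proportional
#'   abundance in (0,1)), `area` (km2), `NI`, `rel_area` (island's share of
#'   summed area; computed if absent, grouped by `species` when present)
#'   and optionally `family`.
#' @return An [allocation_model()] with estimated coefficients, plus the
#'   underlying fit in attribute `"fit"`.
#' @export
fit_allocation_model <- function(training) {
  stopifnot(all(c("share", "area", "NI") %in% names(training)))
  if (!"rel_area" %in% names(training)) {
    grp <- if ("species" %in% names(training)) training$species else 1
    tot <- tapply(training$area, grp, sum)[as.character(grp)]
    training$rel_area <- training$area / as.numeric(tot)
  }
  training$y <- logit(clip_rate(training$share))
  training$la <- log(training$area)
  use_family <- "family" %in% names(training) &&
    length(unique(training$family)) > 1
  if (use_family) {
    fit <- lme4::lmer(
      y ~ la + NI + rel_area + la:NI + NI:rel_area + (1 | family),
      data = training)
    fe <- lme4::fixef(fit)
    re <- lme4::ranef(fit)$family
    fam_eff <- setNames(re[[1]], rownames(re))
  } else {
    fit <- lm(y ~ la + NI + rel_area + la:NI + NI:rel_area, data = training)
    fe <- coef(fit)
    fam_eff <- NULL
  }
  m <- allocation_model(
    intercept = unname(fe["(Intercept)"]),
    log_area = unname(fe["la"]),
    NI = unname(fe["NI"]),
    share = unname(fe["rel_area"]),
    log_area_NI = unname(fe["la:NI"]),
    NI_share = unname(fe["NI:rel_area"]),
    family_effects = fam_eff)
  attr(m, "fit") <- fit
  m
}

#' Partition range-wide K among islands with a floor constraint
#'
#' Splits `K_total` by the allocation proportions, then enforces that each
#' island's `K_i` is at least twice its current abundance. Floored islands
#' keep their floor while the remaining islands are rescaled to preserve
#' `K_total` (iterated until stable, since rescaling can push new islands
#' below their floor). If the floors alone exceed `K_total`, every island
#' is set to its floor, the total is raised accordingly, and a warning is
#' issued.
#'
#' @param K_total Range-wide carrying capacity (females).
#' @param proportions Allocation proportions (summing to 1).
#' @param current_abundances Current female abundance per island.
#' @return Numeric vector of per-island `K_i`.
#' @export
partition_K <- function(K_total, proportions, current_abundances) {
  check_positive(K_total, "K_total")
  if (length(proportions) != length(current_abundances)) {
    stop_invalid("proportions and current_abundances must match in length")
  }
  proportions <- proportions / sum(proportions)
  floors <- 2 * current_abundances
  if (sum(floors) >= K_total) {
    warning("floors (2x current abundance) exceed K_total; raising total K")
    return(floors)
  }
  K <- K_total * proportions
  fixed <- rep(FALSE, length(K))
  repeat {
    below <- !fixed & K < floors
    if (!any(below)) break
    fixed <- fixed | below
    K[fixed] <- floors[fixed]
    rem <- K_total - sum(K[fixed])
    free <- !fixed
    K[free] <- rem * proportions[free] / sum(proportions[free])
  }
  K
}
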