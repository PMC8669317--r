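test_that("trend pseudo-observations reproduce the weight table", {
  tab <- trend_weight_table()
  for (st in c("Increasing", "Stable", "Decreasing", "Unknown")) {
    expect_equal(sum(tab[[st]]), 100)
    tl <- build_trend_pseudo_observations(st)
    expect_length(tl$pseudo_obs, 100)
    expect_true(all(tl$pseudo_obs >= 0.9 & tl$pseudo_obs <= 1.1))
  }
  inc <- build_trend_pseudo_observations("Increasing")
  expect_equal(sum(inc$pseudo_obs == 1.02), 13)
  mode_of <- function(x) as.numeric(names(which.max(table(x))))
  expect_equal(mode_of(inc$pseudo_obs), 1.02)
  stab <- build_trend_pseudo_observations("Stable")
  expect_equal(mode_of(stab$pseudo_obs), 1.00)
  expect_equal(sum(stab$pseudo_obs == 1.00), 14)
  dec <- build_trend_pseudo_observations("Decreasing")
  expect_equal(mode_of(dec$pseudo_obs), 0.98)
  expect_error(build_trend_pseudo_observations("Booming"), "valid")
})

test_that("count series validate their inputs", {
  expect_error(count_series("a", c(2000, 2000), c(1, 2)), "increasing")
  expect_error(count_series("a", 2000:2001, c(-1, 2)), ">= 0")
  s <- count_series("a", 2000:2004, c(10, 12, 9, 11, 10))
  expect_s3_class(s, "count_series")
})

test_that("Poisson observation noise has unit variance-to-mean ratio", {
  set.seed(31)
  N <- 400
  O <- rpois(2e4, N)
  expect_equal(var(O) / mean(O), 1, tolerance = 0.05)
})

test_that("state-space fit is seed-reproducible and finds the hazard sign", {
  w <- make_removal_experiment(seed = 5, n_islands = 4, n_years = 18,
                               removal_year = 10)
  cfgm <- mcmc_config(n_chains = 2, n_burn = 300, n_save = 300)
  f1 <- suppressWarnings(fit_state_space(w$series, w$species_meta,
                                         w$priors, cfgm, seed = 8))
  f2 <- suppressWarnings(fit_state_space(w$series, w$species_meta,
                                         w$priors, cfgm, seed = 8))
  expect_identical(f1$samples, f2$samples)
  # the invaded-island decline pushes the rat hazard ratio above 1
  expect_gt(median(f1$samples[, "delta_rat"]), 1)
  expect_true(all(f1$samples[, "delta_rat"] >= 1))
  expect_true(all(f1$samples[, "phi"] >= 0 & f1$samples[, "phi"] <= 1))
  expect_named(f1$diagnostics, c("rhat", "acceptance", "converged"),
               ignore.order = TRUE)
})

test_that("removal series imply faster growth after the removal year", {
  # generating-model property across many seeded worlds
  deltas <- vapply(1:30, function(s) {
    w <- make_removal_experiment(seed = s, n_islands = 3, n_years = 21,
                                 removal_year = 11)
    s3 <- w$series[[3]]  # invaded island with removal
    lg <- diff(log(pmax(s3$counts, 1)))
    mean(lg[11:20]) - mean(lg[1:10])
  }, numeric(1))
  expect_gt(mean(deltas > 0), 0.8)
  expect_gt(mean(deltas), 0)
})

test_that("trend updating pulls the growth-rate posterior as labelled", {
  priors <- default_recovery_priors()
  cfgm <- mcmc_config(n_chains = 2, n_burn = 400, n_save = 600)
  stab <- suppressWarnings(update_with_trends(
    priors, build_trend_pseudo_observations("Stable"), list(AFR = 4),
    cfgm, seed = 2))
  med_stable <- median(stab$samples[, "lambda_hat"])
  expect_gt(med_stable, 0.99)
  expect_lt(med_stable, 1.01)
  dec <- suppressWarnings(update_with_trends(
    priors, build_trend_pseudo_observations("Decreasing"), list(AFR = 4),
    cfgm, seed = 2))
  expect_lt(median(dec$samples[, "lambda_hat"]), med_stable)
  # hazards enter lambda_hat: with invasives present the same trend is
  # explained by higher baseline rates
  inc <- suppressWarnings(update_with_trends(
    priors, build_trend_pseudo_observations("Increasing"), list(AFR = 4),
    cfgm, seed = 2))
  expect_gt(median(inc$samples[, "lambda_hat"]), med_stable)
})

test_that("a near-flat trend label leaves the prior nearly unchanged", {
  priors <- default_recovery_priors()
  cfgm <- mcmc_config(n_chains = 2, n_burn = 400, n_save = 600)
  unk <- suppressWarnings(update_with_trends(
    priors, build_trend_pseudo_observations("Unknown"), list(AFR = 4),
    cfgm, seed = 6))
  # prior-implied lambda distribution, via direct prior sampling
  set.seed(61)
  lam_prior <- vapply(1:400, function(i) {
    v <- vital_rates(sample_prior(priors$s0, 1), sample_prior(priors$s1, 1),
                     sample_prior(priors$s2, 1), sample_prior(priors$s3, 1),
                     sample_prior(priors$b, 1),
                     max(sample_prior(priors$e, 1), 0.5),
                     sample_prior(priors$h, 1), sample_prior(priors$f, 1),
                     4)
    build_matrix(v)$lambda
  }, numeric(1))
  med_shift <- abs(median(unk$samples[, "lambda_hat"]) - median(lam_prior))
  # the Unknown label is weakly informative: it can shrink the spread but
  # should barely move the centre
  expect_lt(med_shift, 0.05)
})
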