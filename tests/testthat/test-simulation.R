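test_that("spatial correlation passes exactly through both anchors", {
  d <- matrix(c(0, 100, 1000, 100, 0, 900, 1000, 900, 0), 3)
  R <- spatial_correlation(d)
  expect_equal(R[1, 2], 0.9, tolerance = 1e-12)
  expect_equal(R[1, 3], 0.5, tolerance = 1e-12)
  expect_equal(diag(R), rep(1, 3))
  # monotone decay to zero
  dd <- seq(0, 20000, by = 500)
  rr <- spatial_correlation(as.matrix(dist(c(0, dd))))[1, -1]
  expect_true(all(diff(rr) < 0))
  expect_lt(rr[length(rr)], 0.01)
})

test_that("environmental deviates honour sigma, lag-1 r and reproducibility", {
  cfg <- stochasticity_config()
  z0 <- generate_env_deviates(50, 2, det_config(), seed = 1)
  expect_true(all(z0 == 0))
  d1 <- generate_env_deviates(200, 3, cfg,
                              distances = test_geometry()$distances,
                              seed = 4)
  d2 <- generate_env_deviates(200, 3, cfg,
                              distances = test_geometry()$distances,
                              seed = 4)
  expect_identical(d1, d2)
  # per-rate scaling: fledgling survival slice has twice the SD of others
  expect_equal(d1[, , "s0"], 2 * d1[, , "s2"], tolerance = 1e-12)
  # long-run mean of deviates is zero (zero-centred noise)
  big <- generate_env_deviates(2e4, 1, cfg, seed = 9)
  z <- attr(big, "z")
  expect_lt(abs(mean(z)), 3 / sqrt(2e4 * (1 - 0.67^2)))
})

test_that("demographic survival draws have the beta moments", {
  set.seed(12)
  x <- vapply(1:2e4, function(i) demographic_survival_draw(0.5, 50),
              numeric(1))
  expect_equal(mean(x), 0.5, tolerance = 0.005)
  expect_equal(sd(x), sqrt(0.25 / 50), tolerance = 0.02)
  # variance shrinks to zero with n
  xx <- vapply(1:2000, function(i) demographic_survival_draw(0.7, 5000),
               numeric(1))
  expect_lt(sd(xx), 0.01)
  # n = 1 falls back to a Bernoulli draw
  y <- vapply(1:500, function(i) demographic_survival_draw(0.3, 1),
              numeric(1))
  expect_true(all(y %in% c(0, 1)))
  expect_equal(mean(y), 0.3, tolerance = 0.07)
})

test_that("deterministic single-colony runs grow at lambda", {
  v <- test_vitals()
  pm <- build_matrix(v)
  ssd <- stable_stage_distribution(pm)
  conf <- species_config(islands = list(list(id = "a", area = 2, K = 1e12)),
                         AFR = 4)
  r <- run_inner(v, conf, matrix(ssd * 1000, 3), years = 100,
                 cfg = det_config(), qe = 0, seed = 1)
  growth <- r$totals[-1] / r$totals[-101]
  expect_equal(growth, rep(pm$lambda, 100), tolerance = 1e-6)
  # and matches the explicit matrix power A^10 n0
  n10 <- ssd * 1000
  for (i in 1:10) n10 <- pm$A %*% n10
  expect_equal(r$totals[11], sum(n10), tolerance = 1e-6)
})

test_that("survival-only bookkeeping holds without reproduction", {
  # all survival 1, no breeding: adults accumulate in the non-breeding
  # stage, sub-adults transition out, nothing is lost
  v <- vital_rates(1, 1, 1, 1, 0, 2, 0, 0.7, AFR = 2)
  conf <- species_config(islands = list(list(id = "a", area = 2, K = 1e12)),
                         AFR = 2)
  r <- run_inner(v, conf, matrix(c(100, 200, 50), 3), years = 10,
                 cfg = det_config(), qe = 0)
  expect_equal(r$totals, rep(350, 11))
  expect_equal(r$trajectory[11, 1, 1], 0)
})

test_that("dispersal conserves individuals inside the simulator", {
  v <- vital_rates(1, 1, 1, 1, 0, 2, 0, 0.7, AFR = 2)
  conf <- species_config(
    islands = list(list(id = "a", area = 2, K = 1e12),
                   list(id = "b", area = 1, K = 1e12),
                   list(id = "c", area = 5, K = 1e12)),
    AFR = 2, geometry = test_geometry(),
    dispersal = dispersal_spec(0.4, 0.2, 0.3, 150))
  r <- run_inner(v, conf, matrix(rep(c(100, 200, 50), 3), 3),
                 years = 15, cfg = det_config(), qe = 0)
  expect_equal(r$totals, rep(1050, 16), tolerance = 1e-10)
})

test_that("initialization paths follow the stage distribution rules", {
  ssd <- c(0.3, 0.5, 0.2)
  expect_equal(initialize_population(ssd, totals = 200),
               matrix(c(30, 50, 20), 3))
  expect_equal(initialize_population(ssd, pairs = 50),
               matrix(c(30, 50, 20), 3))
  out <- initialize_population(ssd, species_total = 400,
                               proportions = c(0.75, 0.25))
  expect_equal(out, matrix(c(45, 75, 30, 15, 25, 10), 3))
  expect_equal(initialize_population(ssd, totals = c(200, 0))[, 2],
               rep(0, 3))
  expect_error(initialize_population(ssd), "abundance")
})

test_that("QE threshold and QEP counting are exact", {
  expect_equal(choose_qe(250), 50)
  expect_equal(choose_qe(200), 10)
  expect_equal(choose_qe(150), 10)
  traj <- rbind(c(100, 90, 80), c(100, 40, 90), c(100, 99, 98),
                c(30, 50, 70), c(100, 100, 100), c(100, 60, 55),
                c(100, 80, 70), c(100, 70, 60), c(49, 60, 70),
                c(100, 90, 85))
  expect_equal(compute_qep(traj, 50), 0.3)
  expect_equal(compute_qep(matrix(100, 4, 5), 50), 0)
  expect_equal(compute_qep(matrix(5, 4, 5), 50), 1)
})

test_that("quasi-extinction is absorbing", {
  v <- vital_rates(0.2, 0.3, 0.4, 0.4, 0.5, 1, 0.5, 0.4, 3)  # crashing
  conf <- species_config(islands = list(list(id = "a", area = 2, K = 1e9)),
                         AFR = 3)
  r <- run_inner(v, conf, matrix(c(50, 80, 20), 3), years = 40,
                 cfg = det_config(), qe = 50, seed = 2)
  hit <- which(r$totals == 0)[1]
  expect_false(is.na(hit))
  expect_true(all(r$totals[hit:41] == 0))
})

test_that("run_full is reproducible and summarises both metrics", {
  v <- test_vitals()
  samp <- cbind(s0 = rep(v$s0, 30), s1 = v$s1, s2 = v$s2, s3 = v$s3,
                b = v$b, e = v$e, h = v$h, f = v$f)
  conf <- species_config(islands = list(list(id = "a", area = 2, K = 4000)),
                         AFR = 4)
  init <- initialize_population(stable_stage_distribution(build_matrix(v)),
                                totals = 1200)
  r1 <- run_full(samp, conf, init, NS1 = 4, NS2 = 6, years = 40, seed = 21)
  r2 <- run_full(samp, conf, init, NS1 = 4, NS2 = 6, years = 40, seed = 21)
  expect_identical(r1$summary, r2$summary)
  expect_true(all(r1$QEP >= 0 & r1$QEP <= 1))
  expect_equal(rownames(r1$summary), c("N_proj", "QEP"))
  expect_length(r1$N_proj, 4)
})

test_that("scenario machinery modifies hazards and founders as declared", {
  v <- test_vitals()
  conf <- species_config(
    islands = list(
      list(id = "a", area = 2, K = 5000,
           assemblage = invasive_assemblage("rat", area = 2)),
      list(id = "b", area = 3, K = 5000)),
    AFR = 4, geometry = colony_geometry(
      distances = matrix(c(0, 150, 150, 0), 2)),
    dispersal = dispersal_spec(),
    hazards = hazard_parameters(delta_x = c(rat = 1.6), phi = 0.5,
                                psi = 0, beta1 = 0.8, beta2 = 1))
  init <- matrix(rep(stable_stage_distribution(build_matrix(v)) * 400, 2), 3)
  base <- run_inner(v, conf, init, scenario_default(), years = 50,
                    cfg = det_config(), qe = 0)
  rem <- run_inner(v, conf, init, scenario_invasive_removal(1, year = 1),
                   years = 50, cfg = det_config(), qe = 0)
  expect_true(all(rem$totals >= base$totals))
  mit <- run_inner(v, conf, init, scenario_at_sea_mitigation(0.1),
                   years = 50, cfg = det_config(), qe = 0)
  expect_true(all(mit$totals[-1] > base$totals[-1]))
  # reintroduction adds founders at the target island in the stated year
  conf2 <- species_config(islands = list(list(id = "a", area = 2, K = 5000),
                                         list(id = "b", area = 3,
                                              K = 5000)),
                          AFR = 4)
  init2 <- cbind(stable_stage_distribution(build_matrix(v)) * 400,
                 c(0, 0, 0))
  re <- run_inner(v, conf2, init2,
                  scenario_reintroduction(2, c(10, 20, 5), K = 2000,
                                          year = 3),
                  years = 10, cfg = det_config(), qe = 0)
  expect_equal(sum(re$trajectory[3, , 2]), 0)
  expect_gt(sum(re$trajectory[4, , 2]), 0)
  # translocation removes its founders from the source colonies, so the
  # metapopulation ends up smaller than under de-novo reintroduction
  tr <- run_inner(v, conf2, init2,
                  scenario_translocation(2, c(10, 20, 5), K = 2000,
                                         year = 3),
                  years = 10, cfg = det_config(), qe = 0)
  expect_equal(tr$totals[3], re$totals[3], tolerance = 1e-9)
  expect_lt(tr$totals[4], re$totals[4])
})
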