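test_that("chick log hazard follows the compensatory scaling", {
  p <- hazard_parameters(delta_x = c(rat = 1.1), phi = 0.3, psi = 0.2)
  empty <- invasive_assemblage(character(), area = 1)
  expect_equal(chick_log_hazard(empty, p), 0)
  one <- invasive_assemblage("rat", area = 1)
  expect_equal(chick_log_hazard(one, p), log(1.1), tolerance = 1e-7)
  expect_equal(chick_log_hazard(one, p), 0.09531, tolerance = 1e-5)
  # two identical invasives are fully compensatory at phi = 1
  two <- invasive_assemblage(c("rat", "rat"), area = 1)
  p1 <- hazard_parameters(delta_x = c(rat = 1.2), phi = 1, psi = 0)
  expect_equal(chick_log_hazard(two, p1), log(1.2), tolerance = 1e-7)
  # and exactly additive at phi = 0
  p0 <- hazard_parameters(delta_x = c(rat = 1.2), phi = 0, psi = 0)
  expect_equal(chick_log_hazard(two, p0), 2 * log(1.2), tolerance = 1e-12)
})

test_that("island size discounts hazards when psi > 0", {
  p <- hazard_parameters(delta_x = c(rat = 1.3), phi = 0.5, psi = 0.4)
  areas <- c(0.5, 1, 5, 20, 100)
  gf <- vapply(areas, function(a) {
    chick_log_hazard(invasive_assemblage("rat", area = a), p)
  }, numeric(1))
  expect_true(all(diff(gf) < 0))
  # tiny islands are floored at 0.01 km2
  g_tiny <- chick_log_hazard(invasive_assemblage("rat", area = 1e-6), p)
  g_floor <- chick_log_hazard(invasive_assemblage("rat", area = 0.01), p)
  expect_equal(g_tiny, g_floor)
})

test_that("adult hazards scale with body size and the zeta switch", {
  expect_equal(adult_log_hazard_single(1.3, 0, 1, 0.5, 1), 0)
  expect_equal(adult_log_hazard_single(1.2, 1, 1, 0.5, 1), 0.04558,
               tolerance = 1e-5)
  # large-bodied limit: denominator tends to 1
  expect_equal(adult_log_hazard_single(1.2, 1, 1e9, 0.5, 1),
               0.5 * log(1.2), tolerance = 1e-6)
  # herbivores pose no adult risk by default
  a <- invasive_assemblage(c("herbivore", "bird"), area = 1)
  p <- hazard_parameters(delta_x = c(herbivore = 1.2, bird = 1.1))
  expect_equal(adult_cumulative_hazard(a, p), 0)
  # single carnivore equals the single-member formula
  a1 <- invasive_assemblage("carnivore", area = 1)
  p1 <- hazard_parameters(delta_x = c(carnivore = 1.25), phi = 0.7,
                          psi = 0.3, beta1 = 0.6, beta2 = 0.8,
                          adult_size = 2)
  expect_equal(adult_cumulative_hazard(a1, p1),
               adult_log_hazard_single(1.25, 1, 2, 0.6, 0.8))
})

test_that("mixed assemblages match a brute-force sum-then-scale", {
  a <- invasive_assemblage(c("rat", "carnivore", "herbivore"), area = 3.7)
  p <- hazard_parameters(delta_x = c(rat = 1.3, carnivore = 1.25,
                                     herbivore = 1.1),
                         phi = 0.4, psi = 0.15, beta1 = 0.55, beta2 = 1.2,
                         adult_size = 1.4)
  dx <- c(1.3, 1.25, 1.1)
  zeta <- c(1, 1, 0)
  scale <- (1 / 3)^0.4 * (1 / 3.7)^0.15
  expect_equal(chick_log_hazard(a, p), sum(log(dx)) * scale,
               tolerance = 1e-12)
  omega <- zeta * 0.55 * log(dx) / (1 / 1.4 + 1)^1.2
  expect_equal(adult_cumulative_hazard(a, p), sum(omega) * scale,
               tolerance = 1e-12)
})

test_that("hazards transform survival as a power of the hazard ratio", {
  out <- apply_hazards(0.7, 0.92, 0, 0)
  expect_equal(out$f, 0.7)
  expect_equal(out$s2, 0.92)
  expect_equal(apply_hazards(0.7, 0.9, log(1.1), 0)$f, 0.7^1.1)
  expect_equal(apply_hazards(0.7, 0.9, log(1.1), 0)$f, 0.6755,
               tolerance = 1e-4)
  expect_equal(apply_hazards(0.7, 0.9, 50, 0)$f, 0, tolerance = 1e-10)
  expect_equal(apply_hazards(0, 0.9, 1, 1)$f, 0)
  # cumulative hazard scales by exp(gamma): -log f' = exp(g) * (-log f)
  g <- 0.37
  fp <- apply_hazards(0.65, 0.9, g, 0)$f
  expect_equal(-log(fp), exp(g) * (-log(0.65)), tolerance = 1e-12)
  # ordering: larger gamma never yields larger survival
  gs <- seq(0, 2, by = 0.25)
  fs <- vapply(gs, function(g) apply_hazards(0.7, 0.9, g, g)$s2, numeric(1))
  expect_true(all(diff(fs) <= 0))
})

test_that("hierarchical hazard draws stay above one and reproduce", {
  d <- draw_delta_x(500, 1.25, 0.2, seed = 9)
  expect_true(all(d >= 1))
  expect_equal(d, draw_delta_x(500, 1.25, 0.2, seed = 9))
  dl <- draw_delta_x(500, 1.25, 0.2, log_scale = TRUE, seed = 9)
  expect_true(all(dl >= 1))
})
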