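test_that("AoO scaling multiplies by the nesting proportion", {
  expect_equal(scale_aoo(40, proportion = 1), 40)
  expect_equal(scale_aoo(40, proportion = 0.25), 10)
  expect_error(scale_aoo(-1, proportion = 0.5), "AoO")
  # model-based path recovers a known proportion from synthetic data
  set.seed(5)
  n <- 120
  train <- data.frame(body_size = exp(rnorm(n, 0, 0.5)))
  train$proportion <- plogis(qlogis(0.3) + rnorm(n, 0, 0.2))
  m <- fit_aoo_model(train)
  got <- scale_aoo(100, model = m, body_size = 1)
  expect_gt(got, 100 * 0.2)
  expect_lt(got, 100 * 0.42)
})

test_that("species K is nesting area times nest density", {
  expect_equal(species_K(10, 100), 1000)
  expect_warning(k0 <- species_K(0, 50), "degenerate")
  expect_equal(k0, 0)
  # K under a sampled eta has mean AoO* x E[eta]
  eta_prior <- fit_prior(exp(rnorm(400, log(150), 0.3)), "eta")
  draws <- sample_prior(eta_prior, 2e4, seed = 3)
  Ks <- 12 * draws
  expect_equal(mean(Ks), 12 * prior_mean(eta_prior),
               tolerance = 3 * sd(Ks) / sqrt(2e4) / mean(Ks))
})

test_that("allocation is symmetric, normalized and area-monotone", {
  m <- allocation_model(log_area = 1)
  expect_equal(allocate(rep(4, 5), m), rep(0.2, 5))
  areas <- c(0.5, 2, 10, 40)
  p <- allocate(areas, m)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(diff(p) > 0))
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  expect_equal(allocate(areas[perm], m), p[perm])
  expect_error(allocate(c(1, 0), m), "positive")
})

test_that("allocation model fitting recovers generating coefficients", {
  set.seed(17)
  true <- allocation_model(intercept = -2, log_area = 0.8, NI = 0.05,
                           share = 1.2, log_area_NI = 0, NI_share = 0)
  rows <- list()
  for (sp in 1:40) {
    ni <- sample(3:8, 1)
    areas <- exp(rnorm(ni, log(3), 0.8))
    shr <- areas / sum(areas)
    lp <- -2 + 0.8 * log(areas) + 0.05 * ni + 1.2 * shr
    obs <- plogis(lp + rnorm(ni, 0, 0.15))
    rows[[sp]] <- data.frame(species = sp, share = obs, area = areas,
                             NI = ni, rel_area = shr)
  }
  train <- do.call(rbind, rows)
  fit <- fit_allocation_model(train)
  sm <- summary(attr(fit, "fit"))$coefficients
  expect_lt(abs(fit$coefficients[["log_area"]] - 0.8),
            2 * sm["la", "Std. Error"] + 0.02)
  expect_lt(abs(fit$coefficients[["share"]] - 1.2),
            2 * sm["rel_area", "Std. Error"] + 0.05)
  # predicted allocation ordering matches the truth on a fresh island set
  areas <- c(1, 5, 20)
  expect_equal(order(allocate(areas, fit)), order(allocate(areas, true)))
})

test_that("partition_K enforces the 2x floor by water-filling", {
  # no floors binding: exact proportional split
  K <- partition_K(1000, c(0.5, 0.3, 0.2), c(10, 10, 10))
  expect_equal(K, c(500, 300, 200))
  # one island floored, total preserved, others scaled down
  K2 <- partition_K(1000, c(0.5, 0.3, 0.2), c(10, 10, 140))
  expect_equal(K2[3], 280)
  expect_equal(sum(K2), 1000)
  expect_equal(K2[1] / K2[2], 0.5 / 0.3, tolerance = 1e-12)
  expect_true(all(K2 >= 2 * c(10, 10, 140)))
  # independent water-filling oracle on random instances
  oracle <- function(K_total, p, cur) {
    flo <- 2 * cur
    n <- length(p)
    fixed <- rep(FALSE, n)
    repeat {
      Ki <- numeric(n)
      Ki[fixed] <- flo[fixed]
      Ki[!fixed] <- (K_total - sum(flo[fixed])) * p[!fixed] / sum(p[!fixed])
      newly <- !fixed & (Ki < flo - 1e-12)
      if (!any(newly)) return(Ki)
      fixed <- fixed | newly
    }
  }
  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    p <- runif(n); p <- p / sum(p)
    cur <- runif(n, 0, 50)
    Kt <- runif(1, 10 + sum(2 * cur), 500 + sum(2 * cur))
    got <- partition_K(Kt, p, cur)
    expect_equal(got, oracle(Kt, p, cur), tolerance = 1e-9)
    expect_true(all(got >= 2 * cur - 1e-9))
    expect_equal(sum(got), Kt, tolerance = 1e-9)
  }
  # infeasible: floors returned with a warning
  expect_warning(K3 <- partition_K(100, c(0.5, 0.5), c(40, 40)), "floors")
  expect_equal(K3, c(80, 80))
})
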