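test_that("connectivity normalizes exponential kernels by column", {
  g2 <- colony_geometry(distances = matrix(c(0, 250, 250, 0), 2))
  IP2 <- build_connectivity(g2, delta = 100)
  expect_equal(IP2[2, 1], 1)
  expect_equal(IP2[1, 2], 1)
  expect_equal(diag(IP2), c(island_1 = -1, island_2 = -1))
  # equidistant triangle: all destinations equally likely
  g3 <- colony_geometry(distances = matrix(c(0, 50, 50, 50, 0, 50,
                                             50, 50, 0), 3))
  IP3 <- build_connectivity(g3, delta = 120)
  expect_equal(unname(IP3[IP3 > 0]), rep(0.5, 6))
  # two destinations at 100 and 200 km with delta = 100
  gg <- colony_geometry(distances = matrix(c(0, 100, 200, 100, 0, 50,
                                             200, 50, 0), 3))
  IP <- build_connectivity(gg, delta = 100)
  expect_equal(IP[2, 1], exp(-1) / (exp(-1) + exp(-2)), tolerance = 1e-6)
  expect_equal(IP[2, 1], 0.7311, tolerance = 1e-3)
  expect_equal(IP[3, 1], 0.2689, tolerance = 1e-3)
  expect_error(build_connectivity(
    colony_geometry(distances = matrix(0, 1, 1)), 100), "single colony")
})

test_that("connectivity columns sum to one off-diagonal, any geometry", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    pts <- cbind(runif(k, -5, 5), runif(k, -5, 5))
    d <- as.matrix(dist(pts)) * 100
    IP <- build_connectivity(colony_geometry(distances = d),
                             delta = runif(1, 50, 500))
    offsum <- colSums(IP) - diag(IP)
    expect_equal(unname(offsum), rep(1, k), tolerance = 1e-12)
  }
})

test_that("longer dispersal scale shifts probability to distant colonies", {
  gg <- colony_geometry(distances = matrix(c(0, 100, 400, 100, 0, 50,
                                             400, 50, 0), 3))
  p_far <- vapply(c(50, 100, 200, 400), function(delta) {
    build_connectivity(gg, delta)[3, 1]
  }, numeric(1))
  expect_true(all(diff(p_far) > 0))
})

test_that("meta-matrix assembly conserves individuals under dispersal", {
  v <- test_vitals()
  mats <- list(build_matrix(v), build_matrix(v),
               build_matrix(vital_rates(0.5, 0.7, 0.9, 0.85, 0.8, 1, 0.8,
                                        0.6, 5)))
  g <- test_geometry()
  d <- dispersal_spec(d1 = 0.3, d2 = 0.05, d3 = 0.15, delta = 150)
  M <- assemble_metapopulation(mats, d, geom = g)
  C <- assemble_metapopulation(mats)
  expect_equal(colSums(M), colSums(C), tolerance = 1e-10)
  expect_true(all(M >= 0))
  # no dispersal leaves C untouched
  d0 <- dispersal_spec(0, 0, 0, 100)
  expect_equal(assemble_metapopulation(mats, d0, geom = g), C)
  # full emigration empties the diagonal blocks
  d1 <- dispersal_spec(1, 1, 1, 100)
  g2 <- colony_geometry(distances = matrix(c(0, 100, 100, 0), 2))
  M2 <- assemble_metapopulation(mats[1:2], d1, geom = g2)
  expect_equal(unname(M2[1:3, 1:3]), matrix(0, 3, 3))
  expect_equal(unname(M2[4:6, 1:3]), unname(mats[[1]]$A))
})

test_that("block structure places p_ij * D * A_i off-diagonal", {
  v <- test_vitals()
  mats <- list(build_matrix(v), build_matrix(v), build_matrix(v))
  g <- test_geometry()
  d <- dispersal_spec(d1 = 0.2, d2 = 0.1, d3 = 0.05, delta = 150)
  IP <- build_connectivity(g, 150)
  M <- assemble_metapopulation(mats, d, IP = IP)
  D <- diag(c(0.2, 0.1, 0.05))
  # off-diagonal block (2,1) and diagonal block (1,1)
  expect_equal(M[4:6, 1:3], IP[2, 1] * D %*% mats[[1]]$A,
               ignore_attr = TRUE)
  expect_equal(M[1:3, 1:3], (diag(3) - D) %*% mats[[1]]$A,
               ignore_attr = TRUE)
})

test_that("single-colony path and projection behave", {
  v <- test_vitals()
  pm <- build_matrix(v)
  M1 <- assemble_metapopulation(list(pm), dispersal_spec())
  expect_equal(M1, pm$A, ignore_attr = TRUE)
  expect_equal(project_metapopulation(diag(6), rep(2, 6)), rep(2, 6))
  expect_equal(project_metapopulation(M1, rep(0, 3)), rep(0, 3))
  ssd <- stable_stage_distribution(pm)
  out <- project_metapopulation(M1, ssd * 500)
  lam <- max(Re(eigen(pm$A, only.values = TRUE)$values))
  expect_equal(sum(out), lam * 500, tolerance = 1e-8)
  expect_error(project_metapopulation(M1, c(-1, 0, 0)), ">= 0")
})
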