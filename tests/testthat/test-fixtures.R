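test_that("synthetic worlds are seed-deterministic, in memory and on disk", {
  w1 <- make_world(seed = 21)
  w2 <- make_world(seed = 21)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$records, w2$records)
  expect_identical(lapply(w1$series, `[[`, "counts"),
                   lapply(w2$series, `[[`, "counts"))
  d1 <- file.path(tempdir(), "world_a")
  d2 <- file.path(tempdir(), "world_b")
  make_world(seed = 21, dir = d1)
  make_world(seed = 21, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("every written table round-trips through its reader", {
  d <- file.path(tempdir(), "world_rt")
  w <- make_world(seed = 8, dir = d)
  colonies <- read_colonies(file.path(d, "colonies.csv"))
  expect_equal(colonies$island_id, w$colonies$island_id)
  expect_equal(attr(colonies, "geometry")$distances,
               w$geometry$distances, tolerance = 1e-9)
  vit <- read_vital_rates(file.path(d, "vital_rates.csv"))$focal
  expect_equal(unclass(vit), unclass(w$vitals))
  recs <- read_literature_records(file.path(d, "literature_records.csv"))
  expect_equal(nrow(recs), nrow(w$records))
  expect_equal(recs$value, w$records$value)
  inv <- read_invasives(file.path(d, "invasives.csv"), colonies)
  expect_equal(sort(names(inv)), sort(names(w$assemblages)))
  for (id in names(inv)) {
    expect_equal(inv[[id]]$members$category,
                 w$assemblages[[id]]$members$category)
    expect_equal(inv[[id]]$area, w$assemblages[[id]]$area, tolerance = 1e-3)
  }
  series <- read_count_series(file.path(d, "counts.csv"), colonies)
  for (id in names(w$series)) {
    expect_equal(series[[id]]$counts, w$series[[id]]$counts)
    expect_equal(series[[id]]$years, w$series[[id]]$years)
    expect_equal(series[[id]]$removal_year, w$series[[id]]$removal_year)
    same_inv <- is.null(series[[id]]$assemblage) ==
      is.null(w$series[[id]]$assemblage)
    expect_true(same_inv)
  }
  unlink(d, recursive = TRUE)
})

test_that("invaded islands decline relative to predator-free islands", {
  # sign check on realized growth over many generated worlds
  diffs <- vapply(1:40, function(s) {
    w <- make_world(seed = 100 + s, n_islands = 4, n_years = 20,
                    removal_frac = 2)  # no removal inside the window
    gr <- vapply(w$series, function(srs) {
      mean(diff(log(pmax(srs$counts, 1))))
    }, numeric(1))
    clean <- is.na(match(names(w$series), names(w$assemblages)))
    mean(gr[!clean]) - mean(gr[clean])
  }, numeric(1))
  expect_gt(mean(diffs < 0), 0.85)
  expect_lt(mean(diffs), 0)
})

test_that("removal experiments show the removal-year growth break", {
  w <- make_removal_experiment(seed = 3)
  inv <- Filter(function(s) !is.null(s$assemblage), w$series)
  expect_gte(length(inv), 3)
  # controls have no systematic growth change at the removal year
  ctl <- Filter(function(s) is.null(s$assemblage), w$series)
  shifts <- vapply(1:50, function(s) {
    ww <- make_removal_experiment(seed = 300 + s, n_islands = 3,
                                  n_years = 20, removal_year = 11)
    ctl1 <- ww$series[[1]]
    lg <- diff(log(pmax(ctl1$counts, 1)))
    mean(lg[11:19]) - mean(lg[1:10])
  }, numeric(1))
  expect_lt(abs(mean(shifts)), 0.02)
  # a minimal world runs end-to-end through the simulator
  v <- w$truth$vitals
  conf <- species_config(islands = list(list(id = "a", area = 2, K = 5000),
                                        list(id = "b", area = 1, K = 5000)),
                         AFR = v$AFR,
                         geometry = colony_geometry(
                           distances = matrix(c(0, 200, 200, 0), 2)),
                         dispersal = dispersal_spec())
  init <- initialize_population(
    stable_stage_distribution(build_matrix(v)), totals = c(800, 400))
  r <- run_inner(v, conf, init, years = 30, seed = 5, qe = 10)
  expect_length(r$totals, 31)
  expect_true(all(is.finite(r$totals)))
})
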