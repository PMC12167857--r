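geo_grid <- function() grid_def(-10, 60, 0.1, 100, 100, crs_tag = "geographic")

test_that("cleaning removes duplicates, erroneous and out-of-grid records with counts", {
  g <- geo_grid()
  raw <- data.frame(x = c(-5, -5, -5.2, 200, -6),
                    y = c(55, 55, 54.8, 95, 20),   # dup; lat 95 + lon 200 bad; 20 out of grid
                    species = "beetle")
  occ <- clean_occurrences(raw, g)
  expect_equal(nrow(occ), 2)
  rem <- attr(occ, "removals")
  expect_equal(unname(rem["duplicate"]), 1)
  expect_equal(unname(rem["erroneous"]), 1)
  expect_equal(unname(rem["out_of_grid"]), 1)
  expect_equal(attr(occ, "species_tag"), "beetle")
  expect_error(clean_occurrences(data.frame(x = 500, y = 95), g), "empty-input")
})

test_that("rarefaction keeps the first record per occupied cell and is idempotent", {
  g <- grid_def(0, 10, 1, 10, 10)
  raw <- data.frame(x = c(0.2, 0.8, 0.5, 3.5, 3.2, 5.5, 7.1),
                    y = c(9.5, 9.2, 9.8, 5.5, 5.1, 2.5, 1.1))
  occ <- clean_occurrences(raw, g)
  r1 <- rarefy_to_grid(occ)
  expect_equal(nrow(r1), 4)                      # 7 records occupy 4 cells
  expect_equal(anyDuplicated(r1$cell), 0)
  expect_equal(r1$x[1], 0.2)                     # first in input order wins
  expect_identical(rarefy_to_grid(r1)$cell, r1$cell)
})

test_that("spatial thinning enforces the minimum distance and keeps maximal sets", {
  g <- grid_def(0, 100, 1, 100, 100)
  occ3 <- clean_occurrences(data.frame(x = c(0.5, 4.5, 8.5), y = rep(50.5, 3)), g)
  expect_identical(spatial_thin(occ3, 0), occ3)

  thin3 <- spatial_thin(occ3, 5, n_tries = 5, seed = 3)
  expect_equal(nrow(thin3), 2)                   # endpoints at 0 and 8 survive
  expect_setequal(thin3$x, c(0.5, 8.5))

  occ2 <- clean_occurrences(data.frame(x = c(10, 11), y = c(20, 20)), g)
  expect_equal(nrow(spatial_thin(occ2, 5, seed = 1)), 1)

  # property: random clouds always satisfy the pairwise distance floor
  for (s in 1:5) {
    pts <- withr::with_seed(s, data.frame(x = runif(40, 0, 30),
                                          y = runif(40, 0, 30)))
    th <- spatial_thin(clean_occurrences(pts, g), 4, n_tries = 5, seed = s)
    d <- as.matrix(dist(cbind(th$x, th$y)))
    diag(d) <- Inf
    expect_gte(min(d), 4)
  }
})

test_that("thinning is deterministic under a fixed seed", {
  g <- grid_def(0, 100, 1, 100, 100)
  pts <- withr::with_seed(9, data.frame(x = runif(50, 0, 20), y = runif(50, 0, 20)))
  occ <- clean_occurrences(pts, g)
  a <- spatial_thin(occ, 3, seed = 42)
  b <- spatial_thin(occ, 3, seed = 42)
  expect_identical(a$cell, b$cell)
})

test_that("the SRE envelope uses linear-interpolation quantiles per variable", {
  tbl <- tibble::tibble(v = 1:100, w = rep(7, 100))
  env0 <- build_sre_envelope(tbl, q = 0)
  expect_equal(env0$lower[env0$variable == "v"], 1)
  expect_equal(env0$upper[env0$variable == "v"], 100)

  env <- build_sre_envelope(tbl, q = 0.025)
  expect_equal(env$lower[env$variable == "v"], 3.475)
  expect_equal(env$upper[env$variable == "v"], 97.525)
  expect_equal(env$lower[env$variable == "w"], 7)    # constant -> degenerate
  expect_equal(env$upper[env$variable == "w"], 7)
  expect_error(build_sre_envelope(tbl, q = 0.6), "q must be")
})

test_that("pseudo-absence replicates are outside the envelope, disjoint from presences, and seeded", {
  st <- tiny_stack(20)
  occ <- clean_occurrences(data.frame(x = c(10.5, 9.5), y = c(10.5, 9.5)), st$grid)
  pres <- extract_at_cells(st, occ$cell, rep(1L, nrow(occ)))
  # narrow envelope around the two presences: most of the gradient layer is outside
  env <- build_sre_envelope(pres, q = 0)
  pa <- sample_pseudo_absences(st, occ, env, buffer_km = 100, n = 50,
                               n_reps = 4, seed = 11)
  expect_length(pa, 4)
  for (p in pa) {
    expect_equal(nrow(p), 50)
    expect_length(intersect(p$cell, occ$cell), 0)
    vals <- extract_at_cells(st, p$cell, rep(0L, nrow(p)))
    inside <- sdmflow:::envelope_inside(env, vals)
    expect_false(any(inside))
  }
  # replicates differ when eligible cells are plentiful
  expect_false(identical(sort(pa[[1]]$cell), sort(pa[[2]]$cell)))
  # determinism
  pa2 <- sample_pseudo_absences(st, occ, env, buffer_km = 100, n = 50,
                                n_reps = 4, seed = 11)
  expect_identical(pa[[3]]$cell, pa2[[3]]$cell)
})

test_that("an envelope covering the whole background yields a shortfall error", {
  st <- tiny_stack(10)
  occ <- clean_occurrences(data.frame(x = 5.5, y = 5.5), st$grid)
  all_rows <- extract_at_cells(st, 0:99, rep(1L, 100))
  env_all <- build_sre_envelope(all_rows, q = 0)    # covers every cell
  expect_error(
    sample_pseudo_absences(st, occ, env_all, buffer_km = 100, n = 5, seed = 1),
    "shortfall.*0")
})

test_that("eligible pseudo-absence cells match a hand enumeration", {
  # 5x5 grid, one presence at the centre, buffer covering everything;
  # the envelope [lower, upper] on the gradient layer excludes exactly the
  # cells whose value is outside it.
  g <- grid_def(0, 5, 1, 5, 5)
  vals <- matrix(1:25, 5, 5, byrow = TRUE)
  st <- env_stack(list(env_layer("grad", vals)), g)
  occ <- clean_occurrences(data.frame(x = 2.5, y = 2.5), g)
  env <- tibble::tibble(variable = "grad", lower = 5, upper = 20)
  class(env) <- c("sre_envelope", class(env))
  tbl <- extract_at_cells(st, 0:24, rep(0L, 25))
  expected <- setdiff(tbl$cell[tbl$grad < 5 | tbl$grad > 20], occ$cell)
  pa <- sample_pseudo_absences(st, occ, env, buffer_km = 100,
                               n = length(expected), n_reps = 2, seed = 2)
  for (p in pa) expect_setequal(p$cell, expected)
})

test_that("calibration splits have exact 70:30 sizes, are stratified and seeded", {
  tbl <- noise_table(100)
  splits <- make_cv_splits(tbl, 0.7, n_runs = 3, seed = 5)
  for (s in splits) {
    expect_length(s$train, 70)
    expect_length(s$test, 30)
    expect_setequal(c(s$train, s$test), 1:100)
    expect_length(intersect(s$train, s$test), 0)
    expect_true(any(tbl$label[s$test] == 1) && any(tbl$label[s$test] == 0))
  }
  expect_false(identical(splits[[1]]$train, splits[[2]]$train))
  again <- make_cv_splits(tbl, 0.7, n_runs = 3, seed = 5)
  expect_identical(splits[[2]]$train, again[[2]]$train)

  small <- make_cv_splits(noise_table(10), 0.7, n_runs = 1, seed = 1)
  expect_length(small[[1]]$train, 7)
})
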