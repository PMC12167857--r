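# Build a small pool of cheap fitted GLMs with assigned TSS scores.
glm_pool <- function(n_models, n_rows = 40, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_models), function(i) {
      tbl <- tibble::tibble(label = rep(c(0L, 1L), length.out = n_rows),
                            v1 = rnorm(n_rows), v2 = rnorm(n_rows))
      fit_single_model("GLM", tbl, seed = i)
    })
  })
}

fake_scoreboard <- function(tss, models = NULL) {
  tibble::tibble(tss = tss,
                 model = models %||% glm_pool(length(tss)),
                 auc = NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("member selection applies the TSS floor and keeps scores as weights", {
  sb <- fake_scoreboard(c(0.8, 0.7, 0.69))
  ens <- select_ensemble_members(sb, tss_min = 0.7)
  expect_length(ens$members, 2)
  expect_equal(ens$tss, c(0.8, 0.7))
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  expect_equal(ens$weights, c(0.8, 0.7) / 1.5)

  expect_error(select_ensemble_members(fake_scoreboard(c(0.5, 0.6)), 0.7),
               "no-members")
  all_in <- select_ensemble_members(fake_scoreboard(c(0.2, 0.4)), 0)
  expect_length(all_in$members, 2)
})

test_that("ensemble prediction is the TSS-weighted mean of member predictions", {
  pool <- glm_pool(2, seed = 3)
  tbl <- withr::with_seed(5, tibble::tibble(v1 = rnorm(10), v2 = rnorm(10)))

  one <- structure(list(members = pool[1], tss = 0.9, weights = 1, tss_min = 0),
                   class = "ensemble_model")
  expect_identical(ensemble_predict(one, tbl), predict_suitability(pool[[1]], tbl))

  # hand-evaluated weighted mean: members with TSS .8/.7 predicting p1/p2
  two <- structure(list(members = pool, tss = c(0.8, 0.7),
                        weights = c(0.8, 0.7) / 1.5, tss_min = 0),
                   class = "ensemble_model")
  p1 <- predict_suitability(pool[[1]], tbl)
  p2 <- predict_suitability(pool[[2]], tbl)
  expect_equal(ensemble_predict(two, tbl), (0.8 * p1 + 0.7 * p2) / 1.5,
               tolerance = 1e-15)
})

test_that("ensemble prediction matches the two-loop brute force and stays convex", {
  pool <- glm_pool(6, seed = 9)
  for (s in 1:100) {
    withr::with_seed(s, {
      k <- sample(2:6, 1)
      idx <- sample(6, k)
      tss <- runif(k, 0.3, 1)
      tbl <- tibble::tibble(v1 = rnorm(sample(5:100, 1)), v2 = rnorm(length(v1)))
    })
    ens <- structure(list(members = pool[idx], tss = tss,
                          weights = tss / sum(tss), tss_min = 0),
                     class = "ensemble_model")
    got <- ensemble_predict(ens, tbl)
    preds <- lapply(pool[idx], predict_suitability, table = tbl)
    brute <- numeric(nrow(tbl))
    for (i in seq_len(nrow(tbl))) {
      num <- 0
      for (j in seq_len(k)) num <- num + tss[j] * preds[[j]][i]
      brute[i] <- num / sum(tss)
    }
    expect_equal(got, brute, tolerance = 1e-12)
    lo <- do.call(pmin, preds); hi <- do.call(pmax, preds)
    expect_true(all(got >= lo - 1e-12 & got <= hi + 1e-12))
  }
})

test_that("projection fills non-nodata cells and agrees with direct prediction", {
  st <- tiny_stack(8)
  v <- st$layers$alpha$values; v[1, 1] <- NA
  st <- env_stack(list(env_layer("alpha", v), st$layers$beta, st$layers$kat),
                  st$grid, "current")
  tbl <- withr::with_seed(2, tibble::tibble(
    label = rep(c(0L, 1L), 20),
    alpha = rnorm(40, 30, 15), beta = rnorm(40, 15, 8),
    kat = factor(sample(c(1, 2), 40, TRUE), levels = c(1, 2))))
  m <- fit_single_model("GLM", tbl, seed = 1)
  map <- project_map(m, st)
  expect_true(is.na(map$values[1, 1]))
  expect_equal(sum(is.na(map$values)), 1)
  v_ok <- map$values[!is.na(map$values)]
  expect_true(all(v_ok >= 0 & v_ok <= 1))

  # same-batch prediction over every data cell is reproduced bit-identically
  all_cells <- which(!t(st$nodata)) - 1L
  full <- extract_at_cells(st, all_cells, rep(NA_integer_, length(all_cells)))
  direct <- predict_suitability(m, full)
  rc <- sdmflow:::cell_rowcol(st$grid, full$cell)
  expect_identical(map$values[cbind(rc$row + 1, rc$col + 1)], direct)
})

test_that("permutation importance is zero for inert variables and finds strong ones", {
  sig <- withr::with_seed(3, {
    x <- rnorm(400)
    tibble::tibble(label = rbinom(400, 1, plogis(3 * x)), x = x, z = rnorm(400))
  })
  m <- fit_single_model(algorithm_spec("GLM", list(quadratic = FALSE)), sig, seed = 1)
  # force a truly inert variable: zero out its coefficient
  m$engine$coefficients["z"] <- 0
  imp <- permutation_importance(m, sig, n_shuffles = 20, seed = 4)
  z_row <- imp[imp$variable == "z", ]
  x_row <- imp[imp$variable == "x", ]
  expect_equal(z_row$mean, 0)
  expect_equal(z_row$sd, 0)
  expect_gt(x_row$mean, 0.2)

  # independent re-implementation on the strong single variable
  oracle <- withr::with_seed(99, {
    p0 <- predict_suitability(m, sig)
    mean(replicate(20, {
      sh <- sig; sh$x <- sample(sh$x)
      1 - cor(p0, predict_suitability(m, sh))
    }))
  })
  expect_equal(x_row$mean, oracle, tolerance = 0.15)
})

test_that("ensemble importance aggregates member scores by TSS weight", {
  sig <- withr::with_seed(13, {
    x <- rnorm(300)
    tibble::tibble(label = rbinom(300, 1, plogis(2 * x)), x = x, z = rnorm(300))
  })
  m1 <- fit_single_model(algorithm_spec("GLM", list(quadratic = FALSE)), sig, seed = 1)
  m2 <- fit_single_model(algorithm_spec("GLM", list(quadratic = FALSE)), sig, seed = 2)
  ens <- structure(list(members = list(m1, m2), tss = c(0.9, 0.6),
                        weights = c(0.9, 0.6) / 1.5, tss_min = 0),
                   class = "ensemble_model")
  imp <- permutation_importance(ens, sig, n_shuffles = 3, seed = 5)
  expect_setequal(imp$variable, c("x", "z"))
  expect_gt(imp$mean[imp$variable == "x"], imp$mean[imp$variable == "z"])
  expect_true(all(imp$mean >= 0))
})

test_that("the CV map is SD/mean with sample SD, scale-invariant, zero for identical members", {
  g <- grid_def(0, 3, 1, 3, 3)
  mk <- function(v) sdmflow:::new_map(matrix(v, 3, 3), g, "current", "m",
                                      "suitability_map")
  same <- uncertainty_map(list(mk(0.4), mk(0.4), mk(0.4)))
  expect_true(all(same$values == 0))

  two <- uncertainty_map(list(mk(0.2), mk(0.6)))
  expect_equal(two$values[1, 1], sd(c(0.2, 0.6)) / 0.4)   # 0.7071...
  expect_equal(two$values[2, 2], 0.7071068, tolerance = 1e-6)

  halved <- uncertainty_map(list(mk(0.1), mk(0.3)))
  expect_equal(halved$values, two$values)

  expect_warning(zz <- uncertainty_map(list(mk(0), mk(0))), "mean 0")
  expect_true(all(is.na(zz$values)))

  g2 <- grid_def(0, 4, 1, 4, 4)
  other <- sdmflow:::new_map(matrix(0.5, 4, 4), g2, "current", "m",
                             "suitability_map")
  expect_error(uncertainty_map(list(mk(0.2), other)), "alignment")
})

test_that("binarization applies the >= rule and propagates nodata", {
  g <- grid_def(0, 1, 1, 1, 3)
  m <- sdmflow:::new_map(matrix(c(0.3, 0.5, 0.7), 1, 3), g, "now", "e",
                         "suitability_map")
  expect_equal(as.vector(binarize_map(m, 0.5)$values), c(0, 1, 1))
  expect_equal(as.vector(binarize_map(m, 0)$values), c(1, 1, 1))
  expect_equal(as.vector(binarize_map(m, 1)$values), c(0, 0, 0))
  m$values[1, 2] <- NA
  bm <- binarize_map(m, 0.5)
  expect_true(is.na(bm$values[1, 2]))
  expect_equal(bm$threshold, 0.5)
})

test_that("range change obeys its conservation identities", {
  g <- grid_def(0, 2, 5, 2, 2)   # 4 cells of 25 km2
  mk_bin <- function(v, tag) sdmflow:::new_map(matrix(v, 2, 2), g, tag, "e",
                                               "binary_map", threshold = 0.5)
  cur <- mk_bin(c(1, 1, 1, 1), "current")
  fut <- mk_bin(c(0, 0, 0, 0), "future")
  rc <- range_change(cur, fut, 25)
  expect_equal(rc$contraction_km2, 100)
  expect_equal(rc$expansion_km2, 0)
  expect_equal(rc$unchanged_km2, 0)

  same <- range_change(cur, cur, 25)
  expect_equal(same$expansion_km2, 0)
  expect_equal(same$contraction_km2, 0)

  g20 <- grid_def(0, 20, 1, 20, 20)
  for (s in 1:50) {
    vals <- withr::with_seed(s, list(a = rbinom(400, 1, 0.4),
                                     b = rbinom(400, 1, 0.6)))
    a <- sdmflow:::new_map(matrix(vals$a, 20, 20), g20, "current", "e",
                           "binary_map", threshold = 0.5)
    b <- sdmflow:::new_map(matrix(vals$b, 20, 20), g20, "future", "e",
                           "binary_map", threshold = 0.5)
    rc <- range_change(a, b, 1)
    expect_equal(rc$unchanged_km2 + rc$contraction_km2, rc$current_km2)
    expect_equal(rc$unchanged_km2 + rc$expansion_km2, rc$future_km2)
    expect_true(all(c(rc$expansion_km2, rc$contraction_km2, rc$unchanged_km2) >= 0))
  }

  gx <- grid_def(0, 2, 1, 2, 2)
  cx <- mk_bin(c(1, 0, 1, 0), "current"); cx$grid <- gx
  expect_error(range_change(cur, cx, 25), "alignment")
})
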