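test_that("AUC matches exhaustive pair counting, including ties", {
  expect_equal(compute_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3)), 0.75)
  expect_equal(compute_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(compute_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(compute_auc(c(1, 1), c(0.2, 0.3)), "undefined-metric")

  for (s in 1:100) {
    withr::with_seed(s, {
      n <- sample(4:12, 1)
      lab <- c(1, 0, rbinom(n - 2, 1, 0.5))
      pred <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    })
    expect_equal(compute_auc(lab, pred), pair_count_auc(lab, pred))
  }
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  for (s in 1:10) {
    withr::with_seed(s, {
      lab <- c(1, 0, rbinom(48, 1, 0.5))
      pred <- runif(50)
    })
    ref <- as.numeric(suppressMessages(pROC::auc(lab, pred,
                                                 direction = "<", quiet = TRUE)))
    expect_equal(compute_auc(lab, pred), ref)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  withr::with_seed(1, {
    lab <- rbinom(50, 1, 0.5); lab[1] <- 1; lab[2] <- 0
    pred <- runif(50)
  })
  base <- compute_auc(lab, pred)
  expect_equal(compute_auc(lab, plogis(5 * pred - 2)), base)
  expect_equal(compute_auc(lab, pred^3), base)
  expect_equal(compute_auc(lab, rank(pred)), base)
})

test_that("TSS follows sensitivity + specificity - 1 with >= classification", {
  # TP=30 FN=20 TN=35 FP=15 -> 0.6 + 0.7 - 1 = 0.3
  lab <- c(rep(1, 50), rep(0, 50))
  pred <- c(rep(0.9, 30), rep(0.1, 20), rep(0.1, 35), rep(0.9, 15))
  got <- compute_tss(lab, pred, 0.5)
  expect_equal(got$tss, 0.3)
  expect_equal(unname(got$confusion), c(30, 15, 35, 20))  # TP FP TN FN
  expect_equal(got$tss, got$sensitivity + got$specificity - 1, tolerance = 1e-12)
  expect_equal(sum(got$confusion), 100)

  perfect <- compute_tss(c(1, 1, 0, 0), c(0.8, 0.7, 0.2, 0.1), 0.5)
  expect_equal(perfect$tss, 1)
})

test_that("the best-TSS threshold beats a dense grid search", {
  got <- best_threshold_by_tss(c(0, 0, 1, 1), c(0.2, 0.4, 0.6, 0.8))
  expect_equal(got$threshold, 0.5)
  expect_equal(got$tss, 1)
  expect_equal(best_threshold_by_tss(c(0, 1), c(0, 1))$tss, 1)

  grid <- seq(0, 1, length.out = 10001)
  for (s in 1:100) {
    withr::with_seed(s, {
      n <- sample(4:12, 1)
      lab <- c(1, 0, rbinom(n - 2, 1, 0.5))
      pred <- round(runif(n), 2)
    })
    got <- best_threshold_by_tss(lab, pred)
    grid_best <- max(vapply(grid, function(t) compute_tss(lab, pred, t)$tss, 0))
    expect_gte(got$tss + 1e-12, grid_best)
  }
})

test_that("a GLM separates linearly separable data and fits are seed-deterministic", {
  tbl <- withr::with_seed(77,
    tibble::tibble(label = rep(c(0L, 1L), each = 20),
                   v1 = c(rnorm(20, -3), rnorm(20, 3))))
  m <- fit_single_model("GLM", tbl, seed = 1)
  expect_equal(compute_auc(tbl$label, predict_suitability(m, tbl)), 1)

  sig <- signal_table(150, seed = 5)
  for (alg in c("GBM", "RF", "MAXNET", "XGBOOST", "CTA")) {
    m1 <- fit_single_model(alg, sig, seed = 7)
    m2 <- fit_single_model(alg, sig, seed = 7)
    expect_identical(predict_suitability(m1, sig), predict_suitability(m2, sig),
                     info = alg)
  }
})

test_that("predictions honor the [0,1] contract, empty input, and schema checks", {
  sig <- signal_table(100, seed = 2)
  m <- fit_single_model("RF", sig, seed = 1)
  p <- predict_suitability(m, sig)
  expect_true(all(p >= 0 & p <= 1))
  expect_false(anyNA(p))
  expect_length(predict_suitability(m, sig[0, ]), 0)
  expect_error(predict_suitability(m, sig[, c("label", "v1")]), "schema.*v2")
  expect_error(fit_single_model("GLM", dplyr::mutate(sig, label = 1L)),
               "degenerate-training")
  expect_error(algorithm_spec("SVM"), "configuration")
})

test_that("all six algorithms discriminate a strong planted signal on held-out data", {
  train <- signal_table(300, strength = 3, seed = 11)
  test <- signal_table(200, strength = 3, seed = 12)
  for (alg in c("GLM", "GBM", "RF", "CTA", "MAXNET", "XGBOOST")) {
    m <- fit_single_model(alg, train, seed = 3)
    auc <- compute_auc(test$label, predict_suitability(m, test))
    expect_gte(auc, 0.8)
  }
})

test_that("held-out AUC sits near 0.5 when labels are independent of features", {
  aucs <- vapply(1:20, function(s) {
    tbl <- withr::with_seed(s, {
      t <- noise_table(160, seed = s)
      t$label <- sample(t$label)
      t
    })
    m <- fit_single_model("GLM", tbl[1:110, ], seed = s)
    compute_auc(tbl$label[111:160], predict_suitability(m, tbl[111:160, ]))
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("tuning picks the grid point with the best cross-validated TSS", {
  sig <- signal_table(200, seed = 21)
  one <- algorithm_spec("XGBOOST", tuning_grid = list(list(max_depth = 3)))
  tuned1 <- tune_hyperparameters(one, sig, seed = 1)
  expect_equal(tuned1$hyperparameters$max_depth, 3)

  # XOR interaction: depth-1 stumps cannot represent it, depth-2 trees can
  xor_tbl <- withr::with_seed(31, {
    x1 <- rnorm(400); x2 <- rnorm(400)
    tibble::tibble(label = as.integer(xor(x1 > 0, x2 > 0)),
                   cell = 0:399, x1 = x1, x2 = x2)
  })
  spec <- algorithm_spec("GBM",
                         tuning_grid = list(list(max_depth = 1),
                                            list(max_depth = 2)))
  tuned <- tune_hyperparameters(spec, xor_tbl, seed = 2)
  expect_equal(tuned$hyperparameters$max_depth, 2)

  again <- tune_hyperparameters(spec, xor_tbl, seed = 2)
  expect_identical(tuned$hyperparameters, again$hyperparameters)
})

test_that("evaluate_model composes AUC and the max-TSS threshold", {
  sig <- signal_table(200, seed = 41)
  m <- fit_single_model("GLM", sig[1:140, ], seed = 1)
  hold <- sig[141:200, ]
  ev <- evaluate_model(m, hold)
  p <- predict_suitability(m, hold)
  expect_equal(ev$auc, compute_auc(hold$label, p))
  bt <- best_threshold_by_tss(hold$label, p)
  expect_equal(ev$tss, bt$tss)
  expect_equal(ev$optimal_threshold, bt$threshold)
  expect_equal(ev$n, 60)
  expect_equal(sum(ev$confusion), 60)
  td <- tidy(ev)
  expect_equal(td$auc, ev$auc)

  anti <- dplyr::mutate(hold, label = 1L - label)
  expect_lt(evaluate_model(m, anti)$auc, 0.5)
})
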