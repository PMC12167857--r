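ALGORITHM_ROSTER <- c("GLM", "GBM", "RF", "CTA", "MAXNET", "XGBOOST")

#' Specify a suitability-model algorithm
#'
#' The battery's closed roster of six presence/background learners, each
#' behind one probability-output contract:
#' * `GLM` — logistic regression with optional quadratic terms;
#' * `GBM` — stochastic gradient-boosted trees (row subsampling < 1);
#' * `RF` — random forest of classification trees;
#' * `CTA` — a single cost-complexity-pruned classification tree;
#' * `MAXNET` — elastic-net-regularized logistic model on an expanded
#'   linear + quadratic + hinge feature basis (the maxent-as-GLM form);
#' * `XGBOOST` — second-order gradient boosting with shrinkage and column
#'   subsampling.
#'
#' @param algorithm_id One of the roster names above.
#' @param hyperparameters Named list overriding the algorithm defaults.
#' @param tuning_grid Optional list of named hyperparameter lists, in
#'   preference order, for [tune_hyperparameters()].
#' @return An `algorithm_spec`.
#' @export
algorithm_spec <- function(algorithm_id, hyperparameters = list(),
                           tuning_grid = NULL) {
  if (!algorithm_id %in% ALGORITHM_ROSTER)
    stop("configuration error: unknown algorithm_id '", algorithm_id,
         "' (roster: ", paste(ALGORITHM_ROSTER, collapse = ", "), ")",
         call. = FALSE)
  hp <- utils::modifyList(default_hyperparameters(algorithm_id), hyperparameters)
  structure(list(algorithm_id = algorithm_id, hyperparameters = hp,
                 tuning_grid = tuning_grid),
            class = "algorithm_spec")
}

default_hyperparameters <- function(id) {
  switch(id,
    GLM = list(quadratic = TRUE),
    GBM = list(nrounds = 120, max_depth = 3, eta = 0.1, subsample = 0.5,
               colsample_bytree = 1, lambda = 0),
    RF = list(ntree = 300, mtry = NULL),
    CTA = list(cp = 0.001, minsplit = 10),
    MAXNET = list(alpha = 1, n_hinge = 4, nfolds = 4),
    XGBOOST = list(nrounds = 120, max_depth = 4, eta = 0.1, subsample = 1,
                   colsample_bytree = 0.8, lambda = 1)
  )
}

#' Default small tuning grids for each algorithm
#' @param algorithm_id Roster name.
#' @return List of hyperparameter lists in preference order.
#' @export
default_tuning_grid <- function(algorithm_id) {
  switch(algorithm_id,
    GLM = list(list(quadratic = FALSE), list(quadratic = TRUE)),
    GBM = list(list(max_depth = 2), list(max_depth = 3), list(max_depth = 4)),
    RF = list(list(ntree = 300)),
    CTA = list(list(cp = 0.01), list(cp = 0.001)),
    MAXNET = list(list(alpha = 0.5), list(alpha = 1)),
    XGBOOST = list(list(max_depth = 2, eta = 0.1), list(max_depth = 4, eta = 0.1),
                   list(max_depth = 4, eta = 0.3))
  )
}

# Predictor preparation ------------------------------------------------------

split_predictors <- function(table) {
  tbl <- tibble::as_tibble(table)
  tbl[, setdiff(names(tbl), c("label", "cell")), drop = FALSE]
}

# Record everything predict-time needs to rebuild an identical design:
# variable names, factor levels, and (for MAXNET) hinge knots and ranges.
make_prep <- function(predictors, basis = c("raw", "onehot", "maxnet"),
                      n_hinge = 4) {
  basis <- match.arg(basis)
  is_fac <- vapply(predictors, is.factor, TRUE)
  prep <- list(
    basis = basis,
    variables = names(predictors),
    continuous = names(predictors)[!is_fac],
    factor_levels = lapply(predictors[is_fac], levels)
  )
  if (basis == "maxnet") {
    prep$hinge <- lapply(predictors[prep$continuous], function(v) {
      rng <- range(v)
      knots <- stats::quantile(v, seq_len(n_hinge) / (n_hinge + 1),
                               type = 7, names = FALSE)
      list(range = rng, knots = knots)
    })
  }
  prep
}

apply_prep <- function(prep, table) {
  missing <- setdiff(prep$variables, names(table))
  if (length(missing))
    stop("schema error: missing variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(table[, prep$variables, drop = FALSE])
  for (nm in names(prep$factor_levels))
    df[[nm]] <- factor(df[[nm]], levels = prep$factor_levels[[nm]])
  if (prep$basis == "raw") return(df)

  blocks <- list()
  for (nm in prep$continuous) {
    x <- as.numeric(df[[nm]])
    blocks[[nm]] <- x
    if (prep$basis == "maxnet") {
      h <- prep$hinge[[nm]]
      span <- max(h$range[2] - h$range[1], .Machine$double.eps)
      blocks[[paste0(nm, "__sq")]] <- ((x - h$range[1]) / span)^2
      for (i in seq_along(h$knots)) {
        blocks[[paste0(nm, "__hf", i)]] <- pmax(0, (x - h$knots[i]) / span)
        blocks[[paste0(nm, "__hr", i)]] <- pmax(0, (h$knots[i] - x) / span)
      }
    }
  }
  for (nm in names(prep$factor_levels)) {
    lv <- prep$factor_levels[[nm]]
    for (l in lv[-1])  # first level is the reference
      blocks[[paste0(nm, "__", l)]] <- as.numeric(df[[nm]] == l)
  }
  m <- do.call(cbind, blocks)
  colnames(m) <- names(blocks)
  m
}

# Presences and pseudo-absences weighted to equal total mass (prevalence
# 0.5), normalized to mean weight 1.
prevalence_weights <- function(labels) {
  n <- length(labels); n1 <- sum(labels == 1); n0 <- n - n1
  ifelse(labels == 1, n / (2 * n1), n / (2 * n0))
}

# Fitting --------------------------------------------------------------------

#' Fit one suitability model
#'
#' Trains the requested algorithm on a presence/pseudo-absence design matrix
#' (a `label` column plus predictor columns; factors are treated as
#' categorical). Presences and pseudo-absences are weighted to equal total
#' mass unless `weight_prevalence = FALSE`. Stochastic learners are
#' deterministic given `seed`.
#'
#' @param spec An [algorithm_spec()] (or roster name, taken with defaults).
#' @param train_table Training rows; must contain both labels.
#' @param seed Integer seed.
#' @param weight_prevalence Balance classes to prevalence 0.5 (default TRUE).
#' @return A fitted `sdm_model` honoring the `[0, 1]` output contract.
#' @export
fit_single_model <- function(spec, train_table, seed = 1,
                             weight_prevalence = TRUE) {
  if (is.character(spec)) spec <- algorithm_spec(spec)
  lab <- train_table$label
  if (is.null(lab) || !any(lab == 1) || !any(lab == 0))
    stop("degenerate-training error: training data must contain both classes",
         call. = FALSE)
  predictors <- split_predictors(train_table)
  w <- if (weight_prevalence) prevalence_weights(lab) else rep(1, length(lab))
  hp <- spec$hyperparameters
  id <- spec$algorithm_id

  fit <- withr::with_seed(seed, switch(id,
    GLM = {
      prep <- make_prep(predictors, "raw")
      df <- as.data.frame(predictors)
      rhs <- c(names(df),
               if (isTRUE(hp$quadratic))
                 paste0("I(", prep$continuous, "^2)"))
      f <- stats::as.formula(paste("..y ~", paste(rhs, collapse = " + ")))
      df$..y <- lab
      list(prep = prep,
           engine = suppressWarnings(stats::glm(f, data = df,
                                                family = stats::binomial(),
                                                weights = w)))
    },
    GBM = ,
    XGBOOST = {
      prep <- make_prep(predictors, "onehot")
      X <- apply_prep(prep, predictors)
      dtrain <- xgboost::xgb.DMatrix(X, label = lab, weight = w)
      list(prep = prep,
           engine = xgboost::xgb.train(
             params = list(objective = "binary:logistic",
                           max_depth = hp$max_depth, eta = hp$eta,
                           subsample = hp$subsample,
                           colsample_bytree = hp$colsample_bytree,
                           lambda = hp$lambda, nthread = 1),
             data = dtrain, nrounds = hp$nrounds, verbose = 0))
    },
    RF = {
      prep <- make_prep(predictors, "raw")
      df <- as.data.frame(predictors)
      cw <- if (weight_prevalence) c("0" = 0.5, "1" = 0.5) else NULL
      list(prep = prep,
           engine = randomForest::randomForest(
             x = df, y = factor(lab, levels = c(0, 1)),
             ntree = hp$ntree,
             mtry = hp$mtry %||% max(1, floor(sqrt(ncol(df)))),
             classwt = cw))
    },
    CTA = {
      prep <- make_prep(predictors, "raw")
      df <- as.data.frame(predictors)
      df$..y <- factor(lab, levels = c(0, 1))
      tr <- rpart::rpart(..y ~ ., data = df, weights = w, method = "class",
                         control = rpart::rpart.control(cp = hp$cp,
                                                        minsplit = hp$minsplit,
                                                        xval = 10))
      cp_tab <- tr$cptable
      best_cp <- cp_tab[which.min(cp_tab[, "xerror"]), "CP"]
      list(prep = prep, engine = rpart::prune(tr, cp = best_cp))
    },
    MAXNET = {
      prep <- make_prep(predictors, "maxnet", n_hinge = hp$n_hinge)
      X <- apply_prep(prep, predictors)
      # near-separable tables truncate the lambda path; larger-lambda
      # solutions are still returned, so that warning is noise here
      cv <- withCallingHandlers(
        glmnet::cv.glmnet(X, lab, family = "binomial", weights = w,
                          alpha = hp$alpha, nfolds = hp$nfolds,
                          standardize = TRUE),
        warning = function(cnd) {
          if (grepl("Convergence .* not reached", conditionMessage(cnd)))
            invokeRestart("muffleWarning")
        })
      list(prep = prep, engine = cv, lambda = cv$lambda.min)
    }
  ))

  structure(list(algorithm_id = id, hyperparameters = hp,
                 prep = fit$prep, engine = fit$engine,
                 lambda = fit$lambda, variables = fit$prep$variables,
                 seed = seed, run_id = NA_integer_,
                 pa_replicate_id = NA_integer_),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> %s on %d variables (seed %d)\n",
              x$algorithm_id, length(x$variables), x$seed))
  invisible(x)
}

#' Predict habitat suitability
#'
#' @param model A fitted `sdm_model`.
#' @param table Rows carrying the training variables (extra columns are
#'   ignored; a missing variable raises a schema error naming it).
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_suitability <- function(model, table) {
  if (nrow(table) == 0) return(numeric(0))
  design <- apply_prep(model$prep, table)
  p <- switch(model$algorithm_id,
    GLM = stats::predict(model$engine, newdata = design, type = "response"),
    GBM = ,
    XGBOOST = stats::predict(model$engine, xgboost::xgb.DMatrix(design)),
    RF = stats::predict(model$engine, newdata = design, type = "prob")[, "1"],
    CTA = stats::predict(model$engine, newdata = design, type = "prob")[, "1"],
    MAXNET = as.numeric(stats::predict(model$engine, newx = design,
                                       s = model$lambda, type = "response"))
  )
  pmin(1, pmax(0, unname(as.numeric(p))))
}

#' Select hyperparameters by cross-validated TSS
#'
#' Evaluates every grid point by stratified k-fold cross-validation on the
#' training partition, scoring each fold at its max-TSS threshold, and
#' returns the spec fixed at the grid point with the highest mean TSS (ties
#' go to the earlier point in declared order).
#'
#' @param spec An [algorithm_spec()] with a non-empty `tuning_grid`.
#' @param train_table Training rows.
#' @param n_folds Folds (default 3).
#' @param seed Integer seed for fold assignment and fits.
#' @return The tuned `algorithm_spec` (grid cleared, chosen point merged
#'   into `hyperparameters`, the selection table in attribute `tuning`).
#' @export
tune_hyperparameters <- function(spec, train_table, n_folds = 3, seed = 1) {
  grid <- spec$tuning_grid %||% default_tuning_grid(spec$algorithm_id)
  assert_that(length(grid) >= 1, "tuning grid must be non-empty")
  lab <- train_table$label
  folds <- withr::with_seed(seed, {
    f <- integer(length(lab))
    f[lab == 1] <- sample(rep_len(seq_len(n_folds), sum(lab == 1)))
    f[lab == 0] <- sample(rep_len(seq_len(n_folds), sum(lab == 0)))
    f
  })
  scores <- vapply(seq_along(grid), function(g) {
    point <- utils::modifyList(spec$hyperparameters, grid[[g]])
    sp <- algorithm_spec(spec$algorithm_id, point)
    mean(vapply(seq_len(n_folds), function(k) {
      m <- fit_single_model(sp, train_table[folds != k, ], seed = derive_seed(seed, k))
      p <- predict_suitability(m, train_table[folds == k, ])
      best_threshold_by_tss(lab[folds == k], p)$tss
    }, 0))
  }, 0)
  best <- which.max(scores)
  out <- algorithm_spec(spec$algorithm_id,
                        utils::modifyList(spec$hyperparameters, grid[[best]]))
  attr(out, "tuning") <- tibble::tibble(point = seq_along(grid), mean_tss = scores)
  out
}

#' @export
tidy.sdm_model <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm_id,
                 variable = x$variables,
                 run_id = x$run_id, pa_replicate_id = x$pa_replicate_id)
}
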