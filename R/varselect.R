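#' Pearson correlation matrix with a sampling limit
#'
#' Computes the pairwise Pearson correlation matrix of the continuous
#' columns. With more rows than `sample_limit` a seeded uniform subsample of
#' `sample_limit` rows is used, matching the screening convention of
#' correlation-based predictor selection on large extractions.
#'
#' @param table Data frame of continuous predictor columns (non-numeric and
#'   bookkeeping columns `label`/`cell` are ignored).
#' @param sample_limit Maximum rows entering the computation (default 5000).
#' @param seed Seed for the subsample.
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   columns get correlation 0 off-diagonal, with a warning.
#' @export
correlation_matrix <- function(table, sample_limit = 5000, seed = 1) {
  num <- numeric_predictors(table)
  assert_that(nrow(num) >= 2, "need at least 2 rows")
  if (nrow(num) > sample_limit) {
    idx <- withr::with_seed(seed, sample(nrow(num), sample_limit))
    num <- num[idx, , drop = FALSE]
  }
  sds <- vapply(num, stats::sd, 0)
  r <- suppressWarnings(stats::cor(as.matrix(num)))
  if (any(sds == 0)) {
    warning("zero-variance column(s): ", paste(names(num)[sds == 0], collapse = ", "),
            "; correlations reported as 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  r
}

numeric_predictors <- function(table) {
  tbl <- tibble::as_tibble(table)
  tbl <- tbl[, setdiff(names(tbl), c("label", "cell")), drop = FALSE]
  tbl[, vapply(tbl, is.numeric, TRUE), drop = FALSE]
}

#' Variance inflation factors
#'
#' VIF of predictor k is `1 / (1 - R^2_k)` where `R^2_k` comes from the
#' least-squares regression of k on all other predictors. Perfectly
#' collinear predictors get `Inf`.
#'
#' @inheritParams correlation_matrix
#' @return Named numeric vector of VIF values.
#' @export
vif_scores <- function(table) {
  num <- numeric_predictors(table)
  p <- ncol(num)
  if (p == 1) return(stats::setNames(1, names(num)))
  assert_that(nrow(num) >= p + 1, "need at least p + 1 rows for p predictors")
  X <- as.matrix(num)
  vapply(seq_len(p), function(k) {
    y <- X[, k]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(1)  # constant column inflates nothing
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0) |> stats::setNames(names(num))
}

#' Iterative correlation/VIF predictor selection (vifcor)
#'
#' Reproduces the stepwise exclusion used to fight multicollinearity before
#' model fitting: repeatedly find the pair of predictors with the highest
#' absolute Pearson correlation; while it exceeds `r_threshold`, drop the
#' pair member with the larger VIF (ties drop the later column in input
#' order) and recompute. A second phase then drops the max-VIF predictor
#' until every remaining VIF is below `vif_threshold`. Every drop is logged
#' with the offending pair, its |r| and both VIFs.
#'
#' Categorical (factor) columns never enter the screen and are passed
#' through untouched — Pearson correlation on category codes is meaningless.
#'
#' @inheritParams correlation_matrix
#' @param r_threshold Maximum tolerated pairwise |r| (default 0.7).
#' @param vif_threshold Maximum tolerated VIF (default 10).
#' @return A `selection_report`: list with `kept`, `passthrough`
#'   (categorical columns), `drops` (tibble audit trail), `final_vif`,
#'   `final_max_r`, and the thresholds used.
#' @export
vifcor_select <- function(table, r_threshold = 0.7, vif_threshold = 10,
                          sample_limit = 5000, seed = 1) {
  assert_that(r_threshold > 0 && r_threshold < 1, "r_threshold must be in (0,1)")
  assert_that(vif_threshold > 1, "vif_threshold must be > 1")
  tbl <- tibble::as_tibble(table)
  tbl <- tbl[, setdiff(names(tbl), c("label", "cell")), drop = FALSE]
  is_num <- vapply(tbl, is.numeric, TRUE)
  passthrough <- names(tbl)[!is_num]
  work <- tbl[, is_num, drop = FALSE]
  input_order <- names(work)

  drops <- tibble::tibble(dropped = character(), against = character(),
                          abs_r = numeric(), vif_dropped = numeric(),
                          vif_against = numeric(), phase = character())
  repeat {
    if (ncol(work) < 2) break
    r <- correlation_matrix(work, sample_limit, seed)
    ar <- abs(r); diag(ar) <- 0
    mx <- max(ar)
    if (mx <= r_threshold) break
    pair <- which(ar == mx, arr.ind = TRUE)[1, ]
    v <- vif_scores(work)
    a <- colnames(ar)[pair[1]]; b <- colnames(ar)[pair[2]]
    # drop the larger-VIF member; tie -> later column in input order
    drop_a <- if (v[a] > v[b]) TRUE
      else if (v[a] < v[b]) FALSE
      else match(a, input_order) > match(b, input_order)
    victim <- if (drop_a) a else b
    other <- if (drop_a) b else a
    drops <- dplyr::bind_rows(drops, tibble::tibble(
      dropped = victim, against = other, abs_r = mx,
      vif_dropped = unname(v[victim]), vif_against = unname(v[other]),
      phase = "correlation"))
    work <- work[, setdiff(names(work), victim), drop = FALSE]
  }
  # second phase: explicit VIF ceiling
  repeat {
    if (ncol(work) < 2) break
    v <- vif_scores(work)
    if (max(v) < vif_threshold) break
    victim <- names(v)[which.max(v)]
    drops <- dplyr::bind_rows(drops, tibble::tibble(
      dropped = victim, against = NA_character_, abs_r = NA_real_,
      vif_dropped = unname(max(v)), vif_against = NA_real_, phase = "vif"))
    work <- work[, setdiff(names(work), victim), drop = FALSE]
  }
  if (ncol(work) == 0)
    stop("selection-collapse error: every predictor was dropped", call. = FALSE)

  final_vif <- vif_scores(work)
  final_r <- if (ncol(work) >= 2) {
    rr <- abs(correlation_matrix(work, sample_limit, seed)); diag(rr) <- 0; max(rr)
  } else 0
  structure(
    list(kept = names(work), passthrough = passthrough, drops = drops,
         final_vif = final_vif, final_max_r = final_r,
         r_threshold = r_threshold, vif_threshold = vif_threshold),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> kept %d of %d predictors (max |r| = %.3f, max VIF = %.2f)\n",
              length(x$kept), length(x$kept) + nrow(x$drops),
              x$final_max_r, max(x$final_vif)))
  if (nrow(x$drops)) {
    cat("dropped:\n"); print(x$drops)
  }
  if (length(x$passthrough))
    cat("passed through (categorical):", paste(x$passthrough, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.selection_report <- function(x, ...) {
  tibble::tibble(
    variable = c(x$kept, x$drops$dropped, x$passthrough),
    status = c(rep("kept", length(x$kept)), rep("dropped", nrow(x$drops)),
               rep("passthrough", length(x$passthrough))),
    vif = c(unname(x$final_vif[x$kept]), x$drops$vif_dropped,
            rep(NA_real_, length(x$passthrough)))
  )
}
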