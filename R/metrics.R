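#' ROC AUC by Mann-Whitney pair counting
#'
#' AUC is computed as the Mann-Whitney statistic: the fraction of
#' presence/absence pairs in which the presence scores higher, counting ties
#' as half — `(concordant + 0.5 * tied) / (n1 * n0)` — via the rank-sum
#' identity, so it is exact for any score vector including heavy ties.
#'
#' @param labels 0/1 vector (1 = presence).
#' @param predictions Numeric scores, same length.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(labels, predictions) {
  check_two_classes(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(predictions)  # midranks handle ties as 0.5
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True Skill Statistic at a fixed threshold
#'
#' Rows with `prediction >= threshold` are classified presence. TSS =
#' sensitivity + specificity - 1 = TP/(TP+FN) + TN/(TN+FP) - 1, ranging from
#' -1 to 1 with 0 the no-skill anchor.
#'
#' @inheritParams compute_auc
#' @param threshold Classification cutoff.
#' @return List: `tss`, `sensitivity`, `specificity`, and `confusion`
#'   (named vector TP, FP, TN, FN).
#' @export
compute_tss <- function(labels, predictions, threshold) {
  check_two_classes(labels)
  pos <- predictions >= threshold
  tp <- sum(pos & labels == 1); fn <- sum(!pos & labels == 1)
  tn <- sum(!pos & labels == 0); fp <- sum(pos & labels == 0)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(tss = sens + spec - 1, sensitivity = sens, specificity = spec,
       confusion = c(TP = tp, FP = fp, TN = tn, FN = fn))
}

#' Threshold maximizing TSS
#'
#' Searches the candidate set `{0, 1, midpoints of consecutive sorted unique
#' predictions}`, which contains a maximizer of the piecewise-constant TSS
#' curve; ties resolve to the smallest threshold.
#'
#' @inheritParams compute_auc
#' @return List: `threshold`, `tss`.
#' @export
best_threshold_by_tss <- function(labels, predictions) {
  check_two_classes(labels)
  u <- sort(unique(predictions))
  cand <- sort(unique(c(0, 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  tss <- vapply(cand, function(t) compute_tss(labels, predictions, t)$tss, 0)
  best <- which.max(tss)  # which.max takes the first (smallest) on ties
  list(threshold = cand[best], tss = tss[best])
}

check_two_classes <- function(labels) {
  if (!any(labels == 1) || !any(labels == 0))
    stop("undefined-metric error: both classes must be present", call. = FALSE)
}

#' Evaluate a fitted model on held-out data
#'
#' Scores the 30% evaluation partition of the combined presence/PA table:
#' ROC AUC, the max-TSS threshold, and sensitivity/specificity/confusion
#' counts at that threshold.
#'
#' @param model A fitted `sdm_model` or `ensemble_model`.
#' @param holdout_table Held-out rows with `label` and the training
#'   variables.
#' @return An `sdm_evaluation` object.
#' @export
evaluate_model <- function(model, holdout_table) {
  p <- if (inherits(model, "ensemble_model")) ensemble_predict(model, holdout_table)
       else predict_suitability(model, holdout_table)
  lab <- holdout_table$label
  auc <- compute_auc(lab, p)
  bt <- best_threshold_by_tss(lab, p)
  at <- compute_tss(lab, p, bt$threshold)
  structure(list(tss = bt$tss, auc = auc, optimal_threshold = bt$threshold,
                 sensitivity = at$sensitivity, specificity = at$specificity,
                 confusion = at$confusion, n = length(lab)),
            class = "sdm_evaluation")
}

#' @export
print.sdm_evaluation <- function(x, ...) {
  cat(sprintf("<sdm_evaluation> TSS %.3f (threshold %.3f), AUC %.3f, n = %d\n",
              x$tss, x$optimal_threshold, x$auc, x$n))
  invisible(x)
}

#' @export
tidy.sdm_evaluation <- function(x, ...) {
  tibble::tibble(tss = x$tss, auc = x$auc,
                 optimal_threshold = x$optimal_threshold,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 tp = x$confusion[["TP"]], fp = x$confusion[["FP"]],
                 tn = x$confusion[["TN"]], fn = x$confusion[["FN"]], n = x$n)
}
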