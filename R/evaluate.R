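#' Confusion counts for multiplet calls
#'
#' Multiplet is the positive class: a true positive is a droplet called
#' multiplet that truly is one.
#'
#' @param pred_calls,true_calls Character vectors in
#'   `{"singlet", "multiplet"}`, equal length.
#' @return Named integer vector `c(tp, fp, fn, tn)` partitioning `n`.
#' @export
confusion_counts <- function(pred_calls, true_calls) {
  stopifnot(length(pred_calls) == length(true_calls))
  ok <- c("singlet", "multiplet")
  if (!all(pred_calls %in% ok) || !all(true_calls %in% ok)) {
    stop('calls must be "singlet" or "multiplet"', call. = FALSE)
  }
  pred_pos <- pred_calls == "multiplet"
  true_pos <- true_calls == "multiplet"
  c(tp = sum(pred_pos & true_pos), fp = sum(pred_pos & !true_pos),
    fn = sum(!pred_pos & true_pos), tn = sum(!pred_pos & !true_pos))
}

#' F1 score
#'
#' Harmonic mean of precision and recall,
#' `2 * precision * recall / (precision + recall)`; defined as 0 when both
#' are 0.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Area under the precision-recall curve
#'
#' Traces the PR step curve by descending score threshold, grouping tied
#' scores, and accumulates `sum over thresholds of (R_i - R_{i-1}) * P_i`
#' (step interpolation). Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores Continuous multiplet scores (higher = more multiplet-like;
#'   typically `1 - P(K = 0)`).
#' @param true_calls Character vector in `{"singlet", "multiplet"}`.
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, true_calls) {
  stopifnot(length(scores) == length(true_calls), all(is.finite(scores)))
  pos <- true_calls == "multiplet"
  P <- sum(pos)
  if (P == 0) stop("no positive (multiplet) labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  last_of_group <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(y)[last_of_group]
  np <- seq_along(s)[last_of_group]
  recall <- tp / P
  precision <- tp / np
  sum(diff(c(0, recall)) * precision)
}

#' Score multiplet predictions against ground-truth labels
#'
#' @param pred_calls,true_calls Character vectors in
#'   `{"singlet", "multiplet"}`.
#' @param scores Optional continuous multiplet scores for AUPRC.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `f1`, `auprc` (`NA` when `scores` is omitted). Precision/recall are `NA`
#'   when undefined; `f1` is `NA` when there are no positives at all.
#' @export
evaluate_calls <- function(pred_calls, true_calls, scores = NULL) {
  cc <- confusion_counts(pred_calls, true_calls)
  tp <- cc[["tp"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]; tn <- cc[["tn"]]
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (tp + fn == 0 && fp == 0) {
    NA_real_ # no positives anywhere: undefined, not zero
  } else if (tp == 0) {
    0
  } else {
    f1_score(precision, recall)
  }
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall, f1 = f1,
    auprc = if (is.null(scores)) NA_real_ else auprc(scores, true_calls)
  )
}
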