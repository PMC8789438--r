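#' Detection metrics for imbalanced two-class trials
#'
#' Computes the confusion counts and the four detection measures used for
#' imbalanced target detection: accuracy `(TP+TN)/n`, hit rate (recall on
#' targets `TP/(TP+FN)`), false-alarm rate (`FP/(FP+TN)`), and F1
#' (`2PR/(P+R)` with precision `P = TP/(TP+FP)`; defined as 0 when
#' `TP = 0`).  F1 is the headline measure: with roughly five nontargets per
#' target, accuracy alone rewards never answering "target".
#'
#' @param pred_labels,true_labels Equal-length binary vectors
#'   (1 target / 0 nontarget).
#' @return A `detection_metrics` list: `accuracy`, `hit_rate`,
#'   `false_alarm_rate`, `f1`, and counts `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' compute_metrics(c(1, 0, 1, 0), c(1, 0, 0, 0))
compute_metrics <- function(pred_labels, true_labels) {
  if (length(pred_labels) == 0) stop("empty prediction vector")
  if (length(pred_labels) != length(true_labels))
    stop("prediction/truth length mismatch")
  if (!all(pred_labels %in% c(0, 1)) || !all(true_labels %in% c(0, 1)))
    stop("labels must be binary")
  tp <- sum(pred_labels == 1 & true_labels == 1)
  fp <- sum(pred_labels == 1 & true_labels == 0)
  tn <- sum(pred_labels == 0 & true_labels == 0)
  fn <- sum(pred_labels == 0 & true_labels == 1)
  n_t <- tp + fn; n_nt <- fp + tn
  hit <- if (n_t > 0) tp / n_t else NA_real_
  fa <- if (n_nt > 0) fp / n_nt else NA_real_
  f1 <- if (tp == 0) 0 else {
    prec <- tp / (tp + fp)
    2 * prec * hit / (prec + hit)
  }
  m <- list(accuracy = (tp + tn) / length(pred_labels),
            hit_rate = hit, false_alarm_rate = fa, f1 = f1,
            tp = tp, fp = fp, tn = tn, fn = fn)
  class(m) <- "detection_metrics"
  m
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf(
    "detection metrics: accuracy %.2f | hit %.2f | false alarm %.2f | F1 %.2f\n",
    x$accuracy, x$hit_rate, x$false_alarm_rate, x$f1))
  cat(sprintf("  counts: TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn,
              x$fn))
  invisible(x)
}

#' Reconstruct detection metrics from printed hit/false-alarm rates
#'
#' Rebuilds the confusion counts implied by a (hit rate, false-alarm rate)
#' pair under a given class composition — `TP = round(hit * n_target)`,
#' `FP = round(fa * n_nontarget)` (half away from zero) — and derives the
#' remaining measures exactly as [compute_metrics()] would.  Useful for
#' checking the internal consistency of published performance tables.
#'
#' @param hit,fa Hit and false-alarm rates in `[0, 1]`.
#' @param n_target,n_nontarget Class composition (positive counts).
#' @return A `detection_metrics`.
#' @export
#' @examples
#' metrics_from_rates(0.72, 0.05, 100, 521)
metrics_from_rates <- function(hit, fa, n_target, n_nontarget) {
  if (hit < 0 || hit > 1 || fa < 0 || fa > 1) stop("rates must be in [0, 1]")
  if (n_target <= 0 || n_nontarget <= 0) stop("counts must be positive")
  tp <- round_half_up(hit * n_target, 0)
  fp <- round_half_up(fa * n_nontarget, 0)
  pred <- c(rep(1, tp), rep(0, n_target - tp),
            rep(1, fp), rep(0, n_nontarget - fp))
  truth <- rep(c(1, 0), c(n_target, n_nontarget))
  compute_metrics(pred, truth)
}

#' Round half away from zero
#'
#' Deterministic half-up rounding used for reported tables (2 decimals by
#' convention), avoiding banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
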