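## Classification metrics used across evaluation reports.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with tie correction; equivalent to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric vector of risk scores.
#' @param labels 0/1 (or logical) outcome vector.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) average precision: the sum over descending
#' score thresholds of precision times the increment in recall.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || n_pos == length(labels)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(1L - lab)
  ## evaluate at the last index of each tied score block
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(prec * diff(c(0, rec)))
}

#' F1 score from sensitivity and precision
#'
#' Harmonic mean of sensitivity (recall) and positive predictive value
#' (precision): `2 * sens * ppv / (sens + ppv)`.
#'
#' @param sensitivity,ppv rates in \[0, 1\].
#' @return F1 in \[0, 1\]; 0 when both inputs are 0.
#' @export
f1_score <- function(sensitivity, ppv) {
  ifelse(sensitivity + ppv == 0, 0, 2 * sensitivity * ppv / (sensitivity + ppv))
}

## confusion counts -> named rates; counts are encounter level
confusion_metrics <- function(tp, fp, fn, tn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv  <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv  <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       f1 = if (!is.na(sens) && !is.na(ppv)) f1_score(sens, ppv) else NA_real_)
}

## median [IQR] summary with type-7 quantiles, as used for EWT reporting
median_iqr <- function(x) {
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
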