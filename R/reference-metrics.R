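#' Reference held-out test metrics of the four model variants
#'
#' Held-out test-set performance reported for Models A-D on the original
#' single-center PICU development cohort (n = 13,651 encounters, 8.6% MV
#' prevalence), bundled as input data. Used for internal-consistency checks
#' of the metric definitions (for example that the reported F1 equals the
#' harmonic mean of the reported sensitivity and precision); the cohort
#' itself is not distributable, so these values are not recomputed here.
#'
#' @return data.table with one row per model (A-D): auroc, auprc,
#'   sensitivity, specificity, ppv, npv, f1, ewt_median, ewt_q1, ewt_q3.
#' @export
reference_test_metrics <- function() {
  data.table::data.table(
    model = c("A", "B", "C", "D"),
    auroc = c(0.89, 0.86, 0.85, 0.84),
    auprc = c(0.55, 0.46, 0.45, 0.43),
    sensitivity = c(0.47, 0.43, 0.47, 0.56),
    specificity = c(0.96, 0.95, 0.94, 0.89),
    ppv = c(0.54, 0.45, 0.42, 0.33),
    npv = c(0.95, 0.95, 0.95, 0.96),
    f1 = c(0.50, 0.44, 0.44, 0.41),
    ewt_median = c(9.9, 40.2, 55.2, 6.2),
    ewt_q1 = c(4.2, 11.0, 14.1, 3.6),
    ewt_q3 = c(69.2, 134.3, 151.1, 38.3))
}

#' Reference risk-group metrics
#'
#' Per-risk-group positive predictive value and early warning time reported
#' for the development cohort's held-out test set (Model A), bundled for
#' qualitative comparison with synthetic-cohort runs.
#'
#' @return data.table with one row per risk group.
#' @export
reference_risk_group_metrics <- function() {
  data.table::data.table(
    group = c("low", "medium", "high"),
    n_positive_predictions = c(52L, 106L, 49L),
    ppv = c(0.12, 0.57, 0.92),
    ewt_median = c(43.8, 21.3, 6.0),
    ewt_q1 = c(14.3, 5.1, 3.2),
    ewt_q3 = c(66.1, 111.8, 39.5))
}
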