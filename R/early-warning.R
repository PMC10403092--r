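## Threshold selection, early prediction point (EPP) and early warning time
## (EWT) computation, encounter-level evaluation, and the PEWS comparators.

#' Threshold policy for encounter-level alerting
#'
#' Schemes: `single` (first crossing of `tau`), `dual_threshold` (a crossing
#' of `tau` arms a clock; the encounter is positive only if `tau2 >= tau` is
#' crossed within `inter_threshold_hours`, and the EPP is that second
#' crossing), and `waiting_period` (a crossing counts only if the score
#' stays at or above `tau` for `wait_hours` of consecutive grid points; the
#' EPP is the first point of the sustained run).
#'
#' @param scheme one of "single", "dual_threshold", "waiting_period".
#' @param tau primary threshold in (0, 1).
#' @param tau2 secondary threshold (dual scheme), must satisfy `tau2 >= tau`.
#' @param inter_threshold_hours window between the two crossings (default 6).
#' @param wait_hours sustained-run length for the waiting scheme (default 1).
#' @return object of class `threshold_policy`.
#' @export
threshold_policy <- function(scheme = c("single", "dual_threshold",
                                        "waiting_period"),
                             tau, tau2 = NULL, inter_threshold_hours = 6,
                             wait_hours = 1) {
  scheme <- match.arg(scheme)
  check_fraction(tau, "tau")
  if (scheme == "dual_threshold") {
    check_fraction(tau2, "tau2")
    if (tau2 < tau) stop_field("tau2", "dual scheme requires tau2 >= tau")
  }
  structure(list(scheme = scheme, tau = tau, tau2 = tau2,
                 inter_threshold_hours = check_pos(inter_threshold_hours,
                                                   "inter_threshold_hours"),
                 wait_hours = check_pos(wait_hours, "wait_hours")),
            class = "threshold_policy")
}

#' Select the risk-score threshold by maximum F1
#'
#' Evaluates every unique score value as a candidate threshold for the rule
#' `score >= tau` and returns the one maximizing F1; ties break toward the
#' higher threshold (higher specificity).
#'
#' @param scores numeric scores.
#' @param labels 0/1 outcomes (both classes required).
#' @return list with `tau` and `f1`.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (length(unique(scores)) < 2L)
    stop("degenerate constant scores: no threshold separates anything")
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]; lab <- labels[ord]
  tp <- cumsum(lab); fp <- cumsum(1L - lab)
  n_pos <- sum(lab)
  ## candidate thresholds are the unique score values; the rule score >= tau
  ## classifies every element of a tied block identically, so evaluate at
  ## block ends
  last <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  f1 <- 2 * tp[last] / (2 * tp[last] + fp[last] + (n_pos - tp[last]))
  best <- max(f1)
  ## ties toward higher tau = earlier block in descending order
  pick <- which(f1 >= best - 1e-12)[1]
  list(tau = sc[last[pick]], f1 = best)
}

#' Compute the early prediction point of a risk-score series
#'
#' The EPP is the first grid time at which the series satisfies the
#' threshold policy; `NA` if it never does (negative encounter prediction).
#'
#' @param times grid times (minutes, ascending).
#' @param scores risk scores on the grid.
#' @param policy a [threshold_policy()].
#' @return EPP time in minutes, or `NA_real_`.
#' @export
compute_epp <- function(times, scores, policy) {
  stopifnot(inherits(policy, "threshold_policy"), length(times) == length(scores))
  if (!length(times)) return(NA_real_)
  above <- scores >= policy$tau
  if (policy$scheme == "single") {
    i <- which(above)[1]
    return(if (is.na(i)) NA_real_ else times[i])
  }
  if (policy$scheme == "dual_threshold") {
    win <- policy$inter_threshold_hours * 60
    above2 <- scores >= policy$tau2
    i <- which(above)[1]
    while (!is.na(i)) {
      j <- which(above2 & times >= times[i] & times <= times[i] + win)[1]
      if (!is.na(j)) return(times[j])
      ## re-arm at the first crossing after this window expires
      i <- which(above & times > times[i] + win)[1]
    }
    return(NA_real_)
  }
  ## waiting_period: sustained run covering wait_hours
  need <- policy$wait_hours * 60
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (b in which(r$values)) {
    if (times[ends[b]] - times[starts[b]] >= need) return(times[starts[b]])
  }
  NA_real_
}

#' Early warning time
#'
#' Interval in hours between the EPP and MV onset; defined only for MV
#' encounters with an EPP (true positives).
#'
#' @param epp EPP time(s) in minutes (`NA` for negative predictions).
#' @param mv_onset MV onset time(s) in minutes (`NA` for no-MV encounters).
#' @return EWT in hours (`NA` where undefined).
#' @export
compute_ewt <- function(epp, mv_onset) {
  (mv_onset - epp) / 60
}

#' Encounter-level evaluation report
#'
#' Confusion counts from the encounter predictions (positive iff an EPP
#' exists), AUROC/AUPRC on the per-encounter maximum risk score over the
#' evaluation span, the rate metrics, F1, and the EWT median \[IQR\] over
#' true positives.
#'
#' @param max_scores per-encounter maximum risk score.
#' @param epps per-encounter EPP (minutes; `NA` = negative prediction).
#' @param mv_flag per-encounter outcome.
#' @param mv_onset per-encounter MV onset time (minutes; `NA` for no-MV).
#' @param tau threshold recorded in the report.
#' @return object of class `mv_eval_report`.
#' @export
evaluate_encounters <- function(max_scores, epps, mv_flag, mv_onset,
                                tau = NA_real_) {
  n <- length(mv_flag)
  if (!n) stop("empty evaluation set")
  pred <- !is.na(epps)
  mv_flag <- as.logical(mv_flag)
  tp <- sum(pred & mv_flag); fp <- sum(pred & !mv_flag)
  fn <- sum(!pred & mv_flag); tn <- sum(!pred & !mv_flag)
  cm <- confusion_metrics(tp, fp, fn, tn)
  ewt <- compute_ewt(epps[pred & mv_flag], mv_onset[pred & mv_flag])
  roc_auc <- if (tp + fn > 0 && fp + tn > 0)
    as.numeric(pROC::auc(pROC::roc(response = as.integer(mv_flag),
                                   predictor = max_scores,
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  else NA_real_
  pr_auc <- if (tp + fn > 0 && fp + tn > 0) auprc(max_scores, mv_flag)
            else NA_real_
  structure(c(list(threshold = tau, n = n, auroc = roc_auc, auprc = pr_auc),
              cm, list(ewt_hours = median_iqr(ewt), ewt_values = ewt)),
            class = "mv_eval_report")
}

#' @export
print.mv_eval_report <- function(x, ...) {
  cat(sprintf("Encounter-level evaluation (n = %d, threshold = %s)\n", x$n,
              if (is.na(x$threshold)) "-" else format(round(x$threshold, 4))))
  cat(sprintf("  confusion: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  AUROC %.3f  AUPRC %.3f\n", x$auroc, x$auprc))
  cat(sprintf("  sens %.2f  spec %.2f  PPV %.2f  NPV %.2f  F1 %.2f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv, x$f1))
  e <- x$ewt_hours
  cat(sprintf("  EWT median [IQR]: %.1f [%.1f-%.1f] h over %d true positives\n",
              e["median"], e["q1"], e["q3"], length(x$ewt_values)))
  invisible(x)
}

#' PEWS comparator classifiers
#'
#' Two reference classifiers built from recorded Pediatric Early Warning
#' Scores (consumed as input data; the PEWS rubric is not recomputed):
#' (i) the max-PEWS rule -- positive iff the maximum PEWS until MV onset
#' (cases) or over the stay (controls) exceeds `tau_max`, with lead time
#' from the first exceedance; and (ii) the daily-PEWS rule -- per 24-hour
#' interval, positive iff the interval maximum exceeds `tau_daily`, with
#' the label indicating MV onset within the following 24 hours.
#'
#' @param observations observation table containing `variable == "pews"`
#'   rows (or any table with encounter_id/time/value for PEWS).
#' @param encounters encounter table.
#' @param tau_max threshold for the max-PEWS rule (positive iff PEWS >
#'   `tau_max`).
#' @param tau_daily threshold for the daily-PEWS rule.
#' @return list with `max_pews` (an `mv_eval_report` plus lead-time summary)
#'   and `daily_pews` (interval-level report), or `NULL` with a warning if
#'   no PEWS stream is present.
#' @export
pews_comparator <- function(observations, encounters, tau_max = 5,
                            tau_daily = 6) {
  obs <- data.table::as.data.table(observations)
  pews <- obs[variable == "pews", .(encounter_id, time, pews = value)]
  if (!nrow(pews)) {
    warning("no PEWS stream found; skipping PEWS comparator")
    return(NULL)
  }
  enc <- data.table::as.data.table(encounters)
  pews <- merge(pews, enc[, .(encounter_id, mv_flag, mv_onset_time,
                              discharge_time)], by = "encounter_id")
  ## (i) max-PEWS until onset (cases) / over LOS (controls)
  span <- pews[is.na(mv_onset_time) | !mv_flag | time < mv_onset_time]
  mx <- span[, .(max_pews = max(pews)), by = encounter_id]
  mx <- merge(enc[, .(encounter_id, mv_flag, mv_onset_time)], mx,
              by = "encounter_id", all.x = TRUE)
  mx[is.na(max_pews), max_pews := 0]
  first_hit <- span[pews > tau_max, .(hit = min(time)), by = encounter_id]
  mx <- merge(mx, first_hit, by = "encounter_id", all.x = TRUE)
  epp <- ifelse(mx$max_pews > tau_max, ifelse(is.na(mx$hit), 0, mx$hit), NA_real_)
  max_report <- evaluate_encounters(mx$max_pews, epp, mx$mv_flag,
                                    mx$mv_onset_time, tau = tau_max)

  ## (ii) daily-PEWS: 24-h interval maxima predict MV in the following 24 h
  pews[, day := floor(time / 1440)]
  span_end <- ifelse(pews$mv_flag & !is.na(pews$mv_onset_time),
                     pews$mv_onset_time, pews$discharge_time)
  daily <- pews[time < span_end, .(day_max = max(pews)), by = .(encounter_id, day)]
  daily <- merge(daily, enc[, .(encounter_id, mv_flag, mv_onset_time)],
                 by = "encounter_id")
  daily[, label := as.integer(mv_flag & !is.na(mv_onset_time) &
                                mv_onset_time >= (day + 1) * 1440 &
                                mv_onset_time < (day + 2) * 1440)]
  daily[, pred := day_max > tau_daily]
  cm <- confusion_metrics(tp = daily[, sum(pred & label == 1L)],
                          fp = daily[, sum(pred & label == 0L)],
                          fn = daily[, sum(!pred & label == 1L)],
                          tn = daily[, sum(!pred & label == 0L)])
  d_auroc <- if (length(unique(daily$label)) > 1L) auroc(daily$day_max, daily$label)
             else NA_real_
  d_auprc <- if (length(unique(daily$label)) > 1L) auprc(daily$day_max, daily$label)
             else NA_real_
  ## lead time: first PEWS > tau_daily on the day prior to MV onset
  onset_day <- enc[mv_flag & !is.na(mv_onset_time),
                   .(encounter_id, mv_onset_time, prior = floor(mv_onset_time / 1440) - 1)]
  lead <- merge(pews[pews > tau_daily], onset_day, by = "encounter_id")
  lead <- lead[day == prior, .(first = min(time)), by = .(encounter_id)]
  lead <- merge(lead, onset_day, by = "encounter_id")
  lead_h <- (lead$mv_onset_time - lead$first) / 60

  list(max_pews = max_report,
       daily_pews = c(cm, list(auroc = d_auroc, auprc = d_auprc,
                               n_intervals = nrow(daily),
                               lead_hours = median_iqr(lead_h))))
}
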