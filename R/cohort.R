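## Cohort construction: the study inclusion/exclusion flowchart, MV
## preparation-window labeling, and the stratified train/test split.

VITAL_VARIABLES <- c("heart_rate", "resp_rate", "spo2", "sbp", "dbp", "temp")

#' Cohort filter configuration
#'
#' Thresholds for the inclusion/exclusion flowchart: age range 0-21 years,
#' MV onset at least 12 h after admission, MV duration at least 12 h, MV
#' onset not within 90 minutes after a documented procedure, the cyanotic
#' baseline-SpO2 rule (< 90% for at least 75% of the stay), the required
#' discharge diagnosis categories for MV cases, and the 30-minute MV
#' preparation window.
#'
#' @param min_age_years,max_age_years inclusion age range in years.
#' @param mv_min_hours_after_admit minimum MV onset delay (hours).
#' @param mv_min_duration_hours minimum MV duration (hours).
#' @param procedure_window_minutes exclusion window after a procedure.
#' @param spo2_baseline_threshold SpO2 threshold (%) for the cyanotic rule.
#' @param spo2_fraction_of_stay fraction of stay below threshold that
#'   triggers exclusion.
#' @param required_diagnosis_categories at least one must be present for MV
#'   cases.
#' @param prep_window_minutes MV preparation window before onset.
#' @return object of class `cohort_filter_config`.
#' @export
cohort_filter_config <- function(min_age_years = 0, max_age_years = 21,
                                 mv_min_hours_after_admit = 12,
                                 mv_min_duration_hours = 12,
                                 procedure_window_minutes = 90,
                                 spo2_baseline_threshold = 90,
                                 spo2_fraction_of_stay = 0.75,
                                 required_diagnosis_categories =
                                   c("respiratory", "cardiovascular", "sepsis"),
                                 prep_window_minutes = 30) {
  stopifnot(min_age_years >= 0, max_age_years > min_age_years,
            mv_min_hours_after_admit > 0, mv_min_duration_hours > 0,
            procedure_window_minutes > 0, prep_window_minutes > 0,
            spo2_baseline_threshold > 0, spo2_baseline_threshold <= 100)
  check_fraction(spo2_fraction_of_stay, "spo2_fraction_of_stay")
  structure(as.list(environment()), class = "cohort_filter_config")
}

#' Apply the study inclusion/exclusion flowchart
#'
#' Evaluates the exclusion rules in flowchart order and removes each
#' encounter at the first rule that fires: missing demographics (age,
#' gender, weight, LOS), age outside 0-21 years, no recorded vital sign,
#' tracheostomy, cyanotic heart disease with baseline SpO2 below threshold
#' for at least the stated fraction of the stay (computed on the
#' LOCF-resampled SpO2 grid), documented ventilation-data errors, and -- for
#' MV cases -- onset within 12 h of admission, MV duration under 12 h, onset
#' within 90 minutes after a documented procedure, and absence of all
#' required diagnosis categories.
#'
#' @param encounters encounter table.
#' @param observations observation event table (vital-sign check and SpO2
#'   rule).
#' @param config a [cohort_filter_config()].
#' @return list with `retained` (encounter table subset) and `log`
#'   (data.table: `encounter_id`, `rule_id`, `reason`; one row per removed
#'   encounter, first rule that fired).
#' @export
apply_inclusion_exclusion <- function(encounters, observations,
                                      config = cohort_filter_config()) {
  check_columns(encounters, c("encounter_id", "age_years", "gender",
                              "weight_kg", "admit_time", "discharge_time",
                              "mv_flag", "mv_onset_time", "mv_end_time",
                              "trach_flag", "cyanotic_flag",
                              "diagnosis_categories", "procedure_times"),
                "encounters")
  check_columns(observations, c("encounter_id", "time", "variable"),
                "observations")
  enc <- data.table::as.data.table(encounters)
  obs <- data.table::as.data.table(observations)

  los <- enc$discharge_time - enc$admit_time
  has_vital <- enc$encounter_id %in%
    unique(obs$encounter_id[obs$variable %in% VITAL_VARIABLES])

  ## cyanotic baseline-SpO2 rule on the LOCF grid (grid-time-weighted;
  ## grid points before the first SpO2 observation do not count as low)
  low_spo2 <- rep(FALSE, nrow(enc))
  cand <- which(enc$cyanotic_flag)
  for (i in cand) {
    so <- obs[encounter_id == enc$encounter_id[i] & variable == "spo2"]
    if (!nrow(so)) next
    g <- suppressMessages(resample_locf(so, end_time = los[i]))
    frac <- mean(!is.na(g$spo2) & g$spo2 < config$spo2_baseline_threshold)
    low_spo2[i] <- frac >= config$spo2_fraction_of_stay
  }

  proc_list <- strsplit(ifelse(is.na(enc$procedure_times), "",
                               enc$procedure_times), ";", fixed = TRUE)
  post_proc <- vapply(seq_len(nrow(enc)), function(i) {
    if (!isTRUE(enc$mv_flag[i])) return(FALSE)
    p <- suppressWarnings(as.numeric(proc_list[[i]]))
    p <- p[!is.na(p)]
    any(enc$mv_onset_time[i] - p >= 0 &
          enc$mv_onset_time[i] - p <= config$procedure_window_minutes)
  }, TRUE)

  diag_ok <- vapply(strsplit(ifelse(is.na(enc$diagnosis_categories), "",
                                    enc$diagnosis_categories), ";", fixed = TRUE),
                    function(d) any(d %in% config$required_diagnosis_categories),
                    TRUE)
  data_error <- if ("data_error_flag" %in% names(enc)) enc$data_error_flag
                else rep(FALSE, nrow(enc))
  mv <- enc$mv_flag
  onset_delay <- enc$mv_onset_time - enc$admit_time
  mv_dur <- enc$mv_end_time - enc$mv_onset_time

  rules <- list(
    missing_demographics = list(
      fired = is.na(enc$age_years) | is.na(enc$gender) | is.na(enc$weight_kg) |
        is.na(los),
      reason = "missing age, gender, weight, or length of stay"),
    age_out_of_range = list(
      fired = !is.na(enc$age_years) &
        (enc$age_years < config$min_age_years | enc$age_years > config$max_age_years),
      reason = sprintf("age outside %g-%g years", config$min_age_years,
                       config$max_age_years)),
    no_vital_signs = list(
      fired = !has_vital, reason = "no recorded vital sign"),
    tracheostomy = list(
      fired = enc$trach_flag %in% TRUE, reason = "tracheostomy"),
    cyanotic_low_spo2 = list(
      fired = low_spo2,
      reason = sprintf("cyanotic with baseline SpO2 < %g%% for >= %g%% of stay",
                       config$spo2_baseline_threshold,
                       100 * config$spo2_fraction_of_stay)),
    ventilation_data_error = list(
      fired = data_error %in% TRUE,
      reason = "insufficient ventilation information / transcription error"),
    mv_within_12h = list(
      fired = mv & onset_delay < config$mv_min_hours_after_admit * 60,
      reason = sprintf("MV onset within %g h of admission",
                       config$mv_min_hours_after_admit)),
    mv_duration_lt_12h = list(
      fired = mv & mv_dur < config$mv_min_duration_hours * 60,
      reason = sprintf("MV duration < %g h", config$mv_min_duration_hours)),
    mv_post_procedure = list(
      fired = post_proc,
      reason = sprintf("MV onset within %g min after a documented procedure",
                       config$procedure_window_minutes)),
    mv_no_qualifying_diagnosis = list(
      fired = mv & !diag_ok,
      reason = "MV without respiratory/cardiovascular/sepsis diagnosis"))

  excluded_by <- rep(NA_character_, nrow(enc))
  for (rid in names(rules)) {
    fired <- rules[[rid]]$fired & is.na(excluded_by)
    excluded_by[fired] <- rid
  }
  log <- data.table::data.table(
    encounter_id = enc$encounter_id[!is.na(excluded_by)],
    rule_id = excluded_by[!is.na(excluded_by)])
  log[, reason := vapply(rule_id, function(r) rules[[r]]$reason, "")]
  list(retained = enc[is.na(excluded_by)], log = log[])
}

#' Label the MV preparation time
#'
#' The 30 minutes before MV onset are the preparation window, during which
#' intubation drugs are routinely administered; all grid samples in
#' `[prep_time, onset)` must be dropped from training and testing.
#'
#' @param encounter a single encounter row (must have `mv_flag = TRUE`).
#' @param prep_minutes preparation window length.
#' @return prep time in minutes since admission.
#' @export
label_mv_prep <- function(encounter, prep_minutes = 30L) {
  if (!isTRUE(all(encounter$mv_flag)))
    stop("label_mv_prep requires an MV encounter", call. = FALSE)
  encounter$mv_onset_time - prep_minutes
}

age_group_bins <- function(age) {
  cut(age, breaks = c(0, 1, 5, 12, 21.0001), right = FALSE,
      labels = c("<1", "1-4", "5-11", "12-21"), include.lowest = TRUE)
}

#' Stratified train/test split
#'
#' Randomly assigns `round(train_fraction * n)` encounters of every stratum
#' to the training set, stratifying by MV outcome, gender, age group
#' (<1, 1-4, 5-11, 12-21 years), and non-invasive ventilation status.
#' Strata of size 1 go to the training set with a warning.
#'
#' @param encounters encounter table with `mv_flag`, `gender`, `age_years`,
#'   `niv_flag`.
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with `train` and `test` encounter-id vectors (a partition).
#' @export
stratified_split <- function(encounters, train_fraction = 0.8, seed = 1L) {
  check_columns(encounters, c("encounter_id", "mv_flag", "gender",
                              "age_years", "niv_flag"), "encounters")
  check_fraction(train_fraction, "train_fraction")
  enc <- as.data.frame(encounters)
  strata <- interaction(enc$mv_flag, enc$gender, age_group_bins(enc$age_years),
                        enc$niv_flag, drop = TRUE)
  train <- character(0)
  with_seed(seed, {
    for (s in levels(strata)) {
      ids <- enc$encounter_id[which(strata == s)]
      if (length(ids) == 1L) {
        warning(sprintf("stratum '%s' has a single encounter; assigned to train", s))
        train <- c(train, ids)
      } else {
        n_tr <- round(train_fraction * length(ids))
        train <- c(train, sample(ids, n_tr))
      }
    }
  })
  list(train = sort(train), test = sort(setdiff(enc$encounter_id, train)))
}
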