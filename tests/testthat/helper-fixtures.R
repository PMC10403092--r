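## Shared fixtures, all generated in code. Expensive artifacts (the small
## module-test cohort and the full-scale pipeline runs used by the
## acceptance suite) are computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

## small synthetic cohort for module-level tests
small_cohort <- function() {
  cached("small_cohort",
         generate_cohort(generator_config(n_encounters = 400L, seed = 7L)))
}

small_filtered <- function() {
  cached("small_filtered", {
    coh <- small_cohort()
    filt <- apply_inclusion_exclusion(coh$encounters, coh$observations)
    split <- stratified_split(filt$retained, seed = 11L)
    list(cohort = coh, retained = filt$retained, log = filt$log, split = split)
  })
}

## hand-made three-encounter cohort exercising every feature path
toy_cohort <- function() {
  enc <- data.table::data.table(
    encounter_id = c("mv1", "ctl1", "ctl2"),
    age_years = c(2, 6, 0.5), gender = c("female", "male", "male"),
    race = "white", ethnicity = "non_hispanic",
    height_cm = c(90, NA, 62), weight_kg = c(12, 20, 6.5),
    admit_time = 0L, discharge_time = c(2000L, 1500L, 3000L),
    mv_flag = c(TRUE, FALSE, FALSE),
    mv_onset_time = c(1200L, NA, NA), mv_end_time = c(1990L, NA, NA),
    niv_flag = c(TRUE, FALSE, FALSE), trach_flag = FALSE,
    cyanotic_flag = FALSE, data_error_flag = FALSE,
    diagnosis_categories = c("respiratory;sepsis", "trauma", "neurologic"),
    procedure_times = c("", "400", ""), mv_severity = c(2L, NA, NA))
  obs <- data.table::data.table(
    encounter_id = rep(c("mv1", "ctl1", "ctl2"), times = c(4, 3, 2)),
    time = c(0L, 100L, 700L, 1100L, 0L, 500L, 1000L, 10L, 2000L),
    variable = c("heart_rate", "spo2", "resp_rate", "heart_rate",
                 "heart_rate", "spo2", "resp_effort", "heart_rate", "spo2"),
    value = c(120, 97, 45, 150, 95, 98, NA, 140, 96),
    value_cat = c(NA, NA, NA, NA, NA, NA, "labored", NA, NA))
  meds <- data.table::data.table(
    encounter_id = c("mv1", "mv1", "mv1", "ctl1", "ctl2"),
    time = c(300L, 800L, 1185L, 600L, 100L),
    medication = c("med_a", "med_a", "prep_sedative", "med_b", "med_a"),
    action = c("given", "rate changed", "given", "given", "given"),
    sequence_no = c(1L, 2L, 3L, 1L, 1L))
  list(encounters = enc, observations = obs, medications = meds)
}

## full-scale study-condition pipeline runs shared by the acceptance suite
acceptance_run <- function() {
  cached("acceptance_run", {
    cfg <- run_config(seed = 1L, n_encounters = 2000L, models = "A")
    suppressMessages(suppressWarnings(run_experiment(cfg)))
  })
}

acceptance_null_run <- function() {
  cached("acceptance_null_run", {
    cfg <- run_config(seed = 1L, n_encounters = 2000L, signal_strength = 0,
                      models = "A")
    suppressMessages(suppressWarnings(run_experiment(cfg)))
  })
}

## brute-force oracles -------------------------------------------------------

## last-event-at-or-before-t scan, the independent LOCF oracle
locf_oracle <- function(times, values, grid) {
  vapply(grid, function(t) {
    ok <- which(times <= t)
    if (!length(ok)) NA_real_ else values[max(ok)]
  }, numeric(1))
}

## brute-force max-F1 threshold search over all candidate cutpoints
f1_at <- function(tau, scores, labels) {
  pred <- scores >= tau
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

brute_force_best_f1 <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u, u - 1e-9, max(u) + 1)
  max(vapply(cand, f1_at, numeric(1), scores = scores, labels = labels))
}
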