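## Synthetic PICU cohort generator.
##
## Emulates the statistical structure the downstream pipeline assumes:
## ~8.6% MV prevalence, age/LOS contrasts between the MV and no-MV groups,
## NIV prevalence by group, irregular (inhomogeneous Poisson) observation
## timing, pre-MV physiologic drift, and medication sequences whose ordered
## patterns carry outcome signal. All timestamps are integer minutes since
## PICU admission.

#' Configuration for the synthetic PICU cohort generator
#'
#' All outcome-linked structure (demographic contrasts, physiologic drift,
#' medication escalation, charting-intensity boosts) is scaled by
#' `signal_strength / signal_reference`, so `signal_strength = 0` yields a
#' cohort in which the MV label is pure noise and a correct pipeline attains
#' chance-level discrimination, while the default produces the full
#' group contrasts.
#'
#' @param n_encounters number of PICU encounters to simulate.
#' @param mv_prevalence probability that an encounter receives invasive
#'   mechanical ventilation (default 1176/13651 = 8.61%).
#' @param seed integer seed; identical config + seed gives identical output.
#' @param med_vocab_size number of distinct medication names.
#' @param n_predictive_meds number of medications whose escalation sequences
#'   are enriched before MV onset.
#' @param signal_strength non-negative effect scale (log-odds-like units) of
#'   all planted outcome signal; 0 removes every group contrast.
#' @param signal_reference signal_strength value at which group contrasts
#'   reach their full (study-cohort) magnitudes.
#' @param obs_rate_per_hour base charting rate for vital signs (per hour);
#'   other variable classes scale from it via the feature dictionary.
#' @param med_rate_per_hour base medication event rate (per hour).
#' @param lead_minutes lead time before MV onset over which physiologic
#'   drift and medication escalation ramp up (default 12 h).
#' @param los_lognormal_params list with elements `mv` and `no_mv`, each
#'   `c(meanlog, sdlog)` for length of stay in minutes; defaults put the
#'   group medians at 19.4 and 3.1 days.
#' @param trajectory_archetypes number of severity archetypes among MV cases.
#' @param niv_prevalence_by_group named fractions `c(mv = , no_mv = )` for
#'   non-invasive ventilation prevalence.
#' @param p_mv_early fraction of MV cases with onset < 12 h after admission
#'   (present so cohort filters are exercised).
#' @param p_mv_short fraction of MV cases with MV duration < 12 h.
#' @param p_proc_near_onset fraction of MV cases with a documented procedure
#'   within 90 minutes before MV onset.
#' @param med_escalation_mult rate multiplier for pre-onset escalation
#'   medication events (scaled by signal and severity).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_encounters = 2000L,
                             mv_prevalence = 1176 / 13651,
                             seed = 1L,
                             med_vocab_size = 40L,
                             n_predictive_meds = 6L,
                             signal_strength = 2,
                             signal_reference = 2,
                             obs_rate_per_hour = 1,
                             med_rate_per_hour = 0.12,
                             lead_minutes = 720L,
                             los_lognormal_params = list(
                               mv = c(meanlog = log(19.4 * 1440), sdlog = 0.85),
                               no_mv = c(meanlog = log(3.1 * 1440), sdlog = 1.0)),
                             trajectory_archetypes = 3L,
                             niv_prevalence_by_group = c(mv = 0.284, no_mv = 0.107),
                             p_mv_early = 0.03,
                             p_mv_short = 0.02,
                             p_proc_near_onset = 0.02,
                             med_escalation_mult = 2.5) {
  cfg <- list(
    n_encounters = check_count(n_encounters, "n_encounters"),
    mv_prevalence = check_fraction(mv_prevalence, "mv_prevalence"),
    seed = check_count(seed, "seed", min = 0L),
    med_vocab_size = check_count(med_vocab_size, "med_vocab_size"),
    n_predictive_meds = check_count(n_predictive_meds, "n_predictive_meds"),
    signal_strength = check_nonneg(signal_strength, "signal_strength"),
    signal_reference = check_pos(signal_reference, "signal_reference"),
    obs_rate_per_hour = check_pos(obs_rate_per_hour, "obs_rate_per_hour"),
    med_rate_per_hour = check_pos(med_rate_per_hour, "med_rate_per_hour"),
    lead_minutes = check_count(lead_minutes, "lead_minutes"),
    los_lognormal_params = los_lognormal_params,
    trajectory_archetypes = check_count(trajectory_archetypes, "trajectory_archetypes"),
    niv_prevalence_by_group = niv_prevalence_by_group,
    p_mv_early = check_nonneg(p_mv_early, "p_mv_early"),
    p_mv_short = check_nonneg(p_mv_short, "p_mv_short"),
    p_proc_near_onset = check_nonneg(p_proc_near_onset, "p_proc_near_onset"),
    med_escalation_mult = check_pos(med_escalation_mult, "med_escalation_mult"))
  if (!all(c("mv", "no_mv") %in% names(cfg$los_lognormal_params)))
    stop_field("los_lognormal_params", "must have elements 'mv' and 'no_mv'")
  if (!all(c("mv", "no_mv") %in% names(cfg$niv_prevalence_by_group)))
    stop_field("niv_prevalence_by_group", "must be named c(mv=, no_mv=)")
  for (g in c("mv", "no_mv"))
    check_fraction(cfg$niv_prevalence_by_group[[g]], "niv_prevalence_by_group")
  if (cfg$n_predictive_meds > cfg$med_vocab_size)
    stop_field("n_predictive_meds", "cannot exceed med_vocab_size")
  structure(cfg, class = "generator_config")
}

## effect-scale interpolation factor in [0, 1]
signal_factor <- function(config) {
  min(1, config$signal_strength / config$signal_reference)
}

## linear pre-onset ramp: 0 outside (onset - lead, onset], rising to 1 at onset
drift_ramp <- function(t, onset, lead) {
  r <- 1 - (onset - t) / lead
  r[!is.finite(r)] <- 0
  pmin(pmax(r, 0), 1)
}

med_vocab <- function(config) sprintf("med_%03d", seq_len(config$med_vocab_size))

predictive_meds <- function(config) {
  ## mid-frequency slots of the Zipf-weighted vocabulary carry the signal
  start <- min(5L, config$med_vocab_size - config$n_predictive_meds + 1L)
  start <- max(1L, start)
  med_vocab(config)[seq(start, length.out = config$n_predictive_meds)]
}

#' Generate a synthetic PICU cohort
#'
#' Returns three long-format event tables keyed by `encounter_id`:
#' `encounters` (one row per stay: demographics, MV outcome and timing, flags,
#' diagnosis categories, procedure times), `observations` (timestamped
#' clinical variables, including PEWS under `variable == "pews"` and
#' input/output volumes), and `medications` (timestamped medication name +
#' action events with per-encounter `sequence_no`).
#'
#' MV encounters receive planted signal scaled by `signal_strength`:
#' physiologic drift (rising respiratory/heart rate and FiO2, falling SpO2)
#' ramping over `lead_minutes` before onset, enriched escalation sequences of
#' the predictive medications (ending predominantly in "rate changed"), and a
#' modest charting-intensity boost. Observation timing is an inhomogeneous
#' Poisson process. A small fraction of encounters deliberately violate
#' cohort inclusion rules so the filters are exercised.
#'
#' @param config a [generator_config()].
#' @return list with data.tables `encounters`, `observations`, `medications`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_encounters
  f <- signal_factor(config)
  prev <- config$mv_prevalence
  lead <- config$lead_minutes

  mv <- stats::rbinom(n, 1L, prev) == 1L
  n_mv <- sum(mv)
  eid <- sprintf("e%06d", seq_len(n))

  ## severity archetypes among MV cases drive drift magnitude
  n_arch <- config$trajectory_archetypes
  sev_level <- rep(NA_integer_, n)
  sev_level[mv] <- sample.int(n_arch, n_mv, replace = TRUE)
  sev_mult <- rep(NA_real_, n)
  if (n_arch == 1L) sev_mult[mv] <- 1
  else sev_mult[mv] <- 0.35 + 1.05 * (sev_level[mv] - 1) / (n_arch - 1)

  interp <- function(group_val, pooled) (1 - f) * pooled + f * group_val

  ## age: lognormal medians 1.2 (MV) vs 4.8 (no-MV) years at full signal
  pooled_age <- prev * log(1.2) + (1 - prev) * log(4.8)
  meanlog_age <- ifelse(mv, interp(log(1.2), pooled_age), interp(log(4.8), pooled_age))
  ## dispersions solved from the printed IQRs ([0.2-9] vs [1.1-12.4] years)
  sdlog_age <- ifelse(mv, 2.8, 1.65)
  age <- pmin(pmax(stats::rlnorm(n, meanlog_age, sdlog_age), 0.02), 21)

  ## LOS in minutes: group medians 19.4 vs 3.1 days at full signal
  lp <- config$los_lognormal_params
  pooled_los <- prev * lp$mv[["meanlog"]] + (1 - prev) * lp$no_mv[["meanlog"]]
  meanlog_los <- ifelse(mv, interp(lp$mv[["meanlog"]], pooled_los),
                        interp(lp$no_mv[["meanlog"]], pooled_los))
  sdlog_los <- ifelse(mv, lp$mv[["sdlog"]], lp$no_mv[["sdlog"]])
  los <- round(pmax(stats::rlnorm(n, meanlog_los, sdlog_los), 360))

  ## MV timing: onset mid-to-late stay, duration most of the remainder
  onset <- rep(NA_real_, n); mv_end <- rep(NA_real_, n)
  onset[mv] <- round(stats::runif(n_mv, 0.45, 0.80) * los[mv])
  early <- mv & stats::runif(n) < config$p_mv_early
  onset[early] <- pmin(round(stats::runif(sum(early), 60, 700)),
                       floor(0.8 * los[early]))
  onset[mv] <- pmax(onset[mv], 60)
  dur <- round((los[mv] - onset[mv]) * stats::runif(n_mv, 0.85, 0.97))
  short <- stats::runif(n_mv) < config$p_mv_short
  dur[short] <- round(stats::runif(sum(short), 2, 10) * 60)
  mv_end[mv] <- pmin(onset[mv] + pmax(dur, 30), los[mv])

  ## demographics
  gender <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.564, 0.436))
  race <- sample(c("white", "black", "asian", "pacific_islander", "other"),
                 n, replace = TRUE, prob = c(0.473, 0.063, 0.052, 0.014, 0.398))
  ethnicity <- sample(c("hispanic", "non_hispanic", "other"),
                      n, replace = TRUE, prob = c(0.480, 0.517, 0.003))
  niv_p <- config$niv_prevalence_by_group
  pooled_niv <- prev * niv_p[["mv"]] + (1 - prev) * niv_p[["no_mv"]]
  niv <- stats::runif(n) < ifelse(mv, interp(niv_p[["mv"]], pooled_niv),
                                  interp(niv_p[["no_mv"]], pooled_niv))

  ## anthropometrics from simple growth curves + noise; a few missing values
  ## (and a few missing demographics) so the inclusion filters have work to do
  wt_mu <- ifelse(age < 1, 3.5 + 6 * age, 2 * (age + 4))
  weight <- round(wt_mu * stats::rlnorm(n, 0, 0.18), 1)
  ht_mu <- ifelse(age < 1, 52 + 23 * age,
                  ifelse(age < 12, 75 + 5.8 * (age - 1), pmin(139 + 3.5 * (age - 12), 172)))
  height <- round(ht_mu * stats::rlnorm(n, 0, 0.05), 1)
  height[stats::runif(n) < 0.15] <- NA_real_
  weight[stats::runif(n) < 0.008] <- NA_real_
  age_out <- stats::runif(n) < 0.004
  age[age_out] <- NA_real_
  gender[stats::runif(n) < 0.003] <- NA_character_

  ## deteriorate-and-recover controls: a transient physiologic episode with
  ## the MV drift signature that resolves, so the score-based classifier
  ## faces genuine false-positive pressure (the source of the low-risk
  ## group's decaying trajectories)
  ep <- !mv & stats::runif(n) < 0.18
  ep_center <- ifelse(ep, stats::runif(n, 0.3, 0.8) * los, NA_real_)
  ep_half <- ifelse(ep, stats::runif(n, 2, 5) * 60, NA_real_)
  ep_sev <- ifelse(ep, stats::runif(n, 0.5, 1.2), NA_real_)

  trach <- stats::runif(n) < 0.015
  cyanotic_low <- stats::runif(n) < 0.010
  cyanotic <- cyanotic_low | stats::runif(n) < 0.010
  data_error <- stats::runif(n) < 0.005
  murmur <- stats::runif(n) < 0.10

  ## diagnosis categories (cohort-definition metadata, not model features)
  p_resp <- ifelse(mv, 0.85, 0.35)
  p_card <- ifelse(mv, 0.30, 0.15)
  p_seps <- ifelse(mv, 0.20, 0.05)
  diag <- mapply(function(r, cdv, s) {
    d <- c("respiratory", "cardiovascular", "sepsis")[c(stats::runif(1) < r,
                                                        stats::runif(1) < cdv,
                                                        stats::runif(1) < s)]
    extra <- c("neurologic", "gastrointestinal", "trauma", "oncology")
    d <- c(d, extra[stats::runif(4) < c(0.15, 0.10, 0.08, 0.05)])
    paste(d, collapse = ";")
  }, p_resp, p_card, p_seps)

  ## documented procedures; some MV onsets deliberately fall within 90 min
  n_proc <- stats::rpois(n, 0.6)
  proc_times <- lapply(seq_len(n), function(i)
    if (n_proc[i] > 0) sort(round(stats::runif(n_proc[i], 0, los[i]))) else numeric(0))
  near <- which(mv & stats::runif(n) < config$p_proc_near_onset)
  for (i in near)
    proc_times[[i]] <- sort(c(proc_times[[i]], max(0, onset[i] - round(stats::runif(1, 5, 85)))))

  encounters <- data.table::data.table(
    encounter_id = eid, age_years = age, gender = gender, race = race,
    ethnicity = ethnicity, height_cm = height, weight_kg = weight,
    admit_time = 0L, discharge_time = as.integer(los),
    mv_flag = mv, mv_onset_time = as.integer(round(onset)),
    mv_end_time = as.integer(round(mv_end)),
    niv_flag = niv, trach_flag = trach, cyanotic_flag = cyanotic,
    ctrl_episode_flag = ep,
    data_error_flag = data_error,
    diagnosis_categories = diag,
    procedure_times = vapply(proc_times, function(p) paste(p, collapse = ";"), ""),
    mv_severity = sev_level)

  episode <- list(center = ep_center, half = ep_half, sev = ep_sev)
  observations <- generate_observations(config, encounters, f, sev_mult,
                                        cyanotic_low, murmur, episode)
  medications <- generate_medications(config, encounters, f, sev_mult, episode)

  list(encounters = encounters[], observations = observations,
       medications = medications)
}

## inhomogeneous Poisson event times on [0, los) by thinning:
## base rate boosted 1.5x in the first 24 h (admission workup) and
## (1 + 0.5 * f * sev) in the pre-onset lead window of MV cases
obs_event_times <- function(rate_per_h, los, onset, lead, f, sev) {
  n <- length(los)
  boost <- 1 + 0.5 * f * ifelse(is.na(sev), 0, sev)
  max_mult <- 1.5 * pmax(boost, 1)
  lambda <- rate_per_h * (los / 60) * max_mult
  counts <- stats::rpois(n, lambda)
  idx <- rep.int(seq_len(n), counts)
  t <- stats::runif(length(idx)) * los[idx]
  mult <- ifelse(t < 1440, 1.5, 1)
  in_lead <- !is.na(onset[idx]) & t > (onset[idx] - lead) & t <= onset[idx]
  mult <- mult * ifelse(in_lead, boost[idx], 1)
  keep <- stats::runif(length(idx)) < mult / max_mult[idx]
  list(idx = idx[keep], time = round(t[keep]))
}

generate_observations <- function(config, enc, f, sev_mult, cyanotic_low,
                                  murmur, episode) {
  ## triangular transient-episode shape for deteriorate-and-recover controls
  episode_shape <- function(t, i) {
    sh <- 1 - abs(t - episode$center[i]) / episode$half[i]
    sh[is.na(sh) | sh < 0] <- 0
    sh * ifelse(is.na(episode$sev[i]), 0, episode$sev[i])
  }
  dict <- default_feature_dictionary()
  nrt <- default_normal_ranges()
  los <- as.numeric(enc$discharge_time)
  onset <- as.numeric(enc$mv_onset_time)
  age <- ifelse(is.na(enc$age_years), 4, enc$age_years)
  lead <- config$lead_minutes
  out <- vector("list", nrow(dict) + 1L)

  for (r in seq_len(nrow(dict))) {
    v <- dict$variable[r]
    ev <- obs_event_times(dict$obs_rate_mult[r] * config$obs_rate_per_hour,
                          los, onset, lead, f, sev_mult)
    i <- ev$idx; t <- ev$time
    if (!length(i)) { out[[r]] <- NULL; next }
    ## severity-linked aberration: sicker MV cases deviate persistently over
    ## the whole stay, with an acute ramp over the pre-onset lead window
    sevv <- ifelse(is.na(sev_mult[i]), 0, sev_mult[i])
    acute <- drift_ramp(t, onset[i], lead)
    eps_sh <- episode_shape(t, i)
    ramp <- f * (sevv * (0.12 + 0.88 * acute) + eps_sh)
    if (dict$type[r] == "numeric") {
      ms <- norm_lookup(nrt, v, age[i])
      b <- stats::rnorm(nrow(enc), 0, 0.45)
      ## not every case expresses every drift channel
      expr <- stats::runif(nrow(enc)) < 0.7
      ramp_v <- f * (sevv * expr[i] * (0.12 + 0.88 * acute) + eps_sh)
      val <- ms$mu + ms$sigma * (b[i] + stats::rnorm(length(i), 0, 0.6) +
                                   dict$drift_sd_units[r] * ramp_v)
      if (v == "spo2") {
        val <- ifelse(cyanotic_low[i], 85 + stats::rnorm(length(i), 0, 2), val)
        val <- pmin(val, 100)
      }
      if (v == "fio2") val <- pmax(val, 0.21)
      if (v %in% c("wbc", "lactate", "bilirubin")) val <- pmax(val, 0.05)
      out[[r]] <- data.table::data.table(encounter_id = enc$encounter_id[i],
                                         time = as.integer(t), variable = v,
                                         value = round(val, 2), value_cat = NA_character_)
    } else if (dict$type[r] == "categorical" && v == "resp_effort") {
      base <- c(normal = 0.80, labored = 0.12, tachypneic = 0.08)
      w <- matrix(base, nrow = length(i), ncol = 3, byrow = TRUE)
      w[, 2] <- w[, 2] * exp(1.0 * ramp)
      w[, 3] <- w[, 3] * exp(1.4 * ramp)
      w <- w / rowSums(w)
      u <- stats::runif(length(i))
      lev <- c("normal", "labored", "tachypneic")
      pick <- 1L + (u > w[, 1]) + (u > w[, 1] + w[, 2])
      out[[r]] <- data.table::data.table(encounter_id = enc$encounter_id[i],
                                         time = as.integer(t), variable = v,
                                         value = NA_real_, value_cat = lev[pick])
    } else if (dict$type[r] == "categorical" && v == "heart_sounds") {
      p_mur <- ifelse(murmur[i], 0.9, 0.02)
      out[[r]] <- data.table::data.table(encounter_id = enc$encounter_id[i],
                                         time = as.integer(t), variable = v,
                                         value = NA_real_,
                                         value_cat = ifelse(stats::runif(length(i)) < p_mur,
                                                            "murmur", "normal"))
    } else if (dict$type[r] == "io") {
      base_vol <- if (v == "iv_volume_in") 40 else 60
      mult <- if (v == "iv_volume_in") (1 + 1.0 * ramp) else pmax(1 - 0.4 * ramp, 0.2)
      vol <- stats::rlnorm(length(i), log(base_vol), 0.5) * mult
      out[[r]] <- data.table::data.table(encounter_id = enc$encounter_id[i],
                                         time = as.integer(t), variable = v,
                                         value = round(vol, 1), value_cat = NA_character_)
    }
  }

  ## PEWS roughly every 4 h, drifting up in the final 24 h before MV onset
  ev <- obs_event_times(0.25, los, onset, lead, f, sev_mult)
  i <- ev$idx; t <- ev$time
  ramp24 <- f * (drift_ramp(t, onset[i], 1440) *
                   ifelse(is.na(sev_mult[i]), 0, sev_mult[i]) +
                   episode_shape(t, i))
  pews <- pmin(stats::rpois(length(i), 2) + round(ramp24 * stats::runif(length(i), 1, 4)), 9)
  out[[nrow(dict) + 1L]] <- data.table::data.table(
    encounter_id = enc$encounter_id[i], time = as.integer(t), variable = "pews",
    value = as.numeric(pews), value_cat = NA_character_)

  obs <- data.table::rbindlist(out[!vapply(out, is.null, TRUE)])
  data.table::setorder(obs, encounter_id, time, variable)
  obs[]
}

generate_medications <- function(config, enc, f, sev_mult, episode) {
  vocab <- med_vocab(config)
  pred <- predictive_meds(config)
  zipf <- (1 / seq_along(vocab)^0.8); zipf <- zipf / sum(zipf)
  los <- as.numeric(enc$discharge_time)
  onset <- as.numeric(enc$mv_onset_time)
  lead <- config$lead_minutes
  n <- nrow(enc)

  ## baseline medication stream
  counts <- stats::rpois(n, config$med_rate_per_hour * los / 60)
  idx <- rep.int(seq_len(n), counts)
  t <- round(stats::runif(length(idx)) * los[idx])
  med <- sample(vocab, length(idx), replace = TRUE, prob = zipf)
  esc <- rep(FALSE, length(idx))

  ## escalation stream on predictive meds in the pre-onset lead window
  mvw <- which(enc$mv_flag)
  sev <- ifelse(is.na(sev_mult), 0, sev_mult)
  lam_esc <- config$med_rate_per_hour * config$med_escalation_mult * f *
    sev[mvw] * pmin(lead, onset[mvw]) / 60
  c2 <- stats::rpois(length(mvw), lam_esc)
  idx2 <- rep.int(mvw, c2)
  t2 <- round(onset[idx2] - stats::runif(length(idx2)) * pmin(lead, onset[idx2]))
  med2 <- sample(pred, length(idx2), replace = TRUE)

  ## transient escalation burst for deteriorate-and-recover controls
  epw <- which(!is.na(episode$sev))
  lam_ep <- config$med_rate_per_hour * config$med_escalation_mult * f *
    episode$sev[epw] * (2 * episode$half[epw] / 60) * 0.6
  c4 <- stats::rpois(length(epw), lam_ep)
  idx4 <- rep.int(epw, c4)
  t4 <- round(episode$center[idx4] +
                (stats::runif(length(idx4)) - 0.5) * 2 * episode$half[idx4])
  t4 <- pmin(pmax(t4, 0), los[idx4])
  med4 <- sample(pred, length(idx4), replace = TRUE)

  ## intubation-preparation sedatives inside [onset - 30, onset); these must
  ## never be visible to the model because scoring stops at the prep boundary
  idx3 <- rep.int(mvw, 2L)
  t3 <- round(onset[idx3] - stats::runif(length(idx3), 1, 29))
  med3 <- rep("prep_sedative", length(idx3))

  all_idx <- c(idx, idx2, idx4, idx3)
  meds <- data.table::data.table(
    encounter_id = enc$encounter_id[all_idx],
    time = as.integer(pmax(c(t, t2, t4, t3), 0)),
    medication = c(med, med2, med4, med3),
    escalation = c(esc, rep(TRUE, length(idx2) + length(idx4)),
                   rep(FALSE, length(idx3))))
  data.table::setorder(meds, encounter_id, time)
  meds[, sequence_no := seq_len(.N), by = encounter_id]

  ## actions: first event of a med in a stay is "given"; escalation events
  ## afterwards are predominantly "rate changed" (dose-escalation runs)
  meds[, med_pos := seq_len(.N), by = .(encounter_id, medication)]
  u <- stats::runif(nrow(meds))
  act <- ifelse(meds$med_pos == 1L, "given",
         ifelse(meds$escalation,
                ifelse(u < 0.75, "rate changed", ifelse(u < 0.90, "given", "stopped")),
                ifelse(u < 0.45, "given", ifelse(u < 0.75, "rate changed", "stopped"))))
  meds[, action := act]
  meds[, c("escalation", "med_pos") := NULL]
  data.table::setcolorder(meds, c("encounter_id", "time", "medication", "action", "sequence_no"))
  meds[]
}

#' Generate synthetic risk-score trajectory bundles
#'
#' Fixture generator for the risk-grouping stage: each bundle follows a
#' distinct archetype mean curve on the 73-point 5-minute grid over
#' \[0, 6 h\] after an alert, with additive Gaussian noise, clipped to
#' \[0, 1\]. Default archetypes: sustained-high (~0.9), sustained-medium
#' (~0.6), and low-decaying (from ~0.45); further archetypes interpolate.
#'
#' @param n_per_bundle trajectories per archetype.
#' @param archetypes number of bundles (>= 1).
#' @param noise_sd standard deviation of additive noise (>= 0).
#' @param seed integer seed.
#' @return list with `trajectories` (numeric matrix, rows = trajectories,
#'   73 columns) and `labels` (planted archetype index per row).
#' @export
generate_trajectory_bundles <- function(n_per_bundle, archetypes = 3L,
                                        noise_sd = 0.02, seed = 1L) {
  archetypes <- check_count(archetypes, "archetypes")
  n_per_bundle <- check_count(n_per_bundle, "n_per_bundle")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) || noise_sd < 0)
    stop_field("noise_sd", "must be a non-negative number")
  tgrid <- seq(0, 360, by = 5) / 60  # hours
  curves <- list(
    high = function(t) 0.90 - 0.01 * t / 6,
    medium = function(t) 0.60 + 0.01 * sin(pi * t / 6),
    low = function(t) 0.45 * exp(-t / 2.5),
    rising = function(t) 0.30 + 0.35 * t / 6,
    floor = function(t) rep(0.15, length(t)))
  with_seed(seed, {
    rows <- vector("list", archetypes)
    for (a in seq_len(archetypes)) {
      mu <- curves[[((a - 1L) %% length(curves)) + 1L]](tgrid)
      m <- matrix(rep(mu, each = n_per_bundle), nrow = n_per_bundle) +
        matrix(stats::rnorm(n_per_bundle * length(tgrid), 0, noise_sd),
               nrow = n_per_bundle)
      rows[[a]] <- m
    }
    traj <- do.call(rbind, rows)
    traj <- pmin(pmax(traj, 0), 1)
    list(trajectories = traj,
         labels = rep(seq_len(archetypes), each = n_per_bundle))
  })
}

#' Write or read a cohort as CSV tables
#'
#' `write_cohort()` writes `encounters.csv`, `observations.csv` and
#' `medications.csv` into `dir`; `read_cohort()` reads them back.
#'
#' @param cohort list as returned by [generate_cohort()].
#' @param dir directory path.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` the
#'   cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("encounters", "observations", "medications"))
    data.table::fwrite(cohort[[tb]], file.path(dir, paste0(tb, ".csv")))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  out <- lapply(c("encounters", "observations", "medications"), function(tb)
    data.table::fread(file.path(dir, paste0(tb, ".csv"))))
  names(out) <- c("encounters", "observations", "medications")
  out
}
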