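## Feature engineering: the 5-minute LOCF grid, one-hot encoding,
## age-normalized physiologic z-scores, rolling 6-hour input/output rates,
## medication indicator features, and the median-imputation path used by the
## linear model.

#' Default feature dictionary
#'
#' Declares the synthetic variable set consumed by the generator and the grid
#' builder: variable name, type (`numeric`, `categorical`, `io`), whether the
#' numeric variable is z-scored against the normal-range table, its charting
#' rate relative to the vital-sign base rate, the standard-deviation-units
#' drift planted before MV onset, and (for categoricals) the fixed category
#' set. The full institutional 188-feature dictionary is site-specific; this
#' table is the configurable stand-in and can be replaced by the user.
#'
#' @return data.table with one row per variable.
#' @export
default_feature_dictionary <- function() {
  data.table::data.table(
    variable = c("heart_rate", "resp_rate", "spo2", "sbp", "dbp", "temp",
                 "fio2", "wbc", "lactate", "bilirubin",
                 "resp_effort", "heart_sounds", "iv_volume_in", "urine_out"),
    type = c(rep("numeric", 10), "categorical", "categorical", "io", "io"),
    zscore = c(rep(TRUE, 10), FALSE, FALSE, FALSE, FALSE),
    obs_rate_mult = c(1, 1, 1, 0.7, 0.7, 0.5, 0.5, 0.04, 0.04, 0.03,
                      0.25, 0.25, 1, 0.5),
    drift_sd_units = c(1.5, 2.5, -2, 0, 0, 0.3, 2, 0.5, 1.5, 0.3,
                       0, 0, 0, 0),
    levels = c(rep(NA_character_, 10), "normal;labored;tachypneic",
               "normal;murmur", NA_character_, NA_character_))
}

#' Default normal-range table for physiologic z-scoring
#'
#' Age-banded reference means and standard deviations for the synthetic
#' variable set, in the format of a pediatric normal-values handbook table:
#' one row per (variable, age band), bands covering 0-21 years without
#' overlap. Synthetic stand-in values; replace with an institutional table
#' for real data.
#'
#' @return data.table with columns variable, age_low, age_high, gender,
#'   mu, sigma.
#' @export
default_normal_ranges <- function() {
  band <- function(variable, mu, sigma) {
    data.table::data.table(variable = variable,
                           age_low = c(0, 1, 5, 12), age_high = c(1, 5, 12, 21),
                           gender = "any", mu = mu, sigma = sigma)
  }
  flat <- function(variable, mu, sigma)
    data.table::data.table(variable = variable, age_low = 0, age_high = 21,
                           gender = "any", mu = mu, sigma = sigma)
  data.table::rbindlist(list(
    band("heart_rate", c(130, 110, 95, 80), c(20, 18, 15, 14)),
    band("resp_rate", c(40, 28, 22, 16), c(8, 6, 5, 4)),
    flat("spo2", 98, 1.5),
    band("sbp", c(85, 95, 105, 115), c(12, 12, 12, 12)),
    band("dbp", c(50, 55, 62, 68), c(10, 10, 10, 10)),
    flat("temp", 37, 0.5),
    flat("fio2", 0.25, 0.08),
    flat("wbc", 9, 3),
    flat("lactate", 1.5, 0.8),
    flat("bilirubin", 0.8, 0.5),
    band("weight_kg", c(7, 14, 28, 55), c(2, 3.5, 8, 14)),
    band("height_cm", c(65, 95, 130, 160), c(8, 10, 12, 12))))
}

## vectorized (mu, sigma) lookup; ages clamped into [0, 21]
norm_lookup <- function(table, variable, age, gender = NULL) {
  table <- as.data.frame(table)
  rows <- table[table$variable == variable, ]
  if (!nrow(rows))
    stop(sprintf("no normal-range row for variable '%s'", variable), call. = FALSE)
  if (!is.null(gender) && any(rows$gender != "any")) {
    g <- rows[rows$gender %in% c(gender[1], "any"), ]
    if (nrow(g)) rows <- g
  }
  rows <- rows[order(rows$age_low), ]
  age <- pmin(pmax(age, 0), 21)
  idx <- findInterval(age, rows$age_low)
  if (any(idx == 0))
    stop(sprintf("no normal-range row for variable '%s' at age %s", variable,
                 paste(age[idx == 0][1])), call. = FALSE)
  list(mu = rows$mu[idx], sigma = rows$sigma[idx])
}

#' Resample irregular observations onto a 5-minute LOCF grid
#'
#' For a single encounter's observation events, returns the grid series with
#' each variable's last observed value at or before every grid time carried
#' forward; grid times before a variable's first observation are missing.
#' Duplicate (variable, time) records with conflicting values keep the last
#' by record order.
#'
#' @param events data.frame with columns `time`, `variable`, and `value`
#'   (numeric) and/or `value_cat` (character).
#' @param grid_step grid spacing in minutes (default 5).
#' @param end_time last grid time; defaults to the latest event time.
#' @return data.table with a `time` column and one column per variable.
#' @export
resample_locf <- function(events, grid_step = 5L, end_time = NULL) {
  check_columns(events, c("time", "variable"), "events")
  events <- as.data.frame(events)
  if (is.null(end_time)) end_time <- if (nrow(events)) max(events$time) else 0
  grid <- seq(0L, as.integer(end_time), by = as.integer(grid_step))
  out <- data.table::data.table(time = grid)
  for (v in unique(events$variable)) {
    ev <- events[events$variable == v, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]  # stable: last record wins ties
    dup <- duplicated(ev$time, fromLast = TRUE)
    if (any(dup)) {
      message(sprintf("resample_locf: %d duplicate record(s) for '%s'; keeping last",
                      sum(dup), v))
      ev <- ev[!dup, , drop = FALSE]
    }
    vals <- if ("value" %in% names(ev) && !all(is.na(ev$value))) ev$value else ev$value_cat
    idx <- findInterval(grid, ev$time)
    col <- vals[ifelse(idx == 0L, NA_integer_, idx)]
    data.table::set(out, j = v, value = col)
  }
  out[]
}

#' One-hot encode a categorical series
#'
#' Maps a character/factor vector onto binary columns for a fixed category
#' set (fixed from training data). Unseen categories and missing values
#' produce an all-zero row; unseen categories are reported via `message()`.
#'
#' @param x character vector.
#' @param categories fixed category set (column order).
#' @return integer matrix with `length(categories)` columns named
#'   `<category>`.
#' @export
one_hot <- function(x, categories) {
  m <- matrix(0L, nrow = length(x), ncol = length(categories),
              dimnames = list(NULL, categories))
  idx <- match(x, categories)
  unseen <- !is.na(x) & is.na(idx)
  if (any(unseen))
    message(sprintf("one_hot: %d value(s) outside category set (all-zero rows)",
                    sum(unseen)))
  ok <- which(!is.na(idx))
  m[cbind(ok, idx[ok])] <- 1L
  m
}

#' @rdname one_hot
#' @param m matrix produced by `one_hot()`.
#' @export
one_hot_decode <- function(m, categories = colnames(m)) {
  hit <- m == 1L
  out <- rep(NA_character_, nrow(m))
  any_hit <- rowSums(hit) > 0
  out[any_hit] <- categories[max.col(hit[any_hit, , drop = FALSE], ties.method = "first")]
  out
}

#' Age/gender-normalized physiologic z-score
#'
#' `z = (x - mu) / sigma` with the reference mean and standard deviation
#' taken from the age-band (and optionally gender) matched row of the
#' normal-range table. Missing height values map to z = 0 by convention
#' (controlled by `na_to_zero`).
#'
#' @param value raw measurement(s).
#' @param variable variable name present in `table`.
#' @param age age(s) in years.
#' @param gender optional gender for gender-specific table rows.
#' @param table a normal-range table (see [default_normal_ranges()]).
#' @param na_to_zero replace missing values with z = 0; defaults to TRUE for
#'   height, FALSE otherwise.
#' @return numeric z-score vector.
#' @export
zscore_physiologic <- function(value, variable, age, gender = NULL,
                               table = default_normal_ranges(),
                               na_to_zero = identical(variable, "height_cm")) {
  ms <- norm_lookup(table, variable, age, gender)
  z <- (value - ms$mu) / ms$sigma
  if (na_to_zero) z[is.na(z)] <- 0
  z
}

#' Rolling input/output rate over the preceding 6 hours
#'
#' Sum of event volumes in the half-open window `(t - window, t]`, divided by
#' the window length in hours; windows truncated by admission use the elapsed
#' time since admission as the denominator.
#'
#' @param times event times (minutes since admission).
#' @param volumes event volumes (mL), non-negative.
#' @param t grid time(s) at which to evaluate the rate.
#' @param window_minutes lookback window (default 360 = 6 h).
#' @param admit_time admission time (default 0).
#' @return rate(s) in volume per hour.
#' @export
rolling_io_rate <- function(times, volumes, t, window_minutes = 360L,
                            admit_time = 0L) {
  if (any(volumes < 0)) stop("negative volume in input/output events")
  ord <- order(times)
  times <- times[ord]; volumes <- volumes[ord]
  cum <- c(0, cumsum(volumes))
  hi <- findInterval(t, times)
  lo <- findInterval(t - window_minutes, times)
  vol <- cum[hi + 1L] - cum[lo + 1L]
  denom_h <- pmin(window_minutes, t - admit_time) / 60
  ifelse(denom_h > 0, vol / denom_h, 0)
}

#' Select medications for indicator features
#'
#' A medication is selected if it was given to at least 10% of MV patients,
#' or if the fraction of patients with at least one dose differs by more than
#' 5 percentage points between the MV and no-MV groups. Prevalence counts
#' "given" events only, and MV cases' histories are truncated at the MV
#' preparation boundary. Must be applied to training-set encounters only.
#'
#' @param medications medication event table.
#' @param encounters encounter table with `mv_flag` (and `mv_onset_time`).
#' @param min_mv_fraction,min_prevalence_gap the two selection thresholds.
#' @param prep_minutes preparation window before MV onset (default 30).
#' @return character vector of selected medication names.
#' @export
select_indicator_meds <- function(medications, encounters,
                                  min_mv_fraction = 0.10,
                                  min_prevalence_gap = 0.05,
                                  prep_minutes = 30L) {
  check_columns(encounters, c("encounter_id", "mv_flag"), "encounters")
  check_columns(medications, c("encounter_id", "medication", "action"), "medications")
  enc <- data.table::as.data.table(encounters)
  n_mv <- sum(enc$mv_flag); n_ctrl <- sum(!enc$mv_flag)
  if (n_mv == 0L) stop("no MV encounters in the training set")
  meds <- data.table::as.data.table(medications)[action == "given"]
  meds <- merge(meds, enc[, .(encounter_id, mv_flag, mv_onset_time)],
                by = "encounter_id")
  meds <- meds[!mv_flag | is.na(mv_onset_time) | time < mv_onset_time - prep_minutes]
  got <- unique(meds[, .(encounter_id, medication, mv_flag)])
  tab <- got[, .(n_mv_pat = sum(mv_flag), n_ctrl_pat = sum(!mv_flag)),
             by = medication]
  tab[, frac_mv := n_mv_pat / n_mv]
  tab[, frac_ctrl := if (n_ctrl > 0) n_ctrl_pat / n_ctrl else 0]
  sel <- tab[frac_mv >= min_mv_fraction |
               abs(frac_mv - frac_ctrl) > min_prevalence_gap]
  sort(sel$medication)
}

#' Binary medication indicator features
#'
#' For one encounter, a matrix with one column per selected medication: 1 at
#' grid time `t` iff the medication has at least one event (any action) in
#' the half-open window `(t - window, t]`.
#'
#' @param medications events for one encounter (`time`, `medication`).
#' @param selected medication names defining the columns (fixed on training
#'   data).
#' @param t grid times.
#' @param window_minutes lookback window (default 360).
#' @return integer matrix `length(t)` x `length(selected)`.
#' @export
med_indicator_features <- function(medications, selected, t,
                                   window_minutes = 360L) {
  m <- matrix(0L, nrow = length(t), ncol = length(selected),
              dimnames = list(NULL, paste0("med_ind.", selected)))
  if (!length(selected) || !nrow(medications)) return(m)
  for (j in seq_along(selected)) {
    ev <- sort(medications$time[medications$medication == selected[j]])
    if (!length(ev)) next
    n_hi <- findInterval(t, ev)
    n_lo <- findInterval(t - window_minutes, ev)
    m[, j] <- as.integer(n_hi - n_lo > 0L)
  }
  m
}

#' Median imputation against training medians
#'
#' `fit_medians()` computes per-column medians over observed training values
#' (error if a column is entirely missing); `impute_median()` replaces every
#' missing cell with the corresponding training median. Used only for the
#' L1-logistic path; the tree-ensemble path consumes missingness natively.
#'
#' @param x numeric matrix (training matrix for `fit_medians`).
#' @param medians named numeric vector from `fit_medians()`.
#' @return `fit_medians()`: named numeric vector; `impute_median()`: the
#'   completed matrix.
#' @export
fit_medians <- function(x) {
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  bad <- names(med)[is.na(med)]
  if (length(bad))
    stop(sprintf("column(s) entirely missing in training data: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  med
}

#' @rdname fit_medians
#' @export
impute_median <- function(x, medians) {
  stopifnot(!is.null(colnames(x)), all(colnames(x) %in% names(medians)))
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- medians[[colnames(x)[j]]]
  }
  x
}

## ---- feature grid assembly ------------------------------------------------

#' Build the 5-minute feature grid for a set of encounters
#'
#' Assembles, per encounter, grid rows from admission up to (exclusive) the
#' MV preparation time for MV cases or through discharge for no-MV cases.
#' Rows in the preparation window `[prep, onset)` never appear. Features:
#' LOCF-resampled numeric variables as age-normalized z-scores with per-
#' variable missingness indicators, one-hot categorical variables, rolling
#' 6-hour input/output rates, demographic columns, optional medication
#' indicator columns, and optional medication-history (`medhist*`) columns
#' from a frozen convolutional extractor. The row label is 1 iff the row
#' falls in the 12-hour positive sampling window before preparation of an MV
#' case.
#'
#' @param encounters,observations,medications cohort tables.
#' @param dictionary feature dictionary (see [default_feature_dictionary()]).
#' @param norm_table normal-range table.
#' @param selected_meds medication names for indicator columns (NULL = none).
#' @param extractor frozen medication-history extractor from
#'   [train_extractor()] (NULL = no medhist columns).
#' @param grid_step grid spacing in minutes.
#' @param prep_minutes preparation window before MV onset.
#' @param positive_window_minutes positive sampling window before prep.
#' @return data.table: `encounter_id`, `time`, `label`, feature columns.
#' @export
build_feature_grid <- function(encounters, observations, medications,
                               dictionary = default_feature_dictionary(),
                               norm_table = default_normal_ranges(),
                               selected_meds = NULL, extractor = NULL,
                               grid_step = 5L, prep_minutes = 30L,
                               positive_window_minutes = 720L) {
  enc <- data.table::as.data.table(encounters)
  check_columns(enc, c("encounter_id", "age_years", "gender", "discharge_time",
                       "mv_flag"), "encounters")
  rows <- grid_rows(enc, grid_step = grid_step, prep_minutes = prep_minutes)
  build_features_at(rows, enc, observations, medications,
                    dictionary = dictionary, norm_table = norm_table,
                    selected_meds = selected_meds, extractor = extractor,
                    grid_step = grid_step, prep_minutes = prep_minutes,
                    positive_window_minutes = positive_window_minutes)
}

## full per-encounter grid rows: 5-min steps from admission up to
## (exclusive) prep for MV cases, through discharge for no-MV cases
grid_rows <- function(enc, grid_step = 5L, prep_minutes = 30L) {
  prep <- ifelse(enc$mv_flag, enc$mv_onset_time - prep_minutes, NA_real_)
  end <- ifelse(enc$mv_flag, prep - 1, as.numeric(enc$discharge_time))
  end <- pmax(floor(end / grid_step) * grid_step, 0)
  n_rows <- as.integer(end / grid_step) + 1L
  idx <- rep.int(seq_len(nrow(enc)), n_rows)
  data.table::data.table(
    encounter_id = enc$encounter_id[idx],
    time = as.integer(unlist(lapply(seq_len(nrow(enc)), function(i)
      seq(0L, as.integer(end[i]), by = grid_step)), use.names = FALSE)))
}

## feature computation at arbitrary (encounter_id, time) rows
build_features_at <- function(rows, encounters, observations, medications,
                              dictionary = default_feature_dictionary(),
                              norm_table = default_normal_ranges(),
                              selected_meds = NULL, extractor = NULL,
                              grid_step = 5L, prep_minutes = 30L,
                              positive_window_minutes = 720L) {
  enc <- data.table::as.data.table(encounters)
  obs <- data.table::as.data.table(observations)
  meds <- data.table::as.data.table(medications)
  grid <- data.table::as.data.table(rows)[, .(encounter_id, time)]

  idx <- match(grid$encounter_id, enc$encounter_id)
  prep <- ifelse(enc$mv_flag, enc$mv_onset_time - prep_minutes, NA_real_)
  pr <- prep[idx]
  grid[, label := as.integer(!is.na(pr) & time >= pr - positive_window_minutes &
                               time < pr)]

  age <- ifelse(is.na(enc$age_years), stats::median(enc$age_years, na.rm = TRUE),
                enc$age_years)

  ## demographics
  grid[, age_years := age[idx]]
  grid[, gender_male := as.integer(!is.na(enc$gender[idx]) & enc$gender[idx] == "male")]
  grid[, weight_z := zscore_physiologic(enc$weight_kg, "weight_kg", age,
                                        table = norm_table)[idx]]
  grid[, height_z := zscore_physiologic(enc$height_cm, "height_cm", age,
                                        table = norm_table, na_to_zero = TRUE)[idx]]

  gkey <- grid[, .(encounter_id, time)]

  ## LOCF numeric + categorical variables
  for (r in which(dictionary$type %in% c("numeric", "categorical"))) {
    v <- dictionary$variable[r]
    ov <- obs[variable == v]
    if (dictionary$type[r] == "numeric") {
      vals <- rep(NA_real_, nrow(grid))
      if (nrow(ov)) {
        ov <- unique(ov[order(encounter_id, time)], by = c("encounter_id", "time"),
                     fromLast = TRUE)
        data.table::setkey(ov, encounter_id, time)
        vals <- ov[gkey, on = c("encounter_id", "time"), roll = TRUE, x.value]
      }
      if (isTRUE(dictionary$zscore[r])) {
        ms <- norm_lookup(norm_table, v, grid$age_years)
        zv <- (vals - ms$mu) / ms$sigma
      } else zv <- vals
      data.table::set(grid, j = paste0("z_", v), value = zv)
      data.table::set(grid, j = paste0("miss_", v), value = as.integer(is.na(zv)))
    } else {
      levs <- strsplit(dictionary$levels[r], ";", fixed = TRUE)[[1]]
      cv <- rep(NA_character_, nrow(grid))
      if (nrow(ov)) {
        ov <- unique(ov[order(encounter_id, time)], by = c("encounter_id", "time"),
                     fromLast = TRUE)
        data.table::setkey(ov, encounter_id, time)
        cv <- ov[gkey, on = c("encounter_id", "time"), roll = TRUE, x.value_cat]
      }
      oh <- one_hot(cv, levs)
      colnames(oh) <- paste0(v, ".", levs)
      for (cn in colnames(oh)) data.table::set(grid, j = cn, value = oh[, cn])
      data.table::set(grid, j = paste0("miss_", v), value = as.integer(is.na(cv)))
    }
  }

  ## rolling 6-h io rates
  for (r in which(dictionary$type == "io")) {
    v <- dictionary$variable[r]
    ov <- obs[variable == v][order(encounter_id, time)]
    rate <- rep(0, nrow(grid))
    if (nrow(ov)) {
      splits <- split(seq_len(nrow(ov)), ov$encounter_id)
      gsplit <- split(seq_len(nrow(grid)), grid$encounter_id)
      for (e in names(splits)) {
        gi <- gsplit[[e]]
        if (is.null(gi)) next
        oi <- splits[[e]]
        rate[gi] <- rolling_io_rate(ov$time[oi], ov$value[oi], grid$time[gi])
      }
    }
    data.table::set(grid, j = paste0("rate_", v), value = rate)
  }

  ## medication indicators
  if (length(selected_meds)) {
    data.table::setkey(meds, encounter_id, time)
    for (mname in selected_meds) {
      ev <- meds[medication == mname][, n := seq_len(.N), by = encounter_id]
      ind <- rep(0L, nrow(grid))
      if (nrow(ev)) {
        data.table::setkey(ev, encounter_id, time)
        hi <- ev[gkey, on = c("encounter_id", "time"), roll = TRUE, x.n]
        lo_key <- data.table::data.table(encounter_id = gkey$encounter_id,
                                         time = gkey$time - 360L)
        lo <- ev[lo_key, on = c("encounter_id", "time"), roll = TRUE, x.n]
        hi[is.na(hi)] <- 0L; lo[is.na(lo)] <- 0L
        ind <- as.integer(hi - lo > 0L)
      }
      data.table::set(grid, j = paste0("med_ind.", mname), value = ind)
    }
  }

  ## medication-history features from the frozen extractor
  if (!is.null(extractor)) {
    mh <- medhist_on_grid(extractor, meds, grid)
    for (cn in colnames(mh)) data.table::set(grid, j = cn, value = mh[, cn])
  }

  grid[]
}

feature_columns <- function(grid) {
  setdiff(names(grid), c("encounter_id", "time", "label"))
}
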