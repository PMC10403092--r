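test_that("LOCF resampling carries the last observation forward", {
  ev <- data.frame(time = c(0L, 7L), variable = "heart_rate",
                   value = c(100, 110))
  g <- resample_locf(ev, end_time = 15)
  expect_equal(g$heart_rate, c(100, 100, 110, 110))
  ## a single observation gives a constant series
  g1 <- resample_locf(data.frame(time = 0L, variable = "x", value = 7),
                      end_time = 20)
  expect_equal(g1$x, rep(7, 5))
  ## values before the first observation are missing
  g2 <- resample_locf(data.frame(time = 12L, variable = "x", value = 3),
                      end_time = 20)
  expect_equal(g2$x, c(NA, NA, NA, 3, 3))
  ## conflicting duplicates keep the last record
  ev3 <- data.frame(time = c(5L, 5L), variable = "x", value = c(1, 2))
  expect_message(g3 <- resample_locf(ev3, end_time = 10), "duplicate")
  expect_equal(g3$x, c(NA, 2, 2))
})

test_that("LOCF matches the brute-force last-event scan on random inputs", {
  set.seed(100)
  for (i in 1:1000) {
    n <- sample(1:8, 1)
    times <- sort(sample(0:60, n))
    vals <- round(runif(n), 3)
    end <- 60
    g <- resample_locf(data.frame(time = times, variable = "v", value = vals),
                       end_time = end)
    expect_identical(g$v, locf_oracle(times, vals, seq(0, end, by = 5)))
  }
})

test_that("one-hot encoding round-trips and flags unseen categories", {
  m <- one_hot(c("Murmur", "Normal"), c("Normal", "Murmur"))
  expect_equal(unname(m), rbind(c(0L, 1L), c(1L, 0L)))
  expect_equal(one_hot_decode(m), c("Murmur", "Normal"))
  expect_message(u <- one_hot("Gallop", c("Normal", "Murmur")), "outside")
  expect_equal(unname(u), cbind(0L, 0L))
  expect_equal(unname(one_hot(NA_character_, c("a", "b"))), cbind(0L, 0L))
})

test_that("physiologic z-scores follow the table and handle missing height", {
  tab <- data.frame(variable = "x", age_low = 0, age_high = 21, gender = "any",
                    mu = 100, sigma = 10)
  expect_equal(zscore_physiologic(100, "x", age = 5, table = tab), 0)
  expect_equal(zscore_physiologic(120, "x", age = 5, table = tab), 2)
  expect_equal(zscore_physiologic(NA, "height_cm", age = 2), 0)
  expect_true(is.na(zscore_physiologic(NA, "x", age = 2, table = tab)))
  expect_error(zscore_physiologic(1, "nope", age = 2), "nope")
})

test_that("z-score linearity holds on every normal-range row", {
  tab <- default_normal_ranges()
  for (r in seq_len(nrow(tab))) {
    age <- (tab$age_low[r] + tab$age_high[r]) / 2
    for (a in c(-2, 0, 1.7)) {
      x <- a * tab$sigma[r] + tab$mu[r]
      expect_equal(zscore_physiologic(x, tab$variable[r], age = age), a)
    }
  }
})

test_that("rolling io rate sums the trailing window with truncation", {
  ## 600 mL over the prior 6 h -> 100 mL/h
  expect_equal(rolling_io_rate(c(100, 200), c(300, 300), t = 360), 100)
  ## empty window -> 0
  expect_equal(rolling_io_rate(c(10), c(50), t = 500, window_minutes = 60), 0)
  ## 3 h after admission with 300 mL since admission -> truncated denominator
  expect_equal(rolling_io_rate(c(30, 150), c(100, 200), t = 180), 100)
  ## half-open window: an event exactly at t - 6 h is excluded
  expect_equal(rolling_io_rate(c(0, 100), c(60, 60), t = 360), 10)
  expect_error(rolling_io_rate(10, -5, t = 60), "negative")
})

test_that("indicator medication selection applies both rules", {
  enc <- data.table::data.table(
    encounter_id = sprintf("e%02d", 1:60),
    mv_flag = rep(c(TRUE, FALSE), c(10, 50)),
    mv_onset_time = c(rep(5000L, 10), rep(NA_integer_, 50)))
  given <- function(id, med) data.table::data.table(
    encounter_id = id, time = 100L, medication = med, action = "given",
    sequence_no = 1L)
  meds <- data.table::rbindlist(list(
    given(c("e01", "e02"), "freq_mv"),          # 20% of MV -> selected
    given(sprintf("e%02d", 12:14), "ctrl_only"), # 0% vs 6% -> selected
    given("e03", "rare"),                        # 10% vs 8% -> selected (>=10%)
    given(c("e04", sprintf("e%02d", 15:16)), "balanced"))) # 10% MV -> selected
  sel <- select_indicator_meds(meds, enc)
  expect_true(all(c("freq_mv", "ctrl_only", "rare", "balanced") %in% sel))
  ## 5% MV vs 4% controls: below both rules (approximate with 0 MV, 4% ctrl)
  meds2 <- given(sprintf("e%02d", 17:18), "weak")
  expect_false("weak" %in% select_indicator_meds(meds2, enc))
  expect_error(select_indicator_meds(meds, enc[mv_flag == FALSE]), "no MV")
})

test_that("selection counts 'given' events only and truncates at prep", {
  enc <- data.table::data.table(encounter_id = c("a", "b"),
                                mv_flag = c(TRUE, FALSE),
                                mv_onset_time = c(1000L, NA))
  meds <- data.table::data.table(
    encounter_id = "a", time = c(100L, 985L),
    medication = c("stopped_only", "prep_drug"),
    action = c("stopped", "given"), sequence_no = 1:2)
  expect_length(select_indicator_meds(meds, enc), 0L)
})

test_that("medication indicators use the half-open 6-hour window", {
  meds <- data.frame(time = c(1, 350), medication = c("a", "a"))
  t <- c(0, 355, 360, 361, 700, 711)
  m <- med_indicator_features(meds, "a", t)
  ## event at 1 visible while t - 360 < 1 <= t; event at 350 until t < 710
  expect_equal(unname(m[, 1]), c(0L, 1L, 1L, 1L, 1L, 0L))
  expect_equal(dim(med_indicator_features(meds[0, ], c("a", "b"), t)), c(6L, 2L))
})

test_that("shifting all medication events by +5 min shifts activation one step", {
  set.seed(42)
  times <- sort(sample(0:2000, 15))
  meds <- data.frame(time = times, medication = "m")
  grid <- seq(0, 2400, by = 5)
  base <- med_indicator_features(meds, "m", grid)
  shifted <- med_indicator_features(transform(meds, time = time + 5), "m", grid)
  expect_equal(shifted[-1, 1], base[-length(grid), 1])
})

test_that("median imputation uses training medians only", {
  xtr <- cbind(a = c(1, 2, 3), b = c(10, NA, 30))
  med <- fit_medians(xtr)
  expect_equal(unname(med), c(2, 20))
  xte <- cbind(a = c(NA, 5), b = c(NA, 1))
  expect_equal(impute_median(xte, med), cbind(a = c(2, 5), b = c(20, 1)))
  ## no missing cells -> identity
  expect_equal(impute_median(xtr[1:2, , drop = FALSE], med)[, "a"], c(a1 = 1, 2),
               ignore_attr = TRUE)
  expect_error(fit_medians(cbind(a = c(NA_real_, NA_real_))), "a")
})

test_that("feature grid assembles all declared blocks", {
  coh <- toy_cohort()
  grid <- build_feature_grid(coh$encounters, coh$observations, coh$medications,
                             selected_meds = "med_a")
  expect_true(all(c("z_heart_rate", "miss_heart_rate", "resp_effort.labored",
                    "age_years", "gender_male", "height_z", "weight_z",
                    "rate_iv_volume_in", "med_ind.med_a") %in% names(grid)))
  expect_equal(sort(unique(diff(grid$time[grid$encounter_id == "ctl1"]))), 5L)
  ## missing height maps to z = 0
  expect_equal(unique(grid$height_z[grid$encounter_id == "ctl1"]), 0)
  ## LOCF z-score: heart rate 120 at age 2 against mu 110 sd 18
  g1 <- grid[grid$encounter_id == "mv1", ]
  expect_equal(g1$z_heart_rate[g1$time == 50], (120 - 110) / 18)
  ## missingness indicator flips once the variable is observed
  expect_equal(g1$miss_resp_rate[g1$time == 695], 1L)
  expect_equal(g1$miss_resp_rate[g1$time == 700], 0L)
})

test_that("train-fitted preprocessing never touches test data", {
  fx <- small_filtered()
  enc <- fx$retained
  meds <- fx$cohort$medications
  tr <- enc[enc$encounter_id %in% fx$split$train, ]
  trm <- meds[meds$encounter_id %in% fx$split$train, ]
  sel <- select_indicator_meds(trm, tr)
  ## perturbing test-split medications changes nothing fitted on train
  meds_mut <- data.table::copy(meds)
  mut <- meds_mut$encounter_id %in% fx$split$test
  meds_mut$medication[mut] <- "mutated_drug"
  sel2 <- select_indicator_meds(meds_mut[meds_mut$encounter_id %in% fx$split$train, ],
                                tr)
  expect_identical(sel, sel2)
})
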