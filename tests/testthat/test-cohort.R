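make_enc <- function(...) {
  base <- toy_cohort()$encounters[1]
  mod <- list(...)
  for (nm in names(mod)) data.table::set(base, j = nm, value = mod[[nm]])
  base
}
base_obs <- function(id = "mv1") data.table::data.table(
  encounter_id = id, time = 10L, variable = "heart_rate", value = 100,
  value_cat = NA_character_)

test_that("MV timing exclusions fire with the correct rule ids", {
  ## onset 10 h after admission
  enc <- make_enc(mv_onset_time = 600L, mv_end_time = 1990L)
  res <- apply_inclusion_exclusion(enc, base_obs())
  expect_equal(nrow(res$retained), 0L)
  expect_equal(res$log$rule_id, "mv_within_12h")
  ## onset fine but MV lasts only 8 h
  enc <- make_enc(mv_onset_time = 800L, mv_end_time = 800L + 8L * 60L,
                  discharge_time = 2000L)
  res <- apply_inclusion_exclusion(enc, base_obs())
  expect_equal(res$log$rule_id, "mv_duration_lt_12h")
  ## onset 60 min after a documented procedure
  enc <- make_enc(procedure_times = "1140")
  res <- apply_inclusion_exclusion(enc, base_obs())
  expect_equal(res$log$rule_id, "mv_post_procedure")
  ## no qualifying diagnosis
  enc <- make_enc(diagnosis_categories = "trauma")
  res <- apply_inclusion_exclusion(enc, base_obs())
  expect_equal(res$log$rule_id, "mv_no_qualifying_diagnosis")
})

test_that("a clean no-MV encounter with one vital sign is retained", {
  enc <- toy_cohort()$encounters[2]
  res <- apply_inclusion_exclusion(enc, base_obs("ctl1"))
  expect_equal(nrow(res$retained), 1L)
  expect_equal(nrow(res$log), 0L)
})

test_that("each removed encounter is logged once with the first firing rule", {
  ## trach + short MV: tracheostomy comes first in the flowchart
  enc <- make_enc(trach_flag = TRUE, mv_end_time = 1500L)
  res <- apply_inclusion_exclusion(enc, base_obs())
  expect_equal(res$log$rule_id, "tracheostomy")
  coh <- small_cohort()
  res <- apply_inclusion_exclusion(coh$encounters, coh$observations)
  expect_equal(nrow(res$retained) + nrow(res$log), nrow(coh$encounters))
  expect_equal(anyDuplicated(res$log$encounter_id), 0L)
})

test_that("the filter is idempotent", {
  coh <- small_cohort()
  once <- apply_inclusion_exclusion(coh$encounters, coh$observations)
  twice <- apply_inclusion_exclusion(once$retained, coh$observations)
  expect_equal(twice$retained$encounter_id, once$retained$encounter_id)
  expect_equal(nrow(twice$log), 0L)
})

test_that("the cyanotic low-SpO2 rule uses the LOCF grid fraction", {
  enc <- make_enc(cyanotic_flag = TRUE, mv_flag = FALSE,
                  mv_onset_time = NA_integer_, mv_end_time = NA_integer_)
  ## SpO2 85 from t=0 onward: low for the whole stay -> excluded
  obs <- data.table::data.table(
    encounter_id = "mv1", time = c(0L, 10L), variable = c("spo2", "heart_rate"),
    value = c(85, 100), value_cat = NA_character_)
  res <- apply_inclusion_exclusion(enc, obs)
  expect_equal(res$log$rule_id, "cyanotic_low_spo2")
  ## low only for the last quarter of the stay -> retained
  obs2 <- data.table::data.table(
    encounter_id = "mv1", time = c(0L, 1600L, 10L),
    variable = c("spo2", "spo2", "heart_rate"),
    value = c(97, 85, 100), value_cat = NA_character_)
  res2 <- apply_inclusion_exclusion(enc, obs2)
  expect_equal(nrow(res2$log), 0L)
})

test_that("schema violations raise errors naming the missing column", {
  enc <- toy_cohort()$encounters
  expect_error(apply_inclusion_exclusion(enc[, !"mv_flag"], base_obs()),
               "mv_flag")
})

test_that("MV preparation labeling subtracts the 30-minute window", {
  enc <- toy_cohort()$encounters[1]
  expect_equal(label_mv_prep(enc), 1200L - 30L)
  expect_equal(label_mv_prep(data.frame(mv_flag = TRUE, mv_onset_time = 720)),
               690)
  expect_error(label_mv_prep(data.frame(mv_flag = FALSE, mv_onset_time = 720)),
               "MV encounter")
})

test_that("grid rows in the preparation window are dropped", {
  coh <- toy_cohort()
  grid <- build_feature_grid(coh$encounters, coh$observations, coh$medications)
  g1 <- grid[grid$encounter_id == "mv1", ]
  prep <- 1200 - 30
  ## last grid row strictly before prep; nothing in [prep, onset)
  expect_equal(max(g1$time), 1165L)
  expect_false(any(g1$time >= prep & g1$time < 1200))
  ## positive window is [prep - 720, prep)
  expect_equal(range(g1$time[g1$label == 1L]), c(450L, 1165L))
  expect_true(all(g1$label[g1$time < 450] == 0L))
})

test_that("stratified split partitions deterministically with round(0.8 n)", {
  fx <- small_filtered()
  sp <- fx$split
  enc <- fx$retained
  expect_setequal(c(sp$train, sp$test), enc$encounter_id)
  expect_length(intersect(sp$train, sp$test), 0L)
  sp2 <- suppressWarnings(stratified_split(enc, seed = 11L))
  expect_identical(sp, sp2)
  ## per-stratum training share
  ag <- cut(enc$age_years, c(0, 1, 5, 12, 21.0001), right = FALSE,
            include.lowest = TRUE)
  strata <- interaction(enc$mv_flag, enc$gender, ag, enc$niv_flag, drop = TRUE)
  for (s in levels(strata)) {
    ids <- enc$encounter_id[strata == s]
    if (length(ids) < 2) next
    expect_equal(sum(ids %in% sp$train), round(0.8 * length(ids)))
  }
  ## single-encounter strata go to train with a warning
  small <- enc[1:2]
  small$gender <- c("male", "female")
  expect_warning(sp3 <- stratified_split(small, seed = 1L), "single encounter")
  expect_setequal(sp3$train, small$encounter_id)
})
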