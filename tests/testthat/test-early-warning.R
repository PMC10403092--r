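test_that("max-F1 threshold selection matches the worked example", {
  sel <- select_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(sel$tau, 0.35)
  expect_equal(sel$f1, 0.8)
  ## perfectly separated scores: F1 = 1, tie-break to the highest candidate
  sel2 <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sel2$f1, 1)
  expect_equal(sel2$tau, 0.8)
  expect_error(select_threshold(c(0.1, 0.2), c(1, 1)), "both classes")
  expect_error(select_threshold(rep(0.5, 4), c(0, 1, 0, 1)), "degenerate")
})

test_that("threshold selection equals brute-force argmax-F1 on random draws", {
  set.seed(55)
  for (i in 1:1000) {
    n <- 200
    labels <- rbinom(n, 1, 0.3)
    scores <- round(runif(n) + 0.3 * labels, 2)
    if (length(unique(labels)) < 2 || length(unique(scores)) < 2) next
    sel <- select_threshold(scores, labels)
    expect_equal(sel$f1, brute_force_best_f1(scores, labels))
    expect_equal(f1_at(sel$tau, scores, labels), sel$f1)
  }
})

test_that("raising the threshold trades sensitivity for specificity", {
  set.seed(9)
  scores <- runif(500)
  labels <- rbinom(500, 1, plogis(3 * scores - 1.5))
  taus <- seq(0.05, 0.95, by = 0.05)
  sens <- vapply(taus, function(t) mean(scores[labels == 1] >= t), 0)
  spec <- vapply(taus, function(t) mean(scores[labels == 0] < t), 0)
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("EPP is the first qualifying crossing under each scheme", {
  times <- c(0, 5, 10, 15)
  pol <- threshold_policy("single", tau = 0.5)
  expect_equal(compute_epp(times, c(0.1, 0.2, 0.6, 0.4), pol), 10)
  expect_true(is.na(compute_epp(times, c(0.1, 0.2, 0.3, 0.4), pol)))
  expect_equal(compute_epp(times, c(0.9, 0.2, 0.3, 0.4), pol), 0)
  ## dual threshold: second crossing required within the window
  dual <- threshold_policy("dual_threshold", tau = 0.5, tau2 = 0.8,
                           inter_threshold_hours = 1)
  tt <- seq(0, 120, by = 5)
  sc <- rep(0.1, 25); sc[5] <- 0.6; sc[10] <- 0.85
  expect_equal(compute_epp(tt, sc, dual), tt[10])  # within 60 min of arming
  sc2 <- rep(0.1, 25); sc2[2] <- 0.6; sc2[20] <- 0.85
  expect_equal(compute_epp(tt, sc2, dual), tt[20]) # re-armed by crossing 20
  sc3 <- rep(0.6, 25)                              # tau2 never reached
  expect_true(is.na(compute_epp(tt, sc3, dual)))
  expect_error(threshold_policy("dual_threshold", tau = 0.5, tau2 = 0.3),
               "tau2")
  ## waiting period: crossing must be sustained for an hour
  waitp <- threshold_policy("waiting_period", tau = 0.5, wait_hours = 1)
  sc4 <- rep(0.1, 25); sc4[3:8] <- 0.7             # 25 min only
  expect_true(is.na(compute_epp(tt, sc4, waitp)))
  sc5 <- rep(0.1, 25); sc5[3:16] <- 0.7            # 65 min sustained
  expect_equal(compute_epp(tt, sc5, waitp), tt[3])
})

test_that("dual-threshold alerts are delayed-or-dropped single alerts", {
  set.seed(13)
  single <- threshold_policy("single", tau = 0.5)
  dual <- threshold_policy("dual_threshold", tau = 0.5, tau2 = 0.7)
  for (i in 1:200) {
    tt <- seq(0, 600, by = 5)
    sc <- pmin(pmax(cumsum(rnorm(length(tt), 0, 0.08)) + 0.3, 0), 1)
    e1 <- compute_epp(tt, sc, single)
    e2 <- compute_epp(tt, sc, dual)
    if (!is.na(e2)) {
      expect_false(is.na(e1))
      expect_gte(e2, e1)
      expect_gte(sc[match(e2, tt)], 0.5)  # still a tau crossing
    }
  }
})

test_that("EWT arithmetic and confusion metrics match hand computation", {
  expect_equal(compute_ewt(600, 1194), 9.9)
  expect_equal(compute_ewt(1200 - 30 - 5, 1200), 35 / 60)
  rep <- evaluate_encounters(
    max_scores = c(0.9, 0.8, 0.7, rep(0.2, 7)),
    epps = c(10, 10, 10, rep(NA, 7)),
    mv_flag = c(TRUE, TRUE, FALSE, rep(FALSE, 7)),
    mv_onset = c(1000, 2000, rep(NA, 8)), tau = 0.5)
  expect_equal(rep$tp, 2); expect_equal(rep$fp, 1)
  expect_equal(rep$fn, 0); expect_equal(rep$tn, 7)
  expect_equal(rep$ppv, 2 / 3)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 7 / 8)
  expect_equal(rep$npv, 1)
  expect_equal(rep$ewt_hours[["median"]],
               median(c(990, 1990) / 60))
  expect_error(evaluate_encounters(numeric(0), numeric(0), logical(0),
                                   numeric(0)), "empty")
})

test_that("F1 is the harmonic mean of sensitivity and precision", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(round(f1_score(0.47, 0.54), 2), 0.50)
  expect_equal(f1_score(0, 0), 0)
})

test_that("AUROC/AUPRC implementations agree with pROC on random data", {
  set.seed(2)
  for (i in 1:20) {
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- runif(60) + 0.4 * y
    expect_equal(auroc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                                direction = "<", quiet = TRUE))))
  }
  ## AUPRC of a perfect ranking is 1; of a constant-prevalence ranking ~ prev
  y <- rep(c(1, 0), c(10, 30))
  expect_equal(auprc(seq(40, 1), y), 1)
})

test_that("PEWS comparators match hand-counted confusion on a toy cohort", {
  enc <- data.table::data.table(
    encounter_id = sprintf("p%02d", 1:10),
    mv_flag = rep(c(TRUE, FALSE), c(3, 7)),
    mv_onset_time = c(3000L, 2000L, 5000L, rep(NA_integer_, 7)),
    discharge_time = rep(6000L, 10))
  ## cases: p01 max 7 before onset (TP), p02 max 4 (FN), p03 max 6 (TP)
  ## controls: p04 max 7 (FP), others max <= 5 (TN)
  pews_rows <- function(id, times, vals) data.table::data.table(
    encounter_id = id, time = times, variable = "pews", value = vals,
    value_cat = NA_character_)
  obs <- data.table::rbindlist(list(
    pews_rows("p01", c(240, 1000), c(3, 7)),
    pews_rows("p02", c(240, 1500), c(4, 4)),
    pews_rows("p03", c(100, 4000), c(2, 6)),
    pews_rows("p04", c(500), 7),
    data.table::rbindlist(lapply(5:10, function(i)
      pews_rows(sprintf("p%02d", i), 300, 3)))))
  out <- pews_comparator(obs, enc, tau_max = 5)
  expect_equal(out$max_pews$tp, 2)
  expect_equal(out$max_pews$fn, 1)
  expect_equal(out$max_pews$fp, 1)
  expect_equal(out$max_pews$tn, 6)
  ## lead time for p01: alert at 1000, onset 3000 -> 33.3 h... scaled: 2000/60
  expect_equal(out$max_pews$ewt_hours[["median"]],
               median(c((3000 - 1000) / 60, (5000 - 4000) / 60)))
  ## daily rule: p01 day0 max 7 > 6, onset at minute 3000 is in day 2 -> FP
  expect_gte(out$daily_pews$fp, 1)
  expect_warning(pews_comparator(obs[variable != "pews"], enc), "no PEWS")
})
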