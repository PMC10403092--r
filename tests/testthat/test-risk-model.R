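## deterministic separable instance set
toy_instances <- function(n = 400, p = 4, seed = 5) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- as.integer(x[, 1] + 0.2 * rnorm(n) > 0)
  list(x = x, y = y)
}

test_that("instance sampling balances classes and respects the prep gap", {
  fx <- small_filtered()
  enc <- fx$retained
  tr <- enc[enc$encounter_id %in% fx$split$train, ]
  grid <- build_feature_grid(tr, fx$cohort$observations, fx$cohort$medications)
  inst <- sample_training_instances(grid, tr, seed = 3)
  expect_equal(sum(inst$label == 1L), sum(inst$label == 0L))
  ## every negative row comes from a no-MV encounter
  neg_enc <- unique(inst$encounter_id[inst$label == 0L])
  expect_true(all(neg_enc %in% tr$encounter_id[!tr$mv_flag]))
  ## no sampled row falls in [prep, onset)
  m <- merge(inst[, c("encounter_id", "time")],
             tr[, c("encounter_id", "mv_flag", "mv_onset_time")],
             by = "encounter_id")
  mv <- m[m$mv_flag, ]
  expect_false(any(mv$time >= mv$mv_onset_time - 30 & mv$time < mv$mv_onset_time))
  ## a case with prep at 20 h contributes 144 positive rows (12 h / 5 min)
  one <- tr[tr$mv_flag, ][which(tr[tr$mv_flag, ]$mv_onset_time > 1500)[1], ]
  expect_equal(sum(inst$label == 1L & inst$encounter_id == one$encounter_id),
               144L)
  ## deterministic given the seed
  inst2 <- sample_training_instances(grid, tr, seed = 3)
  expect_identical(inst, inst2)
})

test_that("the tree learner separates separable data and is seeded", {
  d <- toy_instances()
  fit <- fit_risk_model(d$x, d$y, seed = 1)
  p <- predict(fit, d$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(auroc(p, d$y), 0.999)
  fit2 <- fit_risk_model(d$x, d$y, seed = 1)
  expect_identical(predict(fit2, d$x), p)
  expect_error(fit_risk_model(d$x, rep(1L, nrow(d$x))), "both classes")
  expect_error(predict(fit, d$x[, 1:2]), "f3")
})

test_that("permuted labels give chance-level cross-validated discrimination", {
  set.seed(8)
  n <- 5000
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- sample(rep(c(0L, 1L), each = n / 2))
  fold <- sample(rep(1:10, length.out = n))
  oof <- numeric(n)
  for (k in 1:10) {
    fit <- fit_risk_model(x[fold != k, ], y[fold != k], seed = k,
                          params = list(nrounds = 40L))
    oof[fold == k] <- predict(fit, x[fold == k, ])
  }
  expect_gt(auroc(oof, y), 0.45)
  expect_lt(auroc(oof, y), 0.55)
})

test_that("the lasso comparator imputes with training medians internally", {
  d <- toy_instances(n = 300)
  x <- d$x
  x[sample(length(x), 50)] <- NA
  fit <- fit_risk_model(x, d$y, learner = "l1_logistic", seed = 2)
  p <- predict(fit, x)
  expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1))
  expect_gt(auroc(p, d$y), 0.8)
  expect_s4_class(coef(fit), "dgCMatrix")
})

test_that("constant features give constant scores", {
  d <- toy_instances()
  fit <- fit_risk_model(d$x, d$y, seed = 1)
  const <- matrix(0.5, 10, 4, dimnames = list(NULL, colnames(d$x)))
  expect_length(unique(predict(fit, const)), 1L)
})

test_that("model feature blocks select the specified columns", {
  cols <- c("z_hr", "age_years", "med_ind.med_001", "medhist1", "medhist12")
  expect_setequal(model_feature_columns("A", cols),
                  c("z_hr", "age_years", "medhist1", "medhist12"))
  expect_setequal(model_feature_columns("B", cols),
                  c("z_hr", "age_years", "med_ind.med_001"))
  expect_setequal(model_feature_columns("C", cols), c("z_hr", "age_years"))
  expect_setequal(model_feature_columns("D", cols), c("medhist1", "medhist12"))
})

test_that("feature importance ranks a planted signal first, SHAP is additive", {
  set.seed(12)
  n <- 600
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("signal", paste0("noise", 1:4))))
  y <- as.integer(x[, "signal"] > 0)
  fit <- fit_risk_model(x, y, seed = 4, params = list(nrounds = 60L))
  imp <- feature_importance(fit, x)
  expect_equal(imp$feature[1], "signal")
  expect_equal(imp$feature[which.max(imp$gain)], "signal")
  ## per-row SHAP + bias reproduces the margin
  contrib <- predict(fit$fit, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
  margin <- predict(fit$fit, xgboost::xgb.DMatrix(x), outputmargin = TRUE)
  expect_equal(unname(rowSums(contrib)), unname(margin), tolerance = 1e-5)
  ## unused features get zero gain
  expect_true(all(imp$gain[is.na(match(imp$feature, "signal")) &
                             imp$mean_abs_shap == 0] == 0))
})

test_that("gain and mean-|SHAP| rankings agree on planted-signal fits", {
  set.seed(21)
  n <- 800
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  eta <- 1.5 * x[, 1] + 1.0 * x[, 2] + 0.5 * x[, 3]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_risk_model(x, y, seed = 9, params = list(nrounds = 80L))
  imp <- feature_importance(fit, x)
  expect_gt(cor(rank(imp$gain), rank(imp$mean_abs_shap), method = "spearman"), 0)
})

test_that("score_series returns one bounded probability per grid row", {
  coh <- toy_cohort()
  grid <- build_feature_grid(coh$encounters, coh$observations, coh$medications)
  featcols <- setdiff(names(grid), c("encounter_id", "time", "label"))
  x <- as.matrix(grid[, featcols, with = FALSE])
  fit <- fit_risk_model(x, grid$label, seed = 2, params = list(nrounds = 20L))
  s <- score_series(fit, grid)
  expect_equal(nrow(s), nrow(grid))
  expect_true(all(s$score >= 0 & s$score <= 1))
})
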