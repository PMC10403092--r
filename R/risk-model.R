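## Risk-score modeling: balanced instance sampling, the gradient-boosted
## tree ensemble and L1-regularized logistic comparator, continuous risk
## scoring, and feature importance (split gain + mean |SHAP|).

MODEL_IDS <- c("A", "B", "C", "D")

#' Feature columns for a model id
#'
#' Model feature blocks: A = non-medication + medication-history (`medhist*`),
#' B = non-medication + medication indicators (`med_ind.*`),
#' C = non-medication only, D = medication-history only.
#'
#' @param model_id one of "A", "B", "C", "D".
#' @param columns candidate feature column names.
#' @return character vector of selected columns.
#' @export
model_feature_columns <- function(model_id, columns) {
  model_id <- match.arg(model_id, MODEL_IDS)
  medhist <- grep("^medhist[0-9]+$", columns, value = TRUE)
  indicators <- grep("^med_ind\\.", columns, value = TRUE)
  nonmed <- setdiff(columns, c(medhist, indicators))
  switch(model_id,
         A = c(nonmed, medhist),
         B = c(nonmed, indicators),
         C = nonmed,
         D = medhist)
}

#' Sample balanced training instances
#'
#' Positives are all grid rows in the 12-hour window preceding the MV
#' preparation time of each MV case; negatives are an equal number of grid
#' rows sampled uniformly without replacement across all no-MV encounters.
#' No row in the preparation window `[prep, onset)` can appear (such rows
#' are never materialized on the grid).
#'
#' @param grid feature grid from [build_feature_grid()] (training split).
#' @param encounters encounter table for the same split (for `mv_flag`).
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return data.table of instance rows (same columns as `grid`).
#' @export
sample_training_instances <- function(grid, encounters, seed = 1L) {
  enc <- data.table::as.data.table(encounters)
  pos <- grid[label == 1L]
  if (!nrow(pos)) stop("no positive instances: no MV case contributes rows")
  neg_pool <- grid[encounter_id %in% enc$encounter_id[!enc$mv_flag]]
  if (nrow(neg_pool) < nrow(pos))
    stop(sprintf("insufficient negative rows: need %d, have %d",
                 nrow(pos), nrow(neg_pool)))
  neg <- with_seed(seed, neg_pool[sample.int(.N, nrow(pos))])
  out <- data.table::rbindlist(list(pos, neg))
  out[]
}

#' Fit a risk-score model
#'
#' Fits either the gradient-boosted tree ensemble (`"gbt"`, the default
#' learner; consumes missing values natively) or the L1-regularized logistic
#' regression comparator (`"l1_logistic"`; the feature matrix is imputed
#' with training-set medians, which are stored and re-applied at
#' prediction). Optional stratified k-fold cross-validation tunes the number
#' of boosting rounds (tree path) or the penalty (lasso path); the deployed
#' scorer is refit on the full training set.
#'
#' @param x numeric feature matrix (column names required).
#' @param y 0/1 outcome vector.
#' @param learner `"gbt"` or `"l1_logistic"`.
#' @param model_id optional label ("A".."D") carried in reports.
#' @param params named list of gradient-boosting hyperparameters; defaults:
#'   max_depth 6, min_child_weight 1, subsample 0.8, colsample_bytree 0.8,
#'   eta 0.1, nrounds 150.
#' @param cv_folds folds for cross-validation (0 skips CV).
#' @param seed integer seed (deterministic fits).
#' @return object of class `mv_risk_model`.
#' @export
fit_risk_model <- function(x, y, learner = c("gbt", "l1_logistic"),
                           model_id = NA_character_, params = list(),
                           cv_folds = 0L, seed = 1L) {
  learner <- match.arg(learner)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present to fit")
  stopifnot(is.matrix(x), !is.null(colnames(x)), nrow(x) == length(y))
  defaults <- list(max_depth = 6, min_child_weight = 1, subsample = 0.8,
                   colsample_bytree = 0.8, eta = 0.1, nrounds = 150L)
  params <- utils::modifyList(defaults, params)
  out <- list(learner = learner, model_id = model_id,
              feature_names = colnames(x), params = params, seed = seed,
              n_train = nrow(x), cv = NULL)
  if (learner == "gbt") {
    xgb_params <- list(objective = "binary:logistic",
                       max_depth = params$max_depth,
                       min_child_weight = params$min_child_weight,
                       subsample = params$subsample,
                       colsample_bytree = params$colsample_bytree,
                       eta = params$eta, nthread = 1, seed = seed,
                       eval_metric = "auc")
    dtrain <- xgboost::xgb.DMatrix(x, label = y, missing = NA)
    nrounds <- params$nrounds
    if (cv_folds > 1L) {
      cv <- with_seed(seed, xgboost::xgb.cv(
        params = xgb_params, data = dtrain, nrounds = params$nrounds,
        nfold = cv_folds, stratified = TRUE, early_stopping_rounds = 20,
        verbose = 0))
      nrounds <- cv$best_iteration %||% params$nrounds
      ev <- as.data.frame(cv$evaluation_log)
      out$cv <- list(best_iteration = nrounds,
                     cv_auc = ev$test_auc_mean[nrounds])
    }
    out$fit <- with_seed(seed, xgboost::xgb.train(
      params = xgb_params, data = dtrain, nrounds = nrounds, verbose = 0))
    out$nrounds <- nrounds
  } else {
    out$medians <- fit_medians(x)
    xi <- impute_median(x, out$medians)
    out$fit <- with_seed(seed, {
      if (cv_folds > 1L) {
        cvfit <- glmnet::cv.glmnet(xi, y, family = "binomial", alpha = 1,
                                   nfolds = cv_folds)
        out$cv <- list(lambda_min = cvfit$lambda.min)
        cvfit
      } else {
        glmnet::cv.glmnet(xi, y, family = "binomial", alpha = 1, nfolds = 5)
      }
    })
  }
  class(out) <- "mv_risk_model"
  out
}

#' @export
print.mv_risk_model <- function(x, ...) {
  cat(sprintf("MV risk-score model%s (%s)\n",
              if (is.na(x$model_id)) "" else paste0(" ", x$model_id),
              if (x$learner == "gbt") "gradient-boosted trees"
              else "L1-regularized logistic regression"))
  cat(sprintf("  features: %d, training instances: %d\n",
              length(x$feature_names), x$n_train))
  if (x$learner == "gbt")
    cat(sprintf("  boosting rounds: %d (eta %.3g, depth %d)\n",
                x$nrounds, x$params$eta, x$params$max_depth))
  if (!is.null(x$cv$cv_auc))
    cat(sprintf("  cross-validated AUROC: %.3f\n", x$cv$cv_auc))
  invisible(x)
}

#' @export
summary.mv_risk_model <- function(object, ...) {
  print(object)
  cat("\nTop features by gain:\n")
  imp <- try(feature_importance(object), silent = TRUE)
  if (!inherits(imp, "try-error")) print(utils::head(imp, 10))
  invisible(object)
}

#' @export
coef.mv_risk_model <- function(object, ...) {
  if (object$learner != "l1_logistic")
    stop("coefficients are only defined for the l1_logistic learner")
  stats::coef(object$fit, s = "lambda.min")
}

#' Predict risk scores
#'
#' @param object an `mv_risk_model`.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return class-1 probabilities in \[0, 1\].
#' @export
predict.mv_risk_model <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_names, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$feature_names)
  if (length(miss))
    stop(sprintf("newdata lacks training feature column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  newdata <- newdata[, object$feature_names, drop = FALSE]
  if (object$learner == "gbt") {
    as.numeric(stats::predict(object$fit,
                              xgboost::xgb.DMatrix(newdata, missing = NA)))
  } else {
    xi <- impute_median(newdata, object$medians)
    as.numeric(stats::predict(object$fit, xi, s = "lambda.min",
                              type = "response"))
  }
}

#' Score a feature grid as a risk-score series
#'
#' One probability per retained grid row, from admission up to the MV
#' preparation time (MV cases) or discharge (no-MV cases).
#'
#' @param model an `mv_risk_model`.
#' @param grid feature grid from [build_feature_grid()].
#' @return data.table: `encounter_id`, `time`, `score`.
#' @export
score_series <- function(model, grid) {
  x <- as.matrix(grid[, model$feature_names, with = FALSE])
  data.table::data.table(encounter_id = grid$encounter_id, time = grid$time,
                         score = predict(model, x))
}

#' Feature importance: split gain and mean |SHAP|
#'
#' For the tree ensemble, gain is the model's split-gain attribution and
#' SHAP values come from the tree-path decomposition; for the linear
#' comparator gain is unavailable (NA) and SHAP values are the exact linear
#' attributions `beta_j (x_ij - mean(x_j))`. Mean |SHAP| is averaged over
#' the supplied rows (training instances).
#'
#' @param model an `mv_risk_model`.
#' @param x rows over which to average |SHAP| (defaults: required for SHAP;
#'   omit for gain-only).
#' @return data.table (feature, gain, mean_abs_shap), sorted by
#'   `mean_abs_shap` (or gain when SHAP is not computed) descending.
#' @export
feature_importance <- function(model, x = NULL) {
  feats <- model$feature_names
  gain <- rep(NA_real_, length(feats))
  if (model$learner == "gbt") {
    imp <- xgboost::xgb.importance(model = model$fit)
    gain <- rep(0, length(feats))  # features never used in a split get 0
    gain[match(imp$Feature, feats)] <- imp$Gain
  }
  shap <- rep(NA_real_, length(feats))
  if (!is.null(x)) {
    x <- x[, feats, drop = FALSE]
    if (model$learner == "gbt") {
      contrib <- stats::predict(model$fit, xgboost::xgb.DMatrix(x, missing = NA),
                                predcontrib = TRUE)
      shap <- colMeans(abs(contrib[, feats, drop = FALSE]))
    } else {
      beta <- as.numeric(stats::coef(model$fit, s = "lambda.min"))[-1]
      xi <- impute_median(x, model$medians)
      centered <- sweep(xi, 2, colMeans(xi))
      shap <- colMeans(abs(sweep(centered, 2, beta, `*`)))
    }
  }
  out <- data.table::data.table(feature = feats, gain = gain,
                                mean_abs_shap = shap)
  key <- if (all(is.na(shap))) out$gain else out$mean_abs_shap
  out[order(-key)][]
}
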