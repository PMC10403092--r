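## End-to-end experiment driver: generate -> filter -> split -> featurize ->
## fit -> threshold -> EPP/EWT -> risk groups -> reports, under one config
## with full seed propagation. Scoring is streamed over encounter chunks so
## the full feature matrix for a cohort never has to be materialized.

#' Experiment run configuration
#'
#' Bundles the stage configurations and derives every stage seed
#' deterministically from the global `seed`.
#'
#' @param seed global integer seed.
#' @param n_encounters cohort size for the default generator.
#' @param signal_strength planted signal scale for the default generator.
#' @param generator optional [generator_config()] (overrides the two
#'   arguments above).
#' @param filter a [cohort_filter_config()].
#' @param extractor a [conv_extractor_config()]; default skips the CNN's
#'   internal cross-validation pass for speed (set `folds` to enable).
#' @param models model ids to fit, in order; the first is the primary model
#'   used for risk grouping and feature importance.
#' @param learner `"gbt"` or `"l1_logistic"`.
#' @param gbt_params gradient-boosting hyperparameter overrides.
#' @param cv_folds cross-validation folds for hyperparameter confirmation
#'   inside the model fit (0 = none).
#' @param score_cv_folds folds for out-of-fold scoring of training-set
#'   courses: each training encounter's risk-score series comes from a model
#'   fit without that encounter's instances, mirroring cross-validated
#'   scoring of the training course; the held-out test set is always scored
#'   by the final refit model. 0 scores everything with the final model.
#' @param evaluate_b_variants also evaluate the dual-threshold (B1) and
#'   waiting-period (B2) alerting schemes for Model B.
#' @param risk_group_K,risk_group_kmax,k_nn risk-grouping parameters.
#' @param stability_boot bootstrap draws for cluster stability (0 = skip).
#' @param train_fraction train split fraction.
#' @param chunk_rows approximate grid rows per scoring chunk.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_encounters = 2000L, signal_strength = 2,
                       generator = NULL, filter = cohort_filter_config(),
                       extractor = NULL,
                       models = c("A", "B", "C", "D"),
                       learner = c("gbt", "l1_logistic"),
                       gbt_params = list(), cv_folds = 0L,
                       score_cv_folds = 10L,
                       evaluate_b_variants = FALSE,
                       risk_group_K = 200L, risk_group_kmax = 8L, k_nn = 15L,
                       stability_boot = 0L, train_fraction = 0.8,
                       chunk_rows = 400000L) {
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(generator))
    generator <- generator_config(n_encounters = n_encounters,
                                  signal_strength = signal_strength,
                                  seed = derive_seed(seed, "generate"))
  if (is.null(extractor))
    extractor <- conv_extractor_config(folds = 0L, seed = derive_seed(seed, "cnn"))
  models <- match.arg(models, MODEL_IDS, several.ok = TRUE)
  structure(list(seed = seed, generator = generator, filter = filter,
                 extractor = extractor, models = models,
                 learner = match.arg(learner), gbt_params = gbt_params,
                 cv_folds = check_count(cv_folds, "cv_folds", min = 0L),
                 score_cv_folds = check_count(score_cv_folds, "score_cv_folds",
                                              min = 0L),
                 evaluate_b_variants = isTRUE(evaluate_b_variants),
                 risk_group_K = check_count(risk_group_K, "risk_group_K"),
                 risk_group_kmax = check_count(risk_group_kmax, "risk_group_kmax"),
                 k_nn = check_count(k_nn, "k_nn"),
                 stability_boot = check_count(stability_boot, "stability_boot", min = 0L),
                 train_fraction = check_fraction(train_fraction, "train_fraction"),
                 chunk_rows = check_count(chunk_rows, "chunk_rows")),
            class = "run_config")
}

## positive instance rows: all grid times in [prep - 12 h, prep) per MV case
positive_instance_rows <- function(enc, grid_step = 5L, prep_minutes = 30L,
                                   positive_window_minutes = 720L) {
  mv <- enc[enc$mv_flag, ]
  if (!nrow(mv)) stop("no MV encounters in the training split")
  prep <- mv$mv_onset_time - prep_minutes
  rows <- lapply(seq_len(nrow(mv)), function(i) {
    lo <- max(0, ceiling((prep[i] - positive_window_minutes) / grid_step) * grid_step)
    hi <- floor((prep[i] - 1) / grid_step) * grid_step
    if (hi < lo) return(NULL)
    data.table::data.table(encounter_id = mv$encounter_id[i],
                           time = as.integer(seq(lo, hi, by = grid_step)))
  })
  data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
}

## uniform random control grid rows without replacement, drawn by index
## arithmetic over per-encounter row counts (no grid materialization)
negative_instance_rows <- function(enc, n_needed, seed, grid_step = 5L) {
  ctrl <- enc[!enc$mv_flag, ]
  n_rows <- floor(as.numeric(ctrl$discharge_time) / grid_step) + 1L
  total <- sum(n_rows)
  if (total < n_needed)
    stop(sprintf("insufficient negative rows: need %d, have %d", n_needed, total))
  idx <- with_seed(seed, sample(total, n_needed))
  cum <- cumsum(n_rows)
  enc_i <- findInterval(idx - 1L, c(0L, cum), rightmost.closed = FALSE)
  offset <- idx - c(0L, cum)[enc_i] - 1L
  data.table::data.table(encounter_id = ctrl$encounter_id[enc_i],
                         time = as.integer(offset * grid_step))
}

## encounter chunks of roughly chunk_rows grid rows each
encounter_chunks <- function(enc, chunk_rows, grid_step = 5L, prep_minutes = 30L) {
  prep <- ifelse(enc$mv_flag, enc$mv_onset_time - prep_minutes,
                 as.numeric(enc$discharge_time))
  n_rows <- pmax(floor(prep / grid_step), 0) + 1L
  grp <- cumsum(n_rows) %/% chunk_rows
  split(seq_len(nrow(enc)), grp)
}

#' Run the full early-warning experiment
#'
#' Generates (or consumes) a cohort, applies the inclusion/exclusion
#' flowchart, splits encounters, learns the medication-history extractor and
#' indicator set on the training split, samples balanced instances, fits the
#' requested models, selects max-F1 thresholds on training-set maximum
#' scores, computes EPP/EWT and the encounter-level evaluation on the
#' held-out test set, clusters post-EPP trajectories of the primary model
#' into risk groups with KNN transfer to test encounters, and evaluates the
#' PEWS comparators.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-generated cohort list (tables `encounters`,
#'   `observations`, `medications`); defaults to
#'   `generate_cohort(config$generator)`.
#' @return object of class `mv_experiment`.
#' @export
run_experiment <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  prep_minutes <- config$filter$prep_window_minutes

  if (is.null(cohort)) {
    message("generating cohort ...")
    cohort <- generate_cohort(config$generator)
  }
  filt <- apply_inclusion_exclusion(cohort$encounters, cohort$observations,
                                    config$filter)
  enc <- filt$retained
  obs <- data.table::as.data.table(cohort$observations)[encounter_id %in% enc$encounter_id]
  meds <- data.table::as.data.table(cohort$medications)[encounter_id %in% enc$encounter_id]

  split <- stratified_split(enc, config$train_fraction,
                            seed = derive_seed(seed, "split"))
  enc[, in_train := encounter_id %in% split$train]
  train_enc <- enc[in_train == TRUE]
  test_enc <- enc[in_train == FALSE]
  tr_meds <- meds[encounter_id %in% train_enc$encounter_id]

  ## medication feature learning (training split only)
  need_medhist <- any(config$models %in% c("A", "D"))
  need_indicators <- "B" %in% config$models
  extractor <- NULL; embeddings <- NULL; selected <- NULL
  if (need_medhist) {
    message("training medication-history extractor ...")
    corpus <- build_training_corpus(tr_meds, train_enc,
                                    prep_minutes = prep_minutes)
    embeddings <- fit_embeddings(corpus$sentences,
                                 seed = derive_seed(seed, "glove"))
    extractor <- train_extractor(corpus$sentences, corpus$labels,
                                 config$extractor, embeddings)
  }
  if (need_indicators)
    selected <- select_indicator_meds(tr_meds, train_enc,
                                      prep_minutes = prep_minutes)

  ## balanced training instances
  message("building training instances ...")
  pos_rows <- positive_instance_rows(train_enc, prep_minutes = prep_minutes)
  neg_rows <- negative_instance_rows(train_enc, nrow(pos_rows),
                                     seed = derive_seed(seed, "sample"))
  inst_rows <- data.table::rbindlist(list(pos_rows, neg_rows))
  inst <- build_features_at(inst_rows, train_enc, obs, meds,
                            selected_meds = selected, extractor = extractor,
                            prep_minutes = prep_minutes)
  featcols <- feature_columns(inst)
  x_inst <- as.matrix(inst[, featcols, with = FALSE])
  y_inst <- inst$label

  message("fitting risk models ...")
  fits <- list()
  for (m in config$models) {
    cols <- model_feature_columns(m, featcols)
    fits[[m]] <- fit_risk_model(x_inst[, cols, drop = FALSE], y_inst,
                                learner = config$learner, model_id = m,
                                params = config$gbt_params,
                                cv_folds = config$cv_folds,
                                seed = derive_seed(seed, "fit") + match(m, MODEL_IDS))
  }

  ## fold models for out-of-fold scoring of training courses
  fold_models <- NULL; fold_of <- NULL
  if (config$score_cv_folds > 1L) {
    message("fitting fold models for cross-validated training scores ...")
    fold_of <- with_seed(derive_seed(seed, "fit") + 97L,
                         setNames(stratified_folds(as.integer(train_enc$mv_flag),
                                                   config$score_cv_folds),
                                  train_enc$encounter_id))
    inst_fold <- fold_of[inst$encounter_id]
    fold_models <- list()
    for (m in config$models) {
      cols <- model_feature_columns(m, featcols)
      fold_models[[m]] <- lapply(seq_len(config$score_cv_folds), function(k) {
        keep <- is.na(inst_fold) | inst_fold != k
        fit_risk_model(x_inst[keep, cols, drop = FALSE], y_inst[keep],
                       learner = config$learner, model_id = m,
                       params = config$gbt_params, cv_folds = 0L,
                       seed = derive_seed(seed, "fit") + 100L * k + match(m, MODEL_IDS))
      })
    }
  }

  ## streamed scoring over encounter chunks
  message("scoring encounter courses ...")
  score_cols <- paste0("score_", config$models)
  chunks <- encounter_chunks(enc, config$chunk_rows, prep_minutes = prep_minutes)
  pieces <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    enc_c <- enc[chunks[[ci]]]
    rows <- grid_rows(enc_c, prep_minutes = prep_minutes)
    g <- build_features_at(rows, enc_c,
                           obs[encounter_id %in% enc_c$encounter_id],
                           meds[encounter_id %in% enc_c$encounter_id],
                           selected_meds = selected, extractor = extractor,
                           prep_minutes = prep_minutes)
    piece <- g[, .(encounter_id, time)]
    gf <- if (is.null(fold_of)) rep(NA_integer_, nrow(g))
          else fold_of[g$encounter_id]
    for (m in config$models) {
      xm <- as.matrix(g[, fits[[m]]$feature_names, with = FALSE])
      sc <- predict(fits[[m]], xm)
      ## training rows are re-scored by the model that never saw them
      if (!is.null(fold_models)) {
        for (k in unique(gf[!is.na(gf)])) {
          ridx <- which(!is.na(gf) & gf == k)
          sc[ridx] <- predict(fold_models[[m]][[k]], xm[ridx, , drop = FALSE])
        }
      }
      data.table::set(piece, j = paste0("score_", m), value = sc)
    }
    pieces[[ci]] <- piece
  }
  series <- data.table::rbindlist(pieces)
  rm(pieces)

  ## per-encounter maxima and thresholds (max-F1 on the training split)
  maxs <- series[, lapply(.SD, max), by = encounter_id, .SDcols = score_cols]
  maxs <- merge(maxs, enc[, .(encounter_id, mv_flag, in_train,
                              mv_onset_time)], by = "encounter_id")
  thresholds <- list(); reports <- list(); epps_all <- list()
  for (m in config$models) {
    sc <- paste0("score_", m)
    sel <- select_threshold(maxs[in_train == TRUE][[sc]],
                            maxs[in_train == TRUE]$mv_flag)
    thresholds[[m]] <- sel$tau
    ## single-scheme EPP: first grid time at or above tau
    ep <- series[get(sc) >= sel$tau, .(epp = min(time)), by = encounter_id]
    epp <- ep$epp[match(maxs$encounter_id, ep$encounter_id)]
    epps_all[[m]] <- data.table::data.table(encounter_id = maxs$encounter_id,
                                            epp = as.numeric(epp))
    te <- maxs$in_train == FALSE
    reports[[m]] <- evaluate_encounters(maxs[[sc]][te], epp[te],
                                        maxs$mv_flag[te],
                                        maxs$mv_onset_time[te], tau = sel$tau)
  }

  ## Model-B alerting variants (dual threshold, waiting period)
  variant_reports <- list()
  if (config$evaluate_b_variants && "B" %in% config$models) {
    variant_reports <- evaluate_b_variants(series, maxs, thresholds[["B"]])
  }

  ## risk grouping on the primary model
  message("risk grouping ...")
  m1 <- config$models[1]
  sc1 <- paste0("score_", m1)
  ser1 <- series[, .(encounter_id, time, score = get(sc1))]
  ep1 <- epps_all[[m1]]
  risk_groups <- NULL
  tr_pos <- merge(ep1[!is.na(epp)], enc[, .(encounter_id, in_train)],
                  by = "encounter_id")[in_train == TRUE]
  if (nrow(tr_pos) >= 3L) {
    epps_tr <- setNames(tr_pos$epp, tr_pos$encounter_id)
    tr_traj <- extract_trajectories(ser1, epps_tr)
    if (!is.null(tr_traj$trajectories) && nrow(tr_traj$trajectories) >= 3L) {
      rg <- fit_risk_groups(tr_traj$trajectories, K = config$risk_group_K,
                            k_max = config$risk_group_kmax,
                            seed = derive_seed(seed, "cluster"),
                            k_nn = config$k_nn)
      stability <- if (config$stability_boot > 0L)
        stability_jaccard(tr_traj$trajectories, n_boot = config$stability_boot,
                          K = config$risk_group_K, k_max = config$risk_group_kmax,
                          seed = derive_seed(seed, "cluster"))
      else NULL
      group_table <- function(labels, truncated_ids) {
        tt <- data.table::data.table(encounter_id = names(labels),
                                     group = rg$group_names[labels],
                                     group_rank = as.integer(labels),
                                     truncated = names(labels) %in% truncated_ids)
        tt <- merge(tt, enc[, .(encounter_id, mv_flag, mv_onset_time)],
                    by = "encounter_id")
        tt <- merge(tt, ep1, by = "encounter_id")
        tt[, ewt_hours := compute_ewt(epp, mv_onset_time)]
        tt
      }
      ## training positives keep their reference cluster labels; truncated
      ## ones (padded prefixes) receive transferred labels
      tr_labels <- setNames(rg$labels, rownames(rg$trajectories))
      if (!is.null(tr_traj$padded) && nrow(tr_traj$padded))
        tr_labels <- c(tr_labels, transfer_labels(rg, tr_traj$padded))
      train_table <- group_table(tr_labels, tr_traj$excluded$encounter_id)
      te_pos <- merge(ep1[!is.na(epp)], enc[, .(encounter_id, in_train)],
                      by = "encounter_id")[in_train == FALSE]
      test_table <- NULL
      if (nrow(te_pos)) {
        epps_te <- setNames(te_pos$epp, te_pos$encounter_id)
        te_traj <- extract_trajectories(ser1, epps_te)
        mat <- rbind(te_traj$trajectories, te_traj$padded)
        test_table <- group_table(transfer_labels(rg, mat),
                                  te_traj$excluded$encounter_id)
      }
      combined_table <- data.table::rbindlist(
        list(train_table, test_table), use.names = TRUE)
      risk_groups <- list(
        model = rg, stability = stability, test_table = test_table,
        train_table = train_table, combined_table = combined_table,
        n_train_trajectories = nrow(tr_traj$trajectories),
        n_train_truncated = nrow(tr_traj$excluded),
        table = if (!is.null(test_table))
          group_metrics(test_table$group_rank, test_table$mv_flag,
                        test_table$ewt_hours, rg$group_names)
        else NULL,
        combined_metrics = group_metrics(combined_table$group_rank,
                                         combined_table$mv_flag,
                                         combined_table$ewt_hours,
                                         rg$group_names))
    }
  }

  message("PEWS comparator ...")
  pews <- suppressWarnings(
    pews_comparator(obs[encounter_id %in% test_enc$encounter_id], test_enc))

  importance <- feature_importance(
    fits[[m1]], x_inst[, fits[[m1]]$feature_names, drop = FALSE])

  structure(list(
    config = config,
    n_generated = nrow(cohort$encounters),
    exclusion_log = filt$log,
    n_retained = nrow(enc),
    split = list(n_train = nrow(train_enc), n_test = nrow(test_enc)),
    selected_meds = selected,
    extractor = extractor,
    fits = fits,
    thresholds = thresholds,
    reports = reports,
    variant_reports = variant_reports,
    risk_groups = risk_groups,
    importance = importance,
    pews = pews,
    encounters = enc,
    instance_rows = inst_rows[, .(encounter_id, time)],
    instance_labels = y_inst,
    epps = epps_all,
    max_scores = maxs,
    series = ser1), class = "mv_experiment")
}

## B1 (dual threshold) / B2 (waiting period) evaluation; tau2 maximizes
## precision subject to retaining >= 90% of the single-threshold sensitivity
evaluate_b_variants <- function(series, maxs, tau) {
  tr <- maxs[in_train == TRUE]
  sens_at <- function(t2) mean(tr$score_B[tr$mv_flag] >= t2)
  prec_at <- function(t2) {
    p <- tr$score_B >= t2
    if (!any(p)) return(0)
    mean(tr$mv_flag[p])
  }
  base_sens <- sens_at(tau)
  cand <- sort(unique(tr$score_B[tr$score_B >= tau]))
  ok <- cand[vapply(cand, sens_at, 0) >= 0.9 * base_sens]
  if (!length(ok)) ok <- tau
  prec <- vapply(ok, prec_at, 0)
  tau2 <- max(ok[prec >= max(prec) - 1e-12])
  policies <- list(
    B1 = threshold_policy("dual_threshold", tau = tau, tau2 = tau2),
    B2 = threshold_policy("waiting_period", tau = tau, wait_hours = 1))
  te_ids <- maxs[in_train == FALSE]$encounter_id
  out <- list()
  for (v in names(policies)) {
    pol <- policies[[v]]
    ep <- series[encounter_id %in% te_ids,
                 .(epp = as.numeric(compute_epp(time, score_B, pol))),
                 by = encounter_id]
    te <- maxs[in_train == FALSE]
    epp <- ep$epp[match(te$encounter_id, ep$encounter_id)]
    out[[v]] <- evaluate_encounters(te$score_B, epp, te$mv_flag,
                                    te$mv_onset_time, tau = tau)
    out[[v]]$policy <- pol
  }
  out
}

#' @export
print.mv_experiment <- function(x, ...) {
  cat(sprintf("MV early-warning experiment: %d generated, %d retained (%d train / %d test)\n",
              x$n_generated, x$n_retained, x$split$n_train, x$split$n_test))
  cat("\nHeld-out test performance:\n")
  tab <- summary_table(x)
  print(tab, row.names = FALSE)
  if (!is.null(x$risk_groups$table)) {
    cat("\nRisk groups (test set, primary model):\n")
    print(x$risk_groups$table, row.names = FALSE)
  }
  invisible(x)
}

#' Model comparison summary table
#'
#' @param x an `mv_experiment`.
#' @return data.table with one row per fitted model.
#' @export
summary_table <- function(x) {
  rows <- lapply(names(x$reports), function(m) {
    r <- x$reports[[m]]
    data.table::data.table(model = m, threshold = round(r$threshold, 4),
                           auroc = round(r$auroc, 3), auprc = round(r$auprc, 3),
                           sensitivity = round(r$sensitivity, 2),
                           specificity = round(r$specificity, 2),
                           ppv = round(r$ppv, 2), npv = round(r$npv, 2),
                           f1 = round(r$f1, 2),
                           ewt_median_h = round(r$ewt_hours[["median"]], 1))
  })
  data.table::rbindlist(rows)
}

#' Write experiment reports to a directory
#'
#' Writes the model-comparison table, per-model evaluation reports, risk
#' group table, feature importance, exclusion log, and a manifest (seed and
#' package version) as JSON/CSV files.
#'
#' @param x an `mv_experiment`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(lapply(x$reports, function(r)
    r[c("threshold", "n", "auroc", "auprc", "tp", "fp", "fn", "tn",
        "sensitivity", "specificity", "ppv", "npv", "f1", "ewt_hours")]),
    file.path(dir, "eval_reports.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(summary_table(x), file.path(dir, "model_comparison.csv"))
  if (!is.null(x$risk_groups$table))
    data.table::fwrite(x$risk_groups$table, file.path(dir, "risk_groups.csv"))
  if (!is.null(x$risk_groups$test_table))
    data.table::fwrite(x$risk_groups$test_table[, .(encounter_id, group, epp,
                                                    ewt_hours, mv_flag)],
                       file.path(dir, "risk_group_assignments.csv"))
  data.table::fwrite(x$importance, file.path(dir, "feature_importance.csv"))
  data.table::fwrite(x$exclusion_log, file.path(dir, "exclusion_log.csv"))
  jsonlite::write_json(list(seed = x$config$seed,
                            n_generated = x$n_generated,
                            package_version = as.character(utils::packageVersion("ventwarn"))),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; the nested
#' `generator`, `filter` and `extractor` maps are passed to
#' [generator_config()], [cohort_filter_config()] and
#' [conv_extractor_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("generator", "filter", "extractor"))]
  if (!is.null(y$generator))
    args$generator <- do.call(generator_config, y$generator)
  if (!is.null(y$filter))
    args$filter <- do.call(cohort_filter_config, y$filter)
  if (!is.null(y$extractor))
    args$extractor <- do.call(conv_extractor_config, y$extractor)
  do.call(run_config, args)
}
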