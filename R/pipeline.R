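## End-to-end orchestration: ingest/generate -> screen descriptors -> cluster
## -aware split -> CV plan -> optional tuning -> fit PC-GBM / BNN / SR ->
## conformal + Bayesian intervals -> ensemble -> metrics -> Y-scrambling,
## applicability domain, associations -> sensitivity.  One global seed fans
## out to per-stage sub-seeds via derive_seed() so stages are individually
## reproducible; test rows are untouched until final evaluation.

#' Build a pipeline configuration
#'
#' Exactly one input source must be given: a CSV `input` path or generator
#' settings (`n`).  The seed is mandatory.
#'
#' @param input optional CSV path of compounds x descriptors (+ pIGC50).
#' @param n synthetic sample size when generating.
#' @param seed global seed (mandatory).
#' @param models character subset of `c("gbm", "bnn", "sr", "ensemble")`.
#' @param frac,n_clusters cluster-aware split parameters.
#' @param k_folds CV folds on the training set.
#' @param tau,r_max,k_select descriptor screening parameters (`k_select =
#'   NULL` keeps all survivors).
#' @param tune_budget surrogate-optimization evaluations per model (0 = off).
#' @param nominal nominal interval level.
#' @param n_perm Y-scrambling permutations.
#' @param n_anchors,grid_size sensitivity parameters.
#' @param gbm,bnn,sr model configurations (defaults used when `NULL`).
#' @param outdir optional output directory for report.json / CSVs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, n = NULL, seed,
                            models = c("gbm", "bnn", "ensemble"),
                            frac = 0.2, n_clusters = 10, k_folds = 10,
                            tau = 1e-8, r_max = 0.9, k_select = NULL,
                            tune_budget = 0, nominal = 0.95, n_perm = 20,
                            n_anchors = 200, grid_size = 21,
                            gbm = NULL, bnn = NULL, sr = NULL,
                            outdir = NULL) {
  if (missing(seed)) stop_tox("pipeline seed is mandatory")
  if (is.null(input) == is.null(n))
    stop_tox("exactly one input source: give either `input` or `n`")
  models <- match.arg(models, c("gbm", "bnn", "sr", "ensemble"),
                      several.ok = TRUE)
  if (!length(models)) stop_tox("no models enabled")
  if ("ensemble" %in% models &&
      !all(c("gbm", "bnn") %in% models))
    stop_tox("the ensemble aggregates PC-GBM and BNN; enable both")
  structure(list(input = input, n = n, seed = as.integer(seed),
                 models = models, frac = frac, n_clusters = n_clusters,
                 k_folds = k_folds, tau = tau, r_max = r_max,
                 k_select = k_select, tune_budget = tune_budget,
                 nominal = nominal, n_perm = n_perm, n_anchors = n_anchors,
                 grid_size = grid_size, gbm = gbm, bnn = bnn, sr = sr,
                 outdir = outdir),
            class = "pipeline_config")
}

stage_log <- function(fmt, ...) {
  message(sprintf("[toxqsar] %s", sprintf(fmt, ...)))
}

config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "outdir")]
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 97 + 1)) %% 2^31
}

#' Run the full modeling pipeline
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report` (per-model metrics, fold table,
#'   Y-scrambling, applicability domain, sensitivity, importances,
#'   provenance).  Written as `report.json` plus prediction CSVs when
#'   `config$outdir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]

  ## stage 1: ingest or generate -------------------------------------------
  stage_log("stage ingest")
  tab <- if (!is.null(config$input)) {
    read_compound_table(config$input)
  } else {
    gen <- calibrate_generator(generator_config())
    generate_compounds(gen, config$n, seed = derive_seed(config$seed, 1L))
  }
  if (is.null(tab$y)) stop_tox("stage ingest: input has no pIGC50 target")

  ## stage 2: cluster-aware split ------------------------------------------
  stage_log("stage split")
  split <- cluster_aware_split(tab$X, frac = config$frac,
                               n_clusters = config$n_clusters,
                               seed = derive_seed(config$seed, 2L))
  train <- table_subset(tab, split$train_idx)
  test <- table_subset(tab, split$test_idx)

  ## stage 3: descriptor screening (training rows only) --------------------
  stage_log("stage preprocess")
  folds <- kfold_plan(nrow(train$X), k = min(config$k_folds, nrow(train$X)),
                      seed = derive_seed(config$seed, 3L))
  prep <- preprocess_chain(train, tau = config$tau, r_max = config$r_max,
                           k = config$k_select, folds = folds)
  keep <- colnames(prep$table$X)
  train <- compound_table(train$ids, train$X[, keep, drop = FALSE], train$y,
                          train$specs[keep])
  test <- compound_table(test$ids, test$X[, keep, drop = FALSE], test$y,
                         test$specs[keep])
  scaler <- fit_scaler(train)
  train_z <- apply_scaler(scaler, train)
  test_z <- apply_scaler(scaler, test)

  gbm_cfg <- if (is.null(config$gbm))
    gbm_config(constraints = constraint_map(train$specs),
               seed = derive_seed(config$seed, 5L)) else config$gbm
  bnn_cfg <- if (is.null(config$bnn))
    bnn_config(seed = derive_seed(config$seed, 6L)) else config$bnn
  sr_cfg <- if (is.null(config$sr))
    sr_config(seed = derive_seed(config$seed, 7L)) else config$sr

  ## stage 4: optional tuning ----------------------------------------------
  tuning <- list()
  if (config$tune_budget > 0) {
    stage_log("stage tune (budget %d)", config$tune_budget)
    tune_folds <- kfold_plan(nrow(train$X), k = 5,
                             seed = derive_seed(config$seed, 8L))
    if ("gbm" %in% config$models) {
      tr <- tune_model(gbm_tune_factory(constraint_map(train$specs),
                                        config$nominal, gbm_cfg),
                       gbm_search_space(), train$X, train$y, tune_folds,
                       budget = config$tune_budget,
                       seed = derive_seed(config$seed, 9L),
                       nominal = config$nominal)
      for (nm in names(tr$best_config)) gbm_cfg[[nm]] <- tr$best_config[[nm]]
      gbm_cfg$n_estimators <- as.integer(gbm_cfg$n_estimators)
      gbm_cfg$max_depth <- as.integer(gbm_cfg$max_depth)
      tuning$gbm <- list(best_config = tr$best_config,
                         best_loss = tr$best_loss)
    }
    if ("bnn" %in% config$models) {
      tr <- tune_model(bnn_tune_factory(config$nominal, bnn_cfg),
                       bnn_search_space(), train_z$X, train$y, tune_folds,
                       budget = config$tune_budget,
                       seed = derive_seed(config$seed, 10L),
                       nominal = config$nominal)
      for (nm in names(tr$best_config)) bnn_cfg[[nm]] <- tr$best_config[[nm]]
      bnn_cfg$patience <- as.integer(bnn_cfg$patience)
      bnn_cfg$mc_samples <- as.integer(bnn_cfg$mc_samples)
      tuning$bnn <- list(best_config = tr$best_config,
                         best_loss = tr$best_loss)
    }
  }

  ## stage 5: cross-validation (fold table + out-of-fold residuals) --------
  stage_log("stage cross-validate")
  fold_rows <- list()
  oof_pred <- rep(NA_real_, nrow(train$X))
  for (f in seq_len(folds$k)) {
    tr_i <- folds$fold_assignments != f
    m <- fit_pcgbm(train$X[tr_i, , drop = FALSE], train$y[tr_i], gbm_cfg)
    pv <- predict(m, train$X[!tr_i, , drop = FALSE])
    oof_pred[!tr_i] <- pv
    yv <- train$y[!tr_i]
    pm <- point_metrics(prediction_set(yv, pv))
    fold_rows[[f]] <- data.frame(
      fold = f, train_size = sum(tr_i), val_size = sum(!tr_i),
      rmse = pm$rmse, r2 = pm$r2, mean_actual = mean(yv),
      mean_predicted = mean(pv), std_actual = sd(yv), std_predicted = sd(pv))
  }
  fold_table <- do.call(rbind, fold_rows)
  oof_abs_resid <- abs(train$y - oof_pred)
  cv_ps <- prediction_set(train$y, oof_pred)
  cv_point <- point_metrics(cv_ps)

  ## stage 6: final fits + test evaluation ---------------------------------
  stage_log("stage fit/evaluate")
  predictions <- list()
  model_metrics <- list()
  cv_rmse <- c()
  models_fitted <- list()

  if ("gbm" %in% config$models) {
    gbm_fit <- fit_pcgbm(train$X, train$y, gbm_cfg)
    models_fitted$gbm <- gbm_fit
    ps_test <- conformal_intervals(test$y, predict(gbm_fit, test$X),
                                   oof_abs_resid, config$nominal)
    ps_train <- prediction_set(train$y, gbm_fit$train_pred)
    predictions$gbm <- ps_test
    cv_rmse["gbm"] <- cv_point$rmse
    model_metrics$gbm <- list(
      train = metric_report(point_metrics(ps_train), ps = ps_train),
      cv = metric_report(cv_point, ps = cv_ps),
      test = metric_report(point_metrics(ps_test),
                           interval_metrics(ps_test, config$nominal),
                           ps_test))
  }

  if ("bnn" %in% config$models) {
    bnn_fit <- fit_bnn(train_z$X, train$y, bnn_cfg)
    models_fitted$bnn <- bnn_fit
    ps_test <- predict_dist(bnn_fit, test_z$X, y = test$y,
                            level = config$nominal,
                            seed = derive_seed(config$seed, 11L))
    ps_train <- prediction_set(train$y, predict(bnn_fit, train_z$X))
    bnn_oof <- rep(NA_real_, nrow(train$X))
    for (f in seq_len(folds$k)) {
      tr_i <- folds$fold_assignments != f
      mb <- fit_bnn(train_z$X[tr_i, , drop = FALSE], train$y[tr_i], bnn_cfg)
      bnn_oof[!tr_i] <- predict(mb, train_z$X[!tr_i, , drop = FALSE])
    }
    bnn_cv_ps <- prediction_set(train$y, bnn_oof)
    predictions$bnn <- ps_test
    cv_rmse["bnn"] <- point_metrics(bnn_cv_ps)$rmse
    model_metrics$bnn <- list(
      train = metric_report(point_metrics(ps_train), ps = ps_train),
      cv = metric_report(point_metrics(bnn_cv_ps), ps = bnn_cv_ps),
      test = metric_report(point_metrics(ps_test),
                           interval_metrics(ps_test, config$nominal),
                           ps_test))
  }

  if ("sr" %in% config$models) {
    sr_fit <- sr_evolve(train$X, train$y, sr_cfg)
    models_fitted$sr <- sr_fit
    yh <- predict(sr_fit, test$X)
    sr_resid <- abs(train$y - predict(sr_fit, train$X))
    ps_test <- conformal_intervals(test$y, yh, sr_resid, config$nominal)
    predictions$sr <- ps_test
    model_metrics$sr <- list(
      expression = sr_format(sr_fit$best),
      test = metric_report(point_metrics(ps_test),
                           interval_metrics(ps_test, config$nominal),
                           ps_test))
  }

  if ("ensemble" %in% config$models) {
    w <- ensemble_weights(cv_rmse[c("gbm", "bnn")])
    ps_test <- ensemble_predict(predictions[c("gbm", "bnn")], w,
                                level = config$nominal)
    predictions$ensemble <- ps_test
    model_metrics$ensemble <- list(
      weights = as.list(w),
      test = metric_report(point_metrics(ps_test),
                           interval_metrics(ps_test, config$nominal),
                           ps_test))
  }

  ## stage 7: validation ----------------------------------------------------
  stage_log("stage validate")
  yscr_cfg <- gbm_cfg
  yscr_cfg$n_estimators <- min(yscr_cfg$n_estimators, 100L)  # scrambles only
  yscr <- yscrambling(function(X, y) fit_pcgbm(X, y, yscr_cfg),
                      train$X, train$y, n_perm = config$n_perm,
                      seed = derive_seed(config$seed, 12L))
  widths <- if ("bnn" %in% config$models)
    predictions$bnn$upper - predictions$bnn$lower else NULL
  ad <- ad_assess(train, test, scaler, widths = widths)
  assoc <- NULL
  if (!is.null(widths) && sd(widths) > 0) {
    err <- abs(test$y - predictions$bnn$y_hat)
    assoc <- uncertainty_associations(ad$distances, widths, err)
  }

  ## stage 8: sensitivity + importances ------------------------------------
  sens <- NULL
  primary <- models_fitted$gbm %||% models_fitted$bnn
  sens_table <- if (!is.null(models_fitted$gbm)) train else train_z
  if (!is.null(primary)) {
    stage_log("stage sensitize")
    sens <- directional_analysis(primary, sens_table,
                                 n_anchors = min(config$n_anchors,
                                                 nrow(train$X)),
                                 grid_size = config$grid_size,
                                 seed = derive_seed(config$seed, 13L))
  }
  imp <- if (!is.null(models_fitted$gbm))
    gbm_importance_cv(train$X, train$y, folds, gbm_cfg) else NULL

  report <- structure(list(
    provenance = list(seed = config$seed, config_hash = config_hash(config),
                      n_total = nrow(tab$X), n_train = nrow(train$X),
                      n_test = nrow(test$X), descriptors = keep,
                      package_version = as.character(
                        utils::packageVersion("toxqsar"))),
    split = list(n_train = length(split$train_idx),
                 n_test = length(split$test_idx),
                 rebalanced_count = split$rebalanced_count),
    preprocess = list(dropped_low_variance = prep$report$dropped_low_variance,
                      dropped_correlated = prep$report$dropped_correlated,
                      selected = prep$report$selected),
    tuning = tuning,
    fold_table = fold_table,
    models = model_metrics,
    yscrambling = list(original_r2 = yscr$original_r2,
                       scrambled_mean = yscr$scrambled_mean,
                       scrambled_sd = yscr$scrambled_sd,
                       scrambled_max = yscr$scrambled_max, z = yscr$z,
                       passed = yscr$passed),
    applicability_domain = list(threshold = ad$threshold,
                                in_domain_fraction = ad$in_domain_fraction),
    associations = assoc,
    sensitivity = if (is.null(sens)) NULL else
      c(sens$summary, list(per_descriptor = sens$per_descriptor)),
    importances = if (is.null(imp)) NULL else as.list(imp$mean)),
    class = "run_report")
  attr(report, "predictions") <- predictions
  attr(report, "test_ids") <- test$ids

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_json_report(unclass(report), file.path(config$outdir, "report.json"))
    for (nm in names(predictions)) {
      ps <- predictions[[nm]]
      df <- data.frame(compound_id = test$ids, y_true = ps$y,
                       y_pred = ps$y_hat,
                       lower = ps$lower %||% NA, upper = ps$upper %||% NA,
                       sigma = ps$sigma %||% NA)
      write.csv(df, file.path(config$outdir,
                              sprintf("predictions_%s.csv", nm)),
                row.names = FALSE)
    }
    report_tables(report, file.path(config$outdir, "tables"))
  }
  stage_log("done in %.1f s", proc.time()[["elapsed"]] - t0)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render the report's tables
#'
#' Formats the fold table, per-model metric comparison, calibration table and
#' sensitivity summary as data frames; optionally writes them as CSVs.
#' Missing sections are skipped with a notice.
#'
#' @param report a [run_pipeline()] result.
#' @param dir optional directory for `tables/*.csv`.
#' @param quiet suppress printing.
#' @return named list of data frames, invisibly.
#' @export
report_tables <- function(report, dir = NULL, quiet = TRUE) {
  out <- list()
  out$folds <- report$fold_table
  if (length(report$models)) {
    rows <- list()
    for (nm in names(report$models)) {
      for (split in intersect(names(report$models[[nm]]),
                              c("train", "cv", "test"))) {
        mm <- report$models[[nm]][[split]]
        rows[[paste(nm, split)]] <- data.frame(
          model = nm, split = split, rmse = mm$rmse, r2 = mm$r2,
          mare = mm$mare, pi = mm$pi, tic = mm$tic)
      }
    }
    out$metrics <- do.call(rbind, c(rows, make.row.names = FALSE))
    cal <- list()
    for (nm in names(report$models)) {
      mm <- report$models[[nm]]$test
      if (!is.null(mm) && !is.na(mm$coverage))
        cal[[nm]] <- data.frame(model = nm, coverage = mm$coverage,
                                calibration_error = mm$calibration_error,
                                avg_interval_width = mm$pi,
                                sharpness = mm$sharpness, nll = mm$nll)
    }
    if (length(cal)) out$calibration <- do.call(rbind,
                                                c(cal, make.row.names = FALSE))
  }
  if (!is.null(report$sensitivity)) {
    out$sensitivity <- report$sensitivity$per_descriptor
  } else if (!quiet) message("sensitivity section missing; table skipped")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
  }
  if (!quiet) for (nm in names(out)) { cat("==", nm, "==\n"); print(out[[nm]]) }
  invisible(out)
}
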