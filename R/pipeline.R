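#' End-to-end pipeline configuration
#'
#' Collects every tunable of the full workflow with defaults matching the
#' method's stated protocol: 82.5% training fraction, 33% false-positive
#' reliability cut, 0.5 decision threshold, and a 10% entropy display
#' threshold. All randomness flows from the single `seed` through named
#' substreams (simulation, split, base nets, meta-learners, permutation),
#' so stages are independently reproducible.
#'
#' @param seed Root seed.
#' @param input_csv Optional cohort CSV to ingest instead of simulating.
#' @param sim_config A [vf_sim_config()] for simulation mode.
#' @param criteria_file Optional YAML of criterion specs (default: the
#'   packaged five).
#' @param meta_kinds Meta-learners to train (subset of lr/gbt/mlp).
#' @param train_fraction Patient-level training fraction (default 0.825).
#' @param max_fpr Reliability cut (default 0.33).
#' @param min_tests,min_follow_up Longitudinal inclusion filter (defaults
#'   2 tests / 0.5 years).
#' @param decision_threshold Probability threshold for the GL call.
#' @param entropy_threshold Display threshold for prediction uncertainty.
#' @param outlier_removal Apply Tukey-fence removal to predicted
#'   probabilities before the entropy summary (default `FALSE`).
#' @param meta_variant Meta-feature construction variant (see
#'   [vf_extract_meta()]).
#' @return A `vf_pipeline_config` list.
#' @export
vf_pipeline_config <- function(seed = 1, input_csv = NULL,
                               sim_config = vf_sim_config(seed = substream_seed(seed, "simulate")),
                               criteria_file = NULL,
                               meta_kinds = c("lr", "gbt", "mlp"),
                               train_fraction = 0.825,
                               max_fpr = 0.33,
                               min_tests = 2, min_follow_up = 0.5,
                               decision_threshold = 0.5,
                               entropy_threshold = 0.10,
                               outlier_removal = FALSE,
                               meta_variant = "weighted") {
  structure(list(seed = as.integer(seed), input_csv = input_csv,
                 sim_config = sim_config, criteria_file = criteria_file,
                 meta_kinds = match.arg(meta_kinds, c("lr", "gbt", "mlp"),
                                        several.ok = TRUE),
                 train_fraction = train_fraction, max_fpr = max_fpr,
                 min_tests = min_tests, min_follow_up = min_follow_up,
                 decision_threshold = decision_threshold,
                 entropy_threshold = entropy_threshold,
                 outlier_removal = isTRUE(outlier_removal),
                 meta_variant = meta_variant),
            class = "vf_pipeline_config")
}

#' Run the full classification pipeline
#'
#' Simulate (or ingest) a cohort, apply reliability and longitudinal
#' filters, label every eye with the five rule-based criteria, train the
#' two base networks on the training patients' criteria labels, extract
#' 132-dimensional meta-features, train the requested meta-learners on
#' the clinical labels, and evaluate everything on the held-out patients.
#' Each stage's output is written as CSV under `out_dir`.
#'
#' @param config A [vf_pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param grid,norm Grid and normative reference.
#' @param quiet Suppress progress messages.
#' @return List with `cohort`, `criteria`, `bundle`, `meta_models`,
#'   `predictions`, `metrics` (data frame: one row per model),
#'   `entropy` (per meta-learner summary), `roc` (curves), `split`.
#' @export
vf_run_pipeline <- function(config = vf_pipeline_config(), out_dir = tempdir(),
                            grid = vf_grid("OD"), norm = vf_normative(grid),
                            quiet = FALSE) {
  stopifnot(inherits(config, "vf_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  # -- stage 1: cohort ------------------------------------------------------
  if (!is.null(config$input_csv)) {
    cohort <- vf_read_cohort(config$input_csv)
    truth <- NULL
    say("ingested %d exams from %s", nrow(cohort), config$input_csv)
  } else {
    sim <- vf_simulate_cohort(config$sim_config, grid, norm)
    cohort <- sim$cohort; truth <- sim$truth
    vf_write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    say("simulated %d exams / %d patients", nrow(cohort),
        length(unique(cohort$patient_id)))
  }
  if (!"label" %in% names(cohort)) stop_vf("cohort stage: no label column")

  # -- stage 2: quality control --------------------------------------------
  cohort <- suppressMessages(vf_filter_reliability(cohort, config$max_fpr))
  cohort <- suppressMessages(
    vf_filter_longitudinal(cohort, config$min_tests, config$min_follow_up))
  if (nrow(cohort) == 0) {
    stop_vf("qc stage: no exams remain after filtering (max_fpr=%g, min_tests=%d)",
            config$max_fpr, config$min_tests)
  }
  say("after QC: %d exams / %d patients", nrow(cohort),
      length(unique(cohort$patient_id)))

  # -- stage 3: rule-based criteria per eye --------------------------------
  specs <- if (is.null(config$criteria_file)) vf_default_criteria()
  else vf_read_criteria(config$criteria_file)
  crit <- vf_run_all_criteria(cohort, specs, grid, norm)
  utils::write.csv(crit$labels, file.path(out_dir, "criteria_verdicts.csv"),
                   row.names = FALSE)

  # one representative exam per eye (the latest) for the learning stages
  key <- paste(cohort$patient_id, cohort$eye, sep = "|")
  latest <- do.call(rbind, lapply(split(cohort, key), function(d) {
    d[order(as.Date(d$date)), , drop = FALSE][nrow(d), , drop = FALSE]
  }))
  latest_key <- paste(latest$patient_id, latest$eye, sep = "|")
  crit_key <- paste(crit$labels$patient_id, crit$labels$eye, sep = "|")
  crit_lab <- crit$labels[match(latest_key, crit_key), names(specs),
                          drop = FALSE]

  # -- stage 4: patient-level split ----------------------------------------
  split <- vf_split_train_test(unique(latest$patient_id),
                               config$train_fraction,
                               substream_seed(config$seed, "split"))
  tr <- latest$patient_id %in% split$train
  say("split: %d train / %d test patients", length(split$train),
      length(split$test))

  # -- stage 5: base networks ----------------------------------------------
  bundle <- vf_train_base(latest[tr, ], crit_lab[tr, , drop = FALSE], specs,
                          seed = substream_seed(config$seed, "base"))

  # -- stage 6: meta-features + meta-learners ------------------------------
  meta <- vf_extract_meta(bundle, latest, variant = config$meta_variant)
  utils::write.csv(cbind(latest[, c("patient_id", "eye")], meta),
                   file.path(out_dir, "meta_features.csv"), row.names = FALSE)
  y_all <- as_binary_label(latest$label)
  meta_models <- list(); predictions <- list()
  for (kind in config$meta_kinds) {
    m <- vf_train_meta(meta[tr, , drop = FALSE], y_all[tr], kind,
                       seed = substream_seed(config$seed, "meta"))
    meta_models[[kind]] <- m
    predictions[[kind]] <- vf_predict_meta(m, meta[!tr, , drop = FALSE],
                                           config$decision_threshold)
  }

  # -- stage 7: evaluation --------------------------------------------------
  y_test <- y_all[!tr]
  metrics <- list(); roc <- list(); entropy <- list(); ent_rows <- list()
  for (kind in names(predictions)) {
    pred <- predictions[[kind]]
    mm <- vf_metrics_from_confusion(vf_confusion(y_test, pred$label))
    ra <- vf_roc_auc(y_test, pred$p)
    H <- vf_prediction_entropy(pred$p)
    keep <- if (config$outlier_removal && length(pred$p) >= 4) {
      !vf_iqr_outlier_mask(pred$p)
    } else rep(TRUE, length(pred$p))
    metrics[[kind]] <- data.frame(
      model = kind, accuracy = mm$accuracy, precision = mm$precision,
      sensitivity = mm$sensitivity, specificity = mm$specificity,
      f_score = mm$f_score, auc = ra$auc,
      entropy_mean = mean(H[keep]), entropy_sd = stats::sd(H[keep]))
    roc[[kind]] <- cbind(model = kind, ra$curve)
    entropy[[kind]] <- c(mean = mean(H[keep]), sd = stats::sd(H[keep]))
    ent_rows[[kind]] <- data.frame(model = kind, p = pred$p, entropy = H,
                                   kept = keep)
  }
  # stand-alone criteria on the same held-out eyes
  for (nm in names(specs)) {
    v <- crit_lab[!tr, nm]
    mm <- vf_metrics_from_confusion(vf_confusion(y_test, v))
    ra <- vf_roc_auc(y_test, v)
    metrics[[nm]] <- data.frame(
      model = nm, accuracy = mm$accuracy, precision = mm$precision,
      sensitivity = mm$sensitivity, specificity = mm$specificity,
      f_score = mm$f_score, auc = ra$auc,
      entropy_mean = NA_real_, entropy_sd = NA_real_)
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, roc), file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, ent_rows),
                   file.path(out_dir, "entropy.csv"), row.names = FALSE)
  say("wrote metrics for %d models to %s", nrow(metrics), out_dir)

  invisible(list(cohort = cohort, truth = truth, criteria = crit,
                 bundle = bundle, meta_models = meta_models,
                 predictions = predictions, metrics = metrics,
                 entropy = entropy, roc = roc, split = split,
                 latest = latest, meta = meta, in_train = tr))
}
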