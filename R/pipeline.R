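# End-to-end driver: filter -> featurize -> split -> train -> evaluate ->
# permutation test -> Grad-CAM, with per-subject seeds derived from the
# master seed and machine-readable skip/warning records.

#' Pipeline run configuration
#'
#' @param diary Behavior diary data.frame or path to a diary CSV.
#' @param target Prediction target: `"seizure"` or a behavior category
#'   (severe variants via `severe_only = TRUE`).
#' @param seizures Seizure log data.frame or CSV path; required for the
#'   seizure target (adds the seizure-history input row).
#' @param window_days Window length in days, 7 or 14.
#' @param train_frac Chronological training fraction (default 0.8).
#' @param min_samples Minimum windows a subject needs (default 5).
#' @param severe_only Restrict to the severe-event subcohort and relabel
#'   windows by severe-event presence.
#' @param min_severe_frac Severe-fraction inclusion threshold (0.10).
#' @param k_top Number of behavior categories kept before the Other
#'   bucket (default 7).
#' @param m Permutations for the significance test (default `1e4`).
#' @param alpha Significance level (default 0.05).
#' @param threshold Decision threshold on predicted probabilities.
#' @param spec A `model_spec` (architecture and training schedule).
#' @param sd_type SD convention for "mean +/- SD" summaries.
#' @param normalize_maps Max-normalize Grad-CAM maps before averaging.
#' @param gradcam Compute Grad-CAM attributions over test windows.
#' @param metadata Optional data.frame (`subject_id`, one grouping column
#'   such as `sex`) for stratified reporting.
#' @param seed Master seed; all per-subject seeds derive from it.
#' @param out_dir Optional output directory for artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(diary, target, seizures = NULL, window_days = 7,
                       train_frac = 0.8, min_samples = 5,
                       severe_only = FALSE, min_severe_frac = 0.10,
                       k_top = 7, m = 1e4, alpha = 0.05, threshold = 0.5,
                       spec = model_spec(), sd_type = "population",
                       normalize_maps = TRUE, gradcam = TRUE,
                       metadata = NULL, seed = 1L, out_dir = NULL) {
  if (is.character(diary)) diary <- read_diary(diary)
  if (is.character(seizures)) seizures <- read_seizure_log(seizures)
  if (!window_days %in% c(7, 14))
    warning("window_days outside the standard {7, 14}", call. = FALSE)
  if (target == "seizure" && is.null(seizures))
    stop_bc("seizure target requires a seizure log")
  stopifnot(inherits(spec, "model_spec"), alpha > 0, alpha < 1, m >= 1)
  structure(list(diary = diary, seizures = seizures, target = target,
                 window_days = as.integer(window_days),
                 train_frac = train_frac, min_samples = min_samples,
                 severe_only = severe_only,
                 min_severe_frac = min_severe_frac,
                 k_top = k_top, m = m, alpha = alpha,
                 threshold = threshold, spec = spec, sd_type = sd_type,
                 normalize_maps = normalize_maps, gradcam = gradcam,
                 metadata = metadata, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), "out_dir")]
  rlang::hash(keep)
}

empty_cohort_report <- function(alpha) {
  structure(list(n_subjects = 0L, subject_ids = character(),
                 macro = NULL, micro = NULL,
                 significance = list(n_significant = 0L, alpha = alpha,
                                     label = "0 from 0"),
                 delta_accuracy = c(mean = NA_real_, sd = NA_real_,
                                    n = 0),
                 p_values = numeric(), sd_type = "population"),
            class = "cohort_report")
}

subject_date_range <- function(diary, seizures, sid) {
  d <- diary$date[diary$subject_id == sid]
  if (!is.null(seizures))
    d <- c(d, seizures$date[seizures$subject_id == sid])
  seq(min(d), max(d), by = "day")
}

#' Run the full forecasting pipeline on a cohort
#'
#' For every eligible subject: binarize the diary, build
#' `window_days`-day windows with next-day labels, split 80/20
#' chronologically, train the per-subject CNN, score the held-out tail,
#' run the prevalence-aware permutation test, and attribute predictions
#' with first-layer Grad-CAM. Identical configuration and seed reproduce
#' the run exactly.
#'
#' @param config A `run_config`.
#' @return An object of class `behavcast_run`: `report`
#'   (a `cohort_report`), `results` (per-subject details), `importance`
#'   (cohort-aggregated `importance_map` or `NULL`), `skipped`
#'   (data.frame of skipped subjects and reasons), `stratified`
#'   (per-group reports when metadata given), `category_map`,
#'   `config`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  diary <- config$diary
  seizures <- config$seizures
  target <- config$target
  seizure_task <- target == "seizure"
  hash <- config_hash(config)

  eligible <- filter_cohort(diary, target, seizures,
                            severe_only = config$severe_only,
                            min_severe_frac = config$min_severe_frac)
  skipped <- list()
  results <- list()
  maps <- list()
  if (length(eligible)) {
    map <- select_top_behaviors(diary, k = config$k_top)
  } else map <- NULL

  for (i in seq_along(eligible)) {
    sid <- eligible[i]
    if (!sid %in% diary$subject_id) {
      skipped[[sid]] <- "no diary records"
      next
    }
    dr <- subject_date_range(diary, if (seizure_task) seizures, sid)
    dm <- daily_binarize(diary, map, sid, dr,
                         seizures = if (seizure_task) seizures)
    labels <- if (seizure_task) {
      dm$values["seizure", ]
    } else if (config$severe_only) {
      severe_daily(diary, sid, target, dr)
    } else {
      tgt_days <- unique(diary$date[diary$subject_id == sid &
                                      diary$behavior == target])
      as.integer(dr %in% tgt_days)
    }
    target_row <- if (seizure_task) "seizure"
                  else if (target %in% map$selected) target
                  else map$other_label
    ws <- withCallingHandlers(
      build_windows(dm, target_row, config$window_days, labels = labels),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(ws) < config$min_samples) {
      skipped[[sid]] <- sprintf("insufficient data (%d windows < %d)",
                                length(ws), config$min_samples)
      next
    }
    split <- suppressWarnings(
      chronological_split(ws, config$train_frac, config$min_samples))
    degenerate <- length(unique(split$train$y)) < 2L
    model <- withCallingHandlers(
      train_subject_model(split$train, config$spec,
                          seed = derive_seed(config$seed, i, 1)),
      warning = function(w) invokeRestart("muffleWarning"))
    probs <- predict_proba(model, split$test)
    sm <- subject_metrics(probs, split$test$y, config$threshold)
    pt <- permutation_test(sm$pred_labels, split$test$y, m = config$m,
                           seed = derive_seed(config$seed, i, 2))
    subj_maps <- NULL
    if (config$gradcam) {
      subj_maps <- lapply(seq_len(length(split$test)), function(j) {
        m_ <- gradcam_first_layer(model, split$test$x[, , j])
        rownames(m_) <- ws$feature_names
        m_
      })
      maps <- c(maps, subj_maps)
    }
    results[[sid]] <- list(subject_id = sid, metrics = sm, perm = pt,
                           n_train = length(split$train),
                           n_test = length(split$test),
                           degenerate_train = degenerate,
                           single_class_test =
                             length(unique(split$test$y)) < 2L,
                           training_log = model$training_log,
                           importance =
                             if (length(subj_maps))
                               aggregate_importance(subj_maps,
                                 normalize = config$normalize_maps))
  }

  report <- if (length(results))
    cohort_report(results, alpha = config$alpha, sd_type = config$sd_type)
  else empty_cohort_report(config$alpha)
  importance <- if (length(maps))
    aggregate_importance(maps, normalize = config$normalize_maps)

  stratified <- NULL
  md <- config$metadata
  if (!is.null(md) && length(results)) {
    gcol <- setdiff(names(md), "subject_id")[1]
    grp <- md[[gcol]][match(names(results), md$subject_id)]
    stratified <- lapply(split(seq_along(results), grp), function(ix)
      cohort_report(results[ix], alpha = config$alpha,
                    sd_type = config$sd_type))
  }

  run <- structure(list(report = report, results = results,
                        importance = importance,
                        skipped = if (length(skipped))
                          data.frame(subject_id = names(skipped),
                                     reason = unlist(skipped),
                                     row.names = NULL)
                          else data.frame(subject_id = character(),
                                          reason = character()),
                        stratified = stratified,
                        category_map = map,
                        config = config,
                        config_hash = hash),
                   class = "behavcast_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.behavcast_run <- function(x, ...) {
  cat(sprintf("behavcast run — target '%s', %d-day windows (hash %s)\n",
              x$config$target, x$config$window_days,
              substr(x$config_hash, 1, 8)))
  print(x$report)
  if (nrow(x$skipped))
    cat("  skipped:", nrow(x$skipped), "subject(s)\n")
  invisible(x)
}

report_to_list <- function(report, config, hash) {
  list(config_hash = hash,
       target = config$target,
       window_days = config$window_days,
       n_subjects = report$n_subjects,
       macro = report$macro,
       n_undefined_auroc = report$n_undefined_auroc %||% 0L,
       micro = if (!is.null(report$micro))
         list(accuracy = report$micro$accuracy, f1 = report$micro$f1,
              confusion = report$micro$confusion),
       significance = report$significance,
       delta_accuracy = report$delta_accuracy,
       p_values = report$p_values,
       subject_ids = report$subject_ids)
}

#' Write pipeline artifacts
#'
#' Writes `subject_metrics.csv`, `cohort_report.json`,
#' `importance.csv` (when Grad-CAM ran) and `config.json` into `dir`;
#' every artifact names the configuration hash that produced it.
#'
#' @param run A `behavcast_run`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- run$config_hash
  paths <- character()

  sm_df <- do.call(rbind, lapply(run$results, function(r)
    data.frame(subject_id = r$subject_id,
               n_train = r$n_train, n_test = r$n_test,
               accuracy = r$metrics$accuracy, f1 = r$metrics$f1,
               auroc = r$metrics$auroc, auprc = r$metrics$auprc,
               p_value = r$perm$p,
               delta_accuracy = r$perm$delta_accuracy,
               null_mean = r$perm$null_mean,
               single_class_test = r$single_class_test,
               degenerate_train = r$degenerate_train)))
  p <- file.path(dir, "subject_metrics.csv")
  writeLines(sprintf("# config_hash: %s", hash), p)
  suppressWarnings(utils::write.table(
    sm_df %||% data.frame(), p, sep = ",", row.names = FALSE,
    append = TRUE, qmethod = "double"))
  paths <- c(paths, p)

  p <- file.path(dir, "cohort_report.json")
  jsonlite::write_json(report_to_list(run$report, run$config, hash), p,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       matrix = "rowmajor")
  paths <- c(paths, p)

  if (!is.null(run$importance)) {
    p <- file.path(dir, "importance.csv")
    writeLines(sprintf("# config_hash: %s", hash), p)
    suppressWarnings(utils::write.table(
      data.frame(feature = rownames(run$importance),
                 unclass(run$importance), check.names = FALSE),
      p, sep = ",", row.names = FALSE, append = TRUE, qmethod = "double"))
    paths <- c(paths, p)
  }

  p <- file.path(dir, "config.json")
  cfg <- run$config
  jsonlite::write_json(
    list(config_hash = hash, target = cfg$target,
         window_days = cfg$window_days, train_frac = cfg$train_frac,
         severe_only = cfg$severe_only, k_top = cfg$k_top, m = cfg$m,
         alpha = cfg$alpha, threshold = cfg$threshold,
         sd_type = cfg$sd_type, seed = cfg$seed,
         spec = unclass(cfg$spec),
         skipped = run$skipped),
    p, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Serialize a cohort report to deterministic JSON
#'
#' @param run A `behavcast_run`.
#' @return A JSON string; identical runs yield identical strings.
#' @export
report_json <- function(run) {
  as.character(jsonlite::toJSON(
    report_to_list(run$report, run$config, run$config_hash),
    auto_unbox = TRUE, digits = 10, matrix = "rowmajor"))
}
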