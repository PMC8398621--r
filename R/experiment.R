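#' Experiment configuration
#'
#' Bundles every tunable of the end-to-end experiment with the study's
#' defaults: a 7-subject cohort (5 training, 2 test), 2-minute trials at
#' 100 Hz pressure / 30 Hz angle, 10-point moving average, 15 Hz 4th-order
#' Butterworth, 30 gait cycles per condition resampled to 100 points, and
#' RMSprop training (learning rate 0.007) of the 100-250-150-100 network.
#'
#' @param n_subjects Cohort size (default 7).
#' @param n_train_subjects Subjects used for training (default 5); the rest
#'   are held out for testing.
#' @param seed Single top-level seed controlling every random draw.
#' @param duration Trial duration in seconds (default 120).
#' @param n_cycles Gait cycles per subject x condition (default 30).
#' @param ma_window,cutoff,order Preprocessing parameters.
#' @param zero_threshold `NULL` for the scale-free default rule.
#' @param train A [train_config()]; its seed is derived from `seed`.
#' @param model_ids Models to train (default M1..M6).
#' @param cnn_model_ids Models for which the convolutional comparison is
#'   also trained (default none; use e.g. `"M6"`).
#' @param noise Simulate sensor/treadmill noise (default `TRUE`).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 7, n_train_subjects = 5,
                              seed = 1L, duration = 120, n_cycles = 30,
                              ma_window = 10, cutoff = 15, order = 4,
                              zero_threshold = NULL,
                              train = train_config(),
                              model_ids = paste0("M", 1:6),
                              cnn_model_ids = character(0),
                              noise = TRUE) {
  if (n_train_subjects >= n_subjects)
    stop("n_train_subjects must be smaller than n_subjects", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 n_train_subjects = n_train_subjects, seed = as.integer(seed),
                 duration = duration, n_cycles = n_cycles,
                 ma_window = ma_window, cutoff = cutoff, order = order,
                 zero_threshold = zero_threshold, train = train,
                 model_ids = model_ids, cnn_model_ids = cnn_model_ids,
                 noise = noise),
            class = "experiment_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %-10s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full end-to-end experiment
#'
#' Simulate the cohort, preprocess every trial into 30 matched cycle pairs,
#' assemble the requested model datasets over the training subjects, train
#' each network, predict the held-out subjects and evaluate. Every random
#' draw (cohort, noise, weight initialization, batch shuffling, dropout)
#' derives from `config$seed`, so identical configurations give identical
#' reports.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory for CSV artifacts (cycle table,
#'   training histories, evaluation tables, serialized models).
#' @param verbose Log each stage (default `TRUE`).
#' @return A list of class `gait_experiment`: `report` ([evaluate_models()]
#'   output for the perceptrons), `cnn_report` (if requested), `models`,
#'   `histories`, `cohort`, `test_subjects`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           verbose = TRUE) {
  say <- if (verbose) log_stage else function(...) invisible(NULL)
  say("simulate", "cohort of %d subjects, seed %d", config$n_subjects,
      config$seed)
  cohort <- make_cohort(config$n_subjects, config$seed)
  trials <- simulate_cohort(cohort, duration = config$duration,
                            seed = config$seed, noise = config$noise)
  say("simulate", "%d trials of %g s", length(trials), config$duration)

  pairs <- lapply(trials, function(tr)
    preprocess_trial_pair(tr, n_cycles = config$n_cycles,
                          ma_window = config$ma_window,
                          cutoff = config$cutoff, order = config$order,
                          zero_threshold = config$zero_threshold))
  cycles <- bind_cycle_pairs(pairs)
  say("preprocess", "%d cycle pairs extracted", nrow(cycles$meta))

  subjects <- vapply(cohort, `[[`, character(1), "subject_id")
  train_subjects <- subjects[seq_len(config$n_train_subjects)]
  test_subjects <- setdiff(subjects, train_subjects)
  test_rows <- cycles$meta$subject %in% test_subjects
  test_cycles <- list(pressure = cycles$pressure[test_rows, , drop = FALSE],
                      angle = cycles$angle[test_rows, , drop = FALSE],
                      meta = cycles$meta[test_rows, , drop = FALSE])

  models <- list(); cnn_models <- list(); histories <- list()
  for (k in seq_along(config$model_ids)) {
    mid <- config$model_ids[k]
    ds <- assemble_dataset(cycles, mid, train_subjects)
    cfg <- config$train
    cfg$seed <- config$seed + 100L * k
    fit <- train_mlp(ds, cfg)
    models[[mid]] <- fit$model
    histories[[mid]] <- data.frame(model = mid, fit$history)
    say("train", "%s: %d cycles, final train MSE %.2e", mid, nrow(ds$inputs),
        tail(fit$history$train_loss, 1))
    if (mid %in% config$cnn_model_ids) {
      cfg$seed <- cfg$seed + 50L
      cfit <- train_cnn(ds, cnn_spec(), cfg)
      cnn_models[[mid]] <- cfit$model
      histories[[paste0(mid, "_cnn")]] <- data.frame(
        model = paste0(mid, "_cnn"), cfit$history)
      say("train", "%s (CNN): final train MSE %.2e", mid,
          tail(cfit$history$train_loss, 1))
    }
  }

  report <- evaluate_models(models, test_cycles, train_subjects)
  say("evaluate", "%d cells | max MRE %.3f | min R %.3f",
      nrow(report$metrics), max(report$metrics$mre), min(report$metrics$r))
  cnn_report <- if (length(cnn_models) > 0)
    evaluate_models(cnn_models, test_cycles, train_subjects) else NULL

  result <- structure(
    list(report = report, cnn_report = cnn_report, models = models,
         cnn_models = cnn_models, histories = do.call(rbind, histories),
         cohort = cohort, test_subjects = test_subjects,
         cycles = cycles, config = config),
    class = "gait_experiment")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cycles_csv(cycles, file.path(out_dir, "cycles.csv"))
    utils::write.csv(result$histories,
                     file.path(out_dir, "training_history.csv"),
                     row.names = FALSE)
    utils::write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(report$agreement, file.path(out_dir, "bland_altman.csv"),
                     row.names = FALSE)
    utils::write.csv(report$flexion, file.path(out_dir, "flexion_patterns.csv"),
                     row.names = FALSE)
    for (mid in names(models))
      write_mlp_json(models[[mid]], file.path(out_dir,
                                              sprintf("model_%s.json", mid)))
    cfg_out <- config
    cfg_out$train <- unclass(cfg_out$train)
    jsonlite::write_json(unclass(cfg_out), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    say("write", "artifacts in %s", out_dir)
  }
  result
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat(sprintf("Gait experiment: %d subjects (%d train), models %s\n",
              x$config$n_subjects, x$config$n_train_subjects,
              paste(names(x$models), collapse = " ")))
  print(x$report)
  invisible(x)
}
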