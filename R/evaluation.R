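#' Accuracy metrics for one predicted gait cycle
#'
#' Computes the three statistics of the accuracy battery with `x` the
#' prediction and `y` the actual angle:
#' \itemize{
#'   \item RMSE = sqrt(mean((x - y)^2)), degrees;
#'   \item MRE = mean(|x - y| / |x|) — note the prediction in the
#'     denominator, as defined; angles in the Kinovea convention never
#'     approach zero, so the ratio is well defined;
#'   \item R = 1 - sum((y - x)^2) / sum((y - mean(y))^2), the
#'     coefficient-of-determination form of the correlation efficiency.
#' }
#'
#' @param prediction Numeric vector of predicted angles (degrees).
#' @param actual Numeric vector of actual angles, same length.
#' @return List of class `metric_set`: `rmse`, `mre`, `r_value`.
#' @export
accuracy_metrics <- function(prediction, actual) {
  if (length(prediction) != length(actual))
    stop("prediction and actual must have equal length", call. = FALSE)
  if (any(prediction == 0))
    stop("zero prediction values make the relative error undefined",
         call. = FALSE)
  d <- prediction - actual
  structure(
    list(rmse = sqrt(mean(d^2)),
         mre = mean(abs(d / prediction)),
         r_value = 1 - sum(d^2) / sum((actual - mean(actual))^2)),
    class = "metric_set")
}

#' Bland-Altman agreement statistics
#'
#' Mean bias and the 95% limits of agreement (bias +/- 1.96 standard
#' deviations, sample SD with n - 1).
#'
#' @param differences Numeric vector of paired differences
#'   (estimate - actual), degrees; at least 2 values.
#' @return List of class `bland_altman_result`: `mean_bias`, `upper_loa`,
#'   `lower_loa` and the input `differences`.
#' @export
bland_altman <- function(differences) {
  if (length(differences) < 2)
    stop("Bland-Altman needs at least 2 differences", call. = FALSE)
  bias <- mean(differences)
  s <- sd(differences)
  structure(list(mean_bias = bias,
                 upper_loa = bias + 1.96 * s,
                 lower_loa = bias - 1.96 * s,
                 differences = differences),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f deg, LOA [%.2f, %.2f]\n",
              x$mean_bias, x$lower_loa, x$upper_loa))
  invisible(x)
}

#' Knee flexion pattern of an angle cycle
#'
#' Flexion = 180 - angle, pointwise, with the gait phases attached: stance
#' covers samples 1-60 (0-60% of the cycle) and swing samples 61-100
#' (60-100%).
#'
#' @param angle_cycle Numeric vector of 100 knee angles (degrees, Kinovea
#'   convention) or an angle [gait_cycle()].
#' @return List of class `flexion_pattern`: `flexion` (100 degrees values),
#'   `stance_range` and `swing_range` (sample indices).
#' @export
flexion_pattern <- function(angle_cycle) {
  values <- if (inherits(angle_cycle, "gait_cycle")) angle_cycle$values
            else as.numeric(angle_cycle)
  stopifnot(length(values) == 100)
  structure(list(flexion = 180 - values,
                 stance_range = 1:60,
                 swing_range = 61:100),
            class = "flexion_pattern")
}

#' Evaluate trained models on held-out subjects
#'
#' For every model and every shoe x speed condition, predicts each test
#' cycle, computes the accuracy metrics per cycle and averages them over the
#' condition's test cycles. Per model, Bland-Altman statistics are computed
#' over the per-cycle mean differences (estimate - actual, one point per
#' test cycle, all conditions pooled). Mean actual and predicted flexion
#' patterns per condition are included for pattern inspection.
#'
#' @param models Named list of trained models (from [train_mlp()] /
#'   [train_cnn()], the `model` element).
#' @param test_cycles Bound cycle table from [bind_cycle_pairs()] restricted
#'   to test subjects.
#' @param training_subjects Subjects used in training; evaluation refuses
#'   any overlap with the test subjects.
#' @return An object of class `eval_report`: data frames `metrics` (model,
#'   shoe, speed, rmse_deg, mre, r, pearson_r), `agreement` (model,
#'   mean_bias, upper_loa, lower_loa) and `flexion` (condition-mean actual
#'   and predicted flexion patterns).
#' @export
evaluate_models <- function(models, test_cycles, training_subjects = NULL) {
  meta <- test_cycles$meta
  if (!is.null(training_subjects) &&
      any(unique(meta$subject) %in% training_subjects))
    stop("test subjects overlap the training subjects", call. = FALSE)
  conditions <- unique(meta[, c("shoe", "speed")])
  metrics <- list(); agreement <- list(); flex <- list()
  for (mid in names(models)) {
    model <- models[[mid]]
    pred_all <- predict_knee_angle(model, test_cycles$pressure)
    cycle_bias <- rowMeans(pred_all - test_cycles$angle)
    agreement[[mid]] <- {
      ba <- bland_altman(cycle_bias)
      data.frame(model = mid, mean_bias = ba$mean_bias,
                 upper_loa = ba$upper_loa, lower_loa = ba$lower_loa)
    }
    for (ci in seq_len(nrow(conditions))) {
      sh <- conditions$shoe[ci]; sp <- conditions$speed[ci]
      rows <- which(meta$shoe == sh & meta$speed == sp)
      ms <- lapply(rows, function(r)
        accuracy_metrics(pred_all[r, ], test_cycles$angle[r, ]))
      pearson <- vapply(rows, function(r)
        stats::cor(pred_all[r, ], test_cycles$angle[r, ]), numeric(1))
      metrics[[paste(mid, sh, sp)]] <- data.frame(
        model = mid, shoe = sh, speed = sp,
        rmse_deg = mean(vapply(ms, `[[`, numeric(1), "rmse")),
        mre = mean(vapply(ms, `[[`, numeric(1), "mre")),
        r = mean(vapply(ms, `[[`, numeric(1), "r_value")),
        pearson_r = mean(pearson))
      flex[[paste(mid, sh, sp)]] <- data.frame(
        model = mid, shoe = sh, speed = sp, sample = 0:99,
        actual_flexion = 180 - colMeans(test_cycles$angle[rows, , drop = FALSE]),
        predicted_flexion = 180 - colMeans(pred_all[rows, , drop = FALSE]))
    }
  }
  structure(list(metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
                 agreement = do.call(rbind, c(agreement,
                                              make.row.names = FALSE)),
                 flexion = do.call(rbind, c(flex, make.row.names = FALSE))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Model evaluation report\n")
  cat(sprintf("  %d model x condition cells\n", nrow(x$metrics)))
  cat(sprintf("  MRE: max %.3f | R: min %.3f | RMSE: max %.2f deg\n",
              max(x$metrics$mre), min(x$metrics$r),
              max(x$metrics$rmse_deg)))
  invisible(x)
}
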