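#' Trim a trial to its central minute
#'
#' Treadmill trials begin and end with unsteady gait; only the centered 60 s
#' window is analysed.
#'
#' @param trial A [pressure_trial()] or [angle_trial()].
#' @param window_s Window length in seconds (default 60).
#' @return A trial of the same class containing `window_s * sampling_rate`
#'   samples.
#' @export
trim_to_mid_minute <- function(trial, window_s = 60) {
  stopifnot(inherits(trial, "pressure_trial") || inherits(trial, "angle_trial"))
  if (trial$duration < window_s)
    stop(sprintf("trial lasts %.1f s; trimming requires at least %.0f s",
                 trial$duration, window_s), call. = FALSE)
  n_keep <- round(window_s * trial$sampling_rate)
  n <- round(trial$duration * trial$sampling_rate)
  from <- floor((n - n_keep) / 2) + 1
  idx <- seq(from, length.out = n_keep)
  out <- trial
  if (inherits(trial, "pressure_trial")) {
    out$channels <- trial$channels[idx, , drop = FALSE]
    out$duration <- nrow(out$channels) / out$sampling_rate
  } else {
    out$angle <- trial$angle[idx]
    out$duration <- length(out$angle) / out$sampling_rate
  }
  out
}

#' Trailing moving-average filter
#'
#' Causal flat-kernel mean over the trailing `window` samples. The leading
#' edge uses partial windows (the mean of however many samples are
#' available), so the output has the same length as the input.
#'
#' @param values Numeric vector.
#' @param window Window length in samples (default 10).
#' @return Filtered vector, same length as `values`.
#' @export
moving_average <- function(values, window = 10) {
  n <- length(values)
  if (n == 0) stop("cannot filter an empty series", call. = FALSE)
  stopifnot(window >= 1, n >= window)
  if (window == 1) return(values)
  cs <- cumsum(values)
  out <- numeric(n)
  head_idx <- seq_len(window - 1)
  out[head_idx] <- cs[head_idx] / head_idx
  rest <- window:n
  out[rest] <- (cs[rest] - c(0, cs)[rest - window + 1]) / window
  out
}

# Steady-state zero-phase filtering: odd-reflection padding at both ends plus
# steady-state initial conditions, applied forward then backward. Constants
# pass through exactly (DC gain 1) and events keep their timing.
zero_phase_filter <- function(b, a, x) {
  one_pass <- function(x) {
    p <- min(length(x) - 1, max(30, 9 * (length(a) - 1)))
    xe <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[length(x)] - rev(x[(length(x) - p):(length(x) - 1)]))
    y <- signal::filter(b, a, xe,
                        init.x = rep(xe[1], length(b) - 1),
                        init.y = rep(xe[1], length(a) - 1))
    as.numeric(y)[(p + 1):(p + length(x))]
  }
  rev(one_pass(rev(one_pass(x))))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a digital Butterworth low-pass filter and applies it forward and
#' backward (zero phase), so gait events are not delayed. Edge effects are
#' controlled by odd-reflection padding with steady-state initial conditions;
#' a constant series passes through unchanged. Set `zero_phase = FALSE` for a
#' single causal pass.
#'
#' @param values Numeric vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param cutoff Cut-off frequency in Hz (default 15).
#' @param order Filter order (default 4).
#' @param zero_phase Apply forward-backward (default) or single-pass.
#' @return Filtered vector, same length as `values`.
#' @export
butterworth_lowpass <- function(values, sampling_rate, cutoff = 15,
                                order = 4, zero_phase = TRUE) {
  if (cutoff >= sampling_rate / 2)
    stop(sprintf("cutoff %.3g Hz must be below the Nyquist frequency %.3g Hz",
                 cutoff, sampling_rate / 2), call. = FALSE)
  bf <- signal::butter(order, cutoff / (sampling_rate / 2))
  if (zero_phase) {
    zero_phase_filter(bf$b, bf$a, values)
  } else {
    as.numeric(signal::filter(bf$b, bf$a, values,
                              init.x = rep(values[1], length(bf$b) - 1),
                              init.y = rep(values[1], length(bf$a) - 1)))
  }
}

#' Total plantar pressure
#'
#' Sums the 10 insole channels sample by sample.
#'
#' @param trial A [pressure_trial()], or a numeric matrix with 10 columns.
#' @return An object of class `total_pressure_series` with fields
#'   `sampling_rate`, `values` (kPa) and `provenance` labels.
#' @export
total_plantar_pressure <- function(trial) {
  if (inherits(trial, "pressure_trial")) {
    ch <- trial$channels
    rate <- trial$sampling_rate
    prov <- list(subject_id = trial$subject_id, shoe = trial$shoe,
                 speed = trial$speed)
  } else {
    ch <- as.matrix(trial)
    rate <- NA_real_
    prov <- list()
  }
  if (ncol(ch) != 10)
    stop("total plantar pressure needs 10 channels, got ", ncol(ch),
         call. = FALSE)
  structure(list(sampling_rate = rate, values = rowSums(ch),
                 provenance = prov),
            class = "total_pressure_series")
}

#' Zero-To-Zero toe-off detection
#'
#' A toe-off is the first sample at or below `zero_threshold` immediately
#' following a run of samples above it: the instant total plantar pressure
#' returns to zero as the foot leaves the ground. Consecutive toe-off indices
#' delimit candidate gait cycles.
#'
#' @param series A `total_pressure_series` or numeric vector.
#' @param zero_threshold Pressure level (kPa) treated as "zero"; must be > 0.
#' @return Integer vector of 1-based sample indices, strictly increasing
#'   (possibly empty).
#' @export
detect_toe_off_events <- function(series, zero_threshold) {
  values <- if (inherits(series, "total_pressure_series")) series$values
            else as.numeric(series)
  if (length(values) == 0) stop("empty series", call. = FALSE)
  stopifnot(zero_threshold > 0)
  above <- values > zero_threshold
  idx <- which(!above[-1] & above[-length(above)]) + 1L
  as.integer(idx)
}

# Heel strikes: first suprathreshold sample after an unloaded run.
detect_heel_strike_events <- function(series, zero_threshold) {
  values <- if (inherits(series, "total_pressure_series")) series$values
            else as.numeric(series)
  above <- values > zero_threshold
  as.integer(which(above[-1] & !above[-length(above)]) + 1L)
}

# Scale-free default zero threshold: 2% of the 95th percentile of the total
# pressure, robust to the sensor noise floor.
default_zero_threshold <- function(values, fraction = 0.02) {
  fraction * as.numeric(quantile(values, 0.95, names = FALSE))
}

#' Extract consecutive gait-cycle segments
#'
#' Returns the `n_cycles` consecutive toe-off-to-toe-off segments nearest the
#' centre of the series. Segments whose duration deviates more than 40% from
#' the median segment duration are treated as artifacts; the chosen window
#' must contain none.
#'
#' @param series A `total_pressure_series` or numeric vector.
#' @param events Toe-off indices from [detect_toe_off_events()].
#' @param n_cycles Number of cycles to extract (default 30).
#' @param max_duration_dev Maximal fractional deviation of a segment's
#'   duration from the median before it is rejected (default 0.4).
#' @return A list of `n_cycles` numeric vectors in temporal order; each
#'   carries attributes `start_index` and `end_index` (the delimiting toe-off
#'   samples in the input series).
#' @export
extract_cycles <- function(series, events, n_cycles = 30,
                           max_duration_dev = 0.4) {
  values <- if (inherits(series, "total_pressure_series")) series$values
            else as.numeric(series)
  if (length(events) < n_cycles + 1)
    stop(sprintf("need at least %d toe-off events for %d cycles, found %d",
                 n_cycles + 1, n_cycles, length(events)), call. = FALSE)
  durations <- diff(events)
  med <- median(durations)
  valid <- abs(durations - med) <= max_duration_dev * med
  n_seg <- length(durations)
  centre <- (length(values) + 1) / 2
  # candidate windows of n_cycles consecutive valid segments
  starts <- which(vapply(seq_len(n_seg - n_cycles + 1), function(j)
    all(valid[j:(j + n_cycles - 1)]), logical(1)))
  if (length(starts) == 0)
    stop("no run of ", n_cycles, " artifact-free cycles found", call. = FALSE)
  mid <- (events[starts] + events[starts + n_cycles]) / 2
  j0 <- starts[which.min(abs(mid - centre))]
  lapply(j0:(j0 + n_cycles - 1), function(j) {
    seg <- values[events[j]:(events[j + 1] - 1L)]
    attr(seg, "start_index") <- events[j]
    attr(seg, "end_index") <- events[j + 1]
    seg
  })
}

#' Resample a gait cycle to 100 points
#'
#' Linear interpolation onto 100 equally spaced points over the cycle's time
#' span; the first and last raw values are preserved.
#'
#' @param raw Numeric vector of length >= 2.
#' @return Numeric vector of length 100.
#' @export
resample_cycle_to_100 <- function(raw) {
  n <- length(raw)
  if (n < 2) stop("cycle must contain at least 2 samples", call. = FALSE)
  if (n == 100) return(as.numeric(raw))
  approx(x = seq_len(n), y = raw, xout = seq(1, n, length.out = 100))$y
}

#' Re-reference a toe-off-started cycle to heel strike
#'
#' A Zero-To-Zero segment starts at toe-off (unloaded swing first). The heel
#' strike is located as the first sample above `zero_threshold`; the cycle is
#' circularly rotated so that sample becomes sample 1, and the stance
#' fraction is recorded as the fraction of the cycle from heel strike to the
#' cycle's end (the following toe-off).
#'
#' @param cycle Numeric vector (typically 100 points) beginning in swing.
#' @param zero_threshold Pressure level (kPa) treated as "zero".
#' @return An object of class `gait_cycle` with fields `values`, `modality`
#'   ("pressure"), `reference_event` ("heel_strike") and `stance_fraction`.
#' @export
rotate_to_heel_strike <- function(cycle, zero_threshold) {
  values <- as.numeric(cycle)
  L <- length(values)
  p <- which(values > zero_threshold)[1]
  if (is.na(p))
    stop("no contact detected: cycle never exceeds the zero threshold",
         call. = FALSE)
  rotated <- values[c(p:L, seq_len(p - 1L))]
  gait_cycle(rotated, modality = "pressure",
             stance_fraction = (L - (p - 1L)) / L, n_points = L)
}

#' Gait-cycle container
#'
#' @param values Numeric vector of exactly 100 samples (kPa or degrees)
#'   unless `n_points` overrides the expected length.
#' @param modality "pressure" or "angle".
#' @param stance_fraction Fraction of the cycle in stance, in (0, 1).
#' @param source_index Ordinal of the cycle within its trial.
#' @param n_points Expected cycle length (default 100).
#' @return An object of class `gait_cycle`.
#' @export
gait_cycle <- function(values, modality = c("pressure", "angle"),
                       stance_fraction = 0.6, source_index = NA_integer_,
                       n_points = 100) {
  modality <- match.arg(modality)
  values <- as.numeric(values)
  if (length(values) != n_points)
    stop("gait cycle must have exactly ", n_points, " points", call. = FALSE)
  if (modality == "pressure" && any(values < 0))
    stop("pressure cycle contains negative values", call. = FALSE)
  if (modality == "angle" && any(values <= 90 | values >= 185))
    stop("angle cycle outside (90, 185) degrees", call. = FALSE)
  if (stance_fraction <= 0 || stance_fraction > 1)
    stop("stance_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(values = values, modality = modality,
                 reference_event = "heel_strike",
                 stance_fraction = stance_fraction,
                 source_index = source_index),
            class = "gait_cycle")
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("Gait cycle (%s), %d points, stance fraction %.2f\n",
              x$modality, length(x$values), x$stance_fraction))
  invisible(x)
}

#' Extract knee-angle cycles at pressure-derived heel strikes
#'
#' Slices the 30 Hz angle stream between consecutive heel-strike times
#' derived from the pressure channel (both streams share the trial clock)
#' and resamples each slice to 100 points on the standard gait-normalization
#' grid: sample 1 is the heel strike and sample 101 would be the next heel
#' strike (half-open cycle).
#'
#' @param trial An [angle_trial()] (already trimmed to the analysis window).
#' @param heel_strike_times Numeric vector of `n_cycles + 1` event times in
#'   seconds on the trial's clock (time 0 = first sample).
#' @param n_cycles Number of cycles (default 30).
#' @return List of `n_cycles` angle [gait_cycle()]s, paired by index with
#'   the pressure cycles.
#' @export
extract_angle_cycles <- function(trial, heel_strike_times, n_cycles = 30) {
  stopifnot(inherits(trial, "angle_trial"))
  if (n_cycles == 0) return(list())
  if (length(heel_strike_times) < n_cycles + 1)
    stop("need n_cycles + 1 heel-strike times", call. = FALSE)
  t_max <- (length(trial$angle) - 1) / trial$sampling_rate
  times <- heel_strike_times[seq_len(n_cycles + 1)]
  if (any(times < 0) || any(times > t_max))
    stop("heel-strike event time outside the angle trial", call. = FALSE)
  t_axis <- (seq_along(trial$angle) - 1) / trial$sampling_rate
  lapply(seq_len(n_cycles), function(i) {
    grid <- times[i] + (0:99) / 100 * (times[i + 1] - times[i])
    # cubic interpolation: the 30 Hz video stream is sparse relative to the
    # 100-point grid and the knee trajectory is smooth
    vals <- stats::spline(t_axis, trial$angle, xout = grid, method = "fmm")$y
    gait_cycle(vals, modality = "angle", stance_fraction = 0.6,
               source_index = i)
  })
}

#' Fit min-max normalization parameters
#'
#' @param x Numeric vector or matrix of training values.
#' @return List of class `minmax_params` with `x_min` and `x_max`.
#' @export
fit_minmax <- function(x) {
  x_min <- min(x)
  x_max <- max(x)
  if (!(x_max > x_min))
    stop("degenerate training data: constant values cannot be min-max scaled",
         call. = FALSE)
  structure(list(x_min = x_min, x_max = x_max), class = "minmax_params")
}

#' Apply or invert min-max normalization
#'
#' Forward: `(x - x_min) / (x_max - x_min)` maps the training extrema to 0
#' and 1. Invert: `x_norm * (x_max - x_min) + x_min`.
#'
#' @param values Numeric vector or matrix.
#' @param params A `minmax_params` from [fit_minmax()].
#' @param invert Apply the inverse map (default `FALSE`).
#' @return Transformed values, same shape as the input.
#' @export
apply_minmax <- function(values, params, invert = FALSE) {
  stopifnot(inherits(params, "minmax_params"))
  rng <- params$x_max - params$x_min
  if (invert) values * rng + params$x_min
  else (values - params$x_min) / rng
}

#' Preprocess one paired trial into 30 matched cycle pairs
#'
#' Runs the full preprocessing chain on a simulated (or loaded) trial pair:
#' trim both streams to the centered analysis window, moving-average and
#' zero-phase Butterworth filter each pressure channel, total the channels,
#' detect toe-offs with the Zero-To-Zero rule, extract `n_cycles` consecutive
#' segments nearest the window centre, resample each to 100 points and
#' re-reference to heel strike, then slice the angle stream at the
#' pressure-derived heel-strike times.
#'
#' @param pair A `trial_pair` from [simulate_trial()], or a list with
#'   elements `pressure` and `angle`.
#' @param n_cycles Cycles to extract per trial (default 30).
#' @param ma_window Moving-average window in samples (default 10; use 1 to
#'   disable smoothing for noise-free data).
#' @param cutoff,order Butterworth low-pass parameters (defaults 15 Hz, 4).
#' @param window_s Analysis window in seconds (default 60).
#' @param zero_threshold "Zero" pressure level in kPa; `NULL` (default) uses
#'   2% of the 95th percentile of the filtered total pressure.
#' @return An object of class `cycle_pairs`: list with `pressure` and
#'   `angle` (each an `n_cycles` x 100 matrix, rows are heel-strike
#'   referenced cycles), `stance_fraction`, `heel_strike_times` (seconds, on
#'   the trimmed clock) and `meta` (subject/shoe/speed labels).
#' @export
preprocess_trial_pair <- function(pair, n_cycles = 30, ma_window = 10,
                                  cutoff = 15, order = 4, window_s = 60,
                                  zero_threshold = NULL) {
  p <- trim_to_mid_minute(pair$pressure, window_s)
  a <- trim_to_mid_minute(pair$angle, window_s)
  filtered <- apply(p$channels, 2, function(ch)
    butterworth_lowpass(moving_average(ch, ma_window), p$sampling_rate,
                        cutoff, order))
  filtered <- pmax(filtered, 0)
  total <- total_plantar_pressure(pressure_trial(filtered, p$sampling_rate,
                                                 p$subject_id, p$shoe,
                                                 p$speed))
  thr <- if (is.null(zero_threshold)) default_zero_threshold(total$values)
         else zero_threshold
  events <- detect_toe_off_events(total, thr)
  segs <- extract_cycles(total, events, n_cycles)
  cycles <- lapply(segs, function(seg)
    rotate_to_heel_strike(resample_cycle_to_100(seg), thr))

  # heel-strike times on the trimmed clock, one per segment plus the closing
  # strike after the last segment (for the final angle slice)
  hs_all <- detect_heel_strike_events(total, thr)
  seg_bounds <- c(vapply(segs, attr, integer(1), "start_index"),
                  attr(segs[[n_cycles]], "end_index"))
  hs_idx <- vapply(seg_bounds, function(e) {
    h <- hs_all[hs_all > e][1]
    if (is.na(h)) NA_integer_ else h
  }, integer(1))
  if (is.na(hs_idx[n_cycles + 1])) {
    med_gap <- median(diff(hs_idx[seq_len(n_cycles)]))
    hs_idx[n_cycles + 1] <- hs_idx[n_cycles] + round(med_gap)
  }
  hs_times <- (hs_idx - 1) / p$sampling_rate
  angle_cycles <- extract_angle_cycles(a, hs_times, n_cycles)

  structure(
    list(pressure = do.call(rbind, lapply(cycles, `[[`, "values")),
         angle = do.call(rbind, lapply(angle_cycles, `[[`, "values")),
         stance_fraction = vapply(cycles, `[[`, numeric(1), "stance_fraction"),
         heel_strike_times = hs_times,
         zero_threshold = thr,
         meta = data.frame(subject = p$subject_id, shoe = p$shoe,
                           speed = p$speed, cycle_index = seq_len(n_cycles),
                           stringsAsFactors = FALSE)),
    class = "cycle_pairs")
}

#' @export
print.cycle_pairs <- function(x, ...) {
  cat(sprintf("Cycle pairs: %s %s %s, %d pressure + %d angle cycles (100 pts)\n",
              x$meta$subject[1], x$meta$shoe[1], x$meta$speed[1],
              nrow(x$pressure), nrow(x$angle)))
  invisible(x)
}
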