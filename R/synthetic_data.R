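#' Shoe specification
#'
#' Geometry of one of the three test shoes: flat (S1), sneaker (S2) and
#' stiletto heel (S3). All three share the 23.5 cm shoe size; they differ in
#' heel height, ball width and heel base area.
#'
#' @param name Shoe label, one of "S1", "S2", "S3" (free labels allowed).
#' @param heel_height Heel height in cm.
#' @param ball_width Ball width in cm.
#' @param shoe_size Shoe size in cm.
#' @param heel_base Heel base area in cm^2.
#' @return An object of class `shoe_spec`.
#' @export
shoe_spec <- function(name, heel_height, ball_width, shoe_size, heel_base) {
  if (any(c(heel_height, ball_width, shoe_size, heel_base) <= 0))
    stop("all shoe dimensions must be > 0", call. = FALSE)
  structure(list(name = name, heel_height = heel_height,
                 ball_width = ball_width, shoe_size = shoe_size,
                 heel_base = heel_base),
            class = "shoe_spec")
}

#' The three default test shoes
#'
#' @return Named list of [shoe_spec()] objects: flat S1 (1.0 cm heel),
#'   sneaker S2 (3.0 cm) and stiletto S3 (9.0 cm).
#' @export
default_shoes <- function() {
  list(
    S1 = shoe_spec("S1", heel_height = 1.0, ball_width = 8.0,
                   shoe_size = 23.5, heel_base = 28.5),
    S2 = shoe_spec("S2", heel_height = 3.0, ball_width = 9.5,
                   shoe_size = 23.5, heel_base = 55.3),
    S3 = shoe_spec("S3", heel_height = 9.0, ball_width = 8.0,
                   shoe_size = 23.5, heel_base = 0.9))
}

#' Simulated walking cohort
#'
#' Draws subject profiles from the cohort statistics of the study population:
#' young healthy women, body mass 50.40 +/- 2.20 kg, self-selected treadmill
#' speeds of 2.40 +/- 0.30 km/h (comfortable) and 5.10 +/- 0.20 km/h (fast).
#' Stride cadences, a subject-specific range-of-motion multiplier and a
#' sensor noise level complete each profile.
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A list of `subject_profile` objects with fields `subject_id`,
#'   `body_weight` (N), `comfortable_speed` / `fast_speed` (km/h),
#'   `cadence_comfortable` / `cadence_fast` (strides/min), `rom_scale`
#'   (dimensionless, in \[0.8, 1.2\]) and `noise_sd` (kPa).
#' @export
make_cohort <- function(n_subjects, seed = 1L) {
  stopifnot(n_subjects >= 0)
  if (n_subjects == 0) return(list())
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      mass <- rnorm(1, 50.40, 2.20)
      v_c <- rnorm(1, 2.40, 0.30)
      v_f <- rnorm(1, 5.10, 0.20)
      while (v_f <= v_c) v_f <- rnorm(1, 5.10, 0.20)
      cad_c <- rnorm(1, 42, 3)
      cad_f <- rnorm(1, 56, 3)
      while (cad_f <= cad_c) cad_f <- rnorm(1, 56, 3)
      structure(
        list(subject_id = sprintf("P%02d", i),
             body_weight = mass * 9.81,
             comfortable_speed = v_c,
             fast_speed = v_f,
             cadence_comfortable = cad_c,
             cadence_fast = cad_f,
             rom_scale = {
               r <- rnorm(1, 1, 0.05)
               while (r < 0.9 || r > 1.1) r <- rnorm(1, 1, 0.05)
               r
             },
             noise_sd = runif(1, 0.3, 0.6)),
        class = "subject_profile")
    })
  })
}

# Speed scaling of the templates. Fast gait loads the insole considerably
# harder (~15%) but widens the knee range of motion only modestly (~8%), in
# line with treadmill kinematics at 2.4 vs 5.1 km/h.
speed_factor <- function(speed, what = c("pressure", "angle")) {
  what <- match.arg(what)
  switch(speed,
         C = 1.0,
         F = if (what == "pressure") 1.15 else 1.08,
         stop("unknown speed label: ", speed, call. = FALSE))
}

#' Noise-free knee-angle gait-cycle template
#'
#' A 100-point heel-strike-referenced knee-angle waveform in the Kinovea
#' lateral-marker convention (about 180 deg at full extension). Knee flexion
#' (180 - angle) is modelled as a sum of raised-cosine bumps: a small
#' loading-response flexion wave peaking near 15% of the gait cycle, a
#' pre-swing build-up, and the large swing flexion peak near 72% of the
#' cycle. The swing peak grows with gait speed and shrinks with heel height
#' (high heels stiffen swing-phase flexion), and scales with the subject's
#' range-of-motion multiplier.
#'
#' @param shoe A [shoe_spec()].
#' @param speed Speed label, "C" (comfortable) or "F" (fast).
#' @param profile A subject profile from [make_cohort()].
#' @return Numeric vector of length 100, degrees.
#' @export
knee_angle_cycle <- function(shoe, speed, profile) {
  knee_angle_fun(shoe, speed, profile)(0:99)
}

# Continuous form of the angle template: a function of gait-cycle phase
# (0-100, wrapped), used both for the 100-point template and for sampling
# trials at exact phases.
knee_angle_fun <- function(shoe, speed, profile) {
  stopifnot(inherits(shoe, "shoe_spec"))
  sf <- speed_factor(speed, "angle")
  # swing flexion loss of ~0.6 deg per cm of heel at the default swing
  # amplitude: a stiff-knee tendency in high heels
  heel_damp <- 1 - 0.012 * (shoe$heel_height - 1)
  rom <- profile$rom_scale
  amp_stance <- 16 * rom * (if (speed == "F") 1.10 else 1.0)
  amp_preswing <- 22 * rom * sf * heel_damp
  amp_swing <- 58 * rom * sf * heel_damp
  # circular phase distance: bumps whose support crosses the cycle boundary
  # stay continuous from one stride into the next
  circ_rc <- function(s, centre, width) {
    d <- abs(s %% 100 - centre)
    raised_cosine(pmin(d, 100 - d), 0, width)
  }
  function(s) {
    180 - (amp_stance * circ_rc(s, 15, 40) +
             amp_preswing * circ_rc(s, 55, 30) +
             amp_swing * circ_rc(s, 72, 44))
  }
}

# Fixed sensor layout: 10 channels split across the three insole regions.
channel_groups <- function() {
  list(forefoot = 1:4, midfoot = 5:6, rearfoot = 7:10)
}

# Within-region channel weights (sum to 1 per region).
.region_channel_weights <- list(
  forefoot = c(0.3, 0.3, 0.2, 0.2),
  midfoot  = c(0.55, 0.45),
  rearfoot = c(0.3, 0.3, 0.2, 0.2))

#' Noise-free plantar-pressure gait-cycle template
#'
#' A 100 x 10 matrix of channel pressures (kPa) over one heel-strike
#' referenced gait cycle. The stance phase (samples 1-60) carries the classic
#' double-bump total-pressure profile: a heel-strike peak loading mostly the
#' rearfoot channels, a push-off peak loading the forefoot, plus a broad
#' mid-stance base load. Swing samples (61-100) are exactly zero. Heel height
#' shifts load from rearfoot towards forefoot channels and softens the
#' heel-strike peak; amplitudes scale with body weight over the minimal
#' insole stress area (tens of kPa) and with gait speed.
#'
#' @inheritParams knee_angle_cycle
#' @return Numeric matrix \[100 x 10\], kPa; rows are cycle samples.
#' @export
pressure_channel_cycle <- function(shoe, speed, profile) {
  stopifnot(inherits(shoe, "shoe_spec"))
  sf <- speed_factor(speed)
  p0 <- profile$body_weight / 0.0188 / 1000  # full-support pressure, kPa
  s <- 0:99
  stance <- s < 60
  # stance envelope: positive from the heel-strike sample on, zero from
  # toe-off; smoothstep edges keep it band-limited below the 15 Hz
  # anti-noise filter while the onset still clears the zero-threshold at
  # the very first stance sample
  smoothstep <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    u * u * (3 - 2 * u)
  }
  env <- smoothstep((s + 2) / 9) * smoothstep((59 - s + 2) / 9) *
    (0.8 + 0.2 * sin(pi * s / 59))
  base <- ifelse(stance, env, 0) * 0.28 * p0 * sf
  # heel height reshapes the double bump: a softer, earlier heel-strike
  # peak and a stronger, later push-off peak give each shoe a recognizable
  # total-pressure signature
  heel_soft <- 1 - 0.022 * (shoe$heel_height - 1)
  hs_bump <- raised_cosine(s, 14 - 0.1 * (shoe$heel_height - 1), 25) *
    0.55 * p0 * sf * heel_soft
  po_bump <- raised_cosine(s, 46 + 0.25 * (shoe$heel_height - 1), 22) *
    0.65 * p0 * sf * (1 + 0.012 * (shoe$heel_height - 1))
  # region shares per waveform component; heel height shifts load forward
  shift <- min(0.03 * (shoe$heel_height - 1), 0.45)
  shift_po <- min(0.015 * (shoe$heel_height - 1), 0.12)
  shares <- list(
    base = c(forefoot = 0.35, midfoot = 0.30, rearfoot = 0.35),
    hs   = c(forefoot = 0.08 + shift, midfoot = 0.12,
             rearfoot = 0.80 - shift),
    po   = c(forefoot = 0.80 + shift_po, midfoot = 0.12 - shift_po / 2,
             rearfoot = 0.08 - shift_po / 2))
  groups <- channel_groups()
  out <- matrix(0, nrow = 100, ncol = 10)
  for (region in names(groups)) {
    w <- .region_channel_weights[[region]]
    region_total <- base * shares$base[[region]] +
      hs_bump * shares$hs[[region]] + po_bump * shares$po[[region]]
    out[, groups[[region]]] <- region_total %o% w
  }
  out[!stance, ] <- 0
  out
}

#' Pressure trial container
#'
#' @param channels Numeric matrix \[n_samples x 10\] of channel pressures, kPa.
#' @param sampling_rate Sampling rate in Hz (100 for the insole).
#' @param subject_id,shoe,speed Condition labels.
#' @return Object of class `pressure_trial`.
#' @export
pressure_trial <- function(channels, sampling_rate = 100,
                           subject_id = NA_character_,
                           shoe = NA_character_, speed = NA_character_) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 10)
    stop("pressure trial must have exactly 10 channels, got ", ncol(channels),
         call. = FALSE)
  if (any(channels < 0))
    stop("pressure trial contains negative pressures", call. = FALSE)
  structure(list(sampling_rate = sampling_rate, channels = channels,
                 subject_id = subject_id, shoe = shoe, speed = speed,
                 duration = nrow(channels) / sampling_rate),
            class = "pressure_trial")
}

#' Knee-angle trial container
#'
#' @param angle Numeric vector of knee joint angles, degrees (Kinovea
#'   convention, about 180 at full extension).
#' @param sampling_rate Sampling rate in Hz (30 for video tracking).
#' @param subject_id,shoe,speed Condition labels.
#' @return Object of class `angle_trial`.
#' @export
angle_trial <- function(angle, sampling_rate = 30,
                        subject_id = NA_character_,
                        shoe = NA_character_, speed = NA_character_) {
  angle <- as.numeric(angle)
  if (any(angle <= 90 | angle >= 185))
    stop("knee angles must lie in (90, 185) degrees", call. = FALSE)
  structure(list(sampling_rate = sampling_rate, angle = angle,
                 subject_id = subject_id, shoe = shoe, speed = speed,
                 duration = length(angle) / sampling_rate),
            class = "angle_trial")
}

#' @export
print.pressure_trial <- function(x, ...) {
  cat(sprintf("Pressure trial: %s %s %s, %.0f s @ %g Hz, 10 channels\n",
              x$subject_id, x$shoe, x$speed, x$duration, x$sampling_rate))
  invisible(x)
}

#' @export
print.angle_trial <- function(x, ...) {
  cat(sprintf("Knee-angle trial: %s %s %s, %.0f s @ %g Hz\n",
              x$subject_id, x$shoe, x$speed, x$duration, x$sampling_rate))
  invisible(x)
}

# Evaluate a 100-point heel-strike-referenced template at arbitrary cycle
# phases in [0, 100). Closure "cyclic" interpolates into the next cycle's
# first sample (for continuous signals); closure "zero" holds zero up to the
# next heel strike, so contact onset stays a step at the cycle boundary.
eval_template <- function(template, phase, closure = c("cyclic", "zero")) {
  closure <- match.arg(closure)
  pad <- function(col) c(col, if (closure == "cyclic") col[1] else 0)
  if (is.matrix(template)) {
    apply(template, 2, function(col)
      approx(x = 0:100, y = pad(col), xout = phase)$y)
  } else {
    approx(x = 0:100, y = pad(template), xout = phase)$y
  }
}

#' Simulate one paired treadmill trial
#'
#' Tiles the noise-free angle and pressure templates at the subject's cadence
#' with small (+/- 3%) per-cycle duration jitter, samples the pressure at
#' 100 Hz and the angle at 30 Hz on a shared clock, and adds measurement
#' noise to the pressure channels: a load-proportional Gaussian component
#' (scaled by `profile$noise_sd`), a high-frequency (> 20 Hz) treadmill
#' vibration that couples through foot contact, and a small constant sensor
#' noise floor. Pressures are clipped at 0 kPa. Ground-truth heel-strike and
#' toe-off times are retained in the `events` element so segmentation can be
#' verified against them.
#'
#' @param profile A subject profile from [make_cohort()].
#' @param shoe A [shoe_spec()].
#' @param speed Speed label "C" or "F".
#' @param duration Trial duration in seconds (>= 10; the protocol uses 120).
#' @param seed Integer seed controlling jitter and noise.
#' @param noise Logical; `FALSE` produces a noise-free trial for recovery
#'   testing.
#' @param jitter Logical; per-cycle duration jitter of +/- 3%. Defaults to
#'   `noise`, so a noise-free trial is fully deterministic.
#' @param start_offset Seconds of the leading (partial) gait cycle already
#'   elapsed when recording starts; `NULL` (default) draws it uniformly from
#'   one cycle. Use 0 to start the trial exactly at a heel strike.
#' @return A list of class `trial_pair` with elements `pressure`
#'   ([pressure_trial()]), `angle` ([angle_trial()]) and `events` (ground
#'   truth `heel_strike_times`, `toe_off_times`, `cycle_durations`, seconds).
#' @export
simulate_trial <- function(profile, shoe, speed, duration = 120, seed = 1L,
                           noise = TRUE, jitter = noise,
                           start_offset = NULL) {
  stopifnot(inherits(shoe, "shoe_spec"))
  cadence <- switch(speed, C = profile$cadence_comfortable,
                    F = profile$cadence_fast,
                    stop("unknown speed label: ", speed, call. = FALSE))
  mean_dur <- 60 / cadence
  if (duration < 10 || duration < 2 * mean_dur)
    stop("trial duration too short: need at least ",
         sprintf("%.1f", max(10, 2 * mean_dur)), " s", call. = FALSE)

  angle_fun <- knee_angle_fun(shoe, speed, profile)
  press_tmpl <- pressure_channel_cycle(shoe, speed, profile)

  with_seed(seed, {
    n_cycles_max <- ceiling(duration / (0.97 * mean_dur)) + 2
    durs <- if (jitter) mean_dur * runif(n_cycles_max, 0.97, 1.03)
            else rep(mean_dur, n_cycles_max)
    t0 <- -(if (is.null(start_offset)) runif(1, 0, mean_dur)
            else start_offset)
    starts <- t0 + c(0, cumsum(durs))[seq_len(n_cycles_max)]

    phase_at <- function(t) {
      idx <- findInterval(t, starts)
      (t - starts[idx]) / durs[idx] * 100
    }

    tp <- (seq_len(duration * 100) - 1) / 100
    ta <- (seq_len(duration * 30) - 1) / 30
    press_clean <- eval_template(press_tmpl, phase_at(tp), closure = "zero")
    angle_vals <- angle_fun(phase_at(ta))

    if (noise) {
      load_scale <- sqrt(press_clean / max(press_clean))
      vib <- (0.25 * sin(2 * pi * 27 * tp + runif(1, 0, 2 * pi)) +
              0.20 * sin(2 * pi * 33 * tp + runif(1, 0, 2 * pi)))
      noisy <- press_clean +
        profile$noise_sd * load_scale *
          matrix(rnorm(length(press_clean)), nrow = nrow(press_clean)) +
        load_scale * vib +
        0.05 * matrix(rnorm(length(press_clean)), nrow = nrow(press_clean))
      press_clean <- pmax(noisy, 0)
    }

    hs <- starts[starts >= 0 & starts < duration]
    keep <- which(starts >= 0 & starts < duration)
    structure(
      list(pressure = pressure_trial(press_clean, 100, profile$subject_id,
                                     shoe$name, speed),
           angle = angle_trial(angle_vals, 30, profile$subject_id,
                               shoe$name, speed),
           events = list(heel_strike_times = hs,
                         toe_off_times = starts[keep] + 0.6 * durs[keep],
                         cycle_durations = durs[keep])),
      class = "trial_pair")
  })
}

#' Simulate the full cohort across all shoe x speed conditions
#'
#' @param cohort List of subject profiles from [make_cohort()].
#' @param shoes Named list of [shoe_spec()]s; default [default_shoes()].
#' @param speeds Character vector of speed labels.
#' @param duration Trial duration in seconds.
#' @param seed Integer base seed; each trial gets a distinct derived seed.
#' @param noise Logical, passed to [simulate_trial()].
#' @return A list of `trial_pair` objects, one per subject x shoe x speed.
#' @export
simulate_cohort <- function(cohort, shoes = default_shoes(),
                            speeds = c("C", "F"), duration = 120,
                            seed = 1L, noise = TRUE) {
  trials <- list()
  k <- 0L
  for (si in seq_along(cohort)) {
    for (sh in shoes) {
      for (sp in speeds) {
        k <- k + 1L
        trials[[k]] <- simulate_trial(cohort[[si]], sh, sp, duration,
                                      seed = as.integer((as.numeric(seed) * 10007 + k) %%
                                                          2147483647),
                                      noise = noise)
      }
    }
  }
  trials
}
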