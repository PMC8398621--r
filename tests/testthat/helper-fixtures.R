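# Shared fixtures. Expensive ones (the full preprocessed cohort) are built
# lazily once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

# A fixed mid-cohort subject used wherever a single profile is enough.
fixture_profile <- function(cadence = 50, rom = 1.0, weight_kg = 50.4,
                            noise_sd = 0.5, cadence_fast = cadence + 14) {
  structure(list(subject_id = "T01", body_weight = weight_kg * 9.81,
                 comfortable_speed = 2.4, fast_speed = 5.1,
                 cadence_comfortable = cadence, cadence_fast = cadence_fast,
                 rom_scale = rom, noise_sd = noise_sd),
            class = "subject_profile")
}

# Noise-free, jitter-free trial starting exactly at a heel strike, with a
# 1 s cycle so the 100 Hz grid lands on integer cycle phases: the cleanest
# configuration for recovery testing.
fixture_clean_trial <- function(shoe = default_shoes()$S1, speed = "C") {
  simulate_trial(fixture_profile(cadence = 60), shoe, speed,
                 duration = 120, seed = 11, noise = FALSE, start_offset = 0)
}

# Full 7-subject x 6-condition cohort, preprocessed; built once.
fixture_cohort_cycles <- function() {
  if (is.null(.fixtures$cycles)) {
    cohort <- make_cohort(7, seed = 20260920L)
    trials <- simulate_cohort(cohort, seed = 20260920L)
    pairs <- lapply(trials, preprocess_trial_pair)
    .fixtures$cycles <- bind_cycle_pairs(pairs)
    .fixtures$subjects <- vapply(cohort, `[[`, character(1), "subject_id")
  }
  list(cycles = .fixtures$cycles, subjects = .fixtures$subjects)
}

# Circular local-average operator: each output sample is the mean of `w`
# neighboring input samples, an exact linear map on 100-point cycles.
local_average_map <- function(w = 3) {
  L <- matrix(0, 100, 100)
  half <- (w - 1) / 2
  for (m in 1:100) {
    idx <- ((m - 1 - half):(m - 1 + half)) %% 100 + 1
    L[m, idx] <- 1 / w
  }
  L
}

# Dataset whose target is an exact linear map of the input. Inputs are
# smooth low-rank waveforms (a common carrier plus random combinations of a
# few harmonics), loosely resembling normalized gait curves; the last 10%
# of rows belong to a second "subject" so LOSO validation has a holdout.
fixture_linear_dataset <- function(n = 200, seed = 5) {
  set.seed(seed)
  s <- (0:99) / 100
  B <- rbind(sin(2 * pi * s), cos(2 * pi * s), sin(4 * pi * s),
             cos(4 * pi * s), sin(6 * pi * s))
  C <- matrix(runif(n * nrow(B), -1, 1), n)
  X <- 0.5 + 0.25 * matrix(sin(2 * pi * s), n, 100, byrow = TRUE) +
    0.4 * C %*% B / nrow(B)
  Y <- X %*% t(local_average_map(3))
  n_b <- max(1, round(0.1 * n))
  structure(
    list(model_id = "M1", inputs = X, targets = Y,
         labels = data.frame(subject = rep(c("A", "B"), c(n - n_b, n_b))),
         norm_input = fit_minmax(X), norm_target = fit_minmax(Y)),
    class = "gait_dataset")
}

# Linear-map dataset built from the package's own noise-free total-pressure
# templates (varying body weight, shoe and speed), for comparing network
# families on gait-shaped inputs.
fixture_gait_linear_dataset <- function(n = 600, seed = 5) {
  set.seed(seed)
  shoes <- default_shoes()
  X <- matrix(0, n, 100)
  for (i in seq_len(n)) {
    prof <- fixture_profile(weight_kg = runif(1, 45, 60))
    sh <- shoes[[sample(3, 1)]]
    sp <- sample(c("C", "F"), 1)
    X[i, ] <- rowSums(pressure_channel_cycle(sh, sp, prof))
  }
  Y <- X %*% t(local_average_map(5))
  nx <- fit_minmax(X); ny <- fit_minmax(Y)
  n_b <- round(0.2 * n)
  structure(
    list(model_id = "M1", inputs = apply_minmax(X, nx),
         targets = apply_minmax(Y, ny),
         labels = data.frame(subject = rep(c("A", "B"), c(n - n_b, n_b))),
         norm_input = nx, norm_target = ny),
    class = "gait_dataset")
}
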