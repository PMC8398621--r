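test_that("trimming keeps the centered minute", {
  prof <- fixture_profile()
  tr <- simulate_trial(prof, default_shoes()$S1, "C", 120, seed = 2)
  p <- trim_to_mid_minute(tr$pressure)
  expect_equal(nrow(p$channels), 6000)
  # samples 3001..9000 of the original 12000 are retained
  expect_identical(p$channels, tr$pressure$channels[3001:9000, ])
  a <- trim_to_mid_minute(tr$angle)
  expect_length(a$angle, 1800)
  expect_identical(a$angle, tr$angle$angle[901:2700])

  short <- pressure_trial(matrix(0, 5900, 10), 100)
  expect_error(trim_to_mid_minute(short), "59.0 s")
})

test_that("trailing moving average has flat-kernel behavior", {
  expect_equal(moving_average(rep(3.5, 50)), rep(3.5, 50))
  x <- numeric(40); x[20] <- 1
  ma <- moving_average(x, 10)
  expect_equal(ma[20:29], rep(0.1, 10))
  expect_equal(ma[c(1:19, 30:40)], rep(0, 30))
  expect_identical(moving_average(1:10, 1), 1:10)
  # partial leading windows are plain means of what is available
  y <- c(4, 8, 6)
  expect_equal(moving_average(y, 3), c(4, 6, 6))
  expect_error(moving_average(numeric(0)), "empty")
})

test_that("Butterworth low-pass meets DC, stop-band and pass-band contracts", {
  expect_equal(butterworth_lowpass(rep(7.2, 300), 100), rep(7.2, 300),
               tolerance = 1e-9)
  t <- (0:1999) / 100
  rms <- function(x) sqrt(mean(x^2))
  hi <- sin(2 * pi * 30 * t)
  expect_lt(rms(butterworth_lowpass(hi, 100)[200:1800]), 0.05 * rms(hi))
  lo <- sin(2 * pi * 2 * t)
  expect_lt(abs(rms(butterworth_lowpass(lo, 100)[200:1800]) - rms(lo)) /
              rms(lo), 0.02)
  expect_error(butterworth_lowpass(lo, 100, cutoff = 50), "Nyquist")
})

test_that("total plantar pressure is the channel sum", {
  z <- matrix(0, 50, 10)
  expect_equal(total_plantar_pressure(z)$values, rep(0, 50))
  s <- seq_len(50)
  one <- z; one[, 4] <- s
  expect_equal(total_plantar_pressure(one)$values, as.numeric(s))
  two <- z; two[, 2] <- 2; two[, 9] <- 2
  expect_equal(total_plantar_pressure(two)$values, rep(4, 50))
  expect_error(total_plantar_pressure(matrix(0, 50, 9)), "10 channels")
})

test_that("Zero-To-Zero toe-off detection follows the stated rule", {
  x <- c(0, 0, 3, 6, 4, 0, 0, 5, 8, 3, 0, 0, 4, 7, 0)
  expect_identical(detect_toe_off_events(x, 0.5), c(6L, 11L, 15L))
  expect_identical(detect_toe_off_events(rep(0, 20), 0.5), integer(0))
  expect_identical(detect_toe_off_events(c(0, 1, 2, 3), 0.5), integer(0))
})

test_that("toe-off detection agrees with the brute-force scan on random series", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    x <- pmax(0, round(rnorm(n, 1, 2), 2))
    thr <- runif(1, 0.1, 2)
    expect_identical(detect_toe_off_events(x, thr),
                     oracle_toe_off_scan(x, thr))
  }
})

test_that("cycle extraction counts, guards and boundary accuracy hold", {
  # 31 equally spaced events over a long series -> exactly 30 segments
  values <- rep(c(rep(0, 10), rep(5, 40)), 35)
  ev <- detect_toe_off_events(values, 0.5)
  segs <- extract_cycles(values, ev[1:31], n_cycles = 30)
  expect_length(segs, 30)
  expect_identical(vapply(segs, attr, integer(1), "start_index"), ev[1:30])
  expect_error(extract_cycles(values, ev[1:20], 30), "found 20")

  # an artifact segment (half duration) is never part of the chosen window
  ev2 <- sort(c(seq(1, 3200, by = 100), 1135))
  segs2 <- extract_cycles(rep(1, 3300), ev2, n_cycles = 10)
  durs <- vapply(segs2, length, integer(1))
  expect_true(all(abs(durs - 100) <= 40))

  # noiseless trial: chosen boundaries within one sample of ground truth
  tr <- fixture_clean_trial()
  cp <- preprocess_trial_pair(tr, ma_window = 1)
  gt_toe <- tr$events$toe_off_times - (tr$pressure$duration - 60) / 2
  p <- trim_to_mid_minute(tr$pressure)
  filt <- apply(p$channels, 2, butterworth_lowpass, sampling_rate = 100)
  total <- total_plantar_pressure(pressure_trial(pmax(filt, 0), 100))
  thr <- kneegait:::default_zero_threshold(total$values)
  ev3 <- detect_toe_off_events(total, thr)
  segs3 <- extract_cycles(total, ev3, 30)
  starts <- (vapply(segs3, attr, integer(1), "start_index") - 1) / 100
  for (s in starts) expect_lte(min(abs(gt_toe - s)), 0.0100001)
})

test_that("resampling to 100 points preserves endpoints and affine shapes", {
  expect_identical(resample_cycle_to_100(1:100), as.numeric(1:100))
  ramp <- seq(2, 14, length.out = 57)
  out <- resample_cycle_to_100(ramp)
  expect_equal(out, seq(2, 14, length.out = 100))
  expect_equal(resample_cycle_to_100(c(0, 10)),
               seq(0, 10, length.out = 100))
  expect_error(resample_cycle_to_100(5), "2 samples")
})

test_that("heel-strike rotation re-references the cycle and sets stance fraction", {
  toy <- c(0, 0, 0, 0, 2, 5, 3, 1)
  gc <- rotate_to_heel_strike(toy, 0.5)
  expect_equal(gc$values, c(2, 5, 3, 1, 0, 0, 0, 0))
  expect_equal(gc$stance_fraction, 0.5)

  loaded <- c(3, 2, 1, rep(0, 5))
  gc2 <- rotate_to_heel_strike(loaded, 0.5)
  expect_equal(gc2$values, loaded)
  expect_error(rotate_to_heel_strike(rep(0, 8), 0.5), "no contact")
})

test_that("angle cycle extraction pairs with pressure events and validates times", {
  tr <- fixture_clean_trial()
  a <- trim_to_mid_minute(tr$angle)
  expect_identical(extract_angle_cycles(a, c(0, 1), n_cycles = 0), list())
  expect_error(extract_angle_cycles(a, c(55, 65), n_cycles = 1), "outside")
  expect_error(extract_angle_cycles(a, c(0.5), n_cycles = 1), "n_cycles")
})

test_that("min-max normalization maps extrema and inverts algebraically", {
  params <- fit_minmax(c(0, 10))
  expect_equal(apply_minmax(0, params), 0)
  expect_equal(apply_minmax(10, params), 1)
  expect_equal(apply_minmax(5, params), 0.5)
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(50, sd = 10)
    p <- fit_minmax(x)
    expect_lt(max(abs(apply_minmax(apply_minmax(x, p), p, invert = TRUE) - x)),
              1e-12)
  }
  expect_error(fit_minmax(rep(3, 10)), "degenerate")
})

test_that("noise-free pipeline recovers generator templates", {
  prof <- fixture_profile(cadence = 60)
  for (sh_name in c("S1", "S3")) {
    sh <- default_shoes()[[sh_name]]
    tr <- simulate_trial(prof, sh, "C", 120, seed = 11, noise = FALSE,
                         start_offset = 0)
    cp <- preprocess_trial_pair(tr, ma_window = 1)
    tmpl_p <- rowSums(pressure_channel_cycle(sh, "C", prof))
    tmpl_a <- knee_angle_cycle(sh, "C", prof)
    expect_lt(max(abs(sweep(cp$pressure, 2, tmpl_p))),
              0.01 * diff(range(tmpl_p)))
    expect_lt(max(abs(sweep(cp$angle, 2, tmpl_a))), 1)
    expect_equal(unique(cp$stance_fraction), 0.6)
  }
})

test_that("noisy pipeline yields 30 paired cycles with unloaded swing tails", {
  prof <- fixture_profile(cadence = 48)
  tr <- simulate_trial(prof, default_shoes()$S2, "F", 120, seed = 21)
  cp <- preprocess_trial_pair(tr)
  expect_equal(nrow(cp$pressure), 30)
  expect_equal(nrow(cp$angle), 30)
  expect_equal(cp$meta$cycle_index, 1:30)
  # every sample at or beyond the stance fraction is at the zero level
  for (i in 1:30) {
    sf <- cp$stance_fraction[i]
    swing <- cp$pressure[i, (floor(100 * sf) + 1):100]
    expect_true(all(swing <= cp$zero_threshold))
  }
})
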