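test_that("cohort generation is seeded, bounded and matches the sampling distributions", {
  co <- make_cohort(7, seed = 4)
  expect_length(co, 7)
  expect_identical(co, make_cohort(7, seed = 4))
  expect_false(identical(co, make_cohort(7, seed = 5)))
  expect_length(unique(vapply(co, `[[`, character(1), "subject_id")), 7)
  expect_identical(make_cohort(0), list())

  big <- make_cohort(10000, seed = 99)
  v_c <- vapply(big, `[[`, numeric(1), "comfortable_speed")
  v_f <- vapply(big, `[[`, numeric(1), "fast_speed")
  rom <- vapply(big, `[[`, numeric(1), "rom_scale")
  expect_lt(abs(mean(v_c) - 2.40), 0.05)
  expect_lt(abs(mean(v_f) - 5.10), 0.05)
  expect_true(all(v_f > v_c))
  expect_true(all(rom >= 0.8 & rom <= 1.2))
  cad_c <- vapply(big, `[[`, numeric(1), "cadence_comfortable")
  cad_f <- vapply(big, `[[`, numeric(1), "cadence_fast")
  expect_true(all(cad_f > cad_c))
})

test_that("knee-angle templates encode the speed and heel-height effects", {
  prof <- fixture_profile()
  shoes <- default_shoes()
  for (sh in shoes) for (sp in c("C", "F")) {
    a <- knee_angle_cycle(sh, sp, prof)
    expect_length(a, 100)
    expect_true(all(a > 90 & a < 185))
    # near extension at heel strike
    expect_lt(180 - a[1], 8)
  }
  for (sh in shoes) {
    flex_c <- 180 - knee_angle_cycle(sh, "C", prof)
    flex_f <- 180 - knee_angle_cycle(sh, "F", prof)
    expect_gt(max(flex_f), max(flex_c))
  }
  for (sp in c("C", "F")) {
    swing <- 61:100
    peak_s1 <- max(180 - knee_angle_cycle(shoes$S1, sp, prof)[swing])
    peak_s3 <- max(180 - knee_angle_cycle(shoes$S3, sp, prof)[swing])
    expect_lt(peak_s3, peak_s1)
  }
  expect_error(knee_angle_cycle(shoes$S1, "X", prof), "speed")
})

test_that("pressure templates are stance-only with shoe-dependent load distribution", {
  prof80 <- fixture_profile(weight_kg = 80)
  shoes <- default_shoes()
  groups <- kneegait:::channel_groups()
  for (sh in shoes) for (sp in c("C", "F")) {
    m <- pressure_channel_cycle(sh, sp, prof80)
    expect_identical(dim(m), c(100L, 10L))
    expect_true(all(m >= 0))
    expect_identical(sum(m[61:100, ]), 0)       # swing exactly unloaded
  }
  # full-support magnitude: summed peak in the tens of kPa for 80 kg
  peak <- max(rowSums(pressure_channel_cycle(shoes$S1, "C", prof80)))
  expect_gt(peak, 30); expect_lt(peak, 60)
  # stilettos shift stance impulse towards the forefoot
  share <- function(sh) {
    m <- pressure_channel_cycle(sh, "C", prof80)
    sum(m[, groups$forefoot]) / sum(m)
  }
  expect_gt(share(shoes$S3), share(shoes$S1))
})

test_that("simulated trials have the protocol's shape and are seed-reproducible", {
  prof <- fixture_profile(cadence = 50)
  sh <- default_shoes()$S2
  tr <- simulate_trial(prof, sh, "C", duration = 120, seed = 3)
  expect_equal(nrow(tr$pressure$channels), 12000)
  expect_length(tr$angle$angle, 3600)
  expect_true(all(tr$pressure$channels >= 0))

  n_gt <- length(tr$events$heel_strike_times)
  expect_true(abs(n_gt - 100) <= 2)   # cadence 50 over 120 s

  tr2 <- simulate_trial(prof, sh, "C", duration = 120, seed = 3)
  expect_identical(tr, tr2)
  tr3 <- simulate_trial(prof, sh, "C", duration = 120, seed = 4)
  expect_false(identical(tr$pressure$channels, tr3$pressure$channels))

  expect_error(simulate_trial(prof, sh, "C", duration = 2, seed = 1),
               "duration")
})

test_that("ground-truth heel strikes align with the zero-to-nonzero transitions", {
  prof <- fixture_profile(cadence = 47)
  tr <- simulate_trial(prof, default_shoes()$S1, "C", duration = 60,
                       seed = 8, noise = FALSE, jitter = TRUE)
  total <- rowSums(tr$pressure$channels)
  onsets <- which(total[-1] > 0 & total[-length(total)] == 0) + 1L
  onset_times <- (onsets - 1) / 100
  for (hs in tr$events$heel_strike_times[-1])
    expect_lte(min(abs(onset_times - hs)), 0.0100001)
})

test_that("the full cohort simulates quickly enough for routine use", {
  elapsed <- system.time({
    cohort <- make_cohort(7, seed = 1)
    trials <- simulate_cohort(cohort, seed = 1)
  })[["elapsed"]]
  expect_length(trials, 42)
  expect_lt(elapsed, 30)
})
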