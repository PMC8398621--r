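test_that("accuracy metrics reproduce hand-evaluated cases", {
  id <- accuracy_metrics(c(170, 150, 130), c(170, 150, 130))
  expect_equal(id$rmse, 0)
  expect_equal(id$mre, 0)
  expect_equal(id$r_value, 1)

  m <- accuracy_metrics(c(2, 4), c(1, 2))
  expect_equal(m$rmse, sqrt(2.5))
  expect_equal(m$mre, 0.5)
  expect_equal(m$r_value, 1 - 5 / 0.5)     # -9

  actual <- c(160, 170, 150, 180)
  flat <- accuracy_metrics(rep(mean(actual), 4), actual)
  expect_equal(flat$r_value, 0)

  expect_error(accuracy_metrics(1:3, 1:4), "equal length")
  expect_error(accuracy_metrics(c(0, 2), c(1, 1)), "zero prediction")
})

test_that("the relative error denominator is the prediction, not the actual", {
  m <- accuracy_metrics(prediction = c(10, 10), actual = c(5, 12))
  expect_equal(m$mre, mean(c(5 / 10, 2 / 10)))
  m_swapped <- accuracy_metrics(prediction = c(5, 12), actual = c(10, 10))
  expect_equal(m_swapped$mre, mean(c(5 / 5, 2 / 12)))
  expect_false(isTRUE(all.equal(m$mre, m_swapped$mre)))
})

test_that("correlation efficiency equals an independent two-pass computation", {
  set.seed(55)
  for (i in 1:25) {
    x <- rnorm(100, 160, 15)
    y <- rnorm(100, 160, 15)
    ss_res <- 0; ss_tot <- 0; ybar <- sum(y) / length(y)
    for (k in seq_along(y)) {
      ss_res <- ss_res + (y[k] - x[k])^2
      ss_tot <- ss_tot + (y[k] - ybar)^2
    }
    expect_equal(accuracy_metrics(x, y)$r_value, 1 - ss_res / ss_tot)
  }
})

test_that("Bland-Altman limits follow the closed form and its symmetries", {
  flat <- bland_altman(c(1, 1, 1))
  expect_equal(flat$mean_bias, 1)
  expect_equal(flat$upper_loa, 1)
  expect_equal(flat$lower_loa, 1)

  ba <- bland_altman(c(1, 3))
  expect_equal(ba$mean_bias, 2)
  expect_equal(ba$upper_loa, 2 + 1.96 * sqrt(2))
  expect_equal(ba$lower_loa, 2 - 1.96 * sqrt(2))

  set.seed(66)
  d <- rnorm(40, 2, 3)
  a <- bland_altman(d)
  b <- bland_altman(-d)
  expect_equal(b$mean_bias, -a$mean_bias)
  expect_equal(b$upper_loa, -a$lower_loa)
  expect_equal(b$lower_loa, -a$upper_loa)
  expect_equal(a$upper_loa - a$lower_loa, 2 * 1.96 * sd(d))
  expect_true(a$lower_loa <= a$mean_bias && a$mean_bias <= a$upper_loa)

  expect_error(bland_altman(3), "at least 2")
})

test_that("flexion patterns subtract from 180 and partition the cycle", {
  fp <- flexion_pattern(rep(180, 100))
  expect_equal(fp$flexion, rep(0, 100))
  a <- rep(180, 100); a[40] <- 120
  expect_equal(flexion_pattern(a)$flexion[40], 60)
  expect_identical(fp$stance_range, 1:60)
  expect_identical(fp$swing_range, 61:100)
  expect_identical(sort(c(fp$stance_range, fp$swing_range)), 1:100)
})

test_that("model evaluation is exact against self-generated targets", {
  ds <- fixture_linear_dataset(n = 60)
  fit <- train_mlp(ds, train_config(seed = 7, epochs = 5,
                                    validation_folds = 1))
  press <- apply_minmax(ds$inputs[1:24, ], ds$norm_input, invert = TRUE)
  angle <- predict_knee_angle(fit$model, press)
  test_cycles <- list(
    pressure = press, angle = angle,
    meta = data.frame(subject = "P09",
                      shoe = rep(c("S1", "S2"), each = 12),
                      speed = rep(c("C", "F"), 12),
                      cycle_index = 1:24, stringsAsFactors = FALSE))
  rep1 <- evaluate_models(list(M1 = fit$model, M2 = fit$model), test_cycles)
  expect_equal(nrow(rep1$metrics), 2 * 2 * 2)   # 2 models x 2 shoes x 2 speeds
  expect_true(all(rep1$metrics$r == 1))
  expect_true(all(rep1$metrics$mre == 0))
  expect_true(all(rep1$agreement$mean_bias == 0))
  expect_error(evaluate_models(list(M1 = fit$model), test_cycles,
                               training_subjects = c("P09", "P01")),
               "overlap")
})
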