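test_that("initialization is seeded with consistent shapes", {
  m1 <- init_mlp(3)
  m2 <- init_mlp(3)
  expect_identical(m1, m2)
  expect_false(identical(init_mlp(3)$W1, init_mlp(4)$W1))
  expect_identical(dim(m1$W1), c(250L, 100L))
  expect_identical(dim(m1$W2), c(150L, 250L))
  expect_identical(dim(m1$W3), c(100L, 150L))
  expect_length(m1$b1, 250)
  expect_length(m1$b3, 100)
})

test_that("forward pass follows the layer equations in closed-form cases", {
  # all-zero weights: hidden-1 sits at 0.5, later layers at exactly 0
  m <- init_mlp(1)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) m[[nm]] <- m[[nm]] * 0
  expect_equal(mlp_forward(m, runif(100)), rep(0, 100))

  # 1-1-1-1 toy network, unit weights, zero bias, input 0:
  # sigmoid(0)=0.5 -> relu(0.5)=0.5 -> elu(0.5)=0.5
  toy <- init_mlp(1, layer_sizes = c(1, 1, 1, 1))
  for (nm in c("W1", "W2", "W3")) toy[[nm]][] <- 1
  for (nm in c("b1", "b2", "b3")) toy[[nm]][] <- 0
  expect_equal(mlp_forward(toy, 0), 0.5)
  expect_equal(oracle_mlp_forward(toy, 0), 0.5)

  # ELU acts as identity on non-negative output pre-activations
  x <- elu_in <- seq(0, 3, by = 0.5)
  expect_equal(kneegait:::elu(elu_in), x)

  expect_error(mlp_forward(init_mlp(1), runif(50)), "input nodes")
})

test_that("vectorized forward agrees with the scalar oracle on random networks", {
  set.seed(31)
  for (rep in 1:20) {
    m <- init_mlp(rep, layer_sizes = c(3, 5, 4, 3))
    for (nm in c("b1", "b2", "b3")) m[[nm]] <- rnorm(length(m[[nm]]))
    x <- rnorm(3, sd = 2)
    expect_lt(max(abs(mlp_forward(m, x) - oracle_mlp_forward(m, x))), 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  m <- init_mlp(6, layer_sizes = c(3, 5, 4, 3))
  set.seed(41)
  X <- matrix(rnorm(12), 4, 3)
  Y <- matrix(runif(12), 4, 3)
  g <- kneegait:::mlp_gradients(m, X, Y)$grads
  for (nm in names(g)) {
    gn <- numeric_gradient(m, nm, X, Y)
    expect_lt(max(abs(gn - g[[nm]])) / max(abs(gn)), 1e-5)
  }
})

test_that("dataset assembly follows the model definitions and normalizes to [0, 1]", {
  # fabricated cycle table: 5 training subjects x 6 conditions x 30 cycles
  subs <- sprintf("P%02d", 1:5)
  grid <- expand.grid(cycle = 1:30, speed = c("C", "F"),
                      shoe = c("S1", "S2", "S3"), subject = subs,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  set.seed(8)
  cycles <- list(pressure = matrix(runif(n * 100, 0, 40), n),
                 angle = matrix(runif(n * 100, 120, 180), n),
                 meta = data.frame(subject = grid$subject, shoe = grid$shoe,
                                   speed = grid$speed,
                                   cycle_index = grid$cycle,
                                   stringsAsFactors = FALSE))
  counts <- c(M1 = 300, M2 = 300, M3 = 300, M4 = 450, M5 = 450, M6 = 900)
  for (mid in names(counts)) {
    ds <- assemble_dataset(cycles, mid, subs)
    expect_equal(nrow(ds$inputs), unname(counts[mid]))
    expect_equal(nrow(ds$targets), nrow(ds$inputs))
    expect_true(all(ds$inputs >= 0 & ds$inputs <= 1))
    expect_true(all(ds$targets >= 0 & ds$targets <= 1))
  }
  # a missing condition is reported by name
  drop <- !(cycles$meta$subject == "P03" & cycles$meta$shoe == "S2" &
              cycles$meta$speed == "F")
  broken <- list(pressure = cycles$pressure[drop, ],
                 angle = cycles$angle[drop, ], meta = cycles$meta[drop, ])
  expect_error(assemble_dataset(broken, "M6", subs), "P03.*S2.*F")
  expect_error(assemble_dataset(cycles, "M9", subs), "unknown model")
})

test_that("training learns an exact linear map and is fully deterministic", {
  ds <- fixture_linear_dataset(n = 1500)
  cfg <- train_config(seed = 2, validation_folds = 1)
  fit <- train_mlp(ds, cfg)
  expect_lt(tail(fit$history$train_loss, 1), 1e-3)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_true(all(is.finite(fit$history$val_loss)))

  ds_small <- fixture_linear_dataset(n = 150)
  cfg_short <- train_config(seed = 2, epochs = 3, validation_folds = 1)
  f1 <- train_mlp(ds_small, cfg_short)
  f2 <- train_mlp(ds_small, cfg_short)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$history, f2$history)

  one_sub <- ds_small
  one_sub$labels$subject <- "A"
  expect_error(train_mlp(one_sub, cfg_short), "2 training subjects")
})

test_that("prediction de-normalizes, smooths gently and validates state", {
  ds <- fixture_linear_dataset(n = 80)
  fit <- train_mlp(ds, train_config(seed = 3, epochs = 10,
                                    validation_folds = 1))
  x <- apply_minmax(ds$inputs[1, ], ds$norm_input, invert = TRUE)
  pred <- predict_knee_angle(fit$model, x)
  expect_length(pred, 100)
  raw <- predict_knee_angle(fit$model, x, smooth = FALSE)
  # the zero-phase post-filter preserves the cycle mean (DC gain 1)
  expect_lt(abs(mean(pred) - mean(raw)), 0.5)

  # normalize-then-invert is an exact algebraic round trip
  y <- runif(100, 120, 180)
  yn <- apply_minmax(y, fit$model$norm_target)
  expect_lt(max(abs(apply_minmax(yn, fit$model$norm_target, invert = TRUE) -
                      y)), 1e-12)

  expect_error(predict_knee_angle(init_mlp(1), runif(100)),
               "normalization")
})

test_that("the convolutional comparison is deterministic and tracks the perceptron", {
  ds <- fixture_linear_dataset(n = 120)
  cfg <- train_config(seed = 4, epochs = 6, validation_folds = 1)
  c1 <- train_cnn(ds, cnn_spec(), cfg)
  c2 <- train_cnn(ds, cnn_spec(), cfg)
  p1 <- cnn_forward(c1$model, ds$inputs[1:5, ])
  expect_identical(p1, cnn_forward(c2$model, ds$inputs[1:5, ]))
  expect_identical(dim(p1), c(5L, 100L))

  # held-out fit quality of CNN and MLP is similar on a gait-shaped
  # linear-map task
  dg <- fixture_gait_linear_dataset(n = 600)
  cfg_full <- train_config(seed = 4, epochs = 40, validation_folds = 1)
  val <- dg$labels$subject == "B"
  r_of <- function(pred) {
    mean(vapply(seq_len(sum(val)), function(i) {
      y <- dg$targets[val, ][i, ]
      1 - sum((y - pred[i, ])^2) / sum((y - mean(y))^2)
    }, numeric(1)))
  }
  mfit <- train_mlp(dg, cfg_full)
  cfit <- train_cnn(dg, cnn_spec(), cfg_full)
  r_mlp <- r_of(mlp_forward(mfit$model, dg$inputs[val, ]))
  r_cnn <- r_of(cnn_forward(cfit$model, dg$inputs[val, ]))
  expect_lt(abs(r_mlp - r_cnn), 0.1)
})
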