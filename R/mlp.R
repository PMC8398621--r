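# Activation functions of the four-layer network and their derivatives.
sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)
elu <- function(x, alpha = 1) ifelse(x >= 0, x, alpha * (exp(x) - 1))

#' Training configuration
#'
#' RMSprop with a learning rate of 0.007 is the study's optimizer; decay and
#' epsilon take the conventional values, mean squared error is the loss, and
#' the epoch/batch protocol mirrors the convolutional comparison model (50
#' epochs, batches of 32).
#'
#' @param learning_rate RMSprop learning rate (default 0.007).
#' @param rho Decay of the squared-gradient moving average (default 0.9).
#' @param epsilon Numerical stabilizer (default 1e-8).
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param validation_folds Number of leave-one-subject-out validation folds
#'   to run; `NULL` (default) rotates through every training subject.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.007, rho = 0.9, epsilon = 1e-8,
                         epochs = 50, batch_size = 32, seed = 1L,
                         validation_folds = NULL) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 epochs = epochs, batch_size = batch_size, seed = seed,
                 validation_folds = validation_folds),
            class = "train_config")
}

#' Initialize the four-layer perceptron
#'
#' Glorot-uniform weights, zero biases. The default layer sizes are the
#' study architecture: 100 input nodes (one pressure gait cycle), hidden
#' layers of 250 (logistic) and 150 (ReLU) units, and 100 output nodes (one
#' angle gait cycle) with ELU activation.
#'
#' @param seed Integer seed; the same seed reproduces the weights.
#' @param layer_sizes Integer vector (input, hidden1, hidden2, output).
#' @param elu_alpha ELU alpha for the output activation (default 1).
#' @return An object of class `mlp_model`.
#' @export
init_mlp <- function(seed = 1L, layer_sizes = c(100, 250, 150, 100),
                     elu_alpha = 1.0) {
  stopifnot(length(layer_sizes) == 4, all(layer_sizes >= 1), elu_alpha > 0)
  glorot <- function(n_out, n_in) {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(runif(n_out * n_in, -lim, lim), nrow = n_out)
  }
  with_seed(seed, {
    structure(
      list(layer_sizes = layer_sizes,
           W1 = glorot(layer_sizes[2], layer_sizes[1]),
           b1 = numeric(layer_sizes[2]),
           W2 = glorot(layer_sizes[3], layer_sizes[2]),
           b2 = numeric(layer_sizes[3]),
           W3 = glorot(layer_sizes[4], layer_sizes[3]),
           b3 = numeric(layer_sizes[4]),
           elu_alpha = elu_alpha,
           norm_input = NULL, norm_target = NULL,
           trained = FALSE),
      class = "mlp_model")
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("Four-layer perceptron %s (sigmoid / ReLU / ELU out)%s\n",
              paste(x$layer_sizes, collapse = "-"),
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

# Forward pass keeping intermediates for backprop. X: n x N_in matrix.
mlp_forward_full <- function(model, X) {
  H1 <- sweep(X %*% t(model$W1), 2, model$b1, `+`)
  A1 <- sigmoid(H1)
  Z2 <- sweep(A1 %*% t(model$W2), 2, model$b2, `+`)
  A2 <- relu(Z2)
  Z3 <- sweep(A2 %*% t(model$W3), 2, model$b3, `+`)
  out <- elu(Z3, model$elu_alpha)
  list(X = X, A1 = A1, Z2 = Z2, A2 = A2, Z3 = Z3, out = out)
}

#' Forward pass of the four-layer perceptron
#'
#' Hidden layer 1 is a linear combination of the 100 normalized pressure
#' inputs passed through the logistic function; hidden layer 2 applies ReLU;
#' the output layer applies ELU. Output values are normalized angles.
#'
#' @param model An [init_mlp()] model.
#' @param input Numeric vector of length `layer_sizes[1]`, or a matrix with
#'   that many columns (one sample per row).
#' @return Numeric vector (or matrix) of normalized outputs.
#' @export
mlp_forward <- function(model, input) {
  stopifnot(inherits(model, "mlp_model"))
  vec <- is.null(dim(input))
  X <- if (vec) matrix(input, nrow = 1) else as.matrix(input)
  if (ncol(X) != model$layer_sizes[1])
    stop("input length ", ncol(X), " does not match the ",
         model$layer_sizes[1], " input nodes", call. = FALSE)
  if (any(!is.finite(X))) stop("input must be finite", call. = FALSE)
  out <- mlp_forward_full(model, X)$out
  if (vec) as.numeric(out) else out
}

# Gradients of the mean squared error over all outputs of the batch.
mlp_gradients <- function(model, X, Y) {
  f <- mlp_forward_full(model, X)
  n_el <- length(Y)
  d_out <- 2 * (f$out - Y) / n_el
  dZ3 <- d_out * ifelse(f$Z3 >= 0, 1, model$elu_alpha * exp(f$Z3))
  dW3 <- t(dZ3) %*% f$A2
  db3 <- colSums(dZ3)
  dA2 <- dZ3 %*% model$W3
  dZ2 <- dA2 * (f$Z2 > 0)
  dW2 <- t(dZ2) %*% f$A1
  db2 <- colSums(dZ2)
  dA1 <- dZ2 %*% model$W2
  dZ1 <- dA1 * f$A1 * (1 - f$A1)
  dW1 <- t(dZ1) %*% f$X
  db1 <- colSums(dZ1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    W3 = dW3, b3 = db3),
       loss = mean((f$out - Y)^2))
}

# One RMSprop update of a named parameter list; `state` carries the moving
# average of squared gradients. Returns updated params and state.
rmsprop_step <- function(params, grads, state, config) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state[[nm]] <- config$rho * state[[nm]] + (1 - config$rho) * g^2
    params[[nm]] <- params[[nm]] -
      config$learning_rate * g / (sqrt(state[[nm]]) + config$epsilon)
  }
  list(params = params, state = state)
}

mse <- function(pred, target) mean((pred - target)^2)

#' Train the four-layer perceptron
#'
#' Minimizes mean squared error on the normalized targets with mini-batch
#' RMSprop. Validation follows the leave-one-subject-out scheme: each fold
#' holds out one training subject (excluded from the gradient updates) and
#' records its loss per epoch; folds rotate through the training subjects.
#' The returned model carries the final-epoch weights of the last fold and
#' the dataset's normalization parameters. Fully deterministic given
#' `config$seed`.
#'
#' @param dataset A dataset from [assemble_dataset()].
#' @param config A [train_config()].
#' @return List with elements `model` (trained [init_mlp()] model) and
#'   `history` (data frame: fold, epoch, train_loss, val_loss).
#' @export
train_mlp <- function(dataset, config = train_config()) {
  stopifnot(inherits(dataset, "gait_dataset"))
  subjects <- unique(dataset$labels$subject)
  if (length(subjects) < 2)
    stop("leave-one-subject-out validation requires at least 2 training subjects",
         call. = FALSE)
  n_folds <- min(length(subjects),
                 if (is.null(config$validation_folds)) length(subjects)
                 else config$validation_folds)
  history <- list()
  model <- NULL
  for (f in seq_len(n_folds)) {
    val_subject <- subjects[length(subjects) - f + 1L]
    val_rows <- dataset$labels$subject == val_subject
    fit <- fit_network_rmsprop(
      init = init_mlp(config$seed, elu_alpha = 1.0,
                      layer_sizes = c(ncol(dataset$inputs), 250, 150,
                                      ncol(dataset$targets))),
      grad_fn = mlp_gradients,
      predict_fn = function(m, X) mlp_forward(m, X),
      X = dataset$inputs[!val_rows, , drop = FALSE],
      Y = dataset$targets[!val_rows, , drop = FALSE],
      X_val = dataset$inputs[val_rows, , drop = FALSE],
      Y_val = dataset$targets[val_rows, , drop = FALSE],
      config = config)
    history[[f]] <- data.frame(fold = f, fit$history)
    model <- fit$model
  }
  model$norm_input <- dataset$norm_input
  model$norm_target <- dataset$norm_target
  model$trained <- TRUE
  model$model_id <- dataset$model_id
  list(model = model, history = do.call(rbind, history))
}

# Shared seeded mini-batch RMSprop loop used by both network types.
# `init` must contain the trainable parameters as named numeric elements
# matching the names of the gradients produced by `grad_fn(model, X, Y)`.
fit_network_rmsprop <- function(init, grad_fn, predict_fn, X, Y,
                                X_val, Y_val, config) {
  model <- init
  param_names <- names(grad_fn(model, X[1, , drop = FALSE],
                               Y[1, , drop = FALSE])$grads)
  state <- lapply(model[param_names], function(p) p * 0)
  n <- nrow(X)
  hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                     val_loss = NA_real_)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (idx in batches) {
        g <- grad_fn(model, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
        upd <- rmsprop_step(model[param_names], g$grads, state, config)
        model[param_names] <- upd$params
        state <- upd$state
      }
      hist$train_loss[epoch] <- mse(predict_fn(model, X), Y)
      hist$val_loss[epoch] <- if (nrow(X_val) > 0)
        mse(predict_fn(model, X_val), Y_val) else NA_real_
    }
  })
  list(model = model, history = hist)
}

#' Predict a knee-angle cycle from a pressure cycle
#'
#' Normalizes the input with the model's stored pressure parameters, runs
#' the forward pass, inverts the angle normalization, and smooths the
#' de-normalized prediction with a zero-phase 4th-order Butterworth low-pass
#' at 0.2 cycles/sample on the 100-point gait-cycle grid.
#'
#' @param model A trained model from [train_mlp()].
#' @param pressure_cycle A pressure [gait_cycle()], numeric vector of length
#'   100, or matrix of cycles (rows).
#' @param smooth Apply the post-filter (default `TRUE`).
#' @return Numeric vector (or matrix) of knee-joint angles in degrees.
#' @export
predict_knee_angle <- function(model, pressure_cycle, smooth = TRUE) {
  stopifnot(inherits(model, "mlp_model") || inherits(model, "cnn_model"))
  if (is.null(model$norm_input) || is.null(model$norm_target))
    stop("model has no stored normalization parameters; train it first",
         call. = FALSE)
  vec <- inherits(pressure_cycle, "gait_cycle") || is.null(dim(pressure_cycle))
  X <- if (inherits(pressure_cycle, "gait_cycle"))
    matrix(pressure_cycle$values, nrow = 1)
  else if (is.null(dim(pressure_cycle))) matrix(pressure_cycle, nrow = 1)
  else as.matrix(pressure_cycle)
  Xn <- apply_minmax(X, model$norm_input)
  Yn <- if (inherits(model, "mlp_model")) mlp_forward(model, Xn)
        else cnn_forward(model, Xn)
  if (is.null(dim(Yn))) Yn <- matrix(Yn, nrow = 1)
  Y <- apply_minmax(Yn, model$norm_target, invert = TRUE)
  if (smooth)
    Y <- t(apply(Y, 1, butterworth_lowpass, sampling_rate = 1,
                 cutoff = 0.2, order = 4))
  if (vec) as.numeric(Y) else Y
}
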