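#' Convolutional comparison model specification
#'
#' The 1-D convolutional network compared against the perceptron: two valid
#' convolutions (32 then 64 filters, kernel length 3) each followed by
#' max-pooling of width 2, 50% dropout, a dense ELU layer and a linear
#' output of 100 nodes. Conv activations are sigmoid and ReLU respectively.
#'
#' @param conv1_filters,conv2_filters Filter counts (defaults 32, 64).
#' @param kernel Kernel length (default 3).
#' @param pool Pooling width (default 2).
#' @param dropout Dropout probability (default 0.5).
#' @param dense_units Units in the dense ELU layer (default 100).
#' @return A list of class `cnn_spec`.
#' @export
cnn_spec <- function(conv1_filters = 32, conv2_filters = 64, kernel = 3,
                     pool = 2, dropout = 0.5, dense_units = 100) {
  structure(list(conv1_filters = conv1_filters,
                 conv2_filters = conv2_filters, kernel = kernel,
                 pool = pool, dropout = dropout, dense_units = dense_units),
            class = "cnn_spec")
}

# Sliding-window (im2col) matrix for a batch of 1-D signals. X: n x T input
# (or n x T x C array); returns (n * T_out) x (kernel * C) matrix.
im2col1d <- function(X, kernel) {
  if (length(dim(X)) == 2) dim(X) <- c(dim(X), 1L)
  n <- dim(X)[1]; T_in <- dim(X)[2]; C <- dim(X)[3]
  T_out <- T_in - kernel + 1
  cols <- lapply(seq_len(kernel), function(k) {
    sl <- X[, k:(k + T_out - 1), , drop = FALSE]
    dim(sl) <- c(n * T_out, C)
    sl
  })
  do.call(cbind, cols)
}

# Initialize CNN parameters (Glorot uniform, zero biases), deterministic.
init_cnn <- function(seed = 1L, spec = cnn_spec(), n_in = 100, n_out = 100) {
  k <- spec$kernel
  t1 <- n_in - k + 1
  p1 <- floor(t1 / spec$pool)
  t2 <- p1 - k + 1
  p2 <- floor(t2 / spec$pool)
  flat <- p2 * spec$conv2_filters
  glorot <- function(n_r, n_c, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(n_r * n_c, -lim, lim), nrow = n_r)
  }
  with_seed(seed, {
    structure(
      list(spec = spec, n_in = n_in, n_out = n_out,
           dims = list(t1 = t1, p1 = p1, t2 = t2, p2 = p2, flat = flat),
           Wc1 = glorot(k, spec$conv1_filters, k, k * spec$conv1_filters),
           bc1 = numeric(spec$conv1_filters),
           Wc2 = glorot(k * spec$conv1_filters, spec$conv2_filters,
                        k * spec$conv1_filters, k * spec$conv2_filters),
           bc2 = numeric(spec$conv2_filters),
           Wd = glorot(spec$dense_units, flat, flat, spec$dense_units),
           bd = numeric(spec$dense_units),
           Wo = glorot(n_out, spec$dense_units, spec$dense_units, n_out),
           bo = numeric(n_out),
           norm_input = NULL, norm_target = NULL, trained = FALSE),
      class = "cnn_model")
  })
}

# Max-pool an n x T x C array along T with non-overlapping windows of 2;
# returns pooled array and the "first element won" mask for backprop.
maxpool2 <- function(A) {
  n <- dim(A)[1]; T_in <- dim(A)[2]
  T_out <- floor(T_in / 2)
  odd <- A[, seq(1, 2 * T_out - 1, by = 2), , drop = FALSE]
  even <- A[, seq(2, 2 * T_out, by = 2), , drop = FALSE]
  list(P = pmax(odd, even), first_won = odd >= even, T_out = T_out)
}

cnn_forward_full <- function(model, X, training = FALSE) {
  n <- nrow(X)
  d <- model$dims
  Xc1 <- im2col1d(X, model$spec$kernel)
  Z1 <- sweep(Xc1 %*% model$Wc1, 2, model$bc1, `+`)
  A1 <- sigmoid(Z1)
  A1a <- A1; dim(A1a) <- c(n, d$t1, model$spec$conv1_filters)
  pl1 <- maxpool2(A1a)
  Xc2 <- im2col1d(pl1$P, model$spec$kernel)
  Z2 <- sweep(Xc2 %*% model$Wc2, 2, model$bc2, `+`)
  A2 <- pmax(Z2, 0)
  A2a <- A2; dim(A2a) <- c(n, d$t2, model$spec$conv2_filters)
  pl2 <- maxpool2(A2a)
  Fl <- pl2$P; dim(Fl) <- c(n, d$flat)
  if (training && model$spec$dropout > 0) {
    keep <- 1 - model$spec$dropout
    M <- matrix(rbinom(n * d$flat, 1, keep) / keep, nrow = n)
    Fd <- Fl * M
  } else {
    M <- NULL
    Fd <- Fl
  }
  Zd <- sweep(Fd %*% t(model$Wd), 2, model$bd, `+`)
  Ad <- elu(Zd)
  out <- sweep(Ad %*% t(model$Wo), 2, model$bo, `+`)
  list(X = X, Xc1 = Xc1, Z1 = Z1, A1 = A1, pl1 = pl1, Xc2 = Xc2, Z2 = Z2,
       A2 = A2, pl2 = pl2, Fd = Fd, M = M, Zd = Zd, Ad = Ad, out = out)
}

#' Forward pass of the convolutional comparison model
#'
#' @param model A `cnn_model` from [train_cnn()].
#' @param input Numeric vector of length 100 or a matrix of cycles (rows);
#'   normalized pressure. Dropout is disabled at inference.
#' @return Numeric vector (or matrix) of normalized outputs.
#' @export
cnn_forward <- function(model, input) {
  stopifnot(inherits(model, "cnn_model"))
  vec <- is.null(dim(input))
  X <- if (vec) matrix(input, nrow = 1) else as.matrix(input)
  if (ncol(X) != model$n_in)
    stop("input length must be ", model$n_in, call. = FALSE)
  out <- cnn_forward_full(model, X, training = FALSE)$out
  if (vec) as.numeric(out) else out
}

# Scatter gradients of an im2col matrix back to the input positions.
im2col1d_backward <- function(dXcol, n, T_in, C, kernel) {
  T_out <- T_in - kernel + 1
  dX <- array(0, dim = c(n, T_in, C))
  for (k in seq_len(kernel)) {
    chunk <- dXcol[, ((k - 1) * C + 1):(k * C), drop = FALSE]
    dim(chunk) <- c(n, T_out, C)
    dX[, k:(k + T_out - 1), ] <- dX[, k:(k + T_out - 1), , drop = FALSE] + chunk
  }
  dX
}

# Route pooled gradients back to the winning pre-pool positions.
maxpool2_backward <- function(dP, first_won, T_in) {
  n <- dim(dP)[1]; T_out <- dim(dP)[2]; C <- dim(dP)[3]
  dA <- array(0, dim = c(n, T_in, C))
  dA[, seq(1, 2 * T_out - 1, by = 2), ] <- dP * first_won
  dA[, seq(2, 2 * T_out, by = 2), ] <- dP * !first_won
  dA
}

cnn_gradients <- function(model, X, Y, training = TRUE) {
  n <- nrow(X)
  d <- model$dims
  f <- cnn_forward_full(model, X, training = training)
  d_out <- 2 * (f$out - Y) / length(Y)
  dWo <- t(d_out) %*% f$Ad
  dbo <- colSums(d_out)
  dAd <- d_out %*% model$Wo
  dZd <- dAd * ifelse(f$Zd >= 0, 1, exp(f$Zd))
  dWd <- t(dZd) %*% f$Fd
  dbd <- colSums(dZd)
  dF <- dZd %*% model$Wd
  if (!is.null(f$M)) dF <- dF * f$M
  dim(dF) <- c(n, d$p2, model$spec$conv2_filters)
  dA2a <- maxpool2_backward(dF, f$pl2$first_won, d$t2)
  dZ2 <- dA2a; dim(dZ2) <- c(n * d$t2, model$spec$conv2_filters)
  dZ2 <- dZ2 * (f$Z2 > 0)
  dWc2 <- t(f$Xc2) %*% dZ2
  dbc2 <- colSums(dZ2)
  dXc2 <- dZ2 %*% t(model$Wc2)
  dP1 <- im2col1d_backward(dXc2, n, d$p1, model$spec$conv1_filters,
                           model$spec$kernel)
  dA1a <- maxpool2_backward(dP1, f$pl1$first_won, d$t1)
  dZ1 <- dA1a; dim(dZ1) <- c(n * d$t1, model$spec$conv1_filters)
  dZ1 <- dZ1 * f$A1 * (1 - f$A1)
  dWc1 <- t(f$Xc1) %*% dZ1
  dbc1 <- colSums(dZ1)
  list(grads = list(Wc1 = dWc1, bc1 = dbc1, Wc2 = dWc2, bc2 = dbc2,
                    Wd = dWd, bd = dbd, Wo = dWo, bo = dbo),
       loss = mean((f$out - Y)^2))
}

#' Train the convolutional comparison model
#'
#' Identical training protocol to [train_mlp()] (mini-batch RMSprop,
#' leave-one-subject-out validation, MSE loss); dropout is active during
#' training only and every draw is seeded, so repeated runs are identical.
#'
#' @param dataset A dataset from [assemble_dataset()].
#' @param spec A [cnn_spec()].
#' @param config A [train_config()].
#' @return List with elements `model` (a `cnn_model`) and `history`.
#' @export
train_cnn <- function(dataset, spec = cnn_spec(), config = train_config()) {
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
      init = init_cnn(config$seed, spec, n_in = ncol(dataset$inputs),
                      n_out = ncol(dataset$targets)),
      grad_fn = function(m, X, Y) cnn_gradients(m, X, Y, training = TRUE),
      predict_fn = function(m, X) cnn_forward(m, X),
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

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("1-D CNN %d-%d conv filters (kernel %d), dense %d, out %d%s\n",
              x$spec$conv1_filters, x$spec$conv2_filters, x$spec$kernel,
              x$spec$dense_units, x$n_out,
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}
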