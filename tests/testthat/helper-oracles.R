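# Independent oracles, deliberately written in the most literal style
# possible so they share no code with the implementation they check.

# Scalar, loop-based forward pass of the four-layer network: every sum is
# written out exactly as the layer definitions state it.
oracle_mlp_forward <- function(model, input) {
  Nl <- model$layer_sizes[1]; Nh <- model$layer_sizes[2]
  Nz <- model$layer_sizes[3]; Nout <- model$layer_sizes[4]
  y1 <- numeric(Nh)
  for (j in seq_len(Nh)) {
    h <- 0
    for (i in seq_len(Nl)) h <- h + input[i] * model$W1[j, i]
    h <- h + model$b1[j]
    y1[j] <- 1 / (1 + exp(-h))
  }
  y2 <- numeric(Nz)
  for (k in seq_len(Nz)) {
    z <- 0
    for (j in seq_len(Nh)) z <- z + y1[j] * model$W2[k, j]
    z <- z + model$b2[k]
    y2[k] <- max(0, z)
  }
  theta <- numeric(Nout)
  for (m in seq_len(Nout)) {
    y3 <- 0
    for (k in seq_len(Nz)) y3 <- y3 + y2[k] * model$W3[m, k]
    y3 <- y3 + model$b3[m]
    theta[m] <- if (y3 >= 0) y3 else model$elu_alpha * (exp(y3) - 1)
  }
  theta
}

# Brute-force sample-by-sample scan for toe-off events: walk the series and
# record every index at or below threshold that directly follows an index
# above it.
oracle_toe_off_scan <- function(values, threshold) {
  out <- integer(0)
  for (i in seq_along(values)) {
    if (i == 1) next
    if (values[i] <= threshold && values[i - 1] > threshold)
      out <- c(out, i)
  }
  out
}

# Central finite-difference gradient of the batch MSE wrt one parameter
# matrix of an mlp model.
numeric_gradient <- function(model, name, X, Y, eps = 1e-6) {
  P <- model[[name]]
  G <- P * 0
  for (i in seq_along(P)) {
    up <- model; up[[name]][i] <- P[i] + eps
    dn <- model; dn[[name]][i] <- P[i] - eps
    G[i] <- (mean((mlp_forward(up, X) - Y)^2) -
               mean((mlp_forward(dn, X) - Y)^2)) / (2 * eps)
  }
  G
}
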