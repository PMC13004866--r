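## Minimal feedforward network machinery used by the autoencoder (IT
## channel) and the value-encoding networks. Weights are stored as
## (out x in) matrices; forward passes operate on n x in sample matrices.

mlp_init <- function(dims, acts, init_sd = 1) {
  stopifnot(length(acts) == length(dims) - 1)
  layers <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    fan_in <- dims[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(dims[l + 1] * fan_in, 0, init_sd / sqrt(fan_in)),
                 dims[l + 1], fan_in),
      b = rep(0, dims[l + 1]),
      act = acts[l]
    )
  }
  layers
}

act_fun <- function(z, act) switch(act, tanh = tanh(z), linear = z,
                                   sigmoid = 1 / (1 + exp(-z)))
act_deriv <- function(a, act) switch(act, tanh = 1 - a^2, linear = 1,
                                     sigmoid = a * (1 - a))

## Forward pass; returns list of layer activations (A[[1]] = input).
mlp_forward <- function(layers, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  A <- vector("list", length(layers) + 1)
  A[[1]] <- X
  for (l in seq_along(layers)) {
    Z <- A[[l]] %*% t(layers[[l]]$W)
    Z <- sweep(Z, 2, layers[[l]]$b, "+")
    A[[l + 1]] <- act_fun(Z, layers[[l]]$act)
  }
  A
}

## Full-batch gradient of the mean squared reconstruction error
## ||out - target||^2 / (n * d), with the loss before the step.
mlp_mse_grad <- function(layers, X, target) {
  A <- mlp_forward(layers, X)
  L <- length(layers)
  n <- nrow(X)
  out <- A[[L + 1]]
  loss <- mean((out - target)^2)
  grads <- vector("list", L)
  delta <- 2 * (out - target) / (n * ncol(target)) *
    act_deriv(out, layers[[L]]$act)
  for (l in L:1) {
    grads[[l]] <- list(W = t(delta) %*% A[[l]], b = colSums(delta))
    if (l > 1)
      delta <- (delta %*% layers[[l]]$W) * act_deriv(A[[l]], layers[[l - 1]]$act)
  }
  list(grads = grads, loss = loss)
}

## Gradient descent with classical momentum on the reconstruction loss.
mlp_train <- function(layers, X, target, epochs, lr, momentum = 0.9) {
  vel <- lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  hist <- numeric(epochs)
  for (e in seq_len(epochs)) {
    g <- mlp_mse_grad(layers, X, target)
    if (!is.finite(g$loss))
      stop("autoencoder training diverged (non-finite loss)", call. = FALSE)
    hist[e] <- g$loss
    for (l in seq_along(layers)) {
      vel[[l]]$W <- momentum * vel[[l]]$W - lr * g$grads[[l]]$W
      vel[[l]]$b <- momentum * vel[[l]]$b - lr * g$grads[[l]]$b
      layers[[l]]$W <- layers[[l]]$W + vel[[l]]$W
      layers[[l]]$b <- layers[[l]]$b + vel[[l]]$b
    }
  }
  list(layers = layers, history = hist)
}

#' Construct a value-encoding network
#'
#' A feedforward value function `V = f(w2 . z + b2)` with `z = W1 u + b1` a
#' single *linear* hidden layer (116 units by default) over the concatenated
#' input channels, and a sigmoid output so `V` lies in (0, 1). With
#' `hidden_units = 0` the readout acts directly on the input, and with
#' `output = "linear"`, `bias = FALSE` and zero initialization the network
#' degenerates to the tabular Rescorla-Wagner learner (a single weight per
#' input component).
#'
#' @param input_dim Total input dimension (IT channel 50 + non-S1 channel 20
#'   = 70 for the full model).
#' @param hidden_units Linear hidden-layer width (116), or 0 for a direct
#'   readout.
#' @param output `"sigmoid"` or `"linear"` output activation.
#' @param bias Include bias terms?
#' @param init_sd Weight initialization scale (s.d. before fan-in scaling);
#'   0 gives exactly zero weights.
#' @param v0 Initial value output: with sigmoid output the output bias is set
#'   to `qlogis(v0)` so a naive network predicts a low association (~0.1),
#'   emulating the low pre-training anticipatory licking. Ignored when
#'   `bias = FALSE`.
#' @param seed Integer seed for the weight draw.
#' @return A `value_network` object.
#' @export
value_network <- function(input_dim, hidden_units = 116L,
                          output = c("sigmoid", "linear"), bias = TRUE,
                          init_sd = 0.1, v0 = 0.1, seed = NULL) {
  output <- match.arg(output)
  with_seed(seed, {
    if (hidden_units > 0) {
      W1 <- matrix(stats::rnorm(hidden_units * input_dim, 0,
                                init_sd / sqrt(input_dim)),
                   hidden_units, input_dim)
      b1 <- rep(0, hidden_units)
      w2 <- stats::rnorm(hidden_units, 0, init_sd / sqrt(hidden_units))
    } else {
      W1 <- NULL; b1 <- NULL
      w2 <- stats::rnorm(input_dim, 0, if (init_sd == 0) 0 else init_sd / sqrt(input_dim))
      if (init_sd == 0) w2 <- rep(0, input_dim)
    }
    b2 <- if (!bias) 0 else if (output == "sigmoid") stats::qlogis(v0) else 0
    structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                   output = output, bias = bias, input_dim = input_dim),
              class = "value_network")
  })
}

#' Predict the value (association strength) of a stimulus
#'
#' `V = f(readout(hidden(u)))` on the concatenation of the IT representation
#' and the non-S1 (raw stimulus) representation. With sigmoid output, V lies
#' strictly in (0, 1).
#'
#' @param vnet A [value_network()].
#' @param h_it IT-channel input (50-dim for the full model; may carry the
#'   whole input when `h_non_s1` is `NULL`).
#' @param h_non_s1 Non-S1 channel input (the raw 20-dim stimulus), or `NULL`.
#' @return Scalar value V.
#' @export
predict_value <- function(vnet, h_it, h_non_s1 = NULL) {
  u <- c(h_it, h_non_s1)
  if (length(u) != vnet$input_dim)
    stop_invalid("input dimension %d does not match network input_dim %d",
                 length(u), vnet$input_dim)
  vnet_forward(vnet, u)$V
}

vnet_forward <- function(vnet, u) {
  z <- if (!is.null(vnet$W1)) drop(vnet$W1 %*% u) + vnet$b1 else u
  a <- sum(vnet$w2 * z) + vnet$b2
  V <- if (vnet$output == "sigmoid") 1 / (1 + exp(-a)) else a
  list(V = V, z = z, a = a)
}

## Gradient of V with respect to every parameter, at input u.
vnet_grad <- function(vnet, u) {
  fw <- vnet_forward(vnet, u)
  g <- if (vnet$output == "sigmoid") fw$V * (1 - fw$V) else 1
  grads <- list(w2 = g * fw$z, b2 = if (vnet$bias) g else 0)
  if (!is.null(vnet$W1)) {
    grads$W1 <- g * outer(vnet$w2, u)
    grads$b1 <- if (vnet$bias) g * vnet$w2 else rep(0, length(vnet$b1))
  }
  list(V = fw$V, grads = grads)
}

#' Reward prediction error
#'
#' `delta = R - V`: the difference between the delivered reward (1 on CS+
#' trials, 0 on CS- trials) and the predicted value.
#'
#' @param R Reward (0 or 1).
#' @param V Predicted value.
#' @return The prediction error `R - V`.
#' @export
rpe <- function(R, V) {
  if (!all(R %in% c(0, 1))) stop_invalid("`R` must be 0 or 1")
  R - V
}

#' Rescorla-Wagner update of the value network
#'
#' Moves every weight along the gradient of the value prediction, scaled by
#' the learning rate and the prediction error:
#' `w <- w + alpha * delta * dV/dw`. A zero prediction error leaves the
#' network unchanged.
#'
#' @param vnet A [value_network()].
#' @param alpha Learning rate.
#' @param delta Reward prediction error for the trial.
#' @param h_it,h_non_s1 The inputs at which the value (and gradient) was
#'   computed.
#' @return The updated `value_network`.
#' @export
rw_update <- function(vnet, alpha, delta, h_it, h_non_s1 = NULL) {
  if (!is.finite(delta)) stop_invalid("prediction error must be finite")
  u <- c(h_it, h_non_s1)
  if (length(u) != vnet$input_dim)
    stop_invalid("input dimension %d does not match network input_dim %d",
                 length(u), vnet$input_dim)
  gr <- vnet_grad(vnet, u)$grads
  if (any(!vapply(gr, function(g) all(is.finite(g)), logical(1))))
    stop("non-finite gradient in value-network update", call. = FALSE)
  vnet$w2 <- vnet$w2 + alpha * delta * gr$w2
  if (vnet$bias) vnet$b2 <- vnet$b2 + alpha * delta * gr$b2
  if (!is.null(vnet$W1)) {
    vnet$W1 <- vnet$W1 + alpha * delta * gr$W1
    if (vnet$bias) vnet$b1 <- vnet$b1 + alpha * delta * gr$b1
  }
  vnet
}

## One gradient-descent step of the transfer sub-network toward the relayed
## value prediction, under squared loss (nu - target)^2.
subnet_mse_update <- function(vnet, lr, target, u) {
  gr <- vnet_grad(vnet, u)
  err <- gr$V - target
  g <- gr$grads
  vnet$w2 <- vnet$w2 - lr * err * g$w2
  if (vnet$bias) vnet$b2 <- vnet$b2 - lr * err * g$b2
  if (!is.null(vnet$W1)) {
    vnet$W1 <- vnet$W1 - lr * err * g$W1
    if (vnet$bias) vnet$b1 <- vnet$b1 - lr * err * g$b1
  }
  vnet
}
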