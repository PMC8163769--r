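## Scalar potential models.
##
## The workhorse is a fully connected scalar-output network with two
## hidden softplus layers. Because the drift is the exact input gradient
## of the potential, and training differentiates a loss on simulated
## trajectories through that drift, we need (a) the analytic input
## gradient of psi and (b) vector-Jacobian products of the drift with
## respect to both inputs and parameters (second derivatives of psi).
## All three are hand-derived below and checked against finite
## differences in the test suite.

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Create a neural potential model
#'
#' Fully connected scalar-output network with two hidden layers and
#' softplus activations: Psi(x) = w3' sp(W2 sp(W1 x + b1) + b2) + b3.
#' The model also carries the fixed process constants of the diffusion it
#' parameterizes: noise scale `sigma`, step size `dt` and regularizer
#' strength `tau`.
#'
#' @param k state dimension.
#' @param hidden sizes of the two hidden layers (default c(400, 400)).
#' @param sigma noise scale of the diffusion (default 0.1).
#' @param dt simulation step size (default 0.1).
#' @param tau entropic regularizer strength (default 1e-6).
#' @param seed RNG seed for the parameter initialization.
#' @param init_scale multiplier on the 1/sqrt(fan-in) init (default 1).
#' @return object of class `potential_mlp`.
#' @export
potential_mlp <- function(k, hidden = c(400, 400), sigma = 0.1, dt = 0.1,
                          tau = 1e-6, seed = 1, init_scale = 1) {
  if (length(hidden) != 2) stop("exactly two hidden layers are supported")
  h1 <- hidden[1]; h2 <- hidden[2]
  params <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(h1 * k, sd = init_scale / sqrt(k)), h1, k),
    b1 = rep(0, h1),
    W2 = matrix(stats::rnorm(h2 * h1, sd = init_scale / sqrt(h1)), h2, h1),
    b2 = rep(0, h2),
    w3 = stats::rnorm(h2, sd = init_scale / sqrt(h2)),
    b3 = 0
  ))
  structure(list(params = params, k = k, hidden = hidden, sigma = sigma,
                 dt = dt, tau = tau, seed = seed),
            class = c("potential_mlp", "potential_model"))
}

#' Analytic potential (test harness / ground truth)
#'
#' Wraps closed-form potential and drift functions, e.g. the quadratic
#' Psi(x) = 0.5 ||x||^2 whose drift is -x, so simulation and evaluation
#' code paths can run against exactly known dynamics.
#'
#' @param psi_fn function(states matrix) -> numeric vector.
#' @param drift_fn function(states matrix) -> matrix of -grad Psi.
#' @param k state dimension.
#' @param sigma,dt process constants.
#' @return object of class `potential_analytic`.
#' @export
potential_analytic <- function(psi_fn, drift_fn, k, sigma = 0.1, dt = 0.1) {
  structure(list(psi_fn = psi_fn, drift_fn = drift_fn, k = k,
                 sigma = sigma, dt = dt, tau = 0),
            class = c("potential_analytic", "potential_model"))
}

#' Quadratic potential Psi(x) = 0.5 * sum(scale * (x - center)^2)
#' @param k state dimension.
#' @param center minimum location (scalar or length-k).
#' @param scale curvature (scalar or length-k).
#' @param sigma,dt process constants.
#' @return `potential_analytic` model.
#' @export
potential_quadratic <- function(k, center = 0, scale = 1,
                                sigma = 0.1, dt = 0.1) {
  center <- rep_len(center, k); scale <- rep_len(scale, k)
  potential_analytic(
    psi_fn = function(x) 0.5 * as.numeric(sweep(x, 2, center)^2 %*% scale),
    drift_fn = function(x) -sweep(sweep(x, 2, center), 2, scale, "*"),
    k = k, sigma = sigma, dt = dt)
}

#' Evaluate the potential at a batch of states
#' @param model a potential model.
#' @param states n x k matrix (or length-k vector).
#' @return numeric vector of n potential values.
#' @export
potential <- function(model, states) UseMethod("potential")

#' @export
potential.potential_mlp <- function(model, states) {
  states <- as_state_matrix(states, model$k)
  mlp_forward(model$params, states)$psi
}

#' @export
potential.potential_analytic <- function(model, states) {
  states <- as_state_matrix(states, model$k)
  model$psi_fn(states)
}

#' Evaluate the drift mu(x) = -grad Psi(x)
#' @param model a potential model.
#' @param states n x k matrix (or length-k vector).
#' @return n x k matrix of drift vectors.
#' @export
drift <- function(model, states) UseMethod("drift")

#' @export
drift.potential_mlp <- function(model, states) {
  states <- as_state_matrix(states, model$k)
  -mlp_input_grad(model$params, states)$G
}

#' @export
drift.potential_analytic <- function(model, states) {
  states <- as_state_matrix(states, model$k)
  model$drift_fn(states)
}

as_state_matrix <- function(states, k) {
  if (is.null(dim(states))) states <- matrix(states, ncol = k)
  states <- as.matrix(states)
  if (ncol(states) != k) stop("state dimension mismatch: expected k = ", k)
  states
}

## ---- forward / gradient internals (potential_mlp) ----

mlp_forward <- function(p, X) {
  A1 <- X %*% t(p$W1) + rep(p$b1, each = nrow(X))
  H1 <- softplus(A1)
  A2 <- H1 %*% t(p$W2) + rep(p$b2, each = nrow(X))
  H2 <- softplus(A2)
  psi <- as.numeric(H2 %*% p$w3) + p$b3
  list(psi = psi, A1 = A1, H1 = H1, A2 = A2, H2 = H2)
}

# Input gradient G[i, ] = d psi_i / d x_i, with the cache needed by the
# second-order reverse pass.
mlp_input_grad <- function(p, X, fw = NULL) {
  if (is.null(fw)) fw <- mlp_forward(p, X)
  Z1 <- sigmoid(fw$A1)
  Z2 <- sigmoid(fw$A2)
  S2 <- sweep(Z2, 2, p$w3, "*")      # d psi / d A2
  M <- S2 %*% p$W2                   # d psi / d H1
  S1 <- Z1 * M                       # d psi / d A1
  G <- S1 %*% p$W1                   # d psi / d X
  list(G = G, X = X, fw = fw, Z1 = Z1, Z2 = Z2, S2 = S2, M = M, S1 = S1)
}

# Gradient of sum_i c_i * psi_i with respect to parameters (first order).
mlp_param_grad <- function(p, X, c_weights, fw = NULL) {
  if (is.null(fw)) fw <- mlp_forward(p, X)
  Z1 <- sigmoid(fw$A1)
  Z2 <- sigmoid(fw$A2)
  H2bar <- outer(c_weights, p$w3)
  A2bar <- H2bar * Z2
  H1bar <- A2bar %*% p$W2
  A1bar <- H1bar * Z1
  list(W1 = t(A1bar) %*% X,
       b1 = colSums(A1bar),
       W2 = t(A2bar) %*% fw$H1,
       b2 = colSums(A2bar),
       w3 = as.numeric(t(fw$H2) %*% c_weights),
       b3 = sum(c_weights))
}

# Vector-Jacobian product of the input-gradient map. Given V = dL/dG
# (n x k) where G = grad_x psi, returns dL/dX and dL/dparams. These are
# second derivatives of psi; used to backpropagate through the drift.
mlp_grad_vjp <- function(p, cache, V) {
  X <- cache$X; Z1 <- cache$Z1; Z2 <- cache$Z2
  S1 <- cache$S1; S2 <- cache$S2; M <- cache$M
  H1 <- cache$fw$H1
  S1bar <- V %*% t(p$W1)
  W1g <- t(S1) %*% V                       # G = S1 W1 term
  Z1bar <- S1bar * M
  Mbar <- S1bar * Z1
  S2bar <- Mbar %*% t(p$W2)
  W2g <- t(S2) %*% Mbar                    # M = S2 W2 term
  Z2bar <- sweep(S2bar, 2, p$w3, "*")
  w3g <- colSums(S2bar * Z2)
  A2bar <- Z2bar * Z2 * (1 - Z2)
  H1bar <- A2bar %*% p$W2
  W2g <- W2g + t(A2bar) %*% H1
  b2g <- colSums(A2bar)
  A1bar <- H1bar * Z1 + Z1bar * Z1 * (1 - Z1)
  Xbar <- A1bar %*% p$W1
  W1g <- W1g + t(A1bar) %*% X
  b1g <- colSums(A1bar)
  list(X = Xbar,
       grads = list(W1 = W1g, b1 = b1g, W2 = W2g, b2 = b2g,
                    w3 = w3g, b3 = 0))
}

## ---- parameter vector utilities ----

flatten_params <- function(p) {
  c(as.numeric(p$W1), p$b1, as.numeric(p$W2), p$b2, p$w3, p$b3)
}

unflatten_params <- function(v, template) {
  out <- template
  pos <- 0
  for (nm in names(template)) {
    n <- length(template[[nm]])
    piece <- v[pos + seq_len(n)]
    out[[nm]] <- if (is.matrix(template[[nm]]))
      matrix(piece, nrow(template[[nm]]), ncol(template[[nm]])) else
        if (n == 1) piece else piece
    pos <- pos + n
  }
  out
}

zero_like_params <- function(p) lapply(p, function(x) x * 0)

add_params <- function(a, b, scale = 1) {
  for (nm in names(a)) a[[nm]] <- a[[nm]] + scale * b[[nm]]
  a
}

param_grad_norm <- function(g) sqrt(sum(vapply(g, function(x) sum(x^2), 0)))

clip_params_norm <- function(g, max_norm) {
  nrm <- param_grad_norm(g)
  if (is.finite(max_norm) && nrm > max_norm && nrm > 0)
    g <- lapply(g, function(x) x * (max_norm / nrm))
  g
}

## ---- checkpoint IO ----

#' Save / load a potential model checkpoint
#'
#' Checkpoints carry parameters, the architecture/process configuration
#' and training metadata, and reload to bit-identical parameters.
#'
#' @param model potential_mlp model.
#' @param file path (.rds).
#' @param meta optional list of training metadata (epoch, seed, losses).
#' @export
save_checkpoint <- function(model, file, meta = NULL) {
  stopifnot(inherits(model, "potential_mlp"))
  obj <- unclass(model)
  obj$checkpoint_meta <- meta
  dir.create(dirname(file), showWarnings = FALSE, recursive = TRUE)
  saveRDS(obj, file)
  invisible(file)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the model with a
#'   `checkpoint_meta` field.
#' @export
load_checkpoint <- function(file) {
  obj <- readRDS(file)
  structure(obj, class = c("potential_mlp", "potential_model"))
}
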