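# Minimal dense-network toolkit shared by the autoencoder, the VCDN fusion
# net and the transfer heads: LeakyReLU, Glorot-style init, Adam updates on
# a named list of parameter matrices, and input dropout. All matrices are
# samples x features.

#' Leaky rectified linear unit
#'
#' Identity for positive inputs, `slope * u` otherwise.
#'
#' @param u Numeric vector or matrix.
#' @param slope Negative-part slope `a` (default 0.1).
#' @return Object of the same shape as `u`.
#' @export
leaky_relu <- function(u, slope = 0.1) {
  ifelse(u > 0, u, slope * u)
}

# derivative wrt pre-activation; at exactly 0 use the negative-side slope
.leaky_relu_grad <- function(u, slope) {
  ifelse(u > 0, 1, slope)
}

# Glorot-uniform weight matrix plus zero bias
.init_dense <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

# Adam state mirrors the parameter list structure (list of matrices/vectors)
.adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

.adam_step <- function(state, params, grads, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# inverted dropout mask on a matrix (training only); rate 0 returns X as is
.dropout <- function(X, rate) {
  if (rate <= 0) return(X)
  keep <- matrix(rbinom(length(X), 1L, 1 - rate), nrow(X), ncol(X))
  X * keep / (1 - rate)
}

# add a bias row-wise; b recycled over rows
.affine <- function(X, W, b) {
  sweep(X %*% W, 2L, b, "+")
}

# numerically safe row-wise softmax
.softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# deterministic stage seed fan-out from a global seed; kept < 2^31
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}
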