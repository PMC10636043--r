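# Minimal dense neural-network machinery: two-layer perceptrons with
# LeakyReLU, manual backpropagation, and an Adam optimizer. No external
# framework is available in this environment, and the networks involved are
# small full-batch MLPs, so explicit matrix-calculus gradients are both
# sufficient and fast (every op is a BLAS-level matrix product).

LRELU_SLOPE <- 0.2
# lrelu(x) = a*x + b*|x| with a = (1+s)/2, b = (1-s)/2 -- branch-free form,
# much faster than logical subscripting on wide activation matrices
LRELU_A <- (1 + LRELU_SLOPE) / 2
LRELU_B <- (1 - LRELU_SLOPE) / 2

lrelu <- function(x) LRELU_A * x + LRELU_B * abs(x)

# derivative: a + b*sign(x)  (subgradient a at exactly 0)
lrelu_grad <- function(x) LRELU_A + LRELU_B * sign(x)

# add a bias row-vector to every row without sweep()'s aperm overhead
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Kaiming-uniform initialization, matching common practice for LeakyReLU nets.
mlp_init <- function(d_in, d_hidden, d_out) {
  lim1 <- sqrt(6 / d_in)
  lim2 <- sqrt(6 / d_hidden)
  list(
    W1 = matrix(stats::runif(d_in * d_hidden, -lim1, lim1), d_in, d_hidden),
    b1 = rep(0, d_hidden),
    W2 = matrix(stats::runif(d_hidden * d_out, -lim2, lim2), d_hidden, d_out),
    b2 = rep(0, d_out)
  )
}

# Forward pass; returns output plus cached pre-activations for backprop.
mlp_forward <- function(p, X) {
  H <- add_bias(X %*% p$W1, p$b1)
  A <- lrelu(H)
  Y <- add_bias(A %*% p$W2, p$b2)
  list(Y = Y, H = H, A = A, X = X)
}

# Backward pass given dL/dY; returns parameter gradients and (optionally)
# dL/dX. The input gradient is skipped for first-layer networks where it is
# never consumed (it is the single most expensive product for a wide net).
mlp_backward <- function(p, cache, dY, input_grad = TRUE) {
  dW2 <- crossprod(cache$A, dY)
  db2 <- colSums(dY)
  dH <- (dY %*% t(p$W2)) * lrelu_grad(cache$H)
  dW1 <- crossprod(cache$X, dH)
  db1 <- colSums(dH)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
       dX = if (input_grad) dH %*% t(p$W1) else NULL)
}

adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))
  list(m = lapply(params, zero_like), v = lapply(params, zero_like),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

# One Adam step along -grads (i.e. descent on the loss whose gradient is
# `grads`); to ascend, pass the negated gradients.
adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g^2
    params[[k]] <- params[[k]] -
      state$lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + state$eps)
  }
  list(params = params, state = state)
}

clip_params <- function(params, bound) {
  lapply(params, function(x) pmin(pmax(x, -bound), bound))
}
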