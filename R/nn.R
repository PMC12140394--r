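# Minimal multilayer-perceptron engine with hand-written reverse-mode
# gradients. All networks in this package are small (tens of units), so a
# dense, batched, BLAS-backed implementation is both simple and fast enough.
# Layers are fully connected; hidden activations are tanh (smooth, so the
# filtering error is differentiable end-to-end); the output layer is linear.

#' Initialise a fully connected network
#'
#' @param sizes integer vector of layer widths, input first, output last,
#'   e.g. `c(2, 32, 32, 1)`. A length-2 vector gives a single linear layer.
#' @param scale multiplier on the Xavier/Glorot initial weight scale.
#' @return an object of class `idras_mlp`: lists of weight matrices `W`
#'   (in-dim x out-dim) and bias vectors `b`.
#' @keywords internal
mlp_init <- function(sizes, scale = 1) {
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  nl <- length(sizes) - 1L
  W <- vector("list", nl)
  b <- vector("list", nl)
  for (l in seq_len(nl)) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1L]
    sd <- scale * sqrt(2 / (fan_in + fan_out))
    W[[l]] <- matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out)
    b[[l]] <- rep(0, fan_out)
  }
  structure(list(W = W, b = b, sizes = as.integer(sizes)), class = "idras_mlp")
}

# Forward pass for a batch X (B x d_in). Returns the linear output (B x d_out)
# plus the per-layer activations needed for the backward pass.
mlp_forward <- function(net, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$sizes[1L])
    stop("input has ", ncol(X), " columns but the network expects ",
         net$sizes[1L], call. = FALSE)
  nl <- length(net$W)
  hs <- vector("list", nl + 1L)
  hs[[1L]] <- X
  H <- X
  for (l in seq_len(nl)) {
    H <- H %*% net$W[[l]]
    H <- H + rep(net$b[[l]], each = nrow(H))
    if (l < nl) H <- tanh(H)
    hs[[l + 1L]] <- H
  }
  list(out = H, hs = hs)
}

# Backward pass: dOut is dLoss/d(output) (B x d_out). Returns parameter
# gradients (same shapes as W, b) and dLoss/d(input) (B x d_in).
# Uses tanh'(x) = 1 - tanh(x)^2 evaluated from the stored activations.
mlp_backward <- function(net, fwd, dOut) {
  nl <- length(net$W)
  dW <- vector("list", nl)
  db <- vector("list", nl)
  delta <- dOut
  for (l in rev(seq_len(nl))) {
    Hprev <- fwd$hs[[l]]
    dW[[l]] <- crossprod(Hprev, delta)
    db[[l]] <- colSums(delta)
    dH <- tcrossprod(delta, net$W[[l]])
    if (l > 1L) delta <- dH * (1 - Hprev * Hprev)
  }
  list(W = dW, b = db, dX = dH)
}

# ---- generic nested-list parameter algebra -------------------------------

# Apply a binary function elementwise over two parallel nested numeric
# structures (used for gradient accumulation and optimiser updates).
par_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- par_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

par_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- par_map(a[[i]], f)
    out
  } else {
    f(a)
  }
}

par_zeros_like <- function(a) par_map(a, function(x) x * 0)

# Flatten a nested numeric structure into one vector (fixed traversal order).
par_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, par_flatten), use.names = FALSE) else as.numeric(a)
}

# Write a flat vector back into the shape of `a`.
par_unflatten <- function(a, v) {
  if (is.list(a)) {
    out <- a
    pos <- 1L
    for (i in seq_along(a)) {
      ni <- length(par_flatten(a[[i]]))
      out[[i]] <- par_unflatten(a[[i]], v[pos:(pos + ni - 1L)])
      pos <- pos + ni
    }
    out
  } else {
    x <- a
    x[] <- v
    x
  }
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = par_zeros_like(params), v = par_zeros_like(params), t = 0L)
}

# One Adam update. Returns list(params, state).
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- par_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- par_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- par_map(state$m, function(m) m / bc1)
  vh <- par_map(state$v, function(v) v / bc2)
  upd <- par_map2(mh, vh, function(m, v) lr * m / (sqrt(v) + eps))
  params <- par_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
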