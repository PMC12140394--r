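# The learned functions: the combination g(z; theta) mapping an observation
# vector to the scalar regulated quantity c, and the one-step prediction
# filter F(c^{k-T..k-1}; Theta) with encoder / latent drift / decoder
# structure. The filtering error of a window is
#
#   e^k = g(z^k; theta) - F(g(z^{k-T}), ..., g(z^{k-1}); Theta)
#
# and is differentiable end-to-end: the history fed to the filter is
# recomputed from the current theta at every evaluation, so gradients flow
# into theta both directly (through c^k) and through the filter input.

#' Initialise a model state
#'
#' Builds the parameter container for the combination and the filter.
#' Default architectures: `g` is an MLP with two tanh hidden layers of
#' `g_width` units; the encoder maps the length-`T` history to a `b_y`-dim
#' latent state through two hidden layers; the drift is a one-hidden-layer
#' MLP on the latent state; the decoder is linear. In `static_mode` the
#' filter is identically zero, which reduces the dynamic problem to the
#' fixed-set-point one (the error then equals the combination value itself).
#'
#' @param n number of observation channels.
#' @param T history length in samples.
#' @param b_y latent state dimension of the filter.
#' @param dt sampling interval used when integrating the latent drift.
#' @param g_width,enc_width,drift_width hidden-layer widths.
#' @param static_mode if `TRUE` the filter F is identically 0.
#' @param integrator `"euler"` (one explicit step over dt) or `"rk4"`.
#' @return an object of class `model_state` holding `g`, `enc`, `drift`,
#'   `dec` networks and the structural hyper-parameters.
#' @export
model_state <- function(n, T, b_y = 3L, dt = 1, g_width = 32L,
                        enc_width = 32L, drift_width = 32L,
                        static_mode = FALSE, integrator = c("euler", "rk4")) {
  integrator <- match.arg(integrator)
  stopifnot(n >= 1, T >= 1, b_y >= 1)
  structure(list(
    g     = mlp_init(c(n, g_width, g_width, 1L)),
    enc   = mlp_init(c(T, enc_width, enc_width, b_y)),
    drift = mlp_init(c(b_y, drift_width, b_y), scale = 0.5),
    dec   = mlp_init(c(b_y, 1L)),
    n = as.integer(n), T = as.integer(T), b_y = as.integer(b_y),
    dt = as.numeric(dt), static_mode = isTRUE(static_mode),
    integrator = integrator
  ), class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  np <- length(par_flatten(model_params(x)))
  cat("<model_state> n = ", x$n, ", T = ", x$T, ", b_y = ", x$b_y,
      ", ", np, " parameters",
      if (x$static_mode) " [static mode: F == 0]", "\n", sep = "")
  invisible(x)
}

# Trainable parameter block (theta = g; Theta = enc, drift, dec).
model_params <- function(model) {
  list(g = model$g[c("W", "b")], enc = model$enc[c("W", "b")],
       drift = model$drift[c("W", "b")], dec = model$dec[c("W", "b")])
}

model_set_params <- function(model, params) {
  for (nm in c("g", "enc", "drift", "dec")) {
    model[[nm]]$W <- params[[nm]]$W
    model[[nm]]$b <- params[[nm]]$b
  }
  model
}

#' Apply the learned combination to observations
#'
#' @param model a [model_state()].
#' @param z an `n`-vector or a `B x n` matrix of observations.
#' @return scalar (or length-`B` vector) of combination values c = g(z).
#' @export
combination_apply <- function(model, z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$n)
    stop("observation has ", ncol(z), " channels; the combination expects ",
         model$n, call. = FALSE)
  drop(mlp_forward(model$g, z)$out)
}

# Advance a batch of latent states by one sampling interval under the drift.
# Returns the advanced state and the caches needed for the backward pass.
drift_advance <- function(model, Y, dt) {
  if (model$integrator == "euler") {
    f1 <- mlp_forward(model$drift, Y)
    list(Y = Y + dt * f1$out, caches = list(f1), scheme = "euler")
  } else {
    f1 <- mlp_forward(model$drift, Y)
    f2 <- mlp_forward(model$drift, Y + dt / 2 * f1$out)
    f3 <- mlp_forward(model$drift, Y + dt / 2 * f2$out)
    f4 <- mlp_forward(model$drift, Y + dt * f3$out)
    Yn <- Y + dt / 6 * (f1$out + 2 * f2$out + 2 * f3$out + f4$out)
    list(Y = Yn, caches = list(f1, f2, f3, f4), scheme = "rk4")
  }
}

# Backward through drift_advance: given dL/dY_next, returns dL/dY and drift
# parameter gradients.
drift_advance_backward <- function(model, adv, dY_next, dt) {
  if (adv$scheme == "euler") {
    bk <- mlp_backward(model$drift, adv$caches[[1L]], dt * dY_next)
    list(dY = dY_next + bk$dX, grads = bk[c("W", "b")])
  } else {
    f <- adv$caches
    g4 <- mlp_backward(model$drift, f[[4L]], dt / 6 * dY_next)
    d3 <- dt / 6 * 2 * dY_next + dt * g4$dX
    g3 <- mlp_backward(model$drift, f[[3L]], d3)
    d2 <- dt / 6 * 2 * dY_next + dt / 2 * g3$dX
    g2 <- mlp_backward(model$drift, f[[2L]], d2)
    d1 <- dt / 6 * dY_next + dt / 2 * g2$dX
    g1 <- mlp_backward(model$drift, f[[1L]], d1)
    grads <- Reduce(function(a, b) par_map2(a, b, `+`),
                    list(g1[c("W", "b")], g2[c("W", "b")],
                         g3[c("W", "b")], g4[c("W", "b")]))
    list(dY = dY_next + g1$dX + g2$dX + g3$dX + g4$dX, grads = grads)
  }
}

#' One-step prediction from a history of combination values
#'
#' Encodes the length-`T` history into a latent state, advances the state by
#' one sampling interval under the learned drift, and decodes the predicted
#' next combination value. In static mode the prediction is exactly 0.
#'
#' @param model a [model_state()].
#' @param c_hist numeric vector of length `T` (oldest first) or a `B x T`
#'   matrix of histories.
#' @param dt integration interval; defaults to the model's `dt`.
#' @return scalar (or length-`B` vector) prediction c-hat.
#' @export
filter_predict <- function(model, c_hist, dt = model$dt) {
  if (!is.matrix(c_hist)) c_hist <- matrix(c_hist, nrow = 1L)
  if (ncol(c_hist) != model$T)
    stop("history has length ", ncol(c_hist), " but the filter expects T = ",
         model$T, call. = FALSE)
  if (model$static_mode) return(rep(0, nrow(c_hist)))
  y_plus <- mlp_forward(model$enc, c_hist)$out
  y_minus <- drift_advance(model, y_plus, dt)$Y
  drop(mlp_forward(model$dec, y_minus)$out)
}

#' Filtering error of observation windows
#'
#' For each length-`T+1` window the error is the combination value at the
#' final sample minus the filter's one-step prediction from the combination
#' values over the preceding `T` samples. In static mode the error is the
#' final combination value itself.
#'
#' @param model a [model_state()].
#' @param windows a `window_ensemble` (from [build_windows()]), a
#'   `surrogate_ensemble`, a `B x (T+1) x n` array, or a single `(T+1) x n`
#'   matrix.
#' @return numeric vector of filtering errors, one per window.
#' @export
filtering_error <- function(model, windows) {
  Z <- if (inherits(windows, c("window_ensemble", "surrogate_ensemble")))
         windows$Z
       else if (is.matrix(windows)) array(windows, dim = c(1L, dim(windows)))
       else if (is.array(windows) && length(dim(windows)) == 3L) windows
       else stop("windows must be a window_ensemble, a (T+1) x n matrix, ",
                 "or a B x (T+1) x n array", call. = FALSE)
  if (dim(Z)[2L] != model$T + 1L)
    stop("windows have length ", dim(Z)[2L], " but the model expects T + 1 = ",
         model$T + 1L, call. = FALSE)
  errors_forward(model, Z, gauge = gauge_identity())$e
}

# ---- batched training-path forward / backward ----------------------------

# The combination output is gauge-fixed (standardised) before entering the
# loss: the variance ratio is scale invariant, so the gauge only pins the
# scale of c for stable optimisation and reporting. The gauge statistics are
# treated as constants of the evaluation (no gradient flows through them).
gauge_identity <- function() list(m = 0, s = 1)

gauge_from_c <- function(cvals) {
  m <- mean(cvals)
  s <- sqrt(mean((cvals - m)^2))
  if (!is.finite(s) || s < 1e-12) s <- 1e-12
  list(m = m, s = s)
}

# Forward over a window array Z (B x (T+1) x n). If gauge is NULL it is
# computed from this batch's combination values. Returns errors, the gauge,
# and all caches required by errors_backward.
errors_forward <- function(model, Z, gauge = NULL) {
  d <- dim(Z)
  B <- d[1L]; Tp1 <- d[2L]
  gf <- mlp_forward(model$g, flatten_windows(Z))
  cmat <- matrix(gf$out, B, Tp1)
  if (is.null(gauge)) gauge <- gauge_from_c(cmat)
  cstd <- (cmat - gauge$m) / gauge$s
  if (model$static_mode) {
    e <- cstd[, Tp1]
    return(list(e = e, gauge = gauge,
                cache = list(gf = gf, B = B, Tp1 = Tp1)))
  }
  ef <- mlp_forward(model$enc, cstd[, seq_len(Tp1 - 1L), drop = FALSE])
  adv <- drift_advance(model, ef$out, model$dt)
  df <- mlp_forward(model$dec, adv$Y)
  e <- cstd[, Tp1] - drop(df$out)
  list(e = e, gauge = gauge,
       cache = list(gf = gf, ef = ef, adv = adv, df = df, B = B, Tp1 = Tp1))
}

# Backward: de is dLoss/d(e) per window. Returns parameter gradients in
# model_params() shape.
errors_backward <- function(model, fwd, de) {
  ca <- fwd$cache
  B <- ca$B; Tp1 <- ca$Tp1
  s <- fwd$gauge$s
  d_cstd <- matrix(0, B, Tp1)
  d_cstd[, Tp1] <- de
  grads <- list()
  if (!model$static_mode) {
    bdec <- mlp_backward(model$dec, ca$df, matrix(-de, ncol = 1L))
    grads$dec <- bdec[c("W", "b")]
    badv <- drift_advance_backward(model, ca$adv, bdec$dX, model$dt)
    grads$drift <- badv$grads
    benc <- mlp_backward(model$enc, ca$ef, badv$dY)
    grads$enc <- benc[c("W", "b")]
    d_cstd[, seq_len(Tp1 - 1L)] <- d_cstd[, seq_len(Tp1 - 1L)] + benc$dX
  } else {
    grads$dec <- par_zeros_like(model$dec[c("W", "b")])
    grads$drift <- par_zeros_like(model$drift[c("W", "b")])
    grads$enc <- par_zeros_like(model$enc[c("W", "b")])
  }
  d_cflat <- matrix(as.numeric(d_cstd) / s, ncol = 1L)
  bg <- mlp_backward(model$g, ca$gf, d_cflat)
  grads$g <- bg[c("W", "b")]
  grads[c("g", "enc", "drift", "dec")]
}

# ---- checkpoints ---------------------------------------------------------

#' Save / load a fitted model state
#'
#' The checkpoint is a single serialized archive holding the named parameter
#' arrays together with the structural configuration (architecture sizes, T,
#' b_y, dt, static flag, integrator).
#'
#' @param model a [model_state()].
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "model_state"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "model_state")) stop("not a model checkpoint", call. = FALSE)
  m
}
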