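# Shared fixtures: tiny time-series generators and hand-rigged models whose
# networks realise known linear maps (so expected values can be computed by
# hand). All fixtures are built in code at test time.

# A ts_set with the given per-series lengths and iid N(0,1) channels.
toy_ts <- function(lengths = c(10L, 7L), n = 2L, dt = 1, seed = 1L) {
  set.seed(seed)
  ts_set(lapply(lengths, function(N) matrix(rnorm(N * n), N, n)), dt = dt)
}

# Zero a network's parameters.
zero_net <- function(net) {
  net$W <- lapply(net$W, function(w) w * 0)
  net$b <- lapply(net$b, function(b) b * 0)
  net
}

# Rig an MLP so that, to O(eps^2), output `out_coord` equals
# gain * input[in_coord]: the input is scaled down by eps so every tanh
# operates in its linear region (later layers pass the already-small value
# through with unit weight), and the linear output layer scales back by
# 1/eps.
rig_linear_path <- function(net, in_coord, out_coord = 1L, gain = 1,
                            eps = 1e-6) {
  net <- zero_net(net)
  nl <- length(net$W)
  net$W[[1L]][in_coord, 1L] <- eps
  if (nl >= 3L) for (l in 2L:(nl - 1L)) net$W[[l]][1L, 1L] <- 1
  net$W[[nl]][1L, out_coord] <- gain / eps
  net
}

# A model whose combination is (approximately) z[, channel] and whose filter
# is the persistence predictor c-hat = c^{k-1} (zero drift). With
# persistence = FALSE the filter decodes 0.
rigged_model <- function(n = 1L, T = 1L, b_y = 2L, channel = 1L,
                         persistence = TRUE, dt = 1, eps = 1e-6) {
  m <- model_state(n = n, T = T, b_y = b_y, dt = dt)
  m$g <- rig_linear_path(m$g, channel, eps = eps)
  m$enc <- if (persistence) rig_linear_path(m$enc, T, eps = eps)
           else zero_net(m$enc)
  m$drift <- zero_net(m$drift)
  m$dec <- zero_net(m$dec)
  if (persistence) m$dec$W[[1L]][1L, 1L] <- 1
  m
}

# Windows as a plain array from per-series matrices (independent of
# build_windows, for cross-checking).
manual_windows <- function(S, T) {
  ks <- (T + 1L):nrow(S)
  Z <- array(NA_real_, dim = c(length(ks), T + 1L, ncol(S)))
  for (i in seq_along(ks)) Z[i, , ] <- S[(ks[i] - T):ks[i], , drop = FALSE]
  Z
}

# Critical value of the two-sample KS statistic at level alpha.
ks_crit <- function(n1, n2, alpha = 0.01) {
  sqrt(-log(alpha / 2) / 2) * sqrt((n1 + n2) / (n1 * n2))
}
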