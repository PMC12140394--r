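# Ground-truth generative models. Every model has a known regulated
# combination and a known dynamic reference, so a fit can be scored exactly.
#
# 1. Kinetic gene expression: mRNA M drives production of two proteins P and
#    S whose sum feeds back on transcription; the transcription rate K(t)
#    oscillates slowly, so P + S tracks a slowly oscillating set-point.
# 2. Bacterial growth-division: cells grow exponentially and divide when
#    size crosses a stochastic Ornstein-Uhlenbeck threshold (a "sizer" with
#    a slowly drifting target).
# 3. A two-objective toy with two independent regulated combinations.

# ---- kinetic gene-expression model ---------------------------------------

#' Parameters of the kinetic gene-expression simulator
#'
#' Defaults are a strong-feedback, slow-modulation regime: kinetic rates of
#' order one per time unit (think minutes), a transcription-rate oscillation
#' `tau_K` one hundred times slower than the kinetic relaxation, feedback
#' `f` ten times the degradation rates, and weak intrinsic noise. In this
#' regime the sum P + S tightly tracks the moving set-point.
#'
#' @param K0 baseline transcription rate; `K(t)` oscillates in
#'   `[0.5 K0, 1.5 K0]`.
#' @param tau_K oscillation period of the transcription rate.
#' @param phi_K oscillation phase; if `random_phase` is `TRUE` each series
#'   draws its own phase uniformly and `phi_K` is ignored.
#' @param f feedback rate constant coupling P + S back to transcription.
#' @param gamma_M,gamma_P,gamma_S degradation rates.
#' @param k_P,k_S production rates of the two proteins.
#' @param eta_P,eta_S diffusion (noise) amplitudes of the protein dynamics.
#' @param t_s observation sampling interval.
#' @param sim_dt Euler-Maruyama integration step (must be < `t_s`).
#' @param n_steps observations recorded per series.
#' @param n_series number of independent series.
#' @param burn_in time discarded before the first observation.
#' @param random_phase draw an independent phase per series.
#' @return a list of class `kinetic_params`.
#' @export
kinetic_params <- function(K0 = 30, tau_K = 200, phi_K = 0, f = 10,
                           gamma_M = 1, gamma_P = 1, gamma_S = 1,
                           k_P = 1, k_S = 1, eta_P = 0.1, eta_S = 0.1,
                           t_s = 2, sim_dt = 0.02, n_steps = 500L,
                           n_series = 20L, burn_in = 10, random_phase = TRUE) {
  p <- as.list(environment())
  rates <- c(gamma_M, gamma_P, gamma_S, k_P, k_S, f, K0)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (tau_K <= 0) stop("tau_K must be > 0", call. = FALSE)
  if (sim_dt >= t_s) stop("sim_dt must be smaller than t_s", call. = FALSE)
  class(p) <- "kinetic_params"
  p
}

# TRUE when the modulation is much slower than every kinetic relaxation
# time, the regime in which P + S tracks the set-point tightly.
is_timescale_separated <- function(params, factor = 20) {
  kin_ts <- 1 / min(params$gamma_M, params$gamma_P, params$gamma_S)
  params$tau_K >= factor * kin_ts
}

#' Oscillating transcription rate
#'
#' `K(t) = K0 * (1 + 0.5 * cos(2 * pi * t / tau_K + phi_K))`.
#'
#' @param t time (vectorised).
#' @param params a [kinetic_params()].
#' @param phi_K phase override (defaults to `params$phi_K`).
#' @return transcription rate, in `[0.5 K0, 1.5 K0]`.
#' @export
kinetic_rate_K <- function(t, params, phi_K = params$phi_K) {
  params$K0 * (1 + 0.5 * cos(2 * pi * t / params$tau_K + phi_K))
}

#' Quasi-static set-point of the kinetic model
#'
#' Under timescale separation the feedback holds P + S near
#' `K(t) / (f + gamma_M * gamma_P * gamma_S / (k_P * gamma_S + k_S * gamma_P))`,
#' the noiseless steady state of the kinetics at frozen K. The denominator
#' term equals `gamma_M / A` with `A = k_P / gamma_P + k_S / gamma_S`.
#'
#' @inheritParams kinetic_rate_K
#' @return the reference value c*(t).
#' @export
kinetic_setpoint <- function(t, params, phi_K = params$phi_K) {
  denom <- params$f + params$gamma_M * params$gamma_P * params$gamma_S /
    (params$k_P * params$gamma_S + params$k_S * params$gamma_P)
  if (denom <= 0) stop("set-point denominator must be positive", call. = FALSE)
  kinetic_rate_K(t, params, phi_K) / denom
}

# Noiseless steady state (M, P, S) at a frozen transcription rate K.
kinetic_steady_state <- function(K, params) {
  A <- params$k_P / params$gamma_P + params$k_S / params$gamma_S
  M <- K / (params$f * A + params$gamma_M)
  c(M = M, P = params$k_P * M / params$gamma_P,
    S = params$k_S * M / params$gamma_S)
}

#' Simulate the regulated gene-expression model
#'
#' Euler-Maruyama integration of the M/P/S kinetics with oscillating
#' transcription rate, observed as `z = [P, S]` every `t_s` time units.
#' Concentrations are clipped at zero. Each series starts from the
#' noiseless steady state of its initial transcription rate.
#'
#' @param params a [kinetic_params()].
#' @param seed integer seed; the simulation is deterministic given it.
#' @return list with `ts` (a [ts_set()] with channels `P`, `S`, one series
#'   per simulated trajectory, `dt = t_s`) and `truth` (tibble of
#'   `series_id`, `time_index`, transcription rate `K`, set-point `c_star`,
#'   and the realised regulated sum `P_plus_S`).
#' @export
simulate_kinetic <- function(params = kinetic_params(), seed = 1L) {
  stopifnot(inherits(params, "kinetic_params"))
  set.seed(seed)
  M <- params$n_series
  phis <- if (params$random_phase) stats::runif(M, 0, 2 * pi)
          else rep(params$phi_K, M)
  K0vals <- kinetic_rate_K(0, params, phis)
  st <- vapply(K0vals, kinetic_steady_state, numeric(3L), params = params)
  Mv <- st["M", ]; Pv <- st["P", ]; Sv <- st["S", ]
  sub <- max(1L, round(params$t_s / params$sim_dt))
  dt <- params$t_s / sub                       # exact observation spacing
  n_burn <- ceiling(params$burn_in / dt)
  n_tot <- n_burn + (params$n_steps - 1L) * sub + 1L
  sqdt <- sqrt(dt)
  P_obs <- matrix(NA_real_, params$n_steps, M)
  S_obs <- matrix(NA_real_, params$n_steps, M)
  t_obs <- numeric(params$n_steps)
  obs_i <- 0L
  for (i in seq_len(n_tot)) {
    t <- (i - 1L) * dt
    if (i > n_burn && ((i - n_burn - 1L) %% sub == 0L)) {
      obs_i <- obs_i + 1L
      P_obs[obs_i, ] <- Pv
      S_obs[obs_i, ] <- Sv
      t_obs[obs_i] <- t
    }
    K <- kinetic_rate_K(t, params, phis)
    dM <- (K - params$f * (Pv + Sv) - params$gamma_M * Mv) * dt
    dP <- (params$k_P * Mv - params$gamma_P * Pv) * dt +
      params$eta_P * sqdt * stats::rnorm(M)
    dS <- (params$k_S * Mv - params$gamma_S * Sv) * dt +
      params$eta_S * sqdt * stats::rnorm(M)
    Mv <- Mv + dM
    Pv <- Pv + dP
    Sv <- Sv + dS
    if (any(!is.finite(c(Mv, Pv, Sv))) ||
        max(abs(Mv), abs(Pv), abs(Sv)) > 1e30)
      stop("kinetic integration diverged; use a smaller sim_dt",
           call. = FALSE)
    Mv <- pmax(Mv, 0)
    Pv <- pmax(Pv, 0)
    Sv <- pmax(Sv, 0)
  }
  sids <- sprintf("series_%02d", seq_len(M))
  series <- lapply(seq_len(M), function(m) {
    cbind(P = P_obs[, m], S = S_obs[, m])
  })
  names(series) <- sids
  ts <- ts_set(series, dt = params$t_s, channel_names = c("P", "S"))
  truth <- purrr::map_dfr(seq_len(M), function(m) {
    tibble::tibble(series_id = sids[m],
                   time_index = seq_len(params$n_steps) - 1L,
                   K = kinetic_rate_K(t_obs, params, phis[m]),
                   c_star = kinetic_setpoint(t_obs, params, phis[m]),
                   P_plus_S = P_obs[, m] + S_obs[, m])
  })
  list(ts = ts, truth = truth, params = params)
}

# ---- bacterial growth-division model -------------------------------------

#' Parameters of the bacterial growth-division simulator
#'
#' Cell size grows exponentially at a per-cycle rate drawn from a Gamma
#' distribution and division fires when size crosses a mean-reverting
#' Ornstein-Uhlenbeck threshold. Two presets set the threshold timescale
#' relative to the mean cycle duration `T_bar = log(2) / (shape * scale)`:
#' `"slow_threshold"` uses `tau_u = 10 * T_bar` (threshold nearly frozen
#' within a cycle), and `"nmse_quarter"` uses the `tau_u` at which the
#' analytic one-step prediction floor `1 - exp(-2 * T_bar / tau_u)` equals
#' exactly 0.25.
#'
#' @param preset `"slow_threshold"` or `"nmse_quarter"`.
#' @param mu_u,sigma_u,tau_u mean, stationary s.d. and timescale of the
#'   threshold process (a `tau_u` given explicitly overrides the preset).
#' @param gamma_shape,gamma_scale Gamma parameters of the growth rate.
#' @param sigma_eta s.d. of the division fraction around 0.5 (must be
#'   < 0.25 so divisions stay near-symmetric).
#' @param fixed_alpha if non-`NULL`, every cycle uses this growth rate
#'   instead of a Gamma draw (degenerate, deterministic-growth case).
#' @param n_lineages,n_cycles lineages and growth-division cycles per
#'   lineage.
#' @param grid_frac threshold grid step as a fraction of `tau_u`.
#' @return a list of class `cell_cycle_params` (includes the derived
#'   `T_bar`).
#' @export
cell_cycle_params <- function(preset = c("slow_threshold", "nmse_quarter"),
                              mu_u = 1, sigma_u = 0.1, tau_u = NULL,
                              gamma_shape = 100, gamma_scale = 0.01,
                              sigma_eta = 0.02, n_lineages = 30L,
                              n_cycles = 100L, grid_frac = 1e-3,
                              fixed_alpha = NULL) {
  preset <- match.arg(preset)
  stopifnot(mu_u > 0, sigma_u >= 0, gamma_shape > 0, gamma_scale > 0,
            sigma_eta >= 0, sigma_eta < 0.25)
  T_bar <- log(2) / (gamma_shape * gamma_scale)
  if (is.null(tau_u)) {
    tau_u <- switch(preset,
      slow_threshold = 10 * T_bar,
      nmse_quarter   = 2 * T_bar / (-log(0.75)))
  }
  stopifnot(tau_u > 0)
  p <- list(preset = preset, mu_u = mu_u, sigma_u = sigma_u, tau_u = tau_u,
            gamma_shape = gamma_shape, gamma_scale = gamma_scale,
            sigma_eta = sigma_eta, n_lineages = as.integer(n_lineages),
            n_cycles = as.integer(n_cycles), grid_frac = grid_frac,
            fixed_alpha = fixed_alpha, T_bar = T_bar)
  class(p) <- "cell_cycle_params"
  p
}

#' Exact Ornstein-Uhlenbeck transition
#'
#' Advances the threshold by `dt` using the exact conditional Gaussian:
#' mean `mu_u + (u - mu_u) * exp(-dt / tau_u)`, variance
#' `sigma_u^2 * (1 - exp(-2 * dt / tau_u))`. Vectorised over `u`.
#'
#' @param u current value(s).
#' @param dt time increment (>= 0).
#' @param mu_u,sigma_u,tau_u process mean, stationary s.d., timescale.
#' @return updated value(s).
#' @export
ou_step <- function(u, dt, mu_u, sigma_u, tau_u) {
  if (dt < 0) stop("dt must be >= 0", call. = FALSE)
  if (dt == 0) return(u)
  ef <- exp(-dt / tau_u)
  sd <- sigma_u * sqrt(1 - ef^2)
  mu_u + (u - mu_u) * ef + sd * stats::rnorm(length(u))
}

#' Simulate bacterial lineages with an Ornstein-Uhlenbeck size threshold
#'
#' Per cycle: draw a growth rate from the Gamma distribution and a division
#' fraction from `N(0.5, sigma_eta^2)`; grow exponentially from the birth
#' size while the threshold evolves on a fine grid (exact OU transitions,
#' reflected at zero so the threshold stays positive); divide at the first
#' crossing of size and threshold, refined by bisection between grid points
#' (threshold linearly interpolated) to relative tolerance 1e-8 on the
#' division time. The initial division size is drawn from the threshold's
#' stationary law. Observables per cycle are `[x_b, alpha, T]` - birth
#' size, growth rate and cycle duration - deliberately excluding the
#' division size itself.
#'
#' @param params a [cell_cycle_params()].
#' @param seed integer seed.
#' @param keep_tracks if `TRUE`, also return the full threshold/size tracks
#'   of each lineage (for plotting).
#' @return list with `records` (tibble of `lineage_id`, `cycle`, `x_b`,
#'   `alpha`, `T`, `x_d`, `u_at_division`, `t_b`, `t_d`), `ts` (a
#'   [ts_set()] with channels `x_b`, `alpha`, `T`, one series per lineage,
#'   `dt = 1` cycle), `params`, and optionally `tracks`.
#' @export
simulate_lineages <- function(params = cell_cycle_params(), seed = 1L,
                              keep_tracks = FALSE) {
  stopifnot(inherits(params, "cell_cycle_params"))
  set.seed(seed)
  h <- params$grid_frac * params$tau_u        # threshold grid step
  max_T <- 200 * params$T_bar                 # crossing guard per cycle
  recs <- vector("list", params$n_lineages)
  tracks <- if (keep_tracks) vector("list", params$n_lineages) else NULL
  for (ln in seq_len(params$n_lineages)) {
    x_d_prev <- params$mu_u + params$sigma_u * stats::rnorm(1L)
    x_d_prev <- abs(x_d_prev)
    u <- params$mu_u + params$sigma_u * stats::rnorm(1L)  # stationary start
    u <- abs(u)
    t_now <- 0
    K <- params$n_cycles
    x_b <- alpha <- Tk <- x_d <- u_d <- t_b <- t_d <- etas <- numeric(K)
    tr_t <- tr_u <- tr_x <- if (keep_tracks) list() else NULL
    for (k in seq_len(K)) {
      eta <- 0.5 + params$sigma_eta * stats::rnorm(1L)
      xb <- x_d_prev * eta
      a <- params$fixed_alpha %||%
        stats::rgamma(1L, shape = params$gamma_shape,
                      scale = params$gamma_scale)
      tb <- t_now
      # march the threshold forward until the exponential crosses it
      t_rel <- 0
      u_prev <- u
      x_prev <- xb
      crossed <- xb >= u
      cross_lo <- 0; cross_hi <- 0
      while (!crossed) {
        if (t_rel > max_T)
          stop("no size-threshold crossing within ", max_T,
               " time units; parameterisation looks pathological",
               call. = FALSE)
        u_next <- abs(ou_step(u_prev, h, params$mu_u, params$sigma_u,
                              params$tau_u))
        t_next <- t_rel + h
        x_next <- xb * exp(a * t_next)
        if (keep_tracks) {
          tr_t[[length(tr_t) + 1L]] <- tb + t_next
          tr_u[[length(tr_u) + 1L]] <- u_next
          tr_x[[length(tr_x) + 1L]] <- x_next
        }
        if (x_next >= u_next) {
          crossed <- TRUE
          cross_lo <- t_rel; cross_hi <- t_next
          # bisection: exponential size vs linearly interpolated threshold
          u_lo <- u_prev; u_hi <- u_next
          for (it in seq_len(60L)) {
            mid <- (cross_lo + cross_hi) / 2
            u_mid <- u_lo + (u_hi - u_lo) * (mid - cross_lo) /
              max(cross_hi - cross_lo, .Machine$double.xmin)
            if (xb * exp(a * mid) >= u_mid) {
              cross_hi <- mid; u_hi <- u_mid
            } else {
              cross_lo <- mid; u_lo <- u_mid
            }
            if ((cross_hi - cross_lo) <= 1e-8 * max(cross_hi, h)) break
          }
          t_rel <- cross_hi
          u_prev <- u_hi
        } else {
          t_rel <- t_next
          u_prev <- u_next
          x_prev <- x_next
        }
      }
      Td <- t_rel
      x_div <- xb * exp(a * Td)
      x_b[k] <- xb; alpha[k] <- a; Tk[k] <- Td; x_d[k] <- x_div
      u_d[k] <- u_prev; t_b[k] <- tb; t_d[k] <- tb + Td; etas[k] <- eta
      x_d_prev <- x_div
      u <- u_prev
      t_now <- tb + Td
    }
    recs[[ln]] <- tibble::tibble(
      lineage_id = sprintf("lineage_%02d", ln), cycle = seq_len(K),
      x_b = x_b, alpha = alpha, T = Tk, x_d = x_d, eta = etas,
      u_at_division = u_d, t_b = t_b, t_d = t_d)
    if (keep_tracks)
      tracks[[ln]] <- tibble::tibble(
        lineage_id = sprintf("lineage_%02d", ln),
        t = unlist(tr_t), u = unlist(tr_u), x = unlist(tr_x))
  }
  records <- dplyr::bind_rows(recs)
  series <- lapply(recs, function(r) {
    cbind(x_b = r$x_b, alpha = r$alpha, T = r$T)
  })
  names(series) <- vapply(recs, function(r) r$lineage_id[1L], character(1L))
  ts <- ts_set(series, dt = 1, channel_names = c("x_b", "alpha", "T"))
  out <- list(records = records, ts = ts, params = params)
  if (keep_tracks) out$tracks <- dplyr::bind_rows(tracks)
  out
}

# ---- two-objective toy ---------------------------------------------------

#' Parameters of the two-objective toy simulator
#'
#' Two disjoint channel pairs. Within each pair the two channels split a
#' slow sinusoidal reference equally and carry perfectly anti-correlated
#' noise, so each pair has one linear regulated combination (its channel
#' sum) tracking its own sinusoid. The two references have different
#' periods, different amplitudes and independent random phases per series,
#' making the two objectives uncorrelated and non-interchangeable. The
#' amplitude asymmetry (together with a little observation noise) matters:
#' with exactly symmetric objectives every mixture of the two combinations
#' is as predictable as a pure one and the mixing angle is a flat direction
#' of the variance ratio, so "converge to one objective" would not be a
#' well-posed expectation.
#'
#' @param period_1,period_2 reference periods (in samples).
#' @param amp_1,amp_2 reference amplitudes.
#' @param noise_sd s.d. of the compensating within-pair noise.
#' @param obs_sd s.d. of additive observation noise per channel (does not
#'   cancel in the channel sums, so it sets each objective's tracking
#'   residual).
#' @param n_steps,n_series samples per series, number of series.
#' @return a list of class `two_objective_params`.
#' @export
two_objective_params <- function(period_1 = 40, period_2 = 97,
                                 amp_1 = 1, amp_2 = 0.7,
                                 noise_sd = 0.5, obs_sd = 0.15,
                                 n_steps = 400L, n_series = 10L) {
  p <- as.list(environment())
  stopifnot(period_1 > 2, period_2 > 2, amp_1 > 0, amp_2 > 0,
            noise_sd >= 0, obs_sd >= 0, n_steps >= 10L, n_series >= 1L)
  class(p) <- "two_objective_params"
  p
}

#' Simulate the two-objective toy
#'
#' @param params a [two_objective_params()].
#' @param seed integer seed.
#' @return list with `ts` (channels `a1`, `a2`, `b1`, `b2`; `dt = 1`) and
#'   `truth` (tibble of `series_id`, `time_index`, references `c1`, `c2`).
#'   Ground-truth combinations are `a1 + a2` (tracks `c1`) and `b1 + b2`
#'   (tracks `c2`).
#' @export
simulate_two_objectives <- function(params = two_objective_params(),
                                    seed = 1L) {
  stopifnot(inherits(params, "two_objective_params"))
  set.seed(seed)
  N <- params$n_steps
  sids <- sprintf("series_%02d", seq_len(params$n_series))
  series <- vector("list", params$n_series)
  truth <- vector("list", params$n_series)
  t <- seq_len(N) - 1L
  for (m in seq_len(params$n_series)) {
    ph1 <- stats::runif(1L, 0, 2 * pi)
    ph2 <- stats::runif(1L, 0, 2 * pi)
    c1 <- params$amp_1 * sin(2 * pi * t / params$period_1 + ph1)
    c2 <- params$amp_2 * sin(2 * pi * t / params$period_2 + ph2)
    w1 <- stats::rnorm(N, sd = params$noise_sd)
    w2 <- stats::rnorm(N, sd = params$noise_sd)
    Zm <- cbind(a1 = c1 / 2 + w1, a2 = c1 / 2 - w1,
                b1 = c2 / 2 + w2, b2 = c2 / 2 - w2)
    if (params$obs_sd > 0)
      Zm <- Zm + matrix(stats::rnorm(length(Zm), sd = params$obs_sd),
                        nrow = N)
    series[[m]] <- Zm
    truth[[m]] <- tibble::tibble(series_id = sids[m], time_index = t,
                                 c1 = c1, c2 = c2)
  }
  names(series) <- sids
  list(ts = ts_set(series, dt = 1,
                   channel_names = c("a1", "a2", "b1", "b2")),
       truth = dplyr::bind_rows(truth), params = params)
}
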