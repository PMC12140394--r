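test_that("the transcription rate oscillates as specified", {
  p <- kinetic_params(K0 = 4, tau_K = 50, phi_K = 0, random_phase = FALSE)
  expect_equal(kinetic_rate_K(0, p), 1.5 * 4)          # cos = 1
  expect_equal(kinetic_rate_K(25, p), 0.5 * 4)         # phase pi, cos = -1
  tt <- c(3.2, 17.9, 41)
  expect_equal(kinetic_rate_K(tt, p), kinetic_rate_K(tt + 50, p))
})

test_that("the set-point formula equals the algebraic steady state", {
  # independent derivation: at fixed K, M* = K / (f*A + gamma_M) with
  # A = k_P/gamma_P + k_S/gamma_S, and P* + S* = A * M*
  set.seed(44)
  for (i in 1:10) {
    p <- kinetic_params(K0 = runif(1, 1, 50), f = runif(1, 2, 40),
                        gamma_M = runif(1, 0.3, 3), gamma_P = runif(1, 0.3, 3),
                        gamma_S = runif(1, 0.3, 3), k_P = runif(1, 0.3, 3),
                        k_S = runif(1, 0.3, 3), random_phase = FALSE)
    K <- kinetic_rate_K(0, p)
    A <- p$k_P / p$gamma_P + p$k_S / p$gamma_S
    expect_equal(kinetic_setpoint(0, p), A * K / (p$f * A + p$gamma_M))
  }
  # limits: strong feedback pushes the set-point to K/f -> 0
  pf <- kinetic_params(f = 1e9, random_phase = FALSE)
  expect_lt(kinetic_setpoint(0, pf), 1e-6)
  # linearity in K0
  p1 <- kinetic_params(K0 = 3, random_phase = FALSE)
  p2 <- kinetic_params(K0 = 6, random_phase = FALSE)
  expect_equal(2 * kinetic_setpoint(13, p1), kinetic_setpoint(13, p2))
})

test_that("noiseless kinetics converge to the steady state and decay at K0 = 0", {
  p <- kinetic_params(K0 = 7, eta_P = 0, eta_S = 0, tau_K = 1e12,
                      random_phase = FALSE, n_series = 1L, n_steps = 30L,
                      burn_in = 40)
  sim <- simulate_kinetic(p, seed = 1)
  expect_equal(sim$truth$P_plus_S[30L], kinetic_setpoint(0, p),
               tolerance = 1e-3)
  p0 <- kinetic_params(K0 = 0, eta_P = 0, eta_S = 0, random_phase = FALSE,
                       n_series = 1L, n_steps = 40L, burn_in = 0)
  sim0 <- simulate_kinetic(p0, seed = 1)
  # initial steady state at K = 0 is the origin; all states stay there
  expect_true(all(abs(sim0$truth$P_plus_S) < 1e-12))
  expect_error(kinetic_params(sim_dt = 5, t_s = 2), "smaller than t_s")
})

test_that("an exploding integration is reported with a step-size hint", {
  p <- kinetic_params(eta_P = 1e31, sim_dt = 1, t_s = 10, n_series = 1L,
                      n_steps = 5L)
  expect_error(simulate_kinetic(p, seed = 1), "smaller sim_dt")
})

test_that("the strong-feedback preset tracks the moving set-point tightly", {
  sim <- simulate_kinetic(kinetic_params(n_series = 4L), seed = 2)
  rel <- abs(sim$truth$P_plus_S - sim$truth$c_star) / sim$truth$c_star
  expect_lt(mean(rel), 0.05)
})

test_that("the exact OU transition has the right conditional moments", {
  set.seed(5)
  expect_identical(ou_step(1.3, 0, 1, 0.2, 4), 1.3)
  # conditional variance at dt = tau_u
  u0 <- 1.8
  draws <- replicate(20000L, ou_step(u0, 4, mu_u = 1, sigma_u = 0.2,
                                     tau_u = 4))
  expect_equal(mean(draws), 1 + (u0 - 1) * exp(-1), tolerance = 0.005)
  expect_equal(var(draws), 0.2^2 * (1 - exp(-2)), tolerance = 0.05)
  # dt >> tau_u: stationary law
  far <- replicate(20000L, ou_step(u0, 400, mu_u = 1, sigma_u = 0.2,
                                   tau_u = 4))
  expect_equal(mean(far), 1, tolerance = 0.005)
  expect_equal(var(far), 0.04, tolerance = 0.05)
})

test_that("a long OU path has exponential autocorrelation", {
  set.seed(6)
  tau <- 5; dtg <- 0.5; N <- 60000L
  u <- numeric(N); u[1L] <- 1
  for (i in 2:N) u[i] <- ou_step(u[i - 1L], dtg, 1, 0.3, tau)
  ac <- cor(u[-N], u[-1L])
  # 3 sigma Monte-Carlo band around exp(-dt/tau)
  se <- sqrt(1 / N) * (1 - exp(-2 * dtg / tau))   # conservative
  expect_equal(ac, exp(-dtg / tau), tolerance = max(3 * se, 0.01))
})

test_that("the deterministic sizer divides exactly at the threshold mean", {
  p <- cell_cycle_params(sigma_u = 0, sigma_eta = 0, fixed_alpha = 0.9,
                         n_lineages = 2L, n_cycles = 10L)
  sim <- simulate_lineages(p, seed = 1)
  r <- sim$records
  expect_equal(r$x_d, rep(1, nrow(r)), tolerance = 1e-7)
  expect_equal(r$x_b[r$cycle > 1L], rep(0.5, sum(r$cycle > 1L)),
               tolerance = 1e-7)
  expect_equal(r$T[r$cycle > 1L], rep(log(2) / 0.9, sum(r$cycle > 1L)),
               tolerance = 1e-6)
})

test_that("lineage bookkeeping identities hold exactly", {
  sim <- simulate_lineages(cell_cycle_params(n_lineages = 3L,
                                             n_cycles = 40L), seed = 7)
  r <- dplyr::group_by(sim$records, lineage_id)
  r <- dplyr::mutate(r, x_d_prev = dplyr::lag(x_d))
  r <- dplyr::ungroup(r)
  rr <- r[!is.na(r$x_d_prev), ]
  expect_equal(rr$x_b, rr$eta * rr$x_d_prev, tolerance = 1e-12)
  # division size = exponential growth over the cycle, and hits the threshold
  expect_equal(r$x_d, r$x_b * exp(r$alpha * r$T), tolerance = 1e-9)
  expect_equal(r$x_d, r$u_at_division, tolerance = 1e-6)
})

test_that("division sizes follow the threshold's stationary law", {
  p <- cell_cycle_params(n_lineages = 10L, n_cycles = 200L)
  sim <- simulate_lineages(p, seed = 8)
  xd <- sim$records$x_d
  expect_equal(mean(xd), p$mu_u, tolerance = 0.02)
  expect_equal(sd(xd), p$sigma_u, tolerance = 0.25)
  # size homeostasis: one doubling per cycle on average
  expect_equal(mean(log2(sim$records$x_d / sim$records$x_b)), 1,
               tolerance = 0.02)
})

test_that("the two-objective toy has uncorrelated, trackable objectives", {
  sim <- simulate_two_objectives(two_objective_params(obs_sd = 0), seed = 5)
  tr <- sim$truth
  expect_lt(abs(cor(tr$c1, tr$c2)), 0.1)
  df <- as_tibble(sim$ts)
  # at zero observation noise the channel sums equal the references exactly
  expect_equal(df$a1 + df$a2, tr$c1, tolerance = 1e-12)
  expect_equal(df$b1 + df$b2, tr$c2, tolerance = 1e-12)
  # with observation noise the sums still track their references
  sim2 <- simulate_two_objectives(two_objective_params(), seed = 5)
  df2 <- as_tibble(sim2$ts)
  expect_lt(nmse(sim2$truth$c1, df2$a1 + df2$a2), 0.15)
  expect_lt(nmse(sim2$truth$c2, df2$b1 + df2$b2), 0.25)
})
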