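test_that("combination with zero weights is the output bias", {
  m <- model_state(n = 3L, T = 2L)
  m$g <- zero_net(m$g)
  m$g$b[[length(m$g$b)]] <- 4.2
  Z <- matrix(rnorm(15), 5L, 3L)
  expect_equal(combination_apply(m, Z), rep(4.2, 5L))
})

test_that("rigged linear combination reproduces hand-computed sums", {
  # g ~= z1 + z2 via two rigged channels with gain 1 each
  m <- model_state(n = 2L, T = 1L)
  m$g <- zero_net(m$g)
  eps <- 1e-4
  m$g$W[[1L]][1L, 1L] <- eps
  m$g$W[[1L]][2L, 2L] <- eps
  m$g$W[[2L]][1L, 1L] <- 1
  m$g$W[[2L]][2L, 2L] <- 1
  m$g$W[[3L]][1L, 1L] <- 1 / eps
  m$g$W[[3L]][2L, 1L] <- 1 / eps
  expect_equal(combination_apply(m, c(2, 3)), 5, tolerance = 1e-6)
})

test_that("forward pass matches an independently coded reference", {
  set.seed(31)
  m <- model_state(n = 2L, T = 2L)
  Z <- matrix(rnorm(8), 4L, 2L)
  # reference: explicit per-sample loop over layers
  ref <- apply(Z, 1L, function(z) {
    h <- z
    for (l in seq_along(m$g$W)) {
      h <- drop(h %*% m$g$W[[l]]) + m$g$b[[l]]
      if (l < length(m$g$W)) h <- tanh(h)
    }
    h
  })
  expect_equal(combination_apply(m, Z), ref)
  expect_error(combination_apply(m, matrix(1, 2L, 3L)), "channels")
})

test_that("persistence filter predicts the last history value", {
  m <- rigged_model(n = 1L, T = 3L)
  hist <- matrix(c(0.3, -1.2, 0.7), 1L)
  expect_equal(filter_predict(m, hist), 0.7, tolerance = 1e-6)
  expect_error(filter_predict(m, c(1, 2)), "T = 3")
})

test_that("static mode pins the filter to zero regardless of settings", {
  for (b_y in c(1L, 4L)) {
    m <- model_state(n = 2L, T = 2L, b_y = b_y, static_mode = TRUE)
    expect_equal(filter_predict(m, matrix(rnorm(10), 5L, 2L)), rep(0, 5L))
  }
})

test_that("one Euler step of a rigged linear drift matches hand integration", {
  # drift w(y) = -y on latent coordinate 1; y+ = 2, so y- = 2 * (1 - dt)
  dt <- 0.3
  m <- rigged_model(n = 1L, T = 1L, b_y = 2L, dt = dt)
  m$drift <- rig_linear_path(m$drift, 1L, out_coord = 1L, gain = -1)
  # history (c^{k-1} = 2) -> y+ = 2 -> Euler -> decode coordinate 1
  expect_equal(filter_predict(m, 2), 2 * (1 - dt), tolerance = 1e-5)
  # zero drift: prediction is just decode(encode(history))
  m$drift <- zero_net(m$drift)
  expect_equal(filter_predict(m, 2), 2, tolerance = 1e-6)
})

test_that("rk4 drift integration matches the exact linear solution", {
  dt <- 0.3
  m <- rigged_model(n = 1L, T = 1L, b_y = 2L, dt = dt)
  m$integrator <- "rk4"
  m$drift <- rig_linear_path(m$drift, 1L, out_coord = 1L, gain = -1)
  # rk4 on y' = -y over dt: y * (1 - dt + dt^2/2 - dt^3/6 + dt^4/24)
  expect_equal(filter_predict(m, 2),
               2 * (1 - dt + dt^2 / 2 - dt^3 / 6 + dt^4 / 24),
               tolerance = 1e-5)
})

test_that("filtering error composes combination minus filter prediction", {
  set.seed(7)
  m <- model_state(n = 2L, T = 3L, b_y = 2L)
  W <- array(rnorm(5 * 4 * 2), dim = c(5L, 4L, 2L))
  e <- filtering_error(m, W)
  for (i in 1:5) {
    ck <- combination_apply(m, W[i, 4L, ])
    hist <- combination_apply(m, W[i, 1:3, ])
    expect_equal(e[i], ck - filter_predict(m, hist))
  }
})

test_that("static-mode error equals the combination value exactly", {
  set.seed(8)
  m <- model_state(n = 2L, T = 2L, static_mode = TRUE)
  W <- array(rnorm(6 * 3 * 2), dim = c(6L, 3L, 2L))
  expect_equal(filtering_error(m, W),
               combination_apply(m, matrix(W[, 3L, ], 6L, 2L)),
               tolerance = 1e-14)
})

test_that("a constant series with a persistence filter has zero error", {
  m <- rigged_model(n = 1L, T = 2L)
  W <- array(1.7, dim = c(3L, 3L, 1L))
  expect_equal(filtering_error(m, W), rep(0, 3L), tolerance = 1e-9)
})

test_that("autodiff gradients match finite differences", {
  set.seed(99)
  for (static in c(FALSE, TRUE)) {
    m <- model_state(n = 2L, T = 4L, b_y = 3L, dt = 0.5,
                     static_mode = static)
    Z <- array(rnorm(6L * 5L * 2L), dim = c(6L, 5L, 2L))
    w <- rnorm(6L)
    fwd <- idras:::errors_forward(m, Z, gauge = NULL)
    gr <- idras:::par_flatten(idras:::errors_backward(m, fwd, w))
    params <- idras:::model_params(m)
    flat <- idras:::par_flatten(params)
    f_of <- function(v) {
      mm <- idras:::model_set_params(m, idras:::par_unflatten(params, v))
      sum(w * idras:::errors_forward(mm, Z, gauge = fwd$gauge)$e)
    }
    idx <- sample(length(flat), 30L)
    eps <- 1e-5
    fd <- vapply(idx, function(i) {
      vp <- flat; vm <- flat
      vp[i] <- vp[i] + eps; vm[i] <- vm[i] - eps
      (f_of(vp) - f_of(vm)) / (2 * eps)
    }, numeric(1L))
    expect_equal(gr[idx], fd, tolerance = 1e-4)
  }
})

test_that("the filter history is recomputed from the current combination", {
  # with a persistence filter, e = g(z_k) - g(z_{k-1}): adding a constant to
  # g cancels (history recomputed), rescaling g rescales e
  m <- rigged_model(n = 1L, T = 2L)
  W <- array(rnorm(12), dim = c(4L, 3L, 1L))
  e0 <- filtering_error(m, W)
  m_shift <- m
  m_shift$g$b[[length(m_shift$g$b)]] <- 5
  expect_equal(filtering_error(m_shift, W), e0, tolerance = 1e-7)
  m_scale <- m
  nl <- length(m_scale$g$W)
  m_scale$g$W[[nl]] <- m_scale$g$W[[nl]] * 3
  expect_equal(filtering_error(m_scale, W), 3 * e0, tolerance = 1e-7)
})

test_that("checkpoints round-trip the full model state", {
  m <- model_state(n = 2L, T = 3L, b_y = 2L, dt = 0.5, integrator = "rk4")
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2, m)
  saveRDS(1:3, f)
  expect_error(load_checkpoint(f), "not a model checkpoint")
})
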