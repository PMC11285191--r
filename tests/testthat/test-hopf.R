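single_node <- matrix(0, 1, 1)

test_that("noise-free oscillator settles on the limit-cycle radius sqrt(a)", {
  p <- hopf_params(a = 0.04, omega = 2 * pi * 0.05, G = 0, beta = 0, dt = 0.002)
  run <- simulate_hopf(single_node, p, n_timepoints = 200, tr = 2, seed = 1,
                       burn_in_s = 400)
  amp <- sqrt(unclass(run)^2 + attr(run, "y")^2)
  expect_equal(mean(amp), sqrt(0.04), tolerance = 1e-3 / 0.2)
  expect_lt(max(abs(amp - sqrt(0.04))), 1e-3)
})

test_that("below the bifurcation the noise-free oscillator decays to zero", {
  p <- hopf_params(a = -0.04, omega = 2 * pi * 0.05, G = 0, beta = 0, dt = 0.01)
  run <- simulate_hopf(single_node, p, n_timepoints = 50, tr = 2, seed = 1,
                       burn_in_s = 400)
  expect_lt(max(abs(unclass(run))), 1e-4)
})

test_that("oscillation frequency matches the intrinsic frequency", {
  p <- hopf_params(a = 0.04, omega = 2 * pi * 0.05, G = 0, beta = 0, dt = 0.01)
  run <- simulate_hopf(single_node, p, n_timepoints = 512, tr = 2, seed = 1,
                       burn_in_s = 200)
  x <- as.numeric(run)
  sp <- abs(stats::fft(x - mean(x)))[1:256]^2
  freq <- (0:255) / (512 * 2)
  expect_equal(freq[which.max(sp)], 0.05, tolerance = 1 / (512 * 2) / 0.05)
})

test_that("same seed gives identical runs; divergence raises", {
  W <- matrix(c(0, 0.2, 0.2, 0), 2)
  p <- hopf_params(a = -0.01, omega = 2 * pi * c(0.05, 0.06), G = 1, beta = 0.04)
  r1 <- simulate_hopf(W, p, 50, tr = 2, seed = 42)
  r2 <- simulate_hopf(W, p, 50, tr = 2, seed = 42)
  expect_identical(unclass(r1)[, ], unclass(r2)[, ])
  r3 <- simulate_hopf(W, p, 50, tr = 2, seed = 43)
  expect_false(identical(unclass(r1)[, ], unclass(r3)[, ]))
  # far above the bifurcation with a tiny bound the amplitude must trip it
  pb <- hopf_params(a = 5, omega = 2 * pi * 0.05, G = 0, beta = 0, dt = 0.1)
  expect_error(
    simulate_hopf(single_node, pb, 10, tr = 2, seed = 1, divergence_bound = 0.5),
    "divergence"
  )
  expect_error(simulate_hopf(W, hopf_params(omega = 1, dt = 0.3), 10, tr = 2),
               "divide")
})

test_that("coupling raises pairwise correlation over the uncoupled baseline", {
  # mean gap pinned from 20-seed pre-build computation: 0.89
  W <- matrix(c(0, 0.2, 0.2, 0), 2)
  om <- 2 * pi * c(0.05, 0.055)
  gap <- vapply(1:20, function(s) {
    r1 <- simulate_hopf(W, hopf_params(a = -0.01, omega = om, G = 2, beta = 0.04),
                        896, tr = 2, seed = s)
    r0 <- simulate_hopf(W, hopf_params(a = -0.01, omega = om, G = 0, beta = 0.04),
                        896, tr = 2, seed = s)
    stats::cor(t(unclass(r1)))[1, 2] - stats::cor(t(unclass(r0)))[1, 2]
  }, numeric(1))
  expect_equal(mean(gap), 0.89, tolerance = 0.05)
  expect_gt(min(gap), 0)
})

test_that("intrinsic frequencies are recovered from narrowband signals", {
  tr <- 2
  t <- seq(0, by = tr, length.out = 400)
  mk <- function(f, seed) {
    set.seed(seed)
    bold_run(rbind(sin(2 * pi * f * t) + rnorm(400, 0, 0.05)), tr = tr)
  }
  om <- estimate_intrinsic_frequencies(list(mk(0.05, 1)))
  expect_equal(attr(om, "freq_hz"), 0.05, tolerance = 1 / (400 * tr) / 0.05)
  # two subjects with different peaks average
  om2 <- estimate_intrinsic_frequencies(list(mk(0.045, 2), mk(0.055, 3)))
  expect_equal(attr(om2, "freq_hz"), 0.05, tolerance = 0.03)
  # white noise still yields an in-band frequency (band-limited by construction)
  set.seed(4)
  omw <- estimate_intrinsic_frequencies(list(bold_run(rbind(rnorm(400)), tr = tr)))
  f <- attr(omw, "freq_hz")
  expect_true(f >= 0.04 && f <= 0.07)
  expect_error(
    estimate_intrinsic_frequencies(list(bold_run(rbind(rnorm(10)), tr = tr))),
    "too short"
  )
})

test_that("linearization matches the single-node Ornstein-Uhlenbeck closed form", {
  p <- hopf_params(a = -0.01, omega = 1, G = 0, beta = 0.04)
  lin <- linearize_hopf(single_node, p)
  expect_equal(lin$stationary_cov[1, 1], 0.04^2 / (2 * 0.01), tolerance = 1e-10)
  expect_equal(lin$lagged_cov(0), lin$stationary_cov)
  expect_error(linearize_hopf(single_node, hopf_params(a = 0.01, omega = 1)),
               "a < 0")
})

test_that("model FC/FS behave at the identities the linearization forces", {
  set.seed(8)
  n <- 5
  W <- matrix(runif(n * n, 0, 0.1), n); W <- (W + t(W)) / 2; diag(W) <- 0
  p <- hopf_params(a = -0.05, omega = 2 * pi * runif(n, 0.04, 0.07),
                   G = 0.8, beta = 0.04)
  lin <- linearize_hopf(W, p)
  fc <- model_fc(lin)
  expect_equal(diag(fc), rep(1, n), ignore_attr = TRUE)
  expect_equal(fc, t(fc))
  # G = 0: regions are independent
  lin0 <- linearize_hopf(W, hopf_params(a = -0.05, omega = p$omega, G = 0,
                                        beta = 0.04))
  fc0 <- model_fc(lin0)
  expect_equal(max(abs(fc0[upper.tri(fc0)])), 0, tolerance = 1e-10)
  # symmetric C with shared frequency: FS(tau) symmetric
  ps <- hopf_params(a = -0.05, omega = 2 * pi * 0.05, G = 0.8, beta = 0.04)
  lins <- linearize_hopf(W, ps)
  fs <- model_fs(lins, 2)
  expect_equal(fs, t(fs), tolerance = 1e-8)
  expect_equal(model_fs(lin, 0), fc, tolerance = 1e-10)
})

test_that("stationary covariance agrees with a long stochastic simulation", {
  set.seed(21)
  n <- 10
  W <- matrix(runif(n * n, 0, 0.1), n); W <- (W + t(W)) / 2; diag(W) <- 0
  W <- scale_connectome(W, 0.2)
  p <- hopf_params(a = -0.2, omega = 2 * pi * runif(n, 0.04, 0.07),
                   G = 0.75, beta = 0.04, dt = 0.1)
  lin <- linearize_hopf(W, p)
  fcm <- model_fc(lin)
  run <- simulate_hopf(W, p, n_timepoints = 12000, tr = 2, seed = 5,
                       burn_in_s = 100)
  fce <- empirical_fc(list(run))
  expect_lt(max(abs(fcm - fce)[upper.tri(fcm)]), 0.05)
})

test_that("simulated covariance converges to the linearized one with run length", {
  set.seed(21)
  n <- 10
  W <- matrix(runif(n * n, 0, 0.1), n); W <- (W + t(W)) / 2; diag(W) <- 0
  W <- scale_connectome(W, 0.2)
  p <- hopf_params(a = -0.2, omega = 2 * pi * runif(n, 0.04, 0.07),
                   G = 0.75, beta = 0.04, dt = 0.1)
  fcm <- model_fc(linearize_hopf(W, p))
  d <- vapply(c(500, 4000, 32000), function(T) {
    fce <- empirical_fc(list(simulate_hopf(W, p, T, tr = 2, seed = 3,
                                           burn_in_s = 100)))
    norm(fcm - fce, "F")
  }, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("the hemodynamic-convolution hook changes the signal only when enabled", {
  W <- matrix(c(0, 0.1, 0.1, 0), 2)
  p <- hopf_params(a = -0.01, omega = 2 * pi * c(0.05, 0.06), G = 1, beta = 0.04)
  plain <- simulate_hopf(W, p, 100, tr = 2, seed = 2)
  conv <- simulate_hopf(W, p, 100, tr = 2, seed = 2, conv_hrf = TRUE)
  expect_false(identical(unclass(plain)[, ], unclass(conv)[, ]))
  expect_equal(dim(conv), dim(plain))
})
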