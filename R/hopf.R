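#' Hopf model parameters
#'
#' Parameters of the coupled Stuart-Landau (Hopf normal form) network. Each
#' region is an oscillator with bifurcation parameter `a` (the working point
#' sits just below the bifurcation, `a = -0.01`, so regions produce
#' noise-driven narrowband fluctuations rather than sustained oscillations),
#' intrinsic angular frequency `omega` (rad/s, conventionally the 0.04-0.07
#' Hz BOLD band), global coupling `G` scaling the connectome, and additive
#' Gaussian noise of standard deviation `beta`.
#'
#' @param a Bifurcation parameter, scalar or per-region vector (default -0.01).
#' @param omega Intrinsic angular frequencies in rad/s, scalar or per region.
#' @param G Global coupling scalar (>= 0).
#' @param beta Noise standard deviation (>= 0, default 0.04).
#' @param dt Integration step in seconds (default 0.1).
#' @return List of class `hopf_params`.
#' @export
hopf_params <- function(a = -0.01, omega, G = 1, beta = 0.04, dt = 0.1) {
  if (beta < 0) stop("beta must be >= 0")
  if (G < 0) stop("G must be >= 0")
  if (dt <= 0) stop("dt must be positive")
  structure(list(a = a, omega = omega, G = G, beta = beta, dt = dt),
            class = "hopf_params")
}

expand_params <- function(params, n) {
  a <- rep_len(params$a, n)
  omega <- rep_len(params$omega, n)
  list(a = a, omega = omega, G = params$G, beta = params$beta, dt = params$dt)
}

#' Simulate BOLD-like activity from the coupled Hopf network
#'
#' Integrates the real/imaginary-part equations of the Stuart-Landau network
#' with diffusive coupling `G * sum_k C_jk (x_k - x_j)` by Euler-Maruyama
#' (noise scaled by `sqrt(dt)`, independently for x and y), discards a
#' burn-in, and subsamples the real part `x_j` at interval `tr` as the
#' BOLD-like signal. All randomness flows through R's RNG via `seed`, so
#' identical `(connectome, params, seed)` give identical runs.
#'
#' @param connectome Square nonnegative coupling matrix (structural or GEC;
#'   asymmetric matrices are used as-is).
#' @param params A [hopf_params()]; `dt` must divide `tr`.
#' @param n_timepoints Number of retained samples.
#' @param tr Sampling interval (s).
#' @param seed Integer seed for this run.
#' @param burn_in_s Burn-in discarded before sampling (s, default 50).
#' @param divergence_bound Error if any oscillator amplitude `|z_j|` exceeds
#'   this bound (default 10) — signals an unstable `G`/`dt` combination.
#' @param subject_id Optional identifier attached to the run.
#' @param conv_hrf If `TRUE`, convolve the sampled signal with a canonical
#'   double-gamma hemodynamic response (off by default; the raw oscillator
#'   real part is taken as the BOLD proxy).
#' @return A [bold_run()]; the sampled imaginary part is attached as
#'   attribute `"y"` for amplitude diagnostics.
#' @export
simulate_hopf <- function(connectome, params, n_timepoints, tr = 2,
                          seed = 1, burn_in_s = 50, divergence_bound = 10,
                          subject_id = NULL, conv_hrf = FALSE) {
  n <- nrow(connectome)
  p <- expand_params(params, n)
  steps_per_sample <- tr / p$dt
  if (abs(steps_per_sample - round(steps_per_sample)) > 1e-8) {
    stop("params$dt must divide tr")
  }
  steps_per_sample <- as.integer(round(steps_per_sample))
  burn_steps <- as.integer(round(burn_in_s / p$dt))
  total <- burn_steps + steps_per_sample * n_timepoints
  set.seed(seed)
  x0 <- rnorm(n, 0, 0.1)
  y0 <- rnorm(n, 0, 0.1)
  noise_x <- matrix(rnorm(n * total), n, total)
  noise_y <- matrix(rnorm(n * total), n, total)
  out <- hopf_integrate_cpp(unclass(connectome), p$a, p$omega, p$G, p$beta,
                            p$dt, burn_steps, steps_per_sample,
                            as.integer(n_timepoints), noise_x, noise_y,
                            x0, y0, divergence_bound)
  sig <- out$x
  rownames(sig) <- rownames(connectome)
  if (conv_hrf) sig <- t(apply(sig, 1, convolve_hrf, tr = tr))
  run <- bold_run(sig, tr = tr, subject_id = subject_id)
  attr(run, "y") <- out$y
  run
}

# Canonical double-gamma HRF sampled at the TR; used only when conv_hrf = TRUE.
convolve_hrf <- function(x, tr, length_s = 30) {
  t <- seq(0, length_s, by = tr)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h <- h / sum(h)
  out <- stats::convolve(x, rev(h), type = "open")
  out[seq_along(x)]
}

#' Estimate intrinsic node frequencies from BOLD runs
#'
#' Band-pass filters each regional signal, locates the spectral peak per
#' region per run, and averages peak frequencies across runs/subjects. The
#' returned angular frequencies `omega_j = 2 pi f_j` all lie within the band
#' by construction.
#'
#' @param runs List of [bold_run()]s sharing the same TR.
#' @param band `c(low, high)` in Hz (default `c(0.04, 0.07)`).
#' @return Numeric vector `omega` (rad/s) per region; the peak frequencies
#'   in Hz are attached as attribute `"freq_hz"`.
#' @export
estimate_intrinsic_frequencies <- function(runs, band = c(0.04, 0.07)) {
  if (!length(runs)) stop("need at least one run")
  tr <- run_tr(runs[[1]])
  if (any(vapply(runs, run_tr, numeric(1)) != tr)) stop("runs must share tr")
  min_len <- 2 / band[1] / tr
  if (ncol(runs[[1]]) < min_len) {
    stop("runs too short to resolve the band: need at least ",
         ceiling(min_len), " samples")
  }
  peaks <- vapply(runs, function(run) {
    filt <- band_filter(run, band)
    apply(unclass(filt), 1, spectral_peak_hz, tr = tr, band = band)
  }, numeric(nrow(runs[[1]])))
  f <- rowMeans(matrix(peaks, nrow = nrow(runs[[1]])))
  omega <- 2 * pi * f
  attr(omega, "freq_hz") <- f
  omega
}

spectral_peak_hz <- function(x, tr, band) {
  n <- length(x)
  sp <- abs(fft(x - mean(x)))[seq_len(floor(n / 2))]^2
  freq <- (seq_len(floor(n / 2)) - 1) / (n * tr)
  in_band <- freq >= band[1] & freq <= band[2]
  if (!any(in_band)) return(mean(band))
  freq[in_band][which.max(sp[in_band])]
}

#' Linearize the Hopf network at its fixed point
#'
#' For `a < 0` the deterministic system has a stable fixed point at the
#' origin; linearizing there gives an Ornstein-Uhlenbeck process whose
#' `2n x 2n` Jacobian stacks the real parts over the imaginary parts:
#' diagonal blocks `diag(a) + G (C - diag(rowSums(C)))` (diffusive coupling
#' contributes the negative row-sum self term) and off-diagonal rotation
#' blocks `-diag(omega)` / `diag(omega)`. The stationary covariance `K`
#' solves the continuous Lyapunov equation `J K + K J' + beta^2 I = 0`
#' (solved via the eigendecomposition of `J`), and the lagged covariance is
#' `cov(X(t), X(t + tau)) = K expm(J' tau)`.
#'
#' @param connectome Square nonnegative coupling matrix.
#' @param params A [hopf_params()] with `a < 0` everywhere.
#' @return List of class `hopf_linearized`: `jacobian`, `noise_cov`,
#'   `stationary_cov`, `lagged_cov(tau)` (a function of lag in seconds),
#'   `n`, `eigenvalues`.
#' @export
linearize_hopf <- function(connectome, params) {
  n <- nrow(connectome)
  p <- expand_params(params, n)
  if (any(p$a >= 0)) stop("linearization requires a < 0 for all regions (fluctuation regime)")
  C <- unclass(connectome)
  M <- diag(p$a, n) + p$G * (C - diag(rowSums(C), n))
  J <- rbind(cbind(M, -diag(p$omega, n)), cbind(diag(p$omega, n), M))
  eg <- eigen(J)
  if (any(Re(eg$values) >= 0)) {
    stop("unstable: Jacobian has eigenvalue with nonnegative real part (max Re = ",
         signif(max(Re(eg$values)), 4), ")")
  }
  V <- eg$vectors
  W <- solve(V)
  Q <- diag(p$beta^2, 2 * n)
  # J K + K J' + Q = 0  =>  K = V X V', X_ij = -(W Q W')_ij / (l_i + l_j)
  Qt <- W %*% Q %*% t(W)
  denom <- outer(eg$values, eg$values, `+`)
  K <- V %*% (-Qt / denom) %*% t(V)
  K <- Re(K + t(K)) / 2
  lagged_cov <- function(tau) {
    if (tau == 0) return(K)
    E <- V %*% diag(exp(eg$values * tau)) %*% W
    # cov(X(t), X(t+tau))_ij = E[X_i(t) X_j(t+tau)] = (K expm(J' tau))_ij
    Re(K %*% t(E))
  }
  structure(list(jacobian = J, noise_cov = Q, stationary_cov = K,
                 lagged_cov = lagged_cov, n = n, eigenvalues = eg$values),
            class = "hopf_linearized")
}

#' Model FC and time-shifted covariance from the linearized system
#'
#' `model_fc()` is the correlation-normalized x-block (first `n` rows and
#' columns, the real part mirroring the BOLD signal) of the stationary
#' covariance. `model_fs()` is the x-block of the lagged covariance at lag
#' `tau` seconds, with each pair normalized by the product of the zero-lag
#' standard deviations — the same per-pair scheme applied to the empirical
#' time-shifted covariance, so model and data are compared on one scale and
#' `model_fs(lin, 0)` equals `model_fc(lin)`.
#'
#' @param lin A [linearize_hopf()] result.
#' @param tau Lag in seconds.
#' @return `n x n` matrix (FC has unit diagonal; FS is asymmetric in general).
#' @export
model_fc <- function(lin) {
  Kx <- lin$stationary_cov[seq_len(lin$n), seq_len(lin$n)]
  d <- sqrt(diag(Kx))
  fc <- Kx / outer(d, d)
  diag(fc) <- 1
  fc
}

#' @rdname model_fc
#' @export
model_fs <- function(lin, tau) {
  idx <- seq_len(lin$n)
  Kx <- lin$stationary_cov[idx, idx]
  d <- sqrt(diag(Kx))
  L <- lin$lagged_cov(tau)[idx, idx]
  L / outer(d, d)
}
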