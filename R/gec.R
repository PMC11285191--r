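#' Grand-average empirical FC and time-shifted covariance
#'
#' `empirical_fc()` averages pairwise Pearson correlation matrices across
#' runs/subjects. `empirical_fs()` computes, per run, the lagged covariance
#' `cov(s_i(t), s_j(t + tau))` normalized for each pair by the product of
#' the zero-lag standard deviations of that pair, then grand-averages; with
#' `tau = 0` it reduces exactly to `empirical_fc()`. FS is asymmetric in
#' general — the direction of the lag carries the directed information the
#' GEC update exploits.
#'
#' @param runs List of [bold_run()]s on the same parcellation and TR.
#' @param tau Lag in samples (TR units), `tau >= 0`.
#' @param band Optional band `c(low, high)` in Hz; if given, runs are
#'   band-pass filtered before the statistics are computed.
#' @return `n x n` matrix (FC symmetric with unit diagonal).
#' @export
empirical_fc <- function(runs, band = NULL) {
  if (!length(runs)) stop("need at least one run")
  mats <- lapply(runs, function(run) {
    if (!is.null(band)) run <- band_filter(run, band)
    stats::cor(t(unclass(run)))
  })
  fc <- Reduce(`+`, mats) / length(mats)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

#' @rdname empirical_fc
#' @export
empirical_fs <- function(runs, tau, band = NULL) {
  if (!length(runs)) stop("need at least one run")
  tau <- as.integer(tau)
  if (tau < 0) stop("tau must be >= 0")
  mats <- lapply(runs, function(run) {
    if (!is.null(band)) run <- band_filter(run, band)
    sig <- unclass(run)
    T <- ncol(sig)
    if (T < tau + 3) stop("run too short for lag ", tau, ": need at least tau + 3 samples")
    sds <- apply(sig, 1, stats::sd)
    if (tau == 0) {
      cc <- stats::cov(t(sig))
    } else {
      cc <- stats::cov(t(sig[, seq_len(T - tau), drop = FALSE]),
                       t(sig[, (tau + 1):T, drop = FALSE]))
    }
    cc / outer(sds, sds)
  })
  Reduce(`+`, mats) / length(mats)
}

#' Phase-coherence matrix of a run
#'
#' Alternative "phase" realization of the synchrony target: band-pass
#' filter, Hilbert-transform each regional signal to its instantaneous
#' phase, and average `cos(theta_i - theta_j)` over time (the pairwise
#' phase-locking matrix). Provided as an optional target mode for the GEC
#' fit; the default mode uses correlations of the band-passed signals.
#'
#' @param run A [bold_run()].
#' @param band Band in Hz used before the Hilbert transform.
#' @return Symmetric `n x n` matrix with unit diagonal.
#' @export
phase_coherence <- function(run, band = c(0.04, 0.07)) {
  filt <- unclass(band_filter(run, band))
  theta <- t(apply(filt, 1, function(x) Arg(hilbert_analytic(x))))
  z <- exp(1i * theta)
  pc <- Re(z %*% Conj(t(z))) / ncol(theta)
  pc <- (pc + t(pc)) / 2
  diag(pc) <- 1
  pc
}

# Analytic signal via the frequency-domain Hilbert transform.
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Gaussian mutual-information transform of a correlation matrix
#'
#' Elementwise `-log(1 - r^2) / 2`, the mutual information of a bivariate
#' Gaussian with correlation `r`; maps correlations to nonnegative values
#' and removes their sign. Entries with `|r| = 1` are clipped to
#' `1 - 1e-12` with a warning.
#'
#' @param m Matrix (or vector) of correlations in `[-1, 1]`.
#' @return Transformed matrix, all entries `>= 0`.
#' @export
mi_transform <- function(m) {
  if (any(abs(m) >= 1)) {
    warning("|r| = 1 entries clipped to 1 - 1e-12 before the MI transform")
    m <- pmin(pmax(m, -1 + 1e-12), 1 - 1e-12)
  }
  -0.5 * log(1 - m^2)
}

#' Sweep the global coupling parameter G
#'
#' For each candidate `G`, solves the linearized model on the structural
#' connectome and scores the mean squared difference between the upper
#' triangles of the model FC and the empirical FC; returns the arg-min `G`, ties broken toward the
#' smaller value. Candidates whose Jacobian is unstable are skipped; if all
#' are unstable an error reports the stability boundary.
#'
#' @param structural Structural connectome (scaled, max weight 0.2).
#' @param params_base A [hopf_params()]; its `G` is overridden per candidate.
#' @param runs Healthy [bold_run()]s providing the empirical target.
#' @param g_grid Numeric vector of candidate G values.
#' @param band Optional band in Hz for the empirical FC. The default
#'   (`NULL`, no filtering) keeps the empirical target in the same
#'   covariance domain as the linearized model FC it is compared against;
#'   band-passing only the empirical side inflates its correlations and
#'   biases the selected G upward. Pass a band for the narrowband variant.
#' @return The selected `G`; the per-candidate error curve is attached as
#'   attribute `"errors"` (tibble with columns `g`, `error`).
#' @export
sweep_g <- function(structural, params_base, runs, g_grid = seq(0.1, 2.5, by = 0.05),
                    band = NULL) {
  g_grid <- sort(g_grid)
  fc_emp <- empirical_fc(runs, band = band)
  target <- upper_vals(fc_emp)
  errs <- vapply(g_grid, function(g) {
    p <- params_base
    p$G <- g
    lin <- tryCatch(linearize_hopf(structural, p), error = function(e) NULL)
    if (is.null(lin)) return(Inf)
    mean((target - upper_vals(model_fc(lin)))^2)
  }, numeric(1))
  if (all(!is.finite(errs))) {
    stop("all candidate G values are unstable; stability boundary below G = ",
         min(g_grid))
  }
  g_opt <- g_grid[which.min(errs)]
  attr(g_opt, "errors") <- tibble::tibble(g = g_grid, error = errs)
  g_opt
}

#' GEC fit configuration
#'
#' @param epsilon Learning rate of the gradient update (default 0.001).
#' @param tau Time lag of the shifted-covariance target, in TR units
#'   (default 1).
#' @param g Global coupling; if `NULL`, selected by [sweep_g()] over `g_grid`.
#' @param g_grid Candidate G values for the sweep.
#' @param a,beta Bifurcation parameter and noise SD of the model
#'   (defaults -0.01 and 0.04).
#' @param max_iter Maximum accepted iterations (default 300).
#' @param convergence_tol Stop when the relative error improvement of an
#'   accepted step falls below this (default 1e-5).
#' @param mi_transform If `TRUE`, fit on Gaussian mutual-information
#'   transforms of the FC/FS targets instead of raw values (default FALSE).
#' @param band Optional band (Hz) applied to runs before computing the
#'   FC/FS targets; `NULL` (default) uses unfiltered signals, which matches
#'   the domain of the linearized model the fit inverts.
#' @param sweep_band Optional band for the empirical target of the G sweep
#'   (`NULL`, the default, scores against unfiltered FC; see [sweep_g()]).
#' @param freq_band Band for intrinsic-frequency estimation.
#' @param update_support `"structural"` restricts updates to entries with a
#'   nonzero structural weight (each structural connection individually
#'   adjusted); `"all"` allows every off-diagonal entry.
#' @param fc_mode `"covariance"` (default) targets Pearson FC of the
#'   (optionally band-passed) signals; `"phase"` targets the Hilbert
#'   phase-locking matrix [phase_coherence()] instead.
#' @param max_halvings Learning-rate halvings attempted within one rejected
#'   iteration before the fit stops (default 5).
#' @return List of class `gec_fit_config`.
#' @export
gec_fit_config <- function(epsilon = 0.001, tau = 1, g = NULL,
                           g_grid = seq(0.1, 2.5, by = 0.05),
                           a = -0.01, beta = 0.04,
                           max_iter = 300, convergence_tol = 1e-5,
                           mi_transform = FALSE, band = NULL,
                           sweep_band = NULL,
                           freq_band = c(0.04, 0.07),
                           update_support = c("structural", "all"),
                           fc_mode = c("covariance", "phase"),
                           max_halvings = 5) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (tau < 0) stop("tau must be >= 0")
  structure(list(epsilon = epsilon, tau = tau, g = g, g_grid = g_grid,
                 a = a, beta = beta, max_iter = max_iter,
                 convergence_tol = convergence_tol,
                 mi_transform = mi_transform, band = band,
                 sweep_band = sweep_band, freq_band = freq_band,
                 update_support = match.arg(update_support),
                 fc_mode = match.arg(fc_mode),
                 max_halvings = max_halvings),
            class = "gec_fit_config")
}

#' Fit generative effective connectivity to a healthy cohort
#'
#' Starting from the structural connectome (`C <- SC`), iterates the
#' gradient update
#' `C_jk <- C_jk + eps (FC_emp - FC_mod)_jk + eps (FS_emp(tau) - FS_mod(tau))_jk`
#' over the supported entries, re-solving the linearized model after every
#' update. The scheme is greedy: a step is accepted only if the combined
#' FC + FS error decreases; otherwise the learning rate is halved and the
#' step retried (up to `max_halvings`, after which the fit stops), so the
#' accepted-iteration error trace is non-increasing by construction.
#' Negative weights are clipped to zero after each update. Because the
#' time-shifted target FS is asymmetric, the fitted matrix acquires
#' asymmetry even though it is initialized from a symmetric connectome —
#' this directed matrix is the generative effective connectivity (GEC).
#'
#' @param structural Structural connectome (symmetric, scaled to max 0.2).
#' @param runs Healthy [bold_run()]s supplying the empirical targets.
#' @param config A [gec_fit_config()].
#' @param init Optional initialization matrix (defaults to `structural`);
#'   used e.g. by the patient-specific model, which initializes from the
#'   lesion-masked structural connectome.
#' @param omega Optional angular frequencies; estimated from `runs` via
#'   [estimate_intrinsic_frequencies()] when `NULL`.
#' @param targets Optional list with elements `fc` and `fs`: precomputed
#'   empirical targets that replace the ones derived from `runs` (used for
#'   self-consistency checks and advanced workflows).
#' @return Object of class `gec_fit`: `gec` (fitted matrix), `g_opt`,
#'   `params` ([hopf_params()] used), `trace` (per-iteration tibble),
#'   `final_fc_fit` (Pearson r and MSE vs the empirical FC), `fc_emp`,
#'   `fs_emp`, `converged`, `n_iter`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_gec <- function(structural, runs, config = gec_fit_config(),
                    init = NULL, omega = NULL, targets = NULL) {
  n <- nrow(structural)
  if (is.null(omega)) omega <- estimate_intrinsic_frequencies(runs, config$freq_band)
  tr <- run_tr(runs[[1]])
  g <- config$g
  if (is.null(g)) {
    g <- sweep_g(structural, hopf_params(a = config$a, omega = omega, beta = config$beta),
                 runs, g_grid = config$g_grid, band = config$sweep_band)
  }
  params <- hopf_params(a = config$a, omega = omega, G = as.numeric(g),
                        beta = config$beta)
  tau_s <- config$tau * tr
  if (!is.null(targets)) {
    fc_emp <- targets$fc
    fs_emp <- targets$fs
  } else if (config$fc_mode == "phase") {
    pcs <- lapply(runs, phase_coherence, band = config$band %||% c(0.04, 0.07))
    fc_emp <- Reduce(`+`, pcs) / length(pcs)
    fs_emp <- empirical_fs(runs, tau = config$tau, band = config$band)
  } else {
    fc_emp <- empirical_fc(runs, band = config$band)
    fs_emp <- empirical_fs(runs, tau = config$tau, band = config$band)
  }
  xform <- if (config$mi_transform) mi_transform else identity
  fc_t <- xform(fc_emp)
  fs_t <- xform(pmin(pmax(fs_emp, -1 + 1e-9), 1 - 1e-9))

  support <- if (config$update_support == "structural") {
    unclass(structural) > 0
  } else {
    matrix(TRUE, n, n)
  }
  diag(support) <- FALSE

  offd <- !diag(n)
  model_mats <- function(C) {
    lin <- linearize_hopf(C, params)
    list(fc = model_fc(lin), fs = model_fs(lin, tau_s))
  }
  fit_error <- function(mm) {
    dfc <- fc_t - xform(mm$fc)
    dfs <- fs_t - xform(pmin(pmax(mm$fs, -1 + 1e-9), 1 - 1e-9))
    0.5 * (mean(dfc[upper.tri(dfc)]^2) + mean(dfs[offd]^2))
  }

  C <- unclass(init %||% structural)
  mm <- model_mats(C)
  err <- fit_error(mm)
  trace <- list(tibble::tibble(iteration = 0L, error = err,
                               epsilon = config$epsilon, accepted = TRUE))
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    eps <- config$epsilon
    accepted <- FALSE
    for (h in 0:config$max_halvings) {
      delta <- eps * ((fc_t - xform(mm$fc)) +
                        (fs_t - xform(pmin(pmax(mm$fs, -1 + 1e-9), 1 - 1e-9))))
      Cnew <- C
      Cnew[support] <- pmax(C[support] + delta[support], 0)
      mm_new <- tryCatch(model_mats(Cnew), error = function(e) NULL)
      if (!is.null(mm_new)) {
        err_new <- fit_error(mm_new)
        if (err_new <= err) {
          rel <- if (err > 0) (err - err_new) / err else 0
          C <- Cnew
          mm <- mm_new
          err <- err_new
          accepted <- TRUE
          trace[[length(trace) + 1]] <- tibble::tibble(
            iteration = iter, error = err, epsilon = eps, accepted = TRUE)
          if (rel < config$convergence_tol) converged <- TRUE
          break
        }
      }
      eps <- eps / 2
    }
    if (!accepted) {
      trace[[length(trace) + 1]] <- tibble::tibble(
        iteration = iter, error = err, epsilon = eps, accepted = FALSE)
      converged <- TRUE
    }
    if (converged) break
  }

  gec <- C
  dimnames(gec) <- dimnames(structural)
  attr(gec, "kind") <- "gec"
  fc_mod <- mm$fc
  fit_r <- suppressWarnings(stats::cor(upper_vals(fc_emp), upper_vals(fc_mod)))
  fit_mse <- mean((upper_vals(fc_emp) - upper_vals(fc_mod))^2)
  structure(list(gec = gec, g_opt = as.numeric(g), params = params,
                 trace = dplyr::bind_rows(trace),
                 final_fc_fit = list(r = fit_r, mse = fit_mse),
                 fc_emp = fc_emp, fs_emp = fs_emp,
                 converged = converged, n_iter = iter, config = config),
            class = "gec_fit")
}

#' @export
print.gec_fit <- function(x, ...) {
  cat("<gec_fit> ", nrow(x$gec), " regions, G = ", x$g_opt,
      ", ", x$n_iter, " iterations",
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      "  final error ", signif(utils::tail(x$trace$error, 1), 4),
      "; model-vs-empirical FC: r = ", signif(x$final_fc_fit$r, 3),
      ", MSE = ", signif(x$final_fc_fit$mse, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy methods for GEC fits
#'
#' `tidy()` returns the per-iteration error trace; `glance()` a one-row
#' model summary.
#'
#' @param x A `gec_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gec_fit
#' @export
tidy.gec_fit <- function(x, ...) x$trace

#' @rdname tidy.gec_fit
#' @method glance gec_fit
#' @export
glance.gec_fit <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x$gec),
    g_opt = x$g_opt,
    n_iter = x$n_iter,
    converged = x$converged,
    initial_error = x$trace$error[1],
    final_error = utils::tail(x$trace$error, 1),
    fc_r = x$final_fc_fit$r,
    fc_mse = x$final_fc_fit$mse,
    asymmetry = asymmetry_index(x$gec)
  )
}

#' Asymmetry index of a coupling matrix
#'
#' `||C - C'|| / ||C + C'||` (Frobenius); 0 for symmetric matrices.
#'
#' @param m Square matrix.
#' @return Scalar in `[0, 1]`.
#' @export
asymmetry_index <- function(m) {
  m <- unclass(m)
  s <- norm(m + t(m), "F")
  if (s == 0) return(0)
  norm(m - t(m), "F") / s
}
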