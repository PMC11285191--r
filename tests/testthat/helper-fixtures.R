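# Shared fixtures, built in code. The heavier cohort objects are memoized in
# a session cache so several test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_parcellation <- function(n = 8, n_networks = 2) {
  make_parcellation(n, n_networks)
}

# a small deterministic symmetric FC-like matrix with unit diagonal
toy_fc <- function(n = 8, seed = 1, scale = 0.6) {
  set.seed(seed)
  A <- matrix(rnorm(n * n, 0, scale / 2), n)
  A <- tanh((A + t(A)) / 2)
  diag(A) <- 1
  A
}

# small synthetic cohort (20 regions) shared by gec / lesion tests
small_cohorts <- function() {
  memo("small_cohorts", {
    make_cohorts(synthetic_study_config(
      n_regions = 20, n_networks = 4, n_healthy = 6, n_patients = 4,
      run_length_timepoints = 448, seed = 11
    ))
  })
}

# ground-truth recovery setup used by the GEC tests (20 nodes, 20 subjects)
recovery_setup <- function() {
  memo("recovery_setup", {
    cfg <- synthetic_study_config(n_regions = 20, n_networks = 4,
                                  n_healthy = 20, n_patients = 0, seed = 3)
    parc <- make_parcellation(20, 4)
    sc <- make_structural_connectome(parc, cfg)
    truth <- make_ground_truth_gec(sc, sd = 0.3, seed = 297)
    set.seed(298)
    omega <- 2 * pi * runif(20, 0.04, 0.07)
    tp <- hopf_params(a = -0.01, omega = omega, G = 0.75, beta = 0.04)
    runs <- lapply(1:20, function(s) {
      simulate_hopf(truth, tp, 896, tr = 2, seed = 3000 + s)
    })
    list(parc = parc, sc = sc, truth = truth, omega = omega,
         params = tp, runs = runs)
  })
}

fitted_recovery <- function() {
  memo("fitted_recovery", {
    rs <- recovery_setup()
    fit_gec(rs$sc, rs$runs, gec_fit_config(), omega = rs$omega)
  })
}

# the full default-condition study used by the acceptance tests
acceptance_study <- function() {
  memo("acceptance_study", run_study(synthetic_study_config(seed = 1)))
}
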