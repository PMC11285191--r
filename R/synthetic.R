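#' Synthetic study configuration
#'
#' Defines the conditions of a fully seeded synthetic study: a modular,
#' hemispherically symmetric connectome; healthy BOLD generated by a
#' ground-truth Hopf + GEC model with node frequencies in the 0.04-0.07 Hz
#' band at TR = 2 s; focal lesions producing spatially contiguous
#' disconnection masks; and behaviour scores linearly coupled to total
#' disconnection plus Gaussian noise. One seed determines every output, and
#' each subject draws from its own derived RNG stream, so e.g. changing
#' `n_patients` leaves the healthy cohort bit-identical.
#'
#' @param n_regions Even region count (default 40).
#' @param n_networks Number of resting-state networks (default 4; DAN and
#'   DMN always included).
#' @param n_healthy,n_patients Cohort sizes (defaults 20 and 20).
#' @param lesion_size_range Lesion-core size as a fraction of one
#'   hemisphere's regions, `c(min, max)` in (0, 1] (default `c(0.1, 0.3)`).
#' @param run_length_timepoints Samples per run (default 896).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param seed Master seed (default 1).
#' @param behaviour_noise_sd SD of the Gaussian noise added to behaviour
#'   scores (default 0.3).
#' @param ground_truth_G Global coupling of the generating model
#'   (default 0.75).
#' @param ground_truth_beta Noise SD of the generating model (default 0.04).
#' @param gec_perturbation_sd SD of the log-normal asymmetric perturbation
#'   that turns the structural connectome into the ground-truth GEC
#'   (default 0.3).
#' @param n_domains Number of behaviour domains (default 3).
#' @return List of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_regions = 40, n_networks = 4,
                                   n_healthy = 20, n_patients = 20,
                                   lesion_size_range = c(0.1, 0.3),
                                   run_length_timepoints = 896,
                                   tr_seconds = 2, seed = 1,
                                   behaviour_noise_sd = 0.3,
                                   ground_truth_G = 0.75,
                                   ground_truth_beta = 0.04,
                                   gec_perturbation_sd = 0.3,
                                   n_domains = 3) {
  if (n_regions %% 2 != 0) stop("n_regions must be even")
  if (any(lesion_size_range <= 0) || any(lesion_size_range > 1)) {
    stop("lesion_size_range must lie in (0, 1]")
  }
  structure(list(n_regions = n_regions, n_networks = n_networks,
                 n_healthy = n_healthy, n_patients = n_patients,
                 lesion_size_range = lesion_size_range,
                 run_length_timepoints = run_length_timepoints,
                 tr_seconds = tr_seconds, seed = seed,
                 behaviour_noise_sd = behaviour_noise_sd,
                 ground_truth_G = ground_truth_G,
                 ground_truth_beta = ground_truth_beta,
                 gec_perturbation_sd = gec_perturbation_sd,
                 n_domains = n_domains),
            class = "synthetic_study_config")
}

# Deterministic sub-seeds: each study component owns an offset of the master
# seed, so components are reproducible independently of one another.
sub_seed <- function(seed, offset) (seed * 97L + offset) %% .Machine$integer.max

#' Generate a synthetic modular structural connectome
#'
#' Symmetric, nonnegative, zero-diagonal weights with three features real
#' group connectomes show and the downstream metrics rely on: (i) stronger
#' within-network than between-network coupling (modularity), (ii) an extra
#' weight bonus on homotopic left/right mirror pairs (so inter-hemispheric
#' homotopic FC is a meaningful signature), and (iii) graph connectedness.
#' Weights carry log-normal heterogeneity and the matrix is rescaled so its
#' maximum entry is exactly 0.2.
#'
#' @param parc A [parcellation()] from [make_parcellation()].
#' @param config A [synthetic_study_config()].
#' @param p_within,p_between Edge probabilities within/between networks.
#' @param w_within,w_between,w_homotopic Mean weights of the three classes.
#' @return Structural [connectome()] (max weight 0.2).
#' @export
make_structural_connectome <- function(parc, config,
                                       p_within = 0.9, p_between = 0.3,
                                       w_within = 1, w_between = 0.25,
                                       w_homotopic = 1.4) {
  n <- nrow(parc)
  set.seed(sub_seed(config$seed, 5L))
  same_net <- outer(parc$network, parc$network, `==`)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p_edge <- if (same_net[i, j]) p_within else p_between
      if (runif(1) < p_edge) {
        base <- if (same_net[i, j]) w_within else w_between
        W[i, j] <- base * exp(rnorm(1, 0, 0.3))
      }
    }
  }
  hp <- homotopic_pairs(parc)
  for (k in seq_len(nrow(hp))) {
    W[hp$i[k], hp$j[k]] <- w_homotopic * exp(rnorm(1, 0, 0.15))
  }
  W <- W + t(W)
  # guarantee connectedness: weakly chain any leftover components together
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1) {
    reps <- vapply(seq_len(comp$no), function(k) which(comp$membership == k)[1], integer(1))
    for (k in seq_len(length(reps) - 1)) {
      W[reps[k], reps[k + 1]] <- W[reps[k + 1], reps[k]] <- w_between / 2
    }
  }
  diag(W) <- 0
  connectome(scale_connectome(W, 0.2), parc, kind = "structural")
}

#' Perturb a structural connectome into a ground-truth GEC
#'
#' Applies independent multiplicative log-normal perturbations to each
#' direction of every nonzero entry, yielding an asymmetric matrix with the
#' structural sparsity pattern — the directed ground truth the GEC fit is
#' asked to recover. With `sd = 0` the output equals the input.
#'
#' @param structural Structural [connectome()].
#' @param sd Log-scale SD of the perturbation.
#' @param seed Integer seed.
#' @return Connectome of kind `"gec"`.
#' @export
make_ground_truth_gec <- function(structural, sd = 0.3, seed = 1) {
  set.seed(seed)
  C <- unclass(structural)
  nz <- C > 0
  pert <- matrix(exp(rnorm(length(C), 0, sd)), nrow(C))
  C[nz] <- C[nz] * pert[nz]
  attr(C, "kind") <- "gec"
  C
}

#' Generate a focal synthetic lesion and its disconnection mask
#'
#' Picks a contiguous-in-index block of regions within one hemisphere as the
#' lesion core (size drawn from `lesion_size_range` as a fraction of that
#' hemisphere). Spared fractions: 0 where both endpoints are in the core,
#' uniform in \[0, 0.5\] where exactly one endpoint is in the core and the
#' pair carries structural streamlines (partial spillover — a lesion can
#' only sever fibers that exist), 1 elsewhere; symmetric with unit
#' diagonal.
#'
#' @param parc A [parcellation()].
#' @param config A [synthetic_study_config()].
#' @param seed Integer seed for this lesion.
#' @param patient_id Optional identifier.
#' @param structural Optional structural connectome; when supplied, partial
#'   spillover is restricted to structurally connected pairs.
#' @return An [sdc_mask()] with the lesioned-region indices attached as
#'   attribute `"core"`.
#' @export
make_lesion <- function(parc, config, seed = 1, patient_id = NULL,
                        structural = NULL) {
  set.seed(seed)
  n <- nrow(parc)
  hemi <- sample(c("left", "right"), 1)
  hemi_idx <- which(parc$hemisphere == hemi)
  nh <- length(hemi_idx)
  frac <- runif(1, config$lesion_size_range[1], config$lesion_size_range[2])
  size <- max(1L, round(frac * nh))
  start <- sample.int(nh - size + 1L, 1)
  core <- hemi_idx[start:(start + size - 1L)]
  spared <- matrix(1, n, n)
  in_core <- seq_len(n) %in% core
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (in_core[i] && in_core[j]) {
        spared[i, j] <- spared[j, i] <- 0
      } else if (in_core[i] || in_core[j]) {
        connected <- is.null(structural) || unclass(structural)[i, j] > 0
        if (connected) spared[i, j] <- spared[j, i] <- runif(1, 0, 0.5)
      }
    }
  }
  m <- sdc_mask(spared, parc, patient_id = patient_id)
  attr(m, "core") <- core
  m
}

#' Generate full synthetic cohorts
#'
#' Builds the parcellation, structural connectome and ground-truth GEC, then
#' simulates the healthy cohort from the ground-truth model and each patient
#' from the ground-truth GEC elementwise-multiplied by that patient's spared
#' (SDC) matrix. Behaviour scores per domain are linear in the patient's
#' total-disconnection score (negative slope: more disconnection, larger
#' deficit) plus Gaussian noise. Every subject, lesion and noise draw has
#' its own seed stream derived from `config$seed`.
#'
#' @param config A [synthetic_study_config()].
#' @return List of class `synthetic_cohorts` with elements `parcellation`,
#'   `structural`, `true_gec`, `true_params`, `healthy_runs`,
#'   `patient_runs`, `masks`, `behaviour` (tibble patient x domain, long),
#'   `total_disconnection` (named vector), and `config`.
#' @export
make_cohorts <- function(config) {
  parc <- make_parcellation(config$n_regions, config$n_networks)
  structural <- make_structural_connectome(parc, config)
  true_gec <- make_ground_truth_gec(structural, sd = config$gec_perturbation_sd,
                                    seed = sub_seed(config$seed, 6L))
  set.seed(sub_seed(config$seed, 7L))
  omega <- 2 * pi * runif(config$n_regions, 0.04, 0.07)
  true_params <- hopf_params(a = -0.01, omega = omega, G = config$ground_truth_G,
                             beta = config$ground_truth_beta)

  set.seed(sub_seed(config$seed, 1L))
  healthy_seeds <- sample.int(.Machine$integer.max - 1L, config$n_healthy)
  set.seed(sub_seed(config$seed, 2L))
  patient_seeds <- sample.int(.Machine$integer.max - 1L, max(config$n_patients, 1L))
  set.seed(sub_seed(config$seed, 3L))
  lesion_seeds <- sample.int(.Machine$integer.max - 1L, max(config$n_patients, 1L))

  healthy_runs <- lapply(seq_len(config$n_healthy), function(i) {
    simulate_hopf(true_gec, true_params, config$run_length_timepoints,
                  tr = config$tr_seconds, seed = healthy_seeds[i],
                  subject_id = sprintf("H%02d", i))
  })

  patient_ids <- sprintf("P%02d", seq_len(config$n_patients))
  masks <- lapply(seq_len(config$n_patients), function(i) {
    make_lesion(parc, config, seed = lesion_seeds[i], patient_id = patient_ids[i],
                structural = structural)
  })
  names(masks) <- patient_ids
  patient_runs <- lapply(seq_len(config$n_patients), function(i) {
    lesioned <- apply_sdc(true_gec, masks[[i]])
    simulate_hopf(lesioned, true_params, config$run_length_timepoints,
                  tr = config$tr_seconds, seed = patient_seeds[i],
                  subject_id = patient_ids[i])
  })
  names(patient_runs) <- patient_ids

  tds <- vapply(masks, total_disconnection, numeric(1))
  set.seed(sub_seed(config$seed, 4L))
  slopes <- -(0.03 + 0.03 * seq_len(config$n_domains))
  behaviour <- purrr::map_dfr(seq_len(config$n_domains), function(d) {
    tibble::tibble(
      patient_id = patient_ids,
      domain = sprintf("domain_%s", letters[d]),
      score = slopes[d] * tds + rnorm(config$n_patients, 0, config$behaviour_noise_sd)
    )
  })

  structure(list(parcellation = parc, structural = structural,
                 true_gec = true_gec, true_params = true_params,
                 healthy_runs = healthy_runs, patient_runs = patient_runs,
                 masks = masks, behaviour = behaviour,
                 total_disconnection = tds, config = config),
            class = "synthetic_cohorts")
}

#' @export
print.synthetic_cohorts <- function(x, ...) {
  cat("<synthetic_cohorts> ", x$config$n_regions, " regions, ",
      length(x$healthy_runs), " healthy, ", length(x$patient_runs),
      " patients, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to a directory
#'
#' Serializes every object in the core text formats (parcellation TSV,
#' matrix TSVs with YAML sidecars, run TSVs, behaviour TSV) plus a
#' `manifest.json` listing every file and the seed.
#'
#' @param cohorts A [make_cohorts()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(cohorts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wp <- function(rel) {
    files <<- c(files, rel)
    file.path(dir, rel)
  }
  write_parcellation(cohorts$parcellation, wp("parcellation.tsv"))
  write_matrix_tsv(cohorts$structural, wp("structural.tsv"),
                   meta = list(kind = "structural"))
  write_matrix_tsv(cohorts$true_gec, wp("true_gec.tsv"), meta = list(kind = "gec"))
  dir.create(file.path(dir, "healthy"), showWarnings = FALSE)
  for (i in seq_along(cohorts$healthy_runs)) {
    write_bold_run(cohorts$healthy_runs[[i]], wp(sprintf("healthy/H%02d.tsv", i)))
  }
  dir.create(file.path(dir, "patients"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  for (id in names(cohorts$patient_runs)) {
    write_bold_run(cohorts$patient_runs[[id]], wp(sprintf("patients/%s.tsv", id)))
    write_matrix_tsv(cohorts$masks[[id]], wp(sprintf("masks/%s_sdc.tsv", id)),
                     meta = list(kind = "sdc", patient_id = id))
  }
  readr::write_tsv(cohorts$behaviour, wp("behaviour.tsv"))
  jsonlite::write_json(
    list(seed = cohorts$config$seed, n_regions = cohorts$config$n_regions,
         tr_seconds = cohorts$config$tr_seconds, files = files),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
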