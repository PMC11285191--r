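#' Apply a structural-disconnection mask to a connectome
#'
#' Elementwise product of coupling weights with the symmetric spared-fraction
#' matrix: both directions of an asymmetric GEC entry are multiplied by the
#' same spared fraction, because severed streamlines are direction-blind.
#' No refitting takes place — this single operation is how the healthy model
#' is "lesioned" into a patient model.
#'
#' @param gec Connectome matrix (structural or GEC).
#' @param mask An [sdc_mask()] of matching dimension.
#' @return Masked connectome with the input's `kind` attribute.
#' @export
apply_sdc <- function(gec, mask) {
  if (!all(dim(gec) == dim(mask))) stop("gec and mask dimensions differ")
  out <- unclass(gec) * unclass(mask)
  diag(out) <- 0
  dimnames(out) <- dimnames(gec)
  attr(out, "kind") <- attr(gec, "kind")
  out
}

#' Total-disconnection score of an SDC mask
#'
#' Pairwise disconnections (`1 - spared`) are binarized at the threshold
#' (default 1%); a region counts as disconnected if any incident pair
#' exceeds it, and the score is the number of such regions.
#'
#' @param mask An [sdc_mask()].
#' @param threshold Disconnection fraction above which a pair counts
#'   (default 0.01).
#' @return Integer count of disconnected regions.
#' @export
total_disconnection <- function(mask, threshold = 0.01) {
  disc <- 1 - unclass(mask)
  diag(disc) <- 0
  sum(apply(disc > threshold, 1, any))
}

#' Assign surrogate masks by a seeded derangement
#'
#' Every patient receives the disconnection mask of another patient (no
#' fixed points), so lesion severity is preserved on average while the
#' lesion's location/pattern is wrong — the control condition for testing
#' whether accuracy depends on the *specific* lesion.
#'
#' @param patient_ids Character vector (length >= 2).
#' @param seed Integer seed.
#' @return Named character vector: `result[p]` is the id whose mask patient
#'   `p` receives.
#' @export
assign_surrogate_masks <- function(patient_ids, seed = 1) {
  n <- length(patient_ids)
  if (n < 2) stop("a derangement needs at least 2 patients")
  set.seed(seed)
  repeat {
    perm <- sample.int(n)
    if (!any(perm == seq_len(n))) break
  }
  stats::setNames(patient_ids[perm], patient_ids)
}

#' Build one of the five patient model connectomes
#'
#' * `full_predictive` — healthy GEC masked by the patient's own SDC.
#' * `no_mask` — the unmodified healthy GEC (identical for all patients).
#' * `surrogate_mask` — healthy GEC masked by another patient's SDC.
#' * `g_dsc` — the structural connectome (no GEC fitting; only the healthy
#'   `G` from the sweep is reused) masked by the patient's own SDC.
#' * `patient_specific` — a GEC refit on the patient's own runs, initialized
#'   from the lesion-masked structural connectome (non-predictive: it uses
#'   the patient's functional data).
#'
#' @param model_type One of the five names above.
#' @param patient_id Patient whose model is built.
#' @param healthy_fit A [fit_gec()] result for the healthy group.
#' @param structural Structural connectome.
#' @param masks Named list of [sdc_mask()]s keyed by patient id.
#' @param patient_runs Named list of the patients' own [bold_run()]s
#'   (required for `patient_specific` only).
#' @param surrogate_map Named mapping from [assign_surrogate_masks()]
#'   (required for `surrogate_mask`).
#' @param refit_config Optional [gec_fit_config()] for the
#'   `patient_specific` refit; defaults to the healthy fit's config with
#'   the healthy `g_opt` fixed.
#' @return List with elements `connectome` (the matrix to simulate from)
#'   and `params` (the [hopf_params()] to use, the healthy-fit parameters).
#' @export
build_patient_model <- function(model_type = c("full_predictive", "no_mask",
                                               "surrogate_mask", "g_dsc",
                                               "patient_specific"),
                                patient_id, healthy_fit, structural, masks,
                                patient_runs = NULL, surrogate_map = NULL,
                                refit_config = NULL) {
  model_type <- match.arg(model_type)
  params <- healthy_fit$params
  conn <- switch(
    model_type,
    full_predictive = apply_sdc(healthy_fit$gec, masks[[patient_id]]),
    no_mask = healthy_fit$gec,
    surrogate_mask = {
      if (is.null(surrogate_map)) stop("surrogate_mask requires surrogate_map")
      src <- surrogate_map[[patient_id]]
      if (identical(src, patient_id)) stop("surrogate mask source equals patient")
      apply_sdc(healthy_fit$gec, masks[[src]])
    },
    g_dsc = apply_sdc(unclass(structural), masks[[patient_id]]),
    patient_specific = {
      if (is.null(patient_runs[[patient_id]])) {
        stop("patient_specific requires the patient's own runs")
      }
      cfg <- refit_config %||% healthy_fit$config
      cfg$g <- healthy_fit$g_opt
      masked <- apply_sdc(unclass(structural), masks[[patient_id]])
      refit <- fit_gec(structural, list(patient_runs[[patient_id]]),
                       config = cfg, init = masked,
                       omega = healthy_fit$params$omega)
      refit$gec
    }
  )
  list(connectome = conn, params = params, model_type = model_type,
       patient_id = patient_id)
}
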