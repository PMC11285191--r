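#' Accuracy split by direct vs indirect structural connection
#'
#' Computes the empirical-vs-simulated FC correlation separately over pairs
#' with a direct structural connection (nonzero weight) and pairs connected
#' only indirectly (zero weight). Gauges how much of the model's accuracy
#' rides on the explicit structural scaffold.
#'
#' @param fc_emp,fc_sim FC matrices for one subject.
#' @param structural Structural connectome defining direct pairs.
#' @return One-row tibble: `r_direct`, `r_indirect`, `n_direct`,
#'   `n_indirect`; an empty pair set yields `NA` for its correlation.
#' @export
split_accuracy_by_connection <- function(fc_emp, fc_sim, structural) {
  ut <- upper.tri(structural)
  direct <- unclass(structural)[ut] > 0
  a <- unclass(fc_emp)[ut]
  b <- unclass(fc_sim)[ut]
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  tibble::tibble(
    r_direct = safe_cor(a[direct], b[direct]),
    r_indirect = safe_cor(a[!direct], b[!direct]),
    n_direct = sum(direct),
    n_indirect = sum(!direct)
  )
}

#' Within-subject ANOVA comparing model types
#'
#' One-way repeated-measures ANOVA of per-patient accuracy across model
#' types, followed by pairwise paired t-tests with Bonferroni correction
#' for the post-hoc family.
#'
#' @param accuracy_table Tibble with columns `patient_id`, `model_type`,
#'   `accuracy_r`, balanced (every model for every patient).
#' @return List: `anova` (one-row tibble `df_model`, `df_error`,
#'   `statistic`, `p_value`), `posthoc` (tibble `model_a`, `model_b`,
#'   `statistic`, `df`, `p_value`, `p_bonferroni`).
#' @export
compare_models_anova <- function(accuracy_table) {
  tbl <- dplyr::arrange(accuracy_table, .data$model_type, .data$patient_id)
  counts <- table(tbl$model_type, tbl$patient_id)
  if (length(unique(tbl$model_type)) < 2) stop("need >= 2 model types")
  if (any(counts != 1)) stop("unbalanced table: each patient needs one row per model type")
  tbl$model_type <- factor(tbl$model_type)
  tbl$patient_id <- factor(tbl$patient_id)
  fit <- stats::aov(accuracy_r ~ model_type + Error(patient_id),
                    data = tbl)
  s <- summary(fit)[["Error: Within"]][[1]]
  f_stat <- s["model_type", "F value"]
  p_val <- s["model_type", "Pr(>F)"]
  if (!is.finite(f_stat) || s["model_type", "Sum Sq"] < 1e-12) {
    # accuracies identical across model types up to rounding
    f_stat <- 0
    p_val <- 1
  }
  anova_row <- tibble::tibble(
    df_model = s["model_type", "Df"],
    df_error = s["Residuals", "Df"],
    statistic = f_stat,
    p_value = p_val
  )
  types <- levels(tbl$model_type)
  pairs <- utils::combn(types, 2)
  m <- ncol(pairs)
  posthoc <- purrr::map_dfr(seq_len(m), function(k) {
    a <- tbl$accuracy_r[tbl$model_type == pairs[1, k]]
    b <- tbl$accuracy_r[tbl$model_type == pairs[2, k]]
    d <- a - b
    if (stats::sd(d) == 0) {
      return(tibble::tibble(model_a = pairs[1, k], model_b = pairs[2, k],
                            statistic = 0, df = length(d) - 1, p_value = 1))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    tibble::tibble(model_a = pairs[1, k], model_b = pairs[2, k],
                   statistic = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value)
  })
  posthoc$p_bonferroni <- pmin(posthoc$p_value * m, 1)
  list(anova = anova_row, posthoc = posthoc)
}

#' Run a full synthetic study end to end
#'
#' Orchestrates the whole pipeline under a single seed: generate the
#' synthetic cohorts; estimate node frequencies and sweep the global
#' coupling on the healthy group; fit the healthy GEC; build each requested
#' patient model (full predictive, no-mask, surrogate-mask, G-DSC,
#' patient-specific); simulate BOLD and FC for every subject and model;
#' score accuracies, z-scored FC abnormalities, stroke-signature
#' correlations, graph metrics, accuracy-vs-severity correlations, the
#' direct/indirect split, the within-subject model ANOVA with Bonferroni
#' post-hocs, and the PLSR behaviour/accuracy predictions.
#'
#' @param config A [synthetic_study_config()].
#' @param models Character vector of patient model types to evaluate.
#' @param gec_config A [gec_fit_config()] (default `gec_fit_config()`;
#'   the G sweep runs inside the fit when `g` is `NULL`).
#' @param graph_threshold,graph_method Graph binarization for the metrics,
#'   see [binarize_fc()].
#' @param m_bins Bins for FC entropy.
#' @param plsr_components Latent components for the PLSR analyses.
#' @param out_dir Optional directory: report JSON and per-figure TSV tables
#'   are written there via [write_study_report()].
#' @return Object of class `study_report`; see [glance.study_report()].
#' @export
run_study <- function(config = synthetic_study_config(),
                      models = c("full_predictive", "no_mask",
                                 "surrogate_mask", "g_dsc", "patient_specific"),
                      gec_config = gec_fit_config(),
                      graph_threshold = 0.25, graph_method = "absolute",
                      m_bins = 50, plsr_components = 5,
                      out_dir = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  cohorts <- make_cohorts(config)
  parc <- cohorts$parcellation
  structural <- cohorts$structural
  n_pat <- config$n_patients

  omega <- estimate_intrinsic_frequencies(cohorts$healthy_runs, gec_config$freq_band)
  healthy_fit <- fit_gec(structural, cohorts$healthy_runs, gec_config,
                         omega = omega)

  # --- healthy accuracy: one simulated run per healthy subject ------------
  set.seed(sub_seed(config$seed, 8L))
  h_sim_seeds <- sample.int(.Machine$integer.max - 1L, config$n_healthy)
  healthy_fc_emp <- lapply(cohorts$healthy_runs, function(r) empirical_fc(list(r)))
  healthy_fc_sim <- lapply(seq_len(config$n_healthy), function(i) {
    run <- simulate_hopf(healthy_fit$gec, healthy_fit$params,
                         config$run_length_timepoints, tr = config$tr_seconds,
                         seed = h_sim_seeds[i])
    empirical_fc(list(run))
  })
  healthy_accuracy <- purrr::map_dfr(seq_len(config$n_healthy), function(i) {
    dplyr::mutate(model_accuracy(healthy_fc_emp[[i]], healthy_fc_sim[[i]]),
                  subject_id = sprintf("H%02d", i), .before = 1)
  })

  report <- list(config = config, models = models,
                 healthy_fit = healthy_fit, cohorts = cohorts,
                 parcellation = parc, g_opt = healthy_fit$g_opt,
                 omega = omega, healthy_accuracy = healthy_accuracy,
                 graph_threshold = graph_threshold,
                 graph_method = graph_method, m_bins = m_bins)
  class(report) <- "study_report"
  if (n_pat == 0) {
    report$accuracy <- tibble::tibble(patient_id = character(),
                                      model_type = character(),
                                      accuracy_r = numeric(), mse = numeric())
    if (!is.null(out_dir)) write_study_report(report, out_dir)
    return(report)
  }

  patient_ids <- names(cohorts$patient_runs)
  patient_fc_emp <- lapply(cohorts$patient_runs, function(r) empirical_fc(list(r)))
  surrogate_map <- if ("surrogate_mask" %in% models && n_pat >= 2) {
    assign_surrogate_masks(patient_ids, seed = sub_seed(config$seed, 10L))
  }
  set.seed(sub_seed(config$seed, 9L))
  sim_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_pat * length(models)),
                      n_pat, length(models), dimnames = list(patient_ids, models))

  patient_fc_sim <- list()
  accuracy <- purrr::map_dfr(models, function(mt) {
    purrr::map_dfr(patient_ids, function(pid) {
      pm <- build_patient_model(mt, pid, healthy_fit, structural,
                                cohorts$masks, cohorts$patient_runs,
                                surrogate_map)
      run <- simulate_hopf(pm$connectome, pm$params,
                           config$run_length_timepoints,
                           tr = config$tr_seconds, seed = sim_seeds[pid, mt])
      fc <- empirical_fc(list(run))
      patient_fc_sim[[mt]][[pid]] <<- fc
      dplyr::mutate(model_accuracy(patient_fc_emp[[pid]], fc),
                    patient_id = pid, model_type = mt, .before = 1)
    })
  })
  accuracy <- dplyr::rename(accuracy, accuracy_r = "r")
  report$accuracy <- accuracy
  report$patient_fc_emp <- patient_fc_emp
  report$patient_fc_sim <- patient_fc_sim

  # --- z-scored FC abnormality (full predictive model) --------------------
  if ("full_predictive" %in% models && config$n_healthy >= 3) {
    zcors <- purrr::map_dfr(patient_ids, function(pid) {
      z_emp <- z_abnormality(patient_fc_emp[[pid]], healthy_fc_emp)
      z_sim <- z_abnormality(patient_fc_sim$full_predictive[[pid]], healthy_fc_sim)
      a <- upper_vals(unclass(z_emp))
      b <- upper_vals(unclass(z_sim))
      ok <- is.finite(a) & is.finite(b)
      sig <- dplyr::bind_cols(
        stats::setNames(signature_abnormality(z_emp, parc),
                        c("homotopic_z_emp", "dan_dmn_z_emp")),
        stats::setNames(signature_abnormality(z_sim, parc),
                        c("homotopic_z_sim", "dan_dmn_z_sim")))
      dplyr::bind_cols(tibble::tibble(patient_id = pid,
                                      z_correlation = stats::cor(a[ok], b[ok])),
                       sig)
    })
    report$z_abnormality <- zcors
  }

  # --- stroke-signature scatter: empirical vs simulated -------------------
  if ("full_predictive" %in% models) {
    signatures <- purrr::map_dfr(patient_ids, function(pid) {
      emp <- fc_metric_record(patient_fc_emp[[pid]], parc, pid,
                              graph_threshold, graph_method, m_bins)
      sim <- fc_metric_record(patient_fc_sim$full_predictive[[pid]], parc, pid,
                              graph_threshold, graph_method, m_bins)
      tibble::tibble(
        patient_id = pid,
        intra_emp = emp$intra_dan_dmn_fc, intra_sim = sim$intra_dan_dmn_fc,
        inter_emp = emp$inter_homotopic_fc, inter_sim = sim$inter_homotopic_fc,
        modularity_emp = emp$modularity, modularity_sim = sim$modularity,
        global_efficiency = emp$global_efficiency,
        fc_entropy = emp$fc_entropy,
        average_degree = emp$average_degree
      )
    })
    report$signatures <- signatures
    sig_cor <- function(a, b) {
      ct <- stats::cor.test(a, b)
      c(r = unname(ct$estimate), p = ct$p.value, mse = mean((a - b)^2))
    }
    report$signature_fit <- tibble::tibble(
      signature = c("intra_dan_dmn", "inter_homotopic", "modularity"),
      r = c(sig_cor(signatures$intra_emp, signatures$intra_sim)["r"],
            sig_cor(signatures$inter_emp, signatures$inter_sim)["r"],
            sig_cor(signatures$modularity_emp, signatures$modularity_sim)["r"]),
      p_value = c(sig_cor(signatures$intra_emp, signatures$intra_sim)["p"],
                  sig_cor(signatures$inter_emp, signatures$inter_sim)["p"],
                  sig_cor(signatures$modularity_emp, signatures$modularity_sim)["p"]),
      mse = c(sig_cor(signatures$intra_emp, signatures$intra_sim)["mse"],
              sig_cor(signatures$inter_emp, signatures$inter_sim)["mse"],
              sig_cor(signatures$modularity_emp, signatures$modularity_sim)["mse"]),
      n = n_pat
    )

    # --- accuracy vs severity / graph metrics -----------------------------
    acc_full <- accuracy$accuracy_r[accuracy$model_type == "full_predictive"]
    names(acc_full) <- accuracy$patient_id[accuracy$model_type == "full_predictive"]
    acc_full <- acc_full[patient_ids]
    sev <- function(x, label) {
      ct <- stats::cor.test(acc_full, x)
      tibble::tibble(measure = label, r = unname(ct$estimate),
                     p_value = ct$p.value, n = n_pat)
    }
    report$severity <- dplyr::bind_rows(
      sev(cohorts$total_disconnection[patient_ids], "total_disconnection"),
      sev(signatures$global_efficiency, "global_efficiency"),
      sev(signatures$fc_entropy, "fc_entropy"),
      sev(signatures$average_degree, "average_degree")
    )

    # --- direct / indirect split ------------------------------------------
    split_models <- intersect(c("full_predictive", "no_mask"), models)
    report$connection_split <- purrr::map_dfr(split_models, function(mt) {
      purrr::map_dfr(patient_ids, function(pid) {
        dplyr::mutate(split_accuracy_by_connection(
          patient_fc_emp[[pid]], patient_fc_sim[[mt]][[pid]], structural),
          patient_id = pid, model_type = mt, .before = 1)
      })
    })
  }

  # --- model comparison ANOVA ---------------------------------------------
  if (length(models) >= 2 && n_pat >= 3) {
    report$model_comparison <- compare_models_anova(accuracy)
  }

  # --- PLSR: behaviour and accuracy ---------------------------------------
  if (n_pat >= 10 && "full_predictive" %in% models && config$n_healthy >= 3) {
    z_emp_list <- lapply(patient_ids, function(pid) {
      z <- z_abnormality(patient_fc_emp[[pid]], healthy_fc_emp)
      z[!is.finite(z)] <- 0
      z
    })
    predictors <- list(
      fc_emp = t(vapply(patient_fc_emp[patient_ids], vectorize_predictor,
                        numeric(nrow(parc) * (nrow(parc) - 1) / 2))),
      fc_sim = t(vapply(patient_fc_sim$full_predictive[patient_ids],
                        vectorize_predictor,
                        numeric(nrow(parc) * (nrow(parc) - 1) / 2))),
      fc_zabn = t(vapply(z_emp_list, vectorize_predictor,
                         numeric(nrow(parc) * (nrow(parc) - 1) / 2))),
      sdc = t(vapply(cohorts$masks[patient_ids], vectorize_predictor,
                     numeric(nrow(parc) * (nrow(parc) - 1) / 2)))
    )
    domains <- unique(cohorts$behaviour$domain)
    report$behaviour_plsr <- purrr::map_dfr(domains, function(dom) {
      y <- cohorts$behaviour$score[cohorts$behaviour$domain == dom]
      purrr::map_dfr(names(predictors), function(nm) {
        fit <- fit_predict_plsr(predictors[[nm]], y,
                                n_components = plsr_components)
        tibble::tibble(domain = dom, predictor = nm, r2_cv = fit$r2_cv,
                       r2_insample = fit$r2_insample)
      })
    })
    acc_full <- accuracy$accuracy_r[accuracy$model_type == "full_predictive"]
    report$accuracy_plsr <- accuracy_regression(acc_full, predictors,
                                                n_components = plsr_components)
  }

  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed ", x$config$seed, ": ", x$config$n_regions,
      " regions, ", x$config$n_healthy, " healthy, ", x$config$n_patients,
      " patients\n  G = ", x$g_opt,
      "; healthy accuracy r = ", signif(mean(x$healthy_accuracy$r), 3), "\n",
      sep = "")
  if (nrow(x$accuracy)) {
    acc <- dplyr::summarise(dplyr::group_by(x$accuracy, .data$model_type),
                            mean_r = mean(.data$accuracy_r))
    for (i in seq_len(nrow(acc))) {
      cat("  ", format(acc$model_type[i], width = 18), " mean r = ",
          signif(acc$mean_r[i], 3), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Tidy methods for study reports
#'
#' `tidy()` returns the per-patient, per-model accuracy table; `glance()` a
#' one-row study summary.
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy study_report
#' @export
tidy.study_report <- function(x, ...) x$accuracy

#' @rdname tidy.study_report
#' @method glance study_report
#' @export
glance.study_report <- function(x, ...) {
  acc_mean <- function(mt) {
    v <- x$accuracy$accuracy_r[x$accuracy$model_type == mt]
    if (length(v)) mean(v) else NA_real_
  }
  tibble::tibble(
    seed = x$config$seed,
    n_regions = x$config$n_regions,
    n_healthy = x$config$n_healthy,
    n_patients = x$config$n_patients,
    g_opt = x$g_opt,
    healthy_accuracy_r = mean(x$healthy_accuracy$r),
    patient_accuracy_r = acc_mean("full_predictive"),
    no_mask_accuracy_r = acc_mean("no_mask"),
    surrogate_accuracy_r = acc_mean("surrogate_mask"),
    g_dsc_accuracy_r = acc_mean("g_dsc"),
    patient_specific_accuracy_r = acc_mean("patient_specific"),
    z_correlation_mean = if (!is.null(x$z_abnormality)) {
      mean(x$z_abnormality$z_correlation)
    } else NA_real_,
    severity_r = if (!is.null(x$severity)) {
      x$severity$r[x$severity$measure == "total_disconnection"]
    } else NA_real_,
    anova_f = if (!is.null(x$model_comparison)) {
      x$model_comparison$anova$statistic
    } else NA_real_,
    anova_p = if (!is.null(x$model_comparison)) {
      x$model_comparison$anova$p_value
    } else NA_real_
  )
}

#' Write a study report to disk
#'
#' Serializes the headline summary (`report.json`) and per-figure TSV
#' tables: healthy/patient accuracy distributions, signature scatter,
#' severity correlations, model comparison and the direct/indirect split.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- glance.study_report(report)
  out <- as.list(g)
  if (!is.null(report$model_comparison)) {
    out$posthoc <- report$model_comparison$posthoc
  }
  if (!is.null(report$behaviour_plsr)) out$behaviour_plsr <- report$behaviour_plsr
  if (!is.null(report$accuracy_plsr)) out$accuracy_plsr <- report$accuracy_plsr
  jsonlite::write_json(out, file.path(dir, "report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  readr::write_tsv(report$healthy_accuracy, file.path(dir, "fig2a_accuracy.tsv"))
  if (!is.null(report$signatures)) {
    readr::write_tsv(report$signatures, file.path(dir, "fig2b_signatures.tsv"))
  }
  if (!is.null(report$severity)) {
    readr::write_tsv(report$severity, file.path(dir, "fig3a_severity.tsv"))
  }
  if (nrow(report$accuracy)) {
    readr::write_tsv(report$accuracy, file.path(dir, "fig4c_models.tsv"))
  }
  if (!is.null(report$connection_split)) {
    readr::write_tsv(report$connection_split, file.path(dir, "fig4d_split.tsv"))
  }
  invisible(dir)
}
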