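#' Plot an FC or connectivity matrix as a heatmap
#'
#' @param m Square matrix (FC, connectome, SDC, z-abnormality).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_fc_matrix <- function(m, title = NULL) {
  d <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$value <- as.vector(t(unclass(m)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = title, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot a GEC fit: error trace over iterations
#'
#' @param object A [fit_gec()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gec_fit
#' @export
autoplot.gec_fit <- function(object, ...) {
  tr <- object$trace[object$trace$accepted, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$error)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "accepted iteration", y = "FC + FS fit error",
                  title = sprintf("GEC fit (G = %.2f)", object$g_opt)) +
    ggplot2::theme_minimal()
}

#' Autoplot a study report: accuracy by model type
#'
#' @param object A [run_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, ...) {
  if (!nrow(object$accuracy)) stop("report has no patient accuracy table")
  ggplot2::ggplot(object$accuracy,
                  ggplot2::aes(x = .data$model_type, y = .data$accuracy_r)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "empirical vs simulated FC (Pearson r)",
                  title = "Model accuracy by patient model type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Accuracy versus lesion severity scatter
#'
#' @param report A [run_study()] result containing the severity section.
#' @return A ggplot object.
#' @export
plot_accuracy_severity <- function(report) {
  if (is.null(report$severity)) stop("report has no severity section")
  acc <- report$accuracy[report$accuracy$model_type == "full_predictive", ]
  d <- tibble::tibble(
    total_disconnection =
      report$cohorts$total_disconnection[acc$patient_id],
    accuracy_r = acc$accuracy_r
  )
  r <- report$severity$r[report$severity$measure == "total_disconnection"]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total_disconnection,
                                  y = .data$accuracy_r)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#b2182b") +
    ggplot2::labs(x = "total disconnection (regions)",
                  y = "model accuracy (r)",
                  title = sprintf("Accuracy vs severity (r = %.2f)", r)) +
    ggplot2::theme_minimal()
}
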