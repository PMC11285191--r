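#' Connectome, SDC-mask and FC-matrix constructors
#'
#' All study matrices are plain numeric matrices whose rows/columns follow
#' the parcellation's region order, with `region_id` dimnames. The
#' constructors validate the type-specific invariants:
#'
#' * `connectome()`: nonnegative, zero diagonal; `kind = "structural"` must
#'   be symmetric, `kind = "gec"` (generative effective connectivity) may be
#'   asymmetric and is never assumed symmetric downstream.
#' * `sdc_mask()`: symmetric, unit diagonal, values in \[0, 1\] — the
#'   fraction of streamlines *spared* by the lesion for each region pair.
#' * `fc_matrix()`: symmetric, unit diagonal, values in \[-1, 1\].
#'
#' @param weights,spared,values Square numeric matrix.
#' @param parc A [parcellation()] whose order defines the rows.
#' @param kind `"structural"` or `"gec"`.
#' @param subject_id,patient_id Optional identifier stored as an attribute.
#' @param source `"empirical"` or `"simulated"` for FC matrices.
#' @param tol Numerical tolerance for symmetry/range checks.
#' @return The validated matrix with a `kind`/`source` attribute.
#' @name study-matrices
NULL

check_square <- function(m, parc = NULL, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop(what, " must be a square matrix")
  if (!is.null(parc) && nrow(m) != nrow(parc)) {
    stop(what, " dimension (", nrow(m), ") does not match parcellation (",
         nrow(parc), " regions)")
  }
  invisible(TRUE)
}

#' @rdname study-matrices
#' @export
connectome <- function(weights, parc = NULL, kind = c("structural", "gec"),
                       tol = 1e-8) {
  kind <- match.arg(kind)
  check_square(weights, parc, "connectome")
  if (any(weights < -tol)) stop("connectome weights must be nonnegative")
  if (any(abs(diag(weights)) > tol)) stop("connectome diagonal must be zero")
  if (kind == "structural" && max(abs(weights - t(weights))) > tol) {
    stop("structural connectome must be symmetric")
  }
  diag(weights) <- 0
  weights[weights < 0] <- 0
  if (!is.null(parc)) dimnames(weights) <- list(parc$region_id, parc$region_id)
  attr(weights, "kind") <- kind
  weights
}

#' @rdname study-matrices
#' @export
sdc_mask <- function(spared, parc = NULL, patient_id = NULL, tol = 1e-8) {
  check_square(spared, parc, "SDC mask")
  if (any(spared < -tol) || any(spared > 1 + tol)) {
    stop("spared fractions must lie in [0, 1]")
  }
  if (max(abs(spared - t(spared))) > tol) stop("SDC mask must be symmetric")
  if (any(abs(diag(spared) - 1) > tol)) stop("SDC mask diagonal must be 1")
  spared <- pmin(pmax(spared, 0), 1)
  diag(spared) <- 1
  if (!is.null(parc)) dimnames(spared) <- list(parc$region_id, parc$region_id)
  attr(spared, "patient_id") <- patient_id
  spared
}

#' @rdname study-matrices
#' @export
fc_matrix <- function(values, parc = NULL, subject_id = NULL,
                      source = c("empirical", "simulated"), tol = 1e-6) {
  source <- match.arg(source)
  check_square(values, parc, "FC matrix")
  if (max(abs(values - t(values))) > tol) stop("FC matrix must be symmetric")
  if (any(abs(diag(values) - 1) > tol)) stop("FC matrix diagonal must be 1")
  if (any(values < -1 - tol) || any(values > 1 + tol)) {
    stop("FC values must lie in [-1, 1]")
  }
  values <- (values + t(values)) / 2
  values <- pmin(pmax(values, -1), 1)
  diag(values) <- 1
  if (!is.null(parc)) dimnames(values) <- list(parc$region_id, parc$region_id)
  attr(values, "subject_id") <- subject_id
  attr(values, "source") <- source
  values
}

#' Scale a connectome to a fixed maximum weight
#'
#' Whole-brain Hopf fitting expects the structural connectome rescaled so its
#' strongest connection equals `max_weight` (default 0.2), which places the
#' usual global-coupling range on a common scale across studies.
#'
#' @param weights Nonnegative square matrix.
#' @param max_weight Target maximum (default 0.2).
#' @return Rescaled matrix.
#' @export
scale_connectome <- function(weights, max_weight = 0.2) {
  mx <- max(weights)
  if (mx <= 0) stop("cannot scale an all-zero connectome")
  weights * (max_weight / mx)
}

#' Strict upper-triangle vector of a square matrix
#'
#' Fixed pair order (column-major over `i < j`), shared by every subject, so
#' vectors from different subjects are comparable feature-by-feature.
#'
#' @param m Square matrix.
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @export
vectorize_predictor <- function(m) {
  check_square(m, what = "predictor")
  m[upper.tri(m)]
}

upper_vals <- function(m) m[upper.tri(m)]

#' Read / write a study matrix as TSV with a YAML sidecar
#'
#' The TSV stores region ids both as header and first column so order is
#' explicit, never positional-only; the sidecar (`<path>.yaml`) records the
#' matrix kind and any identifier.
#'
#' @param m Matrix (rows/cols named by region id).
#' @param path Output TSV path.
#' @param meta Named list written to the sidecar.
#' @return `read_matrix_tsv()` returns the matrix with sidecar entries as
#'   attributes; `write_matrix_tsv()` returns `path` invisibly.
#' @export
write_matrix_tsv <- function(m, path, meta = list()) {
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("r%03d", seq_len(nrow(m)))
  d <- data.frame(region_id = ids, m, check.names = FALSE)
  colnames(d) <- c("region_id", ids)
  readr::write_tsv(d, path)
  meta$kind <- meta$kind %||% attr(m, "kind")
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (length(meta)) yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, colnames(d)[-1])
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    for (k in names(meta)) attr(m, k) <- meta[[k]]
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
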