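#' BOLD run container
#'
#' A regional BOLD run is an `n_regions x n_timepoints` matrix sampled at a
#' fixed repetition time (TR). The TR, subject id and any applied band-pass
#' filter travel with the matrix as attributes.
#'
#' @param signal Numeric matrix, regions x timepoints.
#' @param tr Sampling interval in seconds.
#' @param subject_id Optional identifier.
#' @param band Applied filter band `c(low, high)` in Hz, or `NULL`.
#' @param parc Optional [parcellation()] used to name rows.
#' @return Matrix of class `bold_run`.
#' @export
bold_run <- function(signal, tr, subject_id = NULL, band = NULL, parc = NULL) {
  if (!is.matrix(signal)) stop("signal must be a regions x timepoints matrix")
  if (anyNA(signal) || any(!is.finite(signal))) stop("signal contains non-finite values")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be a positive number of seconds")
  if (!is.null(parc)) {
    if (nrow(signal) != nrow(parc)) stop("signal rows must match parcellation")
    rownames(signal) <- parc$region_id
  }
  structure(signal, tr = tr, subject_id = subject_id, band = band,
            class = c("bold_run", "matrix", "array"))
}

#' @export
print.bold_run <- function(x, ...) {
  cat("<bold_run> ", nrow(x), " regions x ", ncol(x), " timepoints, TR = ",
      attr(x, "tr"), " s", sep = "")
  if (!is.null(attr(x, "subject_id"))) cat(", subject ", attr(x, "subject_id"), sep = "")
  b <- attr(x, "band")
  if (!is.null(b)) cat(", band ", b[1], "-", b[2], " Hz", sep = "")
  cat("\n")
  invisible(x)
}

run_tr <- function(run) {
  tr <- attr(run, "tr")
  if (is.null(tr)) stop("run has no tr attribute; build it with bold_run()")
  tr
}

#' Band-pass filter a BOLD run
#'
#' Zero-phase (forward-backward) second-order Butterworth filter, the
#' standard narrowband step before phase/FC analyses of resting BOLD.
#'
#' @param run A [bold_run()].
#' @param band `c(low, high)` in Hz; must sit below the Nyquist frequency
#'   `1 / (2 TR)`.
#' @return Filtered [bold_run()] with the `band` attribute set.
#' @export
band_filter <- function(run, band = c(0.04, 0.07)) {
  tr <- run_tr(run)
  nyq <- 1 / (2 * tr)
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2]) {
    stop("band must satisfy 0 < low < high < Nyquist (", signif(nyq, 3), " Hz)")
  }
  bf <- signal::butter(2, band / nyq, type = "pass")
  sig <- t(apply(unclass(run), 1, function(x) {
    signal::filtfilt(bf, x - mean(x))
  }))
  bold_run(sig, tr = tr, subject_id = attr(run, "subject_id"), band = band)
}

#' Write / read a BOLD run (TSV + YAML sidecar)
#'
#' @param run A [bold_run()].
#' @param path TSV path; the sidecar `<path>.yaml` stores `tr_seconds`,
#'   `subject_id` and the filter band.
#' @return `read_bold_run()` returns a [bold_run()].
#' @export
write_bold_run <- function(run, path) {
  ids <- rownames(run)
  if (is.null(ids)) ids <- sprintf("r%03d", seq_len(nrow(run)))
  d <- data.frame(region_id = ids, unclass(run), check.names = FALSE)
  colnames(d) <- c("region_id", sprintf("t%04d", seq_len(ncol(run))))
  readr::write_tsv(d, path)
  meta <- list(tr_seconds = attr(run, "tr"))
  if (!is.null(attr(run, "subject_id"))) meta$subject_id <- attr(run, "subject_id")
  if (!is.null(attr(run, "band"))) meta$band <- as.numeric(attr(run, "band"))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_bold_run
#' @export
read_bold_run <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(d[[1]], NULL)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  bold_run(m, tr = meta$tr_seconds, subject_id = meta$subject_id,
           band = if (!is.null(meta$band)) as.numeric(meta$band))
}

#' Validate a study's objects against a shared parcellation
#'
#' Checks that every matrix and run is dimensioned by the parcellation and
#' that the type invariants hold (structural symmetry, SDC range, FC range,
#' homotopic involution). Dimension mismatches are hard errors; invariant
#' violations are returned as rows so a study can be triaged in one pass.
#'
#' @param parc A [parcellation()].
#' @param connectome Optional connectome matrix.
#' @param runs Optional list of [bold_run()]s.
#' @param masks Optional list of SDC matrices.
#' @param fcs Optional list of FC matrices.
#' @return Tibble with columns `object`, `check`, `message`; zero rows means
#'   the study is consistent.
#' @export
validate_study <- function(parc, connectome = NULL, runs = NULL,
                           masks = NULL, fcs = NULL) {
  viol <- list()
  add <- function(object, check, message) {
    viol[[length(viol) + 1]] <<- tibble::tibble(
      object = object, check = check, message = message)
  }
  tol <- 1e-8
  tryCatch(check_homotopic_involution(parc),
           error = function(e) add("parcellation", "homotopic", conditionMessage(e)))
  if (!is.null(connectome)) {
    check_square(connectome, parc, "connectome")
    kind <- attr(connectome, "kind") %||% "structural"
    if (any(connectome < -tol)) add("connectome", "nonnegative", "negative weights present")
    if (any(abs(diag(connectome)) > tol)) add("connectome", "zero-diagonal", "nonzero diagonal")
    if (kind == "structural" && max(abs(connectome - t(connectome))) > tol) {
      add("connectome", "symmetry", "structural must be symmetric")
    }
  }
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    if (nrow(r) != nrow(parc)) {
      stop("run ", i, " has ", nrow(r), " regions; parcellation has ", nrow(parc))
    }
    if (anyNA(r)) add(paste0("run", i), "finite", "missing values in signal")
  }
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    check_square(m, parc, paste0("mask", i))
    if (any(m < -tol) || any(m > 1 + tol)) {
      add(paste0("mask", i), "range", "spared out of [0,1]")
    }
    if (max(abs(m - t(m))) > tol) add(paste0("mask", i), "symmetry", "SDC mask must be symmetric")
    if (any(abs(diag(m) - 1) > tol)) add(paste0("mask", i), "diagonal", "SDC diagonal must be 1")
  }
  for (i in seq_along(fcs)) {
    f <- fcs[[i]]
    check_square(f, parc, paste0("fc", i))
    if (any(abs(f) > 1 + 1e-6)) add(paste0("fc", i), "range", "FC out of [-1,1]")
    if (max(abs(f - t(f))) > 1e-6) add(paste0("fc", i), "symmetry", "FC must be symmetric")
  }
  if (!length(viol)) {
    return(tibble::tibble(object = character(), check = character(),
                          message = character()))
  }
  dplyr::bind_rows(viol)
}
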