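#' Cross-validated PLSR prediction of a response from vectorized matrices
#'
#' Partial least-squares regression of a per-subject response (a behaviour
#' domain score, or per-patient model accuracy) on high-dimensional
#' vectorized predictors (upper triangles of FC / z-abnormality / SDC
#' matrices). The model is refit inside every cross-validation training
#' fold with fold-internal standardization, so no held-out subject leaks
#' into the weights; out-of-fold predictions are pooled and
#' `R^2 = cor(pooled predictions, y)^2`. The in-sample `R^2` of the full
#' fit is also reported. Constant features within a training fold are
#' dropped before fitting.
#'
#' @param X Subjects x features numeric matrix (see
#'   [vectorize_predictor()]).
#' @param y Numeric response, one per subject, no missing values.
#' @param n_components Number of latent components (default 5; capped at
#'   `n_subjects - 2` and at the feature count).
#' @param cv `"loo"` (leave-one-out, default) or `"kfold"`.
#' @param k Folds when `cv = "kfold"` (default 10).
#' @param seed Seed for the k-fold shuffle.
#' @return Object of class `plsr_result`: `predictions` tibble (`subject`,
#'   `observed`, `predicted`), `r2_cv`, `r2_insample`, `n_components`,
#'   `weights` (feature loadings of the full fit, first component).
#' @export
fit_predict_plsr <- function(X, y, n_components = 5, cv = c("loo", "kfold"),
                             k = 10, seed = 1) {
  cv <- match.arg(cv)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (anyNA(y)) stop("y contains missing values")
  if (stats::sd(y) == 0) stop("zero-variance response")
  ncomp <- max(1L, min(n_components, n - 2L, ncol(X)))
  colnames(X) <- colnames(X) %||% sprintf("f%05d", seq_len(ncol(X)))

  folds <- if (cv == "loo") {
    as.list(seq_len(n))
  } else {
    set.seed(seed)
    split(sample.int(n), rep_len(seq_len(k), n))
  }

  pred <- rep(NA_real_, n)
  for (fold in folds) {
    tr_idx <- setdiff(seq_len(n), fold)
    keep <- which(apply(X[tr_idx, , drop = FALSE], 2, stats::sd) > 0)
    if (!length(keep)) {
      pred[fold] <- mean(y[tr_idx])
      next
    }
    nc <- min(ncomp, length(keep), length(tr_idx) - 2L)
    fit <- mixOmics::pls(X[tr_idx, keep, drop = FALSE], y[tr_idx],
                         ncomp = nc, mode = "regression", scale = TRUE)
    p <- stats::predict(fit, X[fold, keep, drop = FALSE])
    pred[fold] <- p$predict[, 1, nc]
  }

  keep_all <- which(apply(X, 2, stats::sd) > 0)
  full <- mixOmics::pls(X[, keep_all, drop = FALSE], y,
                        ncomp = min(ncomp, length(keep_all)),
                        mode = "regression", scale = TRUE)
  in_pred <- stats::predict(full, X[, keep_all, drop = FALSE])
  in_pred <- in_pred$predict[, 1, dim(in_pred$predict)[3]]
  w <- stats::setNames(rep(0, ncol(X)), colnames(X))
  w[keep_all] <- full$loadings$X[, 1]

  structure(list(
    predictions = tibble::tibble(subject = rownames(X) %||% seq_len(n),
                                 observed = y, predicted = pred),
    r2_cv = suppressWarnings(stats::cor(pred, y))^2,
    r2_insample = suppressWarnings(stats::cor(in_pred, y))^2,
    n_components = ncomp, cv = cv, weights = w
  ), class = "plsr_result")
}

#' @export
print.plsr_result <- function(x, ...) {
  cat("<plsr_result> ", nrow(x$predictions), " subjects, ",
      x$n_components, " components, ", x$cv, " CV\n",
      "  R2 (out-of-fold) = ", signif(x$r2_cv, 3),
      ", R2 (in-sample) = ", signif(x$r2_insample, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.gec_fit
#' @method tidy plsr_result
#' @export
tidy.plsr_result <- function(x, ...) x$predictions

#' @rdname tidy.gec_fit
#' @method glance plsr_result
#' @export
glance.plsr_result <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$predictions),
                 n_components = x$n_components, cv = x$cv,
                 r2_cv = x$r2_cv, r2_insample = x$r2_insample)
}

#' Permutation null for a PLSR R-squared
#'
#' Refits the cross-validated PLSR on `n_perm` seeded permutations of the
#' response and returns the null distribution of out-of-fold `R^2` together
#' with the permutation p-value of the observed fit.
#'
#' @param X,y,n_components,cv,k As in [fit_predict_plsr()].
#' @param n_perm Number of permutations (default 200).
#' @param seed Seed controlling the permutations.
#' @return List: `observed_r2`, `null_r2` (vector), `p_value`.
#' @export
plsr_permutation_null <- function(X, y, n_components = 5, cv = c("loo", "kfold"),
                                  k = 10, n_perm = 200, seed = 1) {
  cv <- match.arg(cv)
  obs <- fit_predict_plsr(X, y, n_components, cv, k, seed)$r2_cv
  set.seed(seed)
  perms <- replicate(n_perm, sample(y), simplify = FALSE)
  null_r2 <- vapply(perms, function(yp) {
    fit_predict_plsr(X, yp, n_components, cv, k, seed)$r2_cv
  }, numeric(1))
  list(observed_r2 = obs, null_r2 = null_r2,
       p_value = (1 + sum(null_r2 >= obs)) / (1 + n_perm))
}

#' PLSR of per-patient model accuracy on each predictor kind
#'
#' Applies the same PLSR machinery with model accuracy as the response:
#' which representation (SDC, simulated FC, z-abnormality, empirical FC)
#' best explains who the model predicts well?
#'
#' @param accuracy Numeric vector of per-patient accuracy correlations.
#' @param predictors Named list of subjects x features matrices.
#' @param ... Passed to [fit_predict_plsr()].
#' @return Tibble with one row per predictor kind: `predictor`, `r2_cv`,
#'   `r2_insample`.
#' @export
accuracy_regression <- function(accuracy, predictors, ...) {
  purrr::map_dfr(names(predictors), function(nm) {
    fit <- fit_predict_plsr(predictors[[nm]], accuracy, ...)
    tibble::tibble(predictor = nm, r2_cv = fit$r2_cv,
                   r2_insample = fit$r2_insample)
  })
}
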