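#' Model accuracy: empirical vs simulated FC
#'
#' Pearson correlation and mean squared error over the strict upper
#' triangles of the two FC matrices — the per-subject accuracy statistic of
#' the whole pipeline.
#'
#' @param fc_emp,fc_sim Square FC matrices on the same parcellation.
#' @return One-row tibble with columns `r`, `mse`, `n_pairs`; `r` is `NA`
#'   with a warning if either triangle is constant.
#' @export
model_accuracy <- function(fc_emp, fc_sim) {
  if (!all(dim(fc_emp) == dim(fc_sim))) stop("FC matrices must share dimensions")
  a <- upper_vals(fc_emp)
  b <- upper_vals(fc_sim)
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant FC triangle: correlation undefined")
    NA_real_
  } else {
    stats::cor(a, b)
  }
  tibble::tibble(r = r, mse = mean((a - b)^2), n_pairs = length(a))
}

#' Z-scored FC abnormality matrix
#'
#' Entrywise `(FC_subj - mean_healthy) / sd_healthy`, where mean and sample
#' SD (denominator `n - 1`) are taken across the healthy cohort's FC
#' matrices. Entries with zero healthy SD are set to `NA` and excluded from
#' downstream averages.
#'
#' @param fc_subject Subject FC matrix.
#' @param healthy_fcs List of >= 3 healthy FC matrices.
#' @return Matrix of class `zfc_matrix` with attributes `reference_mean`
#'   and `reference_sd`.
#' @export
z_abnormality <- function(fc_subject, healthy_fcs) {
  if (length(healthy_fcs) < 3) stop("need at least 3 healthy FC matrices")
  arr <- simplify2array(lapply(healthy_fcs, unclass))
  mu <- apply(arr, c(1, 2), mean)
  sd_ <- apply(arr, c(1, 2), stats::sd)
  z <- (unclass(fc_subject) - mu) / sd_
  z[sd_ == 0] <- NA
  structure(z, reference_mean = mu, reference_sd = sd_,
            class = c("zfc_matrix", "matrix", "array"))
}

dan_dmn_pairs <- function(parc) {
  dan <- which(parc$network == "DAN")
  dmn <- which(parc$network == "DMN")
  if (!length(dan) || !length(dmn)) stop("parcellation lacks DAN or DMN labels")
  pairs <- expand.grid(i = dan, j = dmn)
  pairs <- pairs[parc$hemisphere[pairs$i] == parc$hemisphere[pairs$j], ]
  if (!nrow(pairs)) stop("no same-hemisphere DAN-DMN pair exists")
  pairs
}

#' Intra-hemispheric DAN-DMN functional connectivity
#'
#' Average pairwise FC between dorsal-attention-network and
#' default-mode-network regions, restricted to same-hemisphere pairs and
#' pooled over both hemispheres. Normally negative (the two systems are
#' anticorrelated); its collapse toward zero is a canonical stroke
#' signature.
#'
#' @param fc FC (or z-abnormality) matrix.
#' @param parc A [parcellation()].
#' @return Scalar mean (NA entries skipped).
#' @export
intra_dan_dmn_fc <- function(fc, parc) {
  pairs <- dan_dmn_pairs(parc)
  mean(unclass(fc)[cbind(pairs$i, pairs$j)], na.rm = TRUE)
}

#' Homotopic inter-hemispheric functional connectivity
#'
#' FC between mirror-image left/right regions, averaged within each network
#' and then across networks (default), or flat across all pairs
#' (`per_network = FALSE`). Normally strong and positive; reduced after
#' stroke. Unpaired (midline/subcortical) regions are skipped.
#'
#' @param fc FC (or z-abnormality) matrix.
#' @param parc A [parcellation()].
#' @param per_network Average within network first (default `TRUE`).
#' @return Scalar mean.
#' @export
inter_homotopic_fc <- function(fc, parc, per_network = TRUE) {
  hp <- homotopic_pairs(parc)
  if (!nrow(hp)) stop("parcellation has no homotopic pairs")
  vals <- unclass(fc)[cbind(hp$i, hp$j)]
  if (!per_network) return(mean(vals, na.rm = TRUE))
  mean(tapply(vals, hp$network, mean, na.rm = TRUE), na.rm = TRUE)
}

#' Newman modularity of FC on the fixed resting-state-network partition
#'
#' Weighted Newman Q computed on the nonnegative FC graph over cortical
#' regions with modules fixed to the network labels (no community
#' detection): `Q = sum_m [ w_mm / W - (k_m / 2W)^2 ]` with `W` the total
#' edge weight, `w_mm` the within-module weight and `k_m` the module's
#' weighted degree. Negative FC edges are dropped; edges below `threshold`
#' are zeroed.
#'
#' @param fc FC matrix.
#' @param parc A [parcellation()]; the partition is `parc$network` over
#'   cortical regions.
#' @param threshold Minimum edge weight retained (default 0, i.e. all
#'   positive edges).
#' @return Scalar Q.
#' @export
fc_modularity <- function(fc, parc, threshold = 0) {
  keep <- which(parc$is_cortical)
  A <- unclass(fc)[keep, keep, drop = FALSE]
  A[A < threshold] <- 0
  A[A < 0] <- 0
  diag(A) <- 0
  W2 <- sum(A)            # 2W: each undirected edge counted twice
  if (W2 == 0) stop("empty graph after thresholding")
  mods <- parc$network[keep]
  within <- sum(A[outer(mods, mods, `==`)]) / W2
  k <- rowSums(A)
  km <- tapply(k, mods, sum)
  within - sum((km / W2)^2)
}

#' Binarize an FC matrix into a graph
#'
#' `method = "absolute"` (default) keeps positive edges with FC above
#' `value`; `method = "proportional"` keeps the strongest
#' `value * n (n - 1) / 2` positive edges (proportional density). The
#' absolute mode lets lesion-induced FC loss change the edge count — which
#' is what the degree/efficiency severity analyses measure; the
#' proportional mode fixes density (and hence average degree) across
#' subjects.
#'
#' @param fc FC matrix.
#' @param value Threshold (absolute FC, default 0.25) or density fraction.
#' @param method `"absolute"` or `"proportional"`.
#' @return Symmetric 0/1 adjacency matrix, zero diagonal.
#' @export
binarize_fc <- function(fc, value = 0.25, method = c("absolute", "proportional")) {
  method <- match.arg(method)
  A <- unclass(fc)
  diag(A) <- 0
  n <- nrow(A)
  B <- matrix(0, n, n)
  if (method == "absolute") {
    B[A > value] <- 1
    B[lower.tri(B)] <- 0
    diag(B) <- 0
    return(B + t(B))
  }
  vals <- A[upper.tri(A)]
  k <- round(value * length(vals))
  pos <- which(vals > 0)
  keep <- pos[order(vals[pos], decreasing = TRUE)][seq_len(min(k, length(pos)))]
  ut <- which(upper.tri(B))
  B[ut[keep]] <- 1
  B + t(B)
}

#' Global efficiency (average inverse shortest path length)
#'
#' `E = (1/n) sum_i sum_{j != i} (1 / d_ij) / (n - 1)` on the binarized
#' graph, with disconnected pairs contributing zero (their path length is
#' infinite) — which is what makes the metric usable on the fragmented
#' graphs stroke produces. Equals 1 iff the graph is complete.
#'
#' @param fc FC matrix (or an already binary adjacency matrix).
#' @param value,method Passed to [binarize_fc()].
#' @param binarize Set `FALSE` if `fc` is already a binary adjacency.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(fc, value = 0.25, method = "absolute",
                              binarize = TRUE) {
  n <- nrow(fc)
  if (n < 2) stop("need at least 2 nodes")
  B <- if (binarize) binarize_fc(fc, value, method) else unclass(fc)
  g <- igraph::graph_from_adjacency_matrix(B > 0, mode = "undirected")
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Normalized FC entropy
#'
#' Histogram of the absolute upper-triangle FC values into `m_bins`
#' equal-width bins on \[0, 1\]; `H = -sum p_i log p_i / log m`, so `H` is 0
#' when all mass falls in one bin and 1 for a uniform histogram. Measures
#' the richness of the functional-connection distribution.
#'
#' @param fc FC matrix.
#' @param m_bins Number of bins (default 50).
#' @return Scalar in `[0, 1]`.
#' @export
fc_entropy <- function(fc, m_bins = 50) {
  if (m_bins < 2) stop("m_bins must be >= 2")
  v <- pmin(abs(upper_vals(unclass(fc))), 1)
  counts <- tabulate(pmin(floor(v * m_bins) + 1L, m_bins), nbins = m_bins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p)) / log(m_bins)
}

#' Average degree of the binarized FC graph
#'
#' `K = sum_v k_v / N` on the proportionally thresholded graph; an overall
#' connectivity level informing about network segregation.
#'
#' @inheritParams global_efficiency
#' @return Scalar mean degree.
#' @export
average_degree <- function(fc, value = 0.25, method = "absolute",
                           binarize = TRUE) {
  B <- if (binarize) binarize_fc(fc, value, method) else unclass(fc)
  mean(rowSums(B > 0))
}

#' Signature abnormality scores from a z-matrix
#'
#' The two stroke-signature means evaluated on a z-scored FC abnormality
#' matrix: homotopic inter-hemispheric entries and intra-hemispheric
#' DAN-DMN entries (same pair definitions as [inter_homotopic_fc()] and
#' [intra_dan_dmn_fc()]).
#'
#' @param z A [z_abnormality()] matrix.
#' @param parc A [parcellation()].
#' @return One-row tibble with columns `homotopic_z`, `dan_dmn_z`.
#' @export
signature_abnormality <- function(z, parc) {
  tibble::tibble(homotopic_z = inter_homotopic_fc(z, parc),
                 dan_dmn_z = intra_dan_dmn_fc(z, parc))
}

#' All per-subject FC metrics in one row
#'
#' @param fc FC matrix.
#' @param parc A [parcellation()].
#' @param subject_id Identifier copied into the row.
#' @param value,method Graph threshold, see [binarize_fc()].
#' @param m_bins Bins for [fc_entropy()].
#' @return One-row tibble: `subject_id`, `intra_dan_dmn_fc`,
#'   `inter_homotopic_fc`, `modularity`, `global_efficiency`, `fc_entropy`,
#'   `average_degree`.
#' @export
fc_metric_record <- function(fc, parc, subject_id = NA_character_,
                             value = 0.25, method = "absolute", m_bins = 50) {
  tibble::tibble(
    subject_id = subject_id,
    intra_dan_dmn_fc = intra_dan_dmn_fc(fc, parc),
    inter_homotopic_fc = inter_homotopic_fc(fc, parc),
    modularity = fc_modularity(fc, parc),
    global_efficiency = global_efficiency(fc, value, method),
    fc_entropy = fc_entropy(fc, m_bins),
    average_degree = average_degree(fc, value, method)
  )
}
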