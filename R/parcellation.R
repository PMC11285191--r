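#' Construct a parcellation table
#'
#' A parcellation is the shared region scheme of a study: every matrix
#' (connectome, SDC mask, FC) and every BOLD run is indexed by its rows, in
#' this fixed order. Regions carry a hemisphere, a resting-state-network
#' label, a cortical flag and an optional homotopic (mirror-image) partner.
#'
#' @param region_id Character vector of unique region identifiers.
#' @param hemisphere One of `"left"`, `"right"`, `"midline"` per region.
#' @param network Resting-state network label per region. Cortical labels
#'   should include at least `"DAN"` and `"DMN"` for the stroke-signature
#'   metrics to be computable.
#' @param is_cortical Logical flag per region.
#' @param homotopic_partner Region id of the mirror region in the opposite
#'   hemisphere, or `NA` for unpaired (e.g. midline/subcortical) regions.
#'   The pairing must be symmetric: `partner(partner(r)) == r`.
#'
#' @return A tibble of class `parcellation` with one row per region.
#' @examples
#' parcellation(
#'   region_id = c("L1", "L2", "R1", "R2"),
#'   hemisphere = c("left", "left", "right", "right"),
#'   network = c("DAN", "DMN", "DAN", "DMN"),
#'   homotopic_partner = c("R1", "R2", "L1", "L2")
#' )
#' @export
parcellation <- function(region_id, hemisphere, network,
                         is_cortical = TRUE,
                         homotopic_partner = NA_character_) {
  if (anyDuplicated(region_id)) stop("region_id values must be unique")
  n <- length(region_id)
  p <- tibble::tibble(
    region_id = as.character(region_id),
    hemisphere = rep_len(as.character(hemisphere), n),
    network = rep_len(as.character(network), n),
    is_cortical = rep_len(as.logical(is_cortical), n),
    homotopic_partner = rep_len(as.character(homotopic_partner), n)
  )
  bad_hemi <- setdiff(unique(p$hemisphere), c("left", "right", "midline"))
  if (length(bad_hemi)) {
    stop("hemisphere must be left/right/midline, got: ", paste(bad_hemi, collapse = ", "))
  }
  check_homotopic_involution(p)
  class(p) <- c("parcellation", class(p))
  p
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation> ", nrow(x), " regions, ",
      length(unique(x$network)), " networks, ",
      nrow(homotopic_pairs(x)), " homotopic pairs\n", sep = "")
  NextMethod()
}

check_homotopic_involution <- function(p) {
  paired <- !is.na(p$homotopic_partner)
  if (!any(paired)) return(invisible(TRUE))
  idx <- match(p$homotopic_partner[paired], p$region_id)
  if (anyNA(idx)) stop("homotopic_partner refers to unknown region_id")
  back <- p$homotopic_partner[idx]
  if (!identical(back, p$region_id[paired])) {
    stop("homotopic pairing is not symmetric/involutive")
  }
  if (any(p$region_id[paired] == p$homotopic_partner[paired])) {
    stop("a region cannot be its own homotopic partner")
  }
  invisible(TRUE)
}

#' Homotopic region pairs
#'
#' @param parc A [parcellation()].
#' @return Tibble with columns `i`, `j` (row indices, `i < j`), `network`;
#'   each left/right mirror pair appears once.
#' @export
homotopic_pairs <- function(parc) {
  paired <- which(!is.na(parc$homotopic_partner))
  if (!length(paired)) {
    return(tibble::tibble(i = integer(), j = integer(), network = character()))
  }
  j <- match(parc$homotopic_partner[paired], parc$region_id)
  keep <- paired < j
  tibble::tibble(i = paired[keep], j = j[keep], network = parc$network[paired[keep]])
}

#' Generate a synthetic mirrored parcellation
#'
#' Builds a hemispherically symmetric scheme: `n_regions / 2` regions per
#' hemisphere, networks assigned in contiguous blocks and mirrored so that
#' left region `k` is the homotopic partner of right region `k`. This is the
#' region scheme all synthetic cohorts use; real studies supply their own
#' table via [parcellation()].
#'
#' @param n_regions Even total region count.
#' @param n_networks Number of resting-state networks (>= 2); the first two
#'   are always DAN and DMN.
#' @param networks Optional character vector of network names (length
#'   `n_networks`, must contain "DAN" and "DMN").
#' @return A [parcellation()] tibble.
#' @export
make_parcellation <- function(n_regions, n_networks = 4, networks = NULL) {
  if (n_regions %% 2 != 0) stop("n_regions must be even so hemispheres balance")
  nh <- n_regions / 2L
  if (n_networks > nh) stop("n_networks may not exceed n_regions / 2")
  if (n_networks < 2) stop("need at least 2 networks (DAN and DMN)")
  if (is.null(networks)) {
    pool <- c("DAN", "DMN", "VIS", "SMN", "FPN", "VAN", "LIM", "AUD")
    if (n_networks > length(pool)) {
      pool <- c(pool, paste0("NET", seq_len(n_networks - length(pool))))
    }
    networks <- pool[seq_len(n_networks)]
  }
  if (!all(c("DAN", "DMN") %in% networks)) stop("networks must include DAN and DMN")
  # contiguous, near-equal blocks within one hemisphere, mirrored to the other
  block <- sort(rep_len(seq_len(n_networks), nh))
  net_h <- networks[block]
  ids_l <- sprintf("L%03d", seq_len(nh))
  ids_r <- sprintf("R%03d", seq_len(nh))
  parcellation(
    region_id = c(ids_l, ids_r),
    hemisphere = rep(c("left", "right"), each = nh),
    network = c(net_h, net_h),
    is_cortical = TRUE,
    homotopic_partner = c(ids_r, ids_l)
  )
}

#' Read / write a parcellation as TSV
#'
#' Columns: region_id, hemisphere, network, is_cortical, homotopic_partner.
#' @param parc A [parcellation()].
#' @param path File path.
#' @return `read_parcellation()` returns a [parcellation()];
#'   `write_parcellation()` returns `path` invisibly.
#' @export
write_parcellation <- function(parc, path) {
  readr::write_tsv(as.data.frame(parc), path)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         region_id = readr::col_character(),
                         hemisphere = readr::col_character(),
                         network = readr::col_character(),
                         is_cortical = readr::col_logical(),
                         homotopic_partner = readr::col_character()
                       ))
  parcellation(d$region_id, d$hemisphere, d$network, d$is_cortical,
               d$homotopic_partner)
}
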