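#' Curate consensus cancer and noncancer labels from two raters
#'
#' Lesions delineated independently by two raters are matched by spatial
#' overlap; only the voxelwise intersection of a matched pair counts as
#' cancer, maximizing certainty in the positive label. Lesions seen by a
#' single rater, or pairs with zero overlap, are excluded and reported
#' (their volume is recorded; `min_volume_cc` flags the small ones the
#' exclusion rule typically removes). The noncancer region is the rest of
#' the peripheral zone. Lesion voxels outside the PZ are clipped to it with
#' a warning.
#'
#' @param rater1,rater2 lists of per-lesion [roi_mask()]s on the PZ grid.
#' @param pz the peripheral-zone [roi_mask()].
#' @param min_volume_cc reporting threshold for small excluded lesions,
#'   default 0.25.
#' @return List with `cancer` and `noncancer` masks and an `exclusions`
#'   tibble (`rater`, `lesion`, `volume_cc`, `reason`, `sub_threshold`).
#' @export
curate_reference_labels <- function(rater1, rater2, pz, min_volume_cc = 0.25) {
  clip <- function(m, who, i) {
    stopifnot_same_grid(m, pz, "lesion mask and PZ")
    if (any(m & !pz)) {
      warning(sprintf("%s lesion %d extends outside the PZ; clipping", who, i),
              call. = FALSE)
      m <- mask_like(m & pz, pz, label = mask_label(m))
    }
    m
  }
  rater1 <- if (length(rater1)) lapply(seq_along(rater1), function(i) {
    clip(rater1[[i]], "rater1", i)
  }) else list()
  rater2 <- if (length(rater2)) lapply(seq_along(rater2), function(i) {
    clip(rater2[[i]], "rater2", i)
  }) else list()

  n1 <- length(rater1); n2 <- length(rater2)
  overlap <- matrix(0L, n1, n2)
  if (n1 > 0 && n2 > 0) {
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      overlap[i, j] <- sum(rater1[[i]] & rater2[[j]])
    }
  }
  cancer <- array(FALSE, dim = dim(pz))
  excl <- list()
  matched1 <- logical(n1); matched2 <- logical(n2)
  # greedy matching by decreasing overlap
  while (any(overlap > 0)) {
    at <- which(overlap == max(overlap), arr.ind = TRUE)[1, ]
    i <- at[1]; j <- at[2]
    cancer <- cancer | (rater1[[i]] & rater2[[j]])
    matched1[i] <- TRUE; matched2[j] <- TRUE
    overlap[i, ] <- 0L; overlap[, j] <- 0L
  }
  note <- function(who, idx, masks, reason) {
    for (i in idx) {
      v <- mask_volume_cc(masks[[i]])
      excl[[length(excl) + 1L]] <<- tibble::tibble(
        rater = who, lesion = i, volume_cc = v, reason = reason,
        sub_threshold = v < min_volume_cc
      )
    }
  }
  note("rater1", which(!matched1), rater1, "no overlapping counterpart")
  note("rater2", which(!matched2), rater2, "no overlapping counterpart")

  cancer_mask <- mask_like(cancer, pz, label = "cancer")
  noncancer_mask <- mask_like(pz & !cancer, pz, label = "noncancer")
  list(
    cancer = cancer_mask,
    noncancer = noncancer_mask,
    exclusions = if (length(excl)) dplyr::bind_rows(excl) else tibble::tibble(
      rater = character(), lesion = integer(), volume_cc = numeric(),
      reason = character(), sub_threshold = logical()
    )
  )
}
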