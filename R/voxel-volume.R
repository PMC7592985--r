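#' 3-D scalar volume with voxel spacing
#'
#' The common currency of all image operations in pzrad. Data are stored as a
#' 3-D numeric array in `(slice, row, column)` axis order with per-axis voxel
#' spacing in millimetres. Intensities are arbitrary units for signal volumes
#' (T2WI, high-b DWI) and mm^2/s for diffusivity maps. Voxels excluded from
#' analysis (e.g. outside a mask in a derived map) carry `NA`, which every
#' statistic in the package skips.
#'
#' @param data numeric 3-D array, axes `(slice, row, column)`.
#' @param spacing numeric length-3, voxel spacing in mm along each axis
#'   (slice thickness first); all components must be positive.
#' @return An object of class `voxel_volume`: the array with a `spacing`
#'   attribute.
#' @examples
#' v <- voxel_volume(array(1, dim = c(2, 4, 4)), spacing = c(4, 0.8, 0.8))
#' dim(v)
#' vox_spacing(v)
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array (slice, row, column)", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive numbers (mm)", call. = FALSE)
  }
  storage.mode(data) <- "double"
  structure(data, spacing = spacing, class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d (slice x row x col), spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], vox_spacing(x)[1], vox_spacing(x)[2], vox_spacing(x)[3]
  ))
  rng <- suppressWarnings(range(x, na.rm = TRUE))
  cat(sprintf("  intensity range: [%.4g, %.4g], %d NA voxel(s)\n",
              rng[1], rng[2], sum(is.na(x))))
  invisible(x)
}

#' @rdname voxel_volume
#' @param x a `voxel_volume` or `roi_mask`.
#' @export
vox_spacing <- function(x) attr(x, "spacing")

#' @rdname voxel_volume
#' @export
is_voxel_volume <- function(x) inherits(x, "voxel_volume")

# Wrap an array with the grid of an existing volume.
vol_like <- function(data, template) {
  dim(data) <- dim(template)
  voxel_volume(data, vox_spacing(template))
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a), dim(b)) && all(abs(vox_spacing(a) - vox_spacing(b)) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    stop(sprintf("%s must share the same grid (shape and spacing)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Binary region-of-interest mask on a voxel grid
#'
#' A logical 3-D array aligned with a companion [voxel_volume()] grid. Masks
#' carry a label naming what they delineate: the peripheral zone (`"pz"`),
#' the reference tissue used for intensity standardization, per-rater cancer
#' delineations, or the curated cancer / noncancer training regions.
#'
#' @param data logical (or 0/1 numeric) 3-D array, axes `(slice, row, column)`.
#' @param spacing voxel spacing in mm, as in [voxel_volume()].
#' @param label one of `"pz"`, `"reference_tissue"`, `"rater1"`, `"rater2"`,
#'   `"cancer"`, `"noncancer"`.
#' @return An object of class `roi_mask`.
#' @examples
#' m <- roi_mask(array(c(TRUE, FALSE), dim = c(1, 2, 1)), label = "pz")
#' mask_volume_cc(m)
#' @export
roi_mask <- function(data, spacing = c(1, 1, 1), label = "pz") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array (slice, row, column)", call. = FALSE)
  }
  label <- match.arg(label, c("pz", "reference_tissue", "rater1", "rater2",
                              "cancer", "noncancer"))
  if (is.numeric(data)) data <- array(data != 0, dim = dim(data))
  if (!is.logical(data)) stop("`data` must be logical or 0/1", call. = FALSE)
  data[is.na(data)] <- FALSE
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive numbers (mm)", call. = FALSE)
  }
  structure(data, spacing = spacing, label = label, class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<roi_mask:%s> %d x %d x %d, %d voxel(s), %.3f cc\n",
              mask_label(x), d[1], d[2], d[3], sum(x), mask_volume_cc(x)))
  invisible(x)
}

#' @rdname roi_mask
#' @param x an `roi_mask`.
#' @export
mask_label <- function(x) attr(x, "label")

#' @rdname roi_mask
#' @export
mask_volume_cc <- function(x) {
  sum(x) * prod(vox_spacing(x)) / 1000
}

mask_like <- function(data, template, label = "pz") {
  dim(data) <- dim(template)
  roi_mask(data, vox_spacing(template), label = label)
}

#' DTI eigenvalue triplet
#'
#' The three sorted eigenvalue volumes of the per-voxel diffusion tensor,
#' lambda1 >= lambda2 >= lambda3, in mm^2/s. On construction the triplet is
#' sorted voxelwise and negative eigenvalues are clamped to zero (their count
#' is recorded in the `n_clamped` attribute) — small negative eigenvalues are
#' a routine artefact of tensor fitting in noisy data.
#'
#' @param lambda1,lambda2,lambda3 `voxel_volume`s on a common grid.
#' @return An object of class `dti_eigenvalues`: a list with elements
#'   `lambda1`, `lambda2`, `lambda3`.
#' @export
dti_eigenvalues <- function(lambda1, lambda2, lambda3) {
  stopifnot_same_grid(lambda1, lambda2, "eigenvalue volumes")
  stopifnot_same_grid(lambda1, lambda3, "eigenvalue volumes")
  m <- cbind(as.numeric(lambda1), as.numeric(lambda2), as.numeric(lambda3))
  n_clamped <- sum(m < 0, na.rm = TRUE)
  m[m < 0] <- 0
  # voxelwise descending sort; NA rows stay NA
  srt <- t(apply(m, 1L, function(r) if (anyNA(r)) r else sort(r, decreasing = TRUE)))
  structure(
    list(
      lambda1 = vol_like(srt[, 1L], lambda1),
      lambda2 = vol_like(srt[, 2L], lambda1),
      lambda3 = vol_like(srt[, 3L], lambda1)
    ),
    n_clamped = n_clamped,
    class = "dti_eigenvalues"
  )
}

#' @export
print.dti_eigenvalues <- function(x, ...) {
  cat("<dti_eigenvalues> lambda1 >= lambda2 >= lambda3\n")
  print(x$lambda1)
  invisible(x)
}

#' One subject of a voxel-wise classification cohort
#'
#' Bundles the co-registered channels and masks of one patient. After
#' [prepare_case()] every volume and mask shares the T2WI grid.
#'
#' @param patient_id character scalar.
#' @param t2w,dwi_highb,adc `voxel_volume`s.
#' @param eigenvalues a [dti_eigenvalues()] triplet.
#' @param pz,reference_tissue `roi_mask`s on the T2WI grid.
#' @param rater_masks list with elements `rater1` and `rater2`, each a list of
#'   per-lesion `roi_mask`s on the T2WI grid.
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(patient_id, t2w, dwi_highb = NULL, adc = NULL,
                         eigenvalues = NULL, pz, reference_tissue = NULL,
                         rater_masks = list(rater1 = list(), rater2 = list())) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  structure(
    list(patient_id = patient_id, t2w = t2w, dwi_highb = dwi_highb, adc = adc,
         eigenvalues = eigenvalues, pz = pz,
         reference_tissue = reference_tissue, rater_masks = rater_masks),
    class = "patient_case"
  )
}

#' @export
print.patient_case <- function(x, ...) {
  chans <- c("t2w", if (!is.null(x$dwi_highb)) "dwi_highb",
             if (!is.null(x$adc)) "adc",
             if (!is.null(x$eigenvalues)) "dti")
  cat(sprintf("<patient_case> %s: channels {%s}, PZ %.2f cc, %d+%d rater lesion(s)\n",
              x$patient_id, paste(chans, collapse = ", "),
              mask_volume_cc(x$pz),
              length(x$rater_masks$rater1), length(x$rater_masks$rater2)))
  invisible(x)
}
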