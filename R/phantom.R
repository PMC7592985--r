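#' Specification of the synthetic mp-MRI phantom cohort
#'
#' Defines the study conditions the generator emulates: a T2WI-resolution
#' grid with 4 mm slices and 0.8 mm in-plane voxels, coarser DWI/DTI
#' channels, an annular posterior peripheral zone with embedded lesion
#' blobs, channel contrasts in the directions seen clinically (lesions dark
#' on T2WI and ADC, bright on high-b DWI, with reduced mean diffusivity and
#' raised anisotropy on DTI), a smooth multiplicative bias field, Gaussian
#' noise, a per-patient global intensity scale on the signal channels, and
#' two raters who disagree at lesion boundaries.
#'
#' @param shape T2WI grid `(slices, rows, cols)`, default `c(8, 64, 64)`.
#' @param spacing T2WI voxel spacing in mm, default `c(4, 0.8, 0.8)`.
#' @param n_patients cohort size, default 16.
#' @param lesion_count_range integer range of lesions per patient.
#' @param lesion_volume_cc lesion volume range in cc.
#' @param t2_background,t2_pz,t2_reference,t2_lesion_delta T2WI means
#'   (arbitrary units); the lesion delta is negative (hypointense). By
#'   default the PZ surroundings share the PZ mean, so lesion contrast is
#'   the only spatial intensity structure and the PZ boundary carries no
#'   signal of its own.
#' @param hb_background,hb_lesion_delta high-b DWI means (lesion brighter).
#' @param adc_background,adc_lesion_delta ADC in mm^2/s (lesion lower).
#' @param eig_background,eig_lesion sorted eigenvalue triplets in mm^2/s for
#'   background PZ and lesion tissue.
#' @param noise_sd named list of channel noise SDs (`t2`, `hb`, `adc`,
#'   `eig`).
#' @param contrast global multiplier on every lesion-vs-background delta;
#'   0 gives the null phantom.
#' @param bias_amplitude amplitude of the smooth multiplicative field.
#' @param patient_scale_range per-patient global scale on the signal
#'   channels (T2WI, high-b DWI); quantitative maps are not scaled.
#' @param coarse_factor in-plane downsampling factor of the DWI/DTI grids
#'   relative to T2WI, default 2.
#' @param rater_radius boundary-disagreement radius (voxels) for the second
#'   rater, default 2 (calibrated so inter-rater Dice falls around 0.78).
#' @param seed master seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(8, 64, 64), spacing = c(4, 0.8, 0.8),
                         n_patients = 16L,
                         lesion_count_range = c(1L, 2L),
                         lesion_volume_cc = c(0.5, 1.5),
                         t2_background = 500, t2_pz = 500, t2_reference = 200,
                         t2_lesion_delta = -25,
                         hb_background = 80, hb_lesion_delta = 120,
                         adc_background = 1.6e-3, adc_lesion_delta = -0.8e-3,
                         eig_background = c(2.2e-3, 1.7e-3, 1.3e-3),
                         eig_lesion = c(1.35e-3, 0.75e-3, 0.45e-3),
                         noise_sd = list(t2 = 30, hb = 40, adc = 0.25e-3,
                                         eig = 0.3e-3),
                         contrast = 1, bias_amplitude = 0.1,
                         patient_scale_range = c(0.7, 1.3),
                         coarse_factor = 2L, rater_radius = 2L, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), all(spacing > 0),
            n_patients >= 1L, contrast >= 0, rater_radius >= 0)
  structure(as.list(environment()), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d patient(s), grid %s @ %s mm, contrast %.2f, seed %d\n",
    x$n_patients, paste(x$shape, collapse = "x"),
    paste(format(x$spacing), collapse = "x"), x$contrast, x$seed))
  invisible(x)
}

# world coordinates (mm) of voxel centers along each axis of a grid
grid_coords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * spacing[a])
}

# posterior half-annulus PZ membership on an arbitrary grid, defined in the
# world coordinates of the T2WI grid so coarse channels align
pz_membership <- function(shape, spacing, t2_shape, t2_spacing) {
  co <- grid_coords(shape, spacing)
  ext <- t2_shape * t2_spacing
  ctr_r <- 0.5 * ext[2]; ctr_c <- 0.5 * ext[3]
  ar <- 0.38 * ext[2]; ac <- 0.42 * ext[3]
  z_ok <- co[[1]] >= 1.5 * t2_spacing[1] & co[[1]] <= ext[1] - 1.5 * t2_spacing[1]
  u <- (co[[2]] - ctr_r) / ar
  v <- (co[[3]] - ctr_c) / ac
  e <- outer(u^2, v^2, "+")
  in_plane <- e >= 0.45 & e <= 1 & outer(co[[2]] >= ctr_r, rep(TRUE, shape[3]))
  arr <- array(FALSE, dim = shape)
  for (s in which(z_ok)) arr[s, , ] <- in_plane
  arr
}

reference_membership <- function(shape, spacing) {
  co <- grid_coords(shape, spacing)
  arr <- array(FALSE, dim = shape)
  rows <- co[[2]] >= 2 & co[[2]] <= 9
  cols <- co[[3]] >= 2 & co[[3]] <= 9
  for (s in seq_len(shape[1])) arr[s, rows, cols] <- TRUE
  arr
}

ellipsoid_membership <- function(center_mm, radii_mm, shape, spacing) {
  co <- grid_coords(shape, spacing)
  ds <- (co[[1]] - center_mm[1]) / radii_mm[1]
  dr <- (co[[2]] - center_mm[2]) / radii_mm[2]
  dc <- (co[[3]] - center_mm[3]) / radii_mm[3]
  arr <- array(0, dim = shape)
  for (s in seq_along(ds)) {
    arr[s, , ] <- ds[s]^2 + outer(dr^2, dc^2, "+")
  }
  arr <= 1
}

# smooth in-plane multiplicative field, 1 + amplitude * low-order polynomial
bias_field <- function(shape, spacing, amplitude, coefs) {
  co <- grid_coords(shape, spacing)
  ext_r <- max(co[[2]]); ext_c <- max(co[[3]])
  u <- co[[2]] / ext_r - 0.5
  v <- co[[3]] / ext_c - 0.5
  plane <- coefs[1] * outer(u, rep(1, length(v))) +
           coefs[2] * outer(rep(1, length(u)), v) +
           coefs[3] * outer(u, v) +
           coefs[4] * outer(u^2 - 1 / 12, rep(1, length(v))) +
           coefs[5] * outer(rep(1, length(u)), v^2 - 1 / 12)
  plane <- plane / max(abs(plane))
  arr <- array(0, dim = shape)
  for (s in seq_len(shape[1])) arr[s, , ] <- plane
  1 + amplitude * arr
}

#' Randomly perturb a mask within a bounded radius
#'
#' Emulates a second rater's delineation: a random in-plane translation of
#' up to `radius` voxels plus a random one-step dilation or erosion.
#' Expected Dice against the input decreases monotonically with `radius`;
#' radius 0 returns the mask unchanged.
#'
#' @param mask an [roi_mask()].
#' @param radius integer >= 0, maximum boundary displacement in voxels.
#' @param seed integer seed.
#' @return The perturbed `roi_mask`.
#' @export
perturb_mask <- function(mask, radius, seed = 1L) {
  radius <- as.integer(radius)
  stopifnot(radius >= 0)
  if (radius == 0L) return(mask)
  with_local_seed(seed, {
    d <- dim(mask)
    arr <- array(as.logical(mask), dim = d)
    shift <- sample(seq(-radius, radius), 2, replace = TRUE)
    ci <- function(i, n) pmin(pmax(i, 1L), n)
    src_r <- ci(seq_len(d[2]) - shift[1], d[2])
    src_c <- ci(seq_len(d[3]) - shift[2], d[3])
    out <- array(FALSE, dim = d)
    for (s in seq_len(d[1])) out[s, , ] <- arr[s, src_r, src_c]
    # one-step morphological jitter: dilate, erode, or leave
    op <- sample(c("dilate", "erode", "none"), 1)
    if (op != "none") {
      nb <- array(if (op == "dilate") FALSE else TRUE, dim = d)
      for (s in seq_len(d[1])) {
        m <- out[s, , ]
        acc <- m
        for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          shifted <- m[ci(seq_len(d[2]) - dd[1], d[2]),
                       ci(seq_len(d[3]) - dd[2], d[3])]
          acc <- if (op == "dilate") acc | shifted else acc & shifted
        }
        nb[s, , ] <- acc
      }
      out <- nb
    }
    mask_like(out, mask, label = "rater2")
  })
}

#' Generate one synthetic patient case
#'
#' Builds the T2WI at full resolution and the high-b DWI, ADC and DTI
#' eigenvalue channels on a coarser in-plane grid (they are upsampled to
#' the T2WI matrix by [prepare_case()]). Each channel is background mean +
#' lesion offset, times a smooth multiplicative field, plus Gaussian noise;
#' the signal channels are additionally multiplied by the per-patient
#' global scale. Eigenvalue fields are sorted and clamped non-negative on
#' construction. Rater 1's lesion masks are the true lesions; rater 2's are
#' perturbed copies.
#'
#' @param spec a [phantom_spec()].
#' @param patient_seed integer seed for this patient.
#' @param patient_id character id.
#' @return A [patient_case()] (channels still on their native grids).
#' @export
generate_patient <- function(spec, patient_seed, patient_id = "P01") {
  sh <- spec$shape; sp <- spec$spacing
  cf <- spec$coarse_factor
  sh_lo <- c(sh[1], sh[2] %/% cf, sh[3] %/% cf)
  sp_lo <- c(sp[1], sp[2] * cf, sp[3] * cf)
  with_local_seed(patient_seed, {
    pz_hi <- pz_membership(sh, sp, sh, sp)
    pz_lo <- pz_membership(sh_lo, sp_lo, sh, sp)
    ref_hi <- reference_membership(sh, sp)
    scale <- stats::runif(1, spec$patient_scale_range[1],
                          spec$patient_scale_range[2])
    n_lesions <- sample(seq(spec$lesion_count_range[1],
                            spec$lesion_count_range[2]), 1)
    co <- grid_coords(sh, sp)
    pz_idx <- which(pz_hi)
    lesions <- list()
    lesion_hi <- array(FALSE, dim = sh)
    lesion_lo <- array(FALSE, dim = sh_lo)
    for (li in seq_len(n_lesions)) {
      vol_cc <- stats::runif(1, spec$lesion_volume_cc[1],
                             spec$lesion_volume_cc[2])
      rz <- 1.2 * sp[1]
      rp <- sqrt(3 * vol_cc * 1000 / (4 * pi * rz))
      if (4 / 3 * pi * rz * rp^2 / 1000 > mask_volume_cc(
            roi_mask(pz_hi, sp, "pz"))) {
        stop("lesion volume exceeds the PZ", call. = FALSE)
      }
      ctr_vox <- arrayInd(sample(pz_idx, 1), sh)
      ctr_mm <- c(co[[1]][ctr_vox[1]], co[[2]][ctr_vox[2]], co[[3]][ctr_vox[3]])
      les_hi <- ellipsoid_membership(ctr_mm, c(rz, rp, rp), sh, sp) & pz_hi
      les_lo <- ellipsoid_membership(ctr_mm, c(rz, rp, rp), sh_lo, sp_lo) & pz_lo
      lesion_hi <- lesion_hi | les_hi
      lesion_lo <- lesion_lo | les_lo
      lesions[[li]] <- roi_mask(les_hi, sp, label = "rater1")
    }
    bias_hi <- bias_field(sh, sp, spec$bias_amplitude, stats::rnorm(5))
    bias_lo <- bias_field(sh_lo, sp_lo, spec$bias_amplitude, stats::rnorm(5))

    mk <- function(base, pzv, lesdelta, grid_pz, grid_les, shape, bias, sd,
                   scaled) {
      arr <- array(base, dim = shape)
      arr[grid_pz] <- pzv
      arr[grid_les] <- pzv + spec$contrast * lesdelta
      arr <- arr * bias
      if (scaled) arr <- arr * scale
      arr + stats::rnorm(length(arr), 0, sd)
    }
    t2 <- mk(spec$t2_background, spec$t2_pz, spec$t2_lesion_delta,
             pz_hi, lesion_hi, sh, bias_hi, spec$noise_sd$t2, TRUE)
    t2[ref_hi] <- spec$t2_reference * scale +
      stats::rnorm(sum(ref_hi), 0, spec$noise_sd$t2 / 3)
    hb <- mk(spec$hb_background, spec$hb_background, spec$hb_lesion_delta,
             pz_lo, lesion_lo, sh_lo, bias_lo, spec$noise_sd$hb, TRUE)
    adc <- mk(spec$adc_background, spec$adc_background, spec$adc_lesion_delta,
              pz_lo, lesion_lo, sh_lo, bias_lo, spec$noise_sd$adc, FALSE)
    eig_vols <- lapply(1:3, function(k) {
      delta <- spec$eig_lesion[k] - spec$eig_background[k]
      v <- mk(spec$eig_background[k], spec$eig_background[k], delta,
              pz_lo, lesion_lo, sh_lo, bias_lo, spec$noise_sd$eig, FALSE)
      voxel_volume(v, sp_lo)
    })
    rater2 <- lapply(seq_along(lesions), function(li) {
      m <- perturb_mask(lesions[[li]], spec$rater_radius,
                        seed = (patient_seed + 7919L * li) %% .Machine$integer.max)
      # raters delineate within the PZ
      mask_like(m & pz_hi, m, label = "rater2")
    })
    patient_case(
      patient_id = patient_id,
      t2w = voxel_volume(t2, sp),
      dwi_highb = voxel_volume(hb, sp_lo),
      adc = voxel_volume(adc, sp_lo),
      eigenvalues = dti_eigenvalues(eig_vols[[1]], eig_vols[[2]],
                                    eig_vols[[3]]),
      pz = roi_mask(pz_hi, sp, label = "pz"),
      reference_tissue = roi_mask(ref_hi, sp, label = "reference_tissue"),
      rater_masks = list(rater1 = lesions, rater2 = rater2)
    )
  })
}

#' Generate a full phantom cohort
#'
#' Per-patient seeds are derived deterministically from the master seed, so
#' two cohorts built from the same spec are identical.
#'
#' @param spec a [phantom_spec()].
#' @param prepare resample every channel onto the T2WI grid via
#'   [prepare_case()] (default `TRUE`).
#' @return List of [patient_case()]s.
#' @export
generate_cohort <- function(spec, prepare = TRUE) {
  ids <- sprintf("P%02d", seq_len(spec$n_patients))
  cases <- lapply(seq_len(spec$n_patients), function(i) {
    ps <- (spec$seed %% 100000L) * 10007L + i * 97L
    generate_patient(spec, patient_seed = ps %% .Machine$integer.max,
                     patient_id = ids[i])
  })
  if (prepare) cases <- lapply(cases, prepare_case)
  cases
}

#' Write a phantom cohort to a NIfTI directory layout
#'
#' One subdirectory per patient holding `t2w.nii.gz`, `dwi_highb.nii.gz`,
#' `adc.nii.gz`, `lambda1..3.nii.gz`, `pz.nii.gz`, `reference.nii.gz`, and
#' per-lesion rater masks, plus a `cohort.yaml` index.
#'
#' @param cohort list of [patient_case()]s.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- list()
  for (case in cohort) {
    pdir <- file.path(dir, case$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    write_volume(case$t2w, file.path(pdir, "t2w.nii.gz"))
    if (!is.null(case$dwi_highb)) {
      write_volume(case$dwi_highb, file.path(pdir, "dwi_highb.nii.gz"))
    }
    if (!is.null(case$adc)) write_volume(case$adc, file.path(pdir, "adc.nii.gz"))
    if (!is.null(case$eigenvalues)) {
      for (k in 1:3) {
        write_volume(case$eigenvalues[[paste0("lambda", k)]],
                     file.path(pdir, sprintf("lambda%d.nii.gz", k)))
      }
    }
    write_volume(case$pz, file.path(pdir, "pz.nii.gz"))
    write_volume(case$reference_tissue, file.path(pdir, "reference.nii.gz"))
    for (who in c("rater1", "rater2")) {
      for (li in seq_along(case$rater_masks[[who]])) {
        write_volume(case$rater_masks[[who]][[li]],
                     file.path(pdir, sprintf("%s_lesion%d.nii.gz", who, li)))
      }
    }
    index[[case$patient_id]] <- list(
      rater1 = length(case$rater_masks$rater1),
      rater2 = length(case$rater_masks$rater2)
    )
  }
  yaml::write_yaml(index, file.path(dir, "cohort.yaml"))
  invisible(dir)
}

#' Read a cohort from the directory layout written by [write_cohort()]
#'
#' @param dir cohort directory containing `cohort.yaml`.
#' @param prepare resample channels onto the T2WI grid (default `TRUE`).
#' @return List of [patient_case()]s.
#' @export
read_cohort <- function(dir, prepare = TRUE) {
  index <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  cases <- lapply(names(index), function(pid) {
    pdir <- file.path(dir, pid)
    rd <- function(f) {
      p <- file.path(pdir, f)
      if (file.exists(p)) read_volume(p) else NULL
    }
    eig <- NULL
    if (file.exists(file.path(pdir, "lambda1.nii.gz"))) {
      eig <- dti_eigenvalues(rd("lambda1.nii.gz"), rd("lambda2.nii.gz"),
                             rd("lambda3.nii.gz"))
    }
    case <- patient_case(
      patient_id = pid,
      t2w = rd("t2w.nii.gz"),
      dwi_highb = rd("dwi_highb.nii.gz"),
      adc = rd("adc.nii.gz"),
      eigenvalues = eig,
      pz = read_mask(file.path(pdir, "pz.nii.gz"), "pz"),
      reference_tissue = read_mask(file.path(pdir, "reference.nii.gz"),
                                   "reference_tissue"),
      rater_masks = list(
        rater1 = lapply(seq_len(index[[pid]]$rater1), function(li) {
          read_mask(file.path(pdir, sprintf("rater1_lesion%d.nii.gz", li)),
                    "rater1")
        }),
        rater2 = lapply(seq_len(index[[pid]]$rater2), function(li) {
          read_mask(file.path(pdir, sprintf("rater2_lesion%d.nii.gz", li)),
                    "rater2")
        })
      )
    )
    if (prepare) prepare_case(case) else case
  })
  cases
}
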