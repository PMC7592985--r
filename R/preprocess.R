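#' Slice-wise median filter
#'
#' Noise reduction applied before intensity standardization: each voxel is
#' replaced by the median of its `window` x `window` in-slice neighbourhood
#' (default 3 x 3). Borders are handled by edge replication. Filtering is
#' 2-D per axial slice, matching slice-wise acquisition and delineation.
#'
#' @param vol a [voxel_volume()].
#' @param window odd integer window width, default 3.
#' @return The filtered `voxel_volume`.
#' @export
median_filter <- function(vol, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  }
  if (window == 1L) return(vol)
  out <- array(NA_real_, dim = dim(vol))
  for (s in seq_len(dim(vol)[1])) {
    out[s, , ] <- cpp_median_filter_2d(array(vol[s, , ], dim = dim(vol)[2:3]),
                                       window)
  }
  vol_like(out, vol)
}

#' Reference-tissue intensity summary (median + IQR)
#'
#' The per-patient standardization divisor: the median plus the interquartile
#' range of the intensities inside the reference-tissue mask. Quantiles use
#' linear interpolation between order statistics (type 7).
#'
#' @param vol a [voxel_volume()].
#' @param ref_mask non-empty [roi_mask()] on the same grid.
#' @return A single number, `median + (Q3 - Q1)`.
#' @export
reference_summary <- function(vol, ref_mask) {
  stopifnot_same_grid(vol, ref_mask, "volume and reference mask")
  vals <- as.numeric(vol)[as.logical(ref_mask)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop("reference mask selects no voxels", call. = FALSE)
  }
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  q[2] + (q[3] - q[1])
}

#' Inter-patient coefficient of variation (%)
#'
#' Reproducibility of a candidate reference tissue across the cohort:
#' `100 * sd / mean` of the per-patient median+IQR summaries, with the
#' sample (n-1) standard deviation.
#'
#' @param summaries numeric vector of per-patient summaries (length >= 2).
#' @return Percent CV.
#' @export
inter_patient_cv <- function(summaries) {
  summaries <- as.numeric(summaries)
  if (length(summaries) < 2L) {
    stop("need summaries from at least two patients", call. = FALSE)
  }
  m <- mean(summaries)
  if (!is.finite(m) || m <= 0) {
    stop("degenerate reference tissue: mean summary is not positive",
         call. = FALSE)
  }
  100 * stats::sd(summaries) / m
}

#' Per-candidate reference-tissue statistics
#'
#' @param tissue_name character scalar.
#' @param per_patient_summary tibble with columns `patient_id`,
#'   `median_plus_iqr`.
#' @return An object of class `reference_stats` with the computed
#'   `inter_cv_percent`.
#' @export
reference_stats <- function(tissue_name, per_patient_summary) {
  stopifnot(all(c("patient_id", "median_plus_iqr") %in%
                  names(per_patient_summary)))
  structure(
    list(
      tissue_name = tissue_name,
      per_patient_summary = tibble::as_tibble(per_patient_summary),
      inter_cv_percent = inter_patient_cv(per_patient_summary$median_plus_iqr)
    ),
    class = "reference_stats"
  )
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats> %s: %%interCV = %.2f%% over %d patient(s)\n",
              x$tissue_name, x$inter_cv_percent, nrow(x$per_patient_summary)))
  invisible(x)
}

#' Pick the most reproducible reference tissue
#'
#' Among candidate tissues (femoral bone marrow, ischioanal fossa, muscle,
#' urine, ...), the one with the lowest inter-patient CV of its median+IQR
#' summary is the standardization reference. Ties break by candidate order.
#'
#' @param candidates list of [reference_stats()] objects.
#' @return The winning `reference_stats`.
#' @export
choose_reference_tissue <- function(candidates) {
  if (length(candidates) == 0L) {
    stop("no candidate reference tissues supplied", call. = FALSE)
  }
  cvs <- vapply(candidates, function(x) x$inter_cv_percent, numeric(1))
  candidates[[which.min(cvs)]]
}

#' Divide a volume by a per-patient standardization divisor
#'
#' After standardization with divisor = [reference_summary()] of the same
#' volume and mask, the reference summary of the result is exactly 1, so
#' patient-specific global intensity scale cancels out of all downstream
#' features.
#'
#' @param vol a [voxel_volume()].
#' @param divisor positive number.
#' @return The standardized `voxel_volume`.
#' @export
standardize_intensity <- function(vol, divisor) {
  if (!is.numeric(divisor) || length(divisor) != 1L || !is.finite(divisor) ||
      divisor <= 0) {
    stop("`divisor` must be a single positive number", call. = FALSE)
  }
  vol_like(as.numeric(vol) / divisor, vol)
}

#' Preprocess a cohort: filter, choose reference, standardize T2WI
#'
#' Runs the preprocessing stage on every case: 3x3 median filtering of the
#' T2WI, computation of the reference-tissue summary on the filtered volume,
#' and division of the T2WI by that per-patient summary. DWI/ADC/DTI maps
#' are left in native units (they are quantitative or handled upstream);
#' `standardize_channels` can extend standardization to other channels.
#'
#' @param cohort list of [patient_case()]s sharing a reference-tissue mask
#'   label.
#' @param median_window odd window for [median_filter()].
#' @param standardize_channels character vector of channels to standardize,
#'   default `"t2w"`.
#' @return A list with `cohort` (preprocessed cases), `reference` (tibble of
#'   per-patient summaries), and `inter_cv_percent`.
#' @export
preprocess_cohort <- function(cohort, median_window = 3L,
                              standardize_channels = "t2w") {
  cohort <- lapply(cohort, function(case) {
    case$t2w <- median_filter(case$t2w, median_window)
    case
  })
  summaries <- vapply(cohort, function(case) {
    reference_summary(case$t2w, case$reference_tissue)
  }, numeric(1))
  ids <- vapply(cohort, function(case) case$patient_id, character(1))
  cohort <- lapply(seq_along(cohort), function(i) {
    case <- cohort[[i]]
    for (ch in standardize_channels) {
      div <- if (ch == "t2w") summaries[i] else {
        reference_summary(case[[ch]], case$reference_tissue)
      }
      case[[ch]] <- standardize_intensity(case[[ch]], div)
    }
    case
  })
  list(
    cohort = cohort,
    reference = tibble::tibble(patient_id = ids, median_plus_iqr = summaries),
    inter_cv_percent = if (length(summaries) >= 2L) {
      inter_patient_cv(summaries)
    } else NA_real_
  )
}
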