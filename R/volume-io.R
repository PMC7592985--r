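#' Read a 3-D volume from NIfTI or NRRD
#'
#' Volumes are read into the package's `(slice, row, column)` array convention
#' with voxel spacing taken from the file header. Intensities are returned
#' unmodified.
#'
#' @param path path to a `.nii`, `.nii.gz`, or `.nrrd` file.
#' @param format `"nifti"` or `"nrrd"`; inferred from the file extension by
#'   default.
#' @return A [voxel_volume()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("cannot read volume: file '%s' does not exist", path),
         call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  }
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
      arr <- array(arr, dim = dim(arr)[1:3])
    }
    if (length(dim(arr)) != 3L) {
      stop(sprintf("'%s' is not a 3-D image (found %d dimension(s))",
                   path, length(dim(arr))), call. = FALSE)
    }
    sp <- RNifti::pixdim(img)[seq_len(3)]
    sp[!is.finite(sp) | sp <= 0] <- 1
    voxel_volume(arr, spacing = sp)
  } else {
    read_nrrd(path)
  }
}

#' Write a 3-D volume to NIfTI or NRRD
#'
#' @param vol a [voxel_volume()] or [roi_mask()] (masks are written as 0/1).
#' @param path output path; `.nii`/`.nii.gz` or `.nrrd`.
#' @param format as in [read_volume()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  }
  sp <- vox_spacing(vol)
  arr <- array(as.numeric(vol), dim = dim(vol))
  if (format == "nifti") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    write_nrrd(arr, sp, path)
  }
  invisible(path)
}

#' @rdname read_volume
#' @param label mask label passed to [roi_mask()].
#' @export
read_mask <- function(path, label = "pz", format = c("auto", "nifti", "nrrd")) {
  v <- read_volume(path, format)
  roi_mask(array(as.numeric(v) != 0, dim = dim(v)), vox_spacing(v), label = label)
}

# --- minimal NRRD (raw little-endian doubles) ----------------------------

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD", magic)) {
    stop(sprintf("'%s' is not an NRRD file", path), call. = FALSE)
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated NRRD header in ", path, call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":\\s*")[[1]]
    fields[[tolower(kv[1])]] <- kv[2]
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.null(ndim) || ndim != 3L) {
    stop(sprintf("'%s' is not a 3-D image (dimension: %s)", path,
                 fields[["dimension"]] %||% "?"), call. = FALSE)
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  spacings <- if (!is.null(fields[["spacings"]])) {
    as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else c(1, 1, 1)
  type <- fields[["type"]]
  enc <- fields[["encoding"]]
  if (!identical(enc, "raw")) stop("only raw NRRD encoding is supported", call. = FALSE)
  n <- prod(sizes)
  vals <- switch(type,
    "double" = readBin(con, "double", n = n, size = 8, endian = "little"),
    "float"  = readBin(con, "double", n = n, size = 4, endian = "little"),
    stop(sprintf("unsupported NRRD type '%s'", type), call. = FALSE)
  )
  voxel_volume(array(vals, dim = sizes), spacing = spacings)
}

write_nrrd <- function(arr, spacing, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    paste("sizes:", paste(dim(arr), collapse = " ")),
    paste("spacings:", paste(format(spacing, digits = 15), collapse = " ")),
    "encoding: raw",
    "endian: little",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- resampling ----------------------------------------------------------

#' Resample a volume onto the grid of another
#'
#' Inputs are assumed co-registered with a shared physical extent
#' (registration happens upstream); resampling only changes grid density.
#' The two grids are aligned at their corners with cell-centered voxels, so a
#' coarse DWI/DTI map and the T2WI matrix covering the same field of view map
#' onto each other directly.
#'
#' @param src `voxel_volume` (or `roi_mask`) to resample.
#' @param target `voxel_volume` whose grid defines the output.
#' @param method `"trilinear"` (intensity images) or `"nearest"` (required
#'   for masks).
#' @return A `voxel_volume` (or `roi_mask`) on the target grid.
#' @export
resample_to_grid <- function(src, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  is_mask <- inherits(src, "roi_mask")
  if (is_mask && method != "nearest") {
    stop("masks must be resampled with method = \"nearest\"", call. = FALSE)
  }
  if (same_grid(src, target)) {
    return(if (is_mask) src else vol_like(as.numeric(src), target))
  }
  sd <- dim(src); td <- dim(target)
  ss <- vox_spacing(src); ts <- vox_spacing(target)
  # cell-centered source index of each target voxel center, per axis
  coord <- lapply(1:3, function(a) {
    (seq_len(td[a]) - 0.5) * ts[a] / ss[a] + 0.5
  })
  src_arr <- array(as.numeric(src), dim = sd)
  eg <- arrayInd(seq_len(prod(td)), td)
  xs <- coord[[1]][eg[, 1]]; xr <- coord[[2]][eg[, 2]]; xc <- coord[[3]][eg[, 3]]
  clamp <- function(i, lo, hi) pmin(pmax(i, lo), hi)
  if (method == "nearest") {
    out <- src_arr[cbind(clamp(as.integer(round(xs)), 1L, sd[1]),
                         clamp(as.integer(round(xr)), 1L, sd[2]),
                         clamp(as.integer(round(xc)), 1L, sd[3]))]
  } else {
    i0s <- clamp(floor(xs), 1, sd[1]); i1s <- clamp(i0s + 1, 1, sd[1])
    i0r <- clamp(floor(xr), 1, sd[2]); i1r <- clamp(i0r + 1, 1, sd[2])
    i0c <- clamp(floor(xc), 1, sd[3]); i1c <- clamp(i0c + 1, 1, sd[3])
    fs <- pmin(pmax(xs - floor(xs), 0), 1)
    fr <- pmin(pmax(xr - floor(xr), 0), 1)
    fc <- pmin(pmax(xc - floor(xc), 0), 1)
    # collapse fractional weight at clamped borders (edge replication)
    fs[floor(xs) < 1] <- 0; fs[floor(xs) >= sd[1]] <- 0
    fr[floor(xr) < 1] <- 0; fr[floor(xr) >= sd[2]] <- 0
    fc[floor(xc) < 1] <- 0; fc[floor(xc) >= sd[3]] <- 0
    out <- numeric(nrow(eg))
    for (a in 0:1) for (b in 0:1) for (ccc in 0:1) {
      w <- (if (a == 0) 1 - fs else fs) *
           (if (b == 0) 1 - fr else fr) *
           (if (ccc == 0) 1 - fc else fc)
      if (all(w == 0)) next
      idx <- cbind(if (a == 0) i0s else i1s,
                   if (b == 0) i0r else i1r,
                   if (ccc == 0) i0c else i1c)
      out <- out + w * src_arr[idx]
    }
  }
  if (is_mask) {
    mask_like(out != 0, target, label = mask_label(src))
  } else {
    vol_like(out, target)
  }
}

#' Bring every channel of a patient case onto the T2WI grid
#'
#' DWI and DTI maps are acquired at coarser in-plane resolution than T2WI and
#' are upsampled to the T2WI matrix (trilinear for intensity maps; the
#' eigenvalue triplet is re-sorted voxelwise after interpolation). Masks use
#' nearest-neighbour resampling.
#'
#' @param case a [patient_case()].
#' @return The case with every volume and mask on the T2WI grid.
#' @export
prepare_case <- function(case) {
  tgt <- case$t2w
  up <- function(v) if (is.null(v)) NULL else resample_to_grid(v, tgt, "trilinear")
  upm <- function(m) if (is.null(m)) NULL else resample_to_grid(m, tgt, "nearest")
  case$dwi_highb <- up(case$dwi_highb)
  case$adc <- up(case$adc)
  if (!is.null(case$eigenvalues)) {
    case$eigenvalues <- dti_eigenvalues(
      up(case$eigenvalues$lambda1),
      up(case$eigenvalues$lambda2),
      up(case$eigenvalues$lambda3)
    )
  }
  case$pz <- upm(case$pz)
  case$reference_tissue <- upm(case$reference_tissue)
  case$rater_masks <- lapply(case$rater_masks, function(lst) lapply(lst, upm))
  case
}
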