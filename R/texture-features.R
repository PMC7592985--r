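# 2-D correlation of a slice with a kernel, border by edge replication.
conv2d_replicate <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kernel); kc <- ncol(kernel)
  cr <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w == 0) next
      ri <- pmin(pmax(seq_len(nr) + (i - cr), 1L), nr)
      ci <- pmin(pmax(seq_len(nc) + (j - cc), 1L), nc)
      out <- out + w * img[ri, ci]
    }
  }
  out
}

gaussian_kernel <- function(sigma) {
  h <- ceiling(3 * sigma)
  x <- -h:h
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

log_kernel <- function(sigma) {
  h <- ceiling(3 * sigma)
  x <- -h:h
  g2 <- outer(x^2, x^2, "+")
  k <- (g2 - 2 * sigma^2) / sigma^4 * exp(-g2 / (2 * sigma^2))
  k - mean(k)  # zero-sum so constants map to 0
}

grad_kernels <- list(
  sobel = list(
    x = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3),
    y = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3),
    diag = matrix(c(-2, -1, 0, -1, 0, 1, 0, 1, 2), 3, 3)
  ),
  prewitt = list(
    x = matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3),
    y = matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3),
    diag = matrix(c(-1, -1, 0, -1, 0, 1, 0, 1, 1), 3, 3)
  ),
  roberts = list(
    x = matrix(c(1, 0, 0, -1), 2, 2),
    y = matrix(c(0, -1, 1, 0), 2, 2),
    diag = matrix(c(1, -1, 1, -1), 2, 2)
  )
)

#' Per-voxel first-order statistics over a sliding window
#'
#' Fifteen first-order texture maps (mean, 25th/75th percentile, variance,
#' SD, median, IQR, mode, min, max, range, skewness, kurtosis, entropy,
#' energy) computed per axial slice over a `window` x `window`
#' neighbourhood with edge replication. Entropy (bits) and energy come from
#' a `nbins` equal-width histogram of the window. Degenerate moments on a
#' constant window are defined as 0 (energy 1).
#'
#' @param vol a [voxel_volume()].
#' @param mask [roi_mask()]: maps are evaluated only at masked voxels (`NA`
#'   elsewhere).
#' @param window odd window width, default 9.
#' @param nbins histogram bins for mode/entropy/energy, default 64.
#' @return Named list of 15 `voxel_volume`s.
#' @export
first_order_maps <- function(vol, mask, window = 9L, nbins = 64L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  }
  stopifnot_same_grid(vol, mask, "volume and mask")
  d <- dim(vol)
  if (d[2] < window || d[3] < window) {
    stop("slice dimensions must be at least the window size", call. = FALSE)
  }
  res <- NULL
  for (s in seq_len(d[1])) {
    sl <- cpp_first_order_2d(array(vol[s, , ], dim = d[2:3]),
                             array(mask[s, , ], dim = d[2:3]),
                             window, as.integer(nbins))
    if (is.null(res)) {
      res <- lapply(sl, function(m) array(NA_real_, dim = d))
    }
    for (k in names(sl)) res[[k]][s, , ] <- sl[[k]]
  }
  lapply(res, vol_like, template = vol)
}

#' Per-voxel GLCM (Haralick) statistics over a sliding window
#'
#' Nineteen second-order texture maps from a gray-level co-occurrence
#' matrix: each masked voxel's `window` x `window` neighbourhood is
#' quantized to `levels` equal-width gray levels over the window's own
#' range, and a single symmetric normalized GLCM is accumulated over the
#' four unit offsets (0/45/90/135 degrees, distance 1). Correlation-type
#' statistics are defined 0 when a marginal SD is 0. Two classical
#' duplicates in the 19-name list are disambiguated by computing `inertia`
#' and `sum_of_squares` from the raw co-occurrence counts while `contrast`
#' and `glcm_variance` use normalized probabilities.
#'
#' @inheritParams first_order_maps
#' @param levels number of gray levels (>= 2), default 32.
#' @return Named list of 19 `voxel_volume`s (see `glcm_stat_names()`).
#' @export
glcm_maps <- function(vol, mask, window = 9L, levels = 32L) {
  window <- as.integer(window); levels <- as.integer(levels)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  }
  if (levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  stopifnot_same_grid(vol, mask, "volume and mask")
  d <- dim(vol)
  res <- NULL
  for (s in seq_len(d[1])) {
    sl <- cpp_glcm_2d(array(vol[s, , ], dim = d[2:3]),
                      array(mask[s, , ], dim = d[2:3]),
                      window, levels)
    if (is.null(res)) {
      res <- lapply(sl, function(m) array(NA_real_, dim = d))
    }
    for (k in names(sl)) res[[k]][s, , ] <- sl[[k]]
  }
  lapply(res, vol_like, template = vol)
}

#' @rdname glcm_maps
#' @export
glcm_stat_names <- function() as.character(cpp_glcm_stat_names())

#' Binary edge maps (six classical operators)
#'
#' Per-slice binary edge detection with Roberts, Prewitt, Sobel, Canny,
#' Laplacian-of-Gaussian, and zero-cross operators, each with its
#' conventional automatic threshold (gradient operators: squared magnitude
#' above 4x its mean; LoG/zero-cross: sign changes whose jump exceeds 0.75x
#' the mean absolute response; Canny: non-maximum suppression with
#' hysteresis at the 70th magnitude percentile and 0.4x that value).
#'
#' @param vol a [voxel_volume()].
#' @return Named list of six 0/1 `voxel_volume`s
#'   (`roberts`, `prewitt`, `sobel`, `canny`, `log`, `zerocross`).
#' @export
edge_maps <- function(vol) {
  d <- dim(vol)
  if (d[2] < 3L || d[3] < 3L) stop("slices must be at least 3 x 3", call. = FALSE)
  ops <- c("roberts", "prewitt", "sobel", "canny", "log", "zerocross")
  res <- lapply(ops, function(o) array(0, dim = d))
  names(res) <- ops
  for (s in seq_len(d[1])) {
    img <- array(vol[s, , ], dim = d[2:3])
    for (op in c("roberts", "prewitt", "sobel")) {
      gx <- conv2d_replicate(img, grad_kernels[[op]]$x)
      gy <- conv2d_replicate(img, grad_kernels[[op]]$y)
      sq <- gx^2 + gy^2
      res[[op]][s, , ] <- (sq > 4 * mean(sq)) * 1
    }
    res$log[s, , ] <- zero_cross_edges(conv2d_replicate(img, log_kernel(2)))
    lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
    res$zerocross[s, , ] <- zero_cross_edges(conv2d_replicate(img, lap))
    res$canny[s, , ] <- canny_edges(img)
  }
  lapply(res, vol_like, template = vol)
}

zero_cross_edges <- function(resp) {
  thr <- 0.75 * mean(abs(resp))
  nr <- nrow(resp); nc <- ncol(resp)
  out <- matrix(0, nr, nc)
  if (thr == 0) return(out)
  right <- cbind(resp[, -1], resp[, nc])
  down <- rbind(resp[-1, ], resp[nr, ])
  cross <- (resp * right < 0 & abs(resp - right) > thr) |
           (resp * down < 0 & abs(resp - down) > thr)
  out[cross] <- 1
  out
}

canny_edges <- function(img, sigma = sqrt(2)) {
  sm <- conv2d_replicate(img, gaussian_kernel(sigma))
  gx <- conv2d_replicate(sm, grad_kernels$sobel$x)
  gy <- conv2d_replicate(sm, grad_kernels$sobel$y)
  mag <- sqrt(gx^2 + gy^2)
  nr <- nrow(img); nc <- ncol(img)
  if (all(mag == 0)) return(matrix(0, nr, nc))
  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4) + 1  # 1:E-W 2:NE-SW 3:N-S 4:NW-SE
  off <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  keep <- matrix(FALSE, nr, nc)
  sh <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[ri, ci]
  }
  for (k in 1:4) {
    o <- off[[k]]
    sel <- sector == k
    keep[sel] <- mag[sel] >= sh(mag, o[1], o[2])[sel] &
                 mag[sel] >= sh(mag, -o[1], -o[2])[sel]
  }
  high <- stats::quantile(mag, 0.7, names = FALSE, type = 7)
  low <- 0.4 * high
  strong <- keep & mag > high
  weak <- keep & mag > low
  # hysteresis: grow strong edges through connected weak voxels
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | (weak & sh(strong, dr, dc))
    }
    if (identical(grown, strong)) break
    strong <- grown
  }
  strong * 1
}

#' Directional gradient maps (sixteen operators)
#'
#' Per-slice continuous gradient responses: Sobel, Prewitt and Roberts
#' kernels in the horizontal (x), vertical (y) and diagonal (xy) directions
#' plus their magnitudes `sqrt(Gx^2 + Gy^2)` (12 maps), and central- and
#' forward(intermediate)-difference derivatives in x and y (4 maps).
#' The x direction runs along columns, y along rows.
#'
#' @param vol a [voxel_volume()].
#' @return Named list of 16 `voxel_volume`s.
#' @export
gradient_maps <- function(vol) {
  d <- dim(vol)
  if (d[2] < 3L || d[3] < 3L) stop("slices must be at least 3 x 3", call. = FALSE)
  nms <- c(t(outer(c("sobel", "prewitt", "roberts"),
                   c("x", "y", "diag", "mag"), paste, sep = "_")),
           "central_x", "central_y", "forward_x", "forward_y")
  res <- lapply(nms, function(o) array(0, dim = d))
  names(res) <- nms
  for (s in seq_len(d[1])) {
    img <- array(vol[s, , ], dim = d[2:3])
    nr <- nrow(img); nc <- ncol(img)
    for (op in c("sobel", "prewitt", "roberts")) {
      gx <- conv2d_replicate(img, grad_kernels[[op]]$x)
      gy <- conv2d_replicate(img, grad_kernels[[op]]$y)
      res[[paste0(op, "_x")]][s, , ] <- gx
      res[[paste0(op, "_y")]][s, , ] <- gy
      res[[paste0(op, "_diag")]][s, , ] <-
        conv2d_replicate(img, grad_kernels[[op]]$diag)
      res[[paste0(op, "_mag")]][s, , ] <- sqrt(gx^2 + gy^2)
    }
    ci <- function(i, n) pmin(pmax(i, 1L), n)
    res$central_x[s, , ] <- (img[, ci(seq_len(nc) + 1, nc)] -
                             img[, ci(seq_len(nc) - 1, nc)]) / 2
    res$central_y[s, , ] <- (img[ci(seq_len(nr) + 1, nr), ] -
                             img[ci(seq_len(nr) - 1, nr), ]) / 2
    res$forward_x[s, , ] <- img[, ci(seq_len(nc) + 1, nc)] - img
    res$forward_y[s, , ] <- img[ci(seq_len(nr) + 1, nr), ] - img
  }
  lapply(res, vol_like, template = vol)
}

#' All 57 per-voxel feature maps for one scalar channel
#'
#' Gray level (1) + first-order (15) + GLCM (19) + edge (6) + gradient (16)
#' maps, named `<channel>_<family>_<statistic>`.
#'
#' @param vol a preprocessed [voxel_volume()].
#' @param mask [roi_mask()] restricting the sliding-window families.
#' @param channel short channel prefix (e.g. `"t2"`, `"hb"`, `"adc"`).
#' @param window,nbins,levels see [first_order_maps()] and [glcm_maps()].
#' @return Named list of 57 `voxel_volume`s.
#' @export
channel_feature_maps <- function(vol, mask, channel, window = 9L,
                                 nbins = 64L, levels = 32L) {
  fo <- first_order_maps(vol, mask, window, nbins)
  gl <- glcm_maps(vol, mask, window, levels)
  ed <- edge_maps(vol)
  gr <- gradient_maps(vol)
  maps <- c(
    stats::setNames(list(vol), "gray"),
    stats::setNames(fo, paste0("fo_", names(fo))),
    stats::setNames(gl, paste0("glcm_", names(gl))),
    stats::setNames(ed, paste0("edge_", names(ed))),
    stats::setNames(gr, paste0("grad_", names(gr)))
  )
  stats::setNames(maps, paste(channel, names(maps), sep = "_"))
}

# which scalar channels + dti a named configuration uses
config_channels <- function(configuration) {
  switch(configuration,
    t2 = list(scalar = c(t2 = "t2w"), dti = FALSE),
    dwi = list(scalar = c(hb = "dwi_highb", adc = "adc"), dti = FALSE),
    t2_dwi = list(scalar = c(t2 = "t2w", hb = "dwi_highb", adc = "adc"),
                  dti = FALSE),
    t2_dti = list(scalar = c(t2 = "t2w"), dti = TRUE),
    full = list(scalar = c(t2 = "t2w", hb = "dwi_highb", adc = "adc"),
                dti = TRUE),
    stop(sprintf("unknown channel configuration '%s'", configuration),
         call. = FALSE)
  )
}

#' Expected feature-column count per channel configuration
#'
#' 57 features per scalar channel plus 20 DTI maps: `t2` 57, `dwi` 114,
#' `t2_dti` 77, `t2_dwi` 171, `full` 191.
#'
#' @param configuration one of `"t2"`, `"dwi"`, `"t2_dwi"`, `"t2_dti"`,
#'   `"full"`.
#' @return Integer column count.
#' @export
expected_feature_count <- function(configuration) {
  ch <- config_channels(configuration)
  57L * length(ch$scalar) + if (ch$dti) 20L else 0L
}

#' Extract every feature map for one patient case
#'
#' @param case a preprocessed, grid-aligned [patient_case()].
#' @param configuration channel configuration (see
#'   [expected_feature_count()]).
#' @param mask evaluation mask, default the case's PZ.
#' @param window,nbins,levels texture parameters.
#' @return Named list of `voxel_volume`s (57 per scalar channel, 20 for DTI,
#'   prefixed `dti_`).
#' @export
extract_case_features <- function(case, configuration = "full", mask = NULL,
                                  window = 9L, nbins = 64L, levels = 32L) {
  ch <- config_channels(configuration)
  if (is.null(mask)) mask <- case$pz
  maps <- list()
  for (pref in names(ch$scalar)) {
    vol <- case[[ch$scalar[[pref]]]]
    if (is.null(vol)) {
      stop(sprintf("case %s lacks channel '%s' required by configuration '%s'",
                   case$patient_id, ch$scalar[[pref]], configuration),
           call. = FALSE)
    }
    maps <- c(maps, channel_feature_maps(vol, mask, pref, window, nbins, levels))
  }
  if (ch$dti) {
    if (is.null(case$eigenvalues)) {
      stop(sprintf("case %s lacks DTI eigenvalues required by configuration '%s'",
                   case$patient_id, configuration), call. = FALSE)
    }
    dm <- compute_dti_maps(case$eigenvalues, mask)
    maps <- c(maps, stats::setNames(dm, paste0("dti_", names(dm))))
  }
  maps
}

#' Tabulate feature maps at masked voxels
#'
#' @param maps named list of `voxel_volume`s on a common grid.
#' @param mask [roi_mask()] selecting the voxels.
#' @return Tibble with `slice`, `row`, `col` and one column per map.
#' @export
features_at_mask <- function(maps, mask) {
  sel <- which(as.logical(mask))
  idx <- arrayInd(sel, dim(mask))
  vals <- lapply(maps, function(m) as.numeric(m)[sel])
  tibble::as_tibble(c(
    list(slice = idx[, 1], row = idx[, 2], col = idx[, 3]),
    vals
  ))
}

#' Assemble the labeled voxel-by-feature matrix for one patient
#'
#' One row per voxel inside the cancer (+1) or noncancer (-1) mask, with
#' coordinates, patient id, label, and every feature column. Voxels with any
#' undefined feature are dropped (count reported in the `n_dropped`
#' attribute).
#'
#' @param maps named list of feature `voxel_volume`s.
#' @param cancer,noncancer disjoint [roi_mask()]s on the map grid.
#' @param patient_id character scalar.
#' @return A tibble with columns `patient_id`, `slice`, `row`, `col`,
#'   `label`, then the features.
#' @export
assemble_feature_matrix <- function(maps, cancer, noncancer, patient_id) {
  stopifnot_same_grid(cancer, noncancer, "label masks")
  if (any(cancer & noncancer)) {
    stop("cancer and noncancer masks overlap", call. = FALSE)
  }
  tab_pos <- features_at_mask(maps, cancer)
  tab_neg <- features_at_mask(maps, noncancer)
  tab <- dplyr::bind_rows(
    dplyr::mutate(tab_pos, label = 1, .after = "col"),
    dplyr::mutate(tab_neg, label = -1, .after = "col")
  )
  tab <- dplyr::mutate(tab, patient_id = patient_id, .before = 1L)
  feat <- feature_columns(tab)
  complete <- stats::complete.cases(tab[feat])
  out <- tab[complete, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!complete)
  out
}

#' @rdname assemble_feature_matrix
#' @param matrix a feature-matrix tibble.
#' @export
feature_columns <- function(matrix) {
  setdiff(names(matrix), c("patient_id", "slice", "row", "col", "label"))
}

#' Min-max normalization fitted on training rows
#'
#' Maps every feature column to `[0, 1]` via `(x - min) / (max - min)` with
#' the extrema learned on the training rows only. Constant columns map to 0;
#' when an existing `state` is applied (test rows), values are clipped to
#' `[0, 1]`.
#'
#' @param matrix feature-matrix tibble (see [assemble_feature_matrix()]).
#' @param state `NULL` to fit, or a state tibble returned by a previous call
#'   to apply.
#' @return List with `matrix` (normalized tibble) and `state` (tibble of
#'   `feature`, `min`, `max`).
#' @export
minmax_fit_apply <- function(matrix, state = NULL) {
  feat <- feature_columns(matrix)
  if (is.null(state)) {
    state <- tibble::tibble(
      feature = feat,
      min = vapply(matrix[feat], function(x) min(x, na.rm = TRUE), numeric(1),
                   USE.NAMES = FALSE),
      max = vapply(matrix[feat], function(x) max(x, na.rm = TRUE), numeric(1),
                   USE.NAMES = FALSE)
    )
    clip <- FALSE
  } else {
    if (!setequal(state$feature, feat)) {
      stop("normalization state columns do not match the feature matrix",
           call. = FALSE)
    }
    clip <- TRUE
  }
  for (i in seq_len(nrow(state))) {
    f <- state$feature[i]
    rng <- state$max[i] - state$min[i]
    x <- if (rng > 0) (matrix[[f]] - state$min[i]) / rng else rep(0, nrow(matrix))
    if (clip) x <- pmin(pmax(x, 0), 1)
    matrix[[f]] <- x
  }
  list(matrix = matrix, state = state)
}
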