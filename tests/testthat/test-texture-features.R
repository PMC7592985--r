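center_mask <- function(d, at = NULL) {
  m <- array(FALSE, dim = d)
  at <- at %||% ceiling(d / 2)
  m[at[1], at[2], at[3]] <- TRUE
  roi_mask(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("first-order maps on a constant window take their degenerate values", {
  vol <- const_vol(5, dim = c(1, 9, 9))
  fo <- first_order_maps(vol, center_mask(dim(vol)), window = 9)
  at <- function(nm) fo[[nm]][1, 5, 5]
  expect_equal(at("variance"), 0)
  expect_equal(at("sd"), 0)
  expect_equal(at("iqr"), 0)
  expect_equal(at("range"), 0)
  expect_equal(at("entropy"), 0)
  expect_equal(at("energy"), 1)
  expect_equal(at("skewness"), 0)
  expect_equal(at("kurtosis"), 0)
  expect_equal(at("mean"), 5)
  expect_equal(at("mode"), 5)
})

test_that("a 9x9 window holding 1..81 yields the textbook statistics", {
  vol <- voxel_volume(array(matrix(1:81, 9, 9), dim = c(1, 9, 9)))
  fo <- first_order_maps(vol, center_mask(dim(vol)), window = 9)
  at <- function(nm) fo[[nm]][1, 5, 5]
  expect_equal(at("mean"), 41)
  expect_equal(at("median"), 41)
  expect_equal(at("min"), 1)
  expect_equal(at("max"), 81)
  expect_equal(at("range"), 80)
})

test_that("first-order maps match the per-statistic brute-force oracle", {
  set.seed(31)
  img <- matrix(rnorm(15 * 15), 15, 15)
  vol <- voxel_volume(array(img, dim = c(1, 15, 15)))
  mask <- roi_mask(array(TRUE, dim = dim(vol)))
  fo <- first_order_maps(vol, mask, window = 9, nbins = 64)
  # includes border voxels, exercising edge replication
  for (rc in list(c(8, 8), c(1, 1), c(2, 13), c(15, 4))) {
    want <- oracle_first_order(oracle_window(img, rc[1], rc[2], 9), 64)
    got <- vapply(names(want), function(nm) fo[[nm]][1, rc[1], rc[2]],
                  numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("first-order maps reject even windows and undersized slices", {
  vol <- const_vol(1, dim = c(1, 9, 9))
  expect_error(first_order_maps(vol, center_mask(dim(vol)), window = 8), "odd")
  small <- const_vol(1, dim = c(1, 5, 5))
  expect_error(first_order_maps(small, center_mask(dim(small)), window = 9),
               "window")
})

test_that("GLCM maps on a constant window collapse to a single cell", {
  vol <- const_vol(2, dim = c(1, 9, 9))
  gl <- glcm_maps(vol, center_mask(dim(vol)), window = 9)
  at <- function(nm) gl[[nm]][1, 5, 5]
  expect_equal(at("energy"), 1)
  expect_equal(at("entropy"), 0)
  expect_equal(at("contrast"), 0)
  expect_equal(at("dissimilarity"), 0)
  expect_equal(at("maximum_probability"), 1)
  expect_equal(at("homogeneity"), 1)
  expect_equal(at("correlation"), 0)  # declared value at zero marginal SD
  expect_equal(at("mcc"), 0)
})

test_that("alternating two-level pattern has the hand-counted horizontal GLCM", {
  win <- matrix(rep(c(0, 1), 8), 4, 4, byrow = TRUE)
  counts <- oracle_glcm_counts(win, levels = 2, offsets = list(c(0, 1)))
  P <- counts / sum(counts)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(P[1, 1], 0)
  st <- oracle_glcm_stats(counts)
  expect_equal(st[["contrast"]], 1)
  expect_equal(st[["energy"]], 0.5)
  expect_equal(st[["entropy"]], 1)
})

test_that("GLCM maps equal the exhaustive pair-enumeration oracle", {
  set.seed(32)
  for (rep_i in 1:20) {
    img <- matrix(rnorm(81), 9, 9)
    vol <- voxel_volume(array(img, dim = c(1, 9, 9)))
    gl <- glcm_maps(vol, center_mask(dim(vol)), window = 9, levels = 32)
    want <- oracle_glcm_stats(oracle_glcm_counts(img, 32))
    got <- vapply(names(want), function(nm) gl[[nm]][1, 5, 5], numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("GLCM maps reject an invalid level count", {
  vol <- const_vol(1, dim = c(1, 9, 9))
  expect_error(glcm_maps(vol, center_mask(dim(vol)), levels = 1), "levels")
})

test_that("edge maps are zero on constants and invariant to offsets", {
  vol <- const_vol(9, dim = c(2, 16, 16))
  ed <- edge_maps(vol)
  expect_length(ed, 6)
  for (m in ed) expect_true(all(m == 0))

  set.seed(33)
  img <- array(rnorm(2 * 16 * 16), dim = c(2, 16, 16))
  e1 <- edge_maps(voxel_volume(img))
  e2 <- edge_maps(voxel_volume(img + 117.3))
  for (nm in names(e1)) {
    expect_equal(as.numeric(e1[[nm]]), as.numeric(e2[[nm]]), info = nm)
  }
})

test_that("gradient operators mark an ideal vertical step as a boundary band", {
  img <- array(0, dim = c(1, 16, 16))
  img[1, , 9:16] <- 10
  ed <- edge_maps(voxel_volume(img))
  for (op in c("sobel", "prewitt", "roberts")) {
    m <- ed[[op]][1, , ]
    # every row crosses the step: some column near 8/9 is flagged
    flagged_cols <- which(colSums(m) > 0)
    expect_true(all(flagged_cols >= 7 & flagged_cols <= 10), info = op)
    expect_true(all(rowSums(m[, 7:10, drop = FALSE]) > 0), info = op)
    # direct kernel + threshold oracle
    k <- pzrad:::grad_kernels[[op]]
    gx <- pzrad:::conv2d_replicate(img[1, , ], k$x)
    gy <- pzrad:::conv2d_replicate(img[1, , ], k$y)
    sq <- gx^2 + gy^2
    expect_equal(m, (sq > 4 * mean(sq)) * 1, info = op)
  }
})

test_that("gradient maps vanish on constants and match ramp closed forms", {
  vol <- const_vol(3, dim = c(1, 12, 12))
  gr <- gradient_maps(vol)
  expect_length(gr, 16)
  for (m in gr) expect_true(all(m == 0))

  ramp <- voxel_volume(array(matrix(rep(1:12, each = 12), 12, 12),
                             dim = c(1, 12, 12)))  # I(row, col) = col
  gr <- gradient_maps(ramp)
  interior <- function(m) m[1, 3:10, 3:10]
  expect_true(all(interior(gr$central_x) == 1))
  expect_true(all(interior(gr$central_y) == 0))
  expect_true(all(interior(gr$forward_x) == 1))
  expect_true(all(interior(gr$sobel_x) == 8))
  expect_true(all(interior(gr$sobel_y) == 0))
  expect_true(all(interior(gr$sobel_mag) == 8))
  expect_true(all(interior(gr$prewitt_x) == 6))

  # rotating the ramp by 90 degrees swaps x and y responses
  rampT <- voxel_volume(array(t(matrix(rep(1:12, each = 12), 12, 12)),
                              dim = c(1, 12, 12)))
  grT <- gradient_maps(rampT)
  expect_equal(interior(grT$sobel_y), interior(gr$sobel_x))
  expect_equal(interior(grT$central_y), interior(gr$central_x))
})

test_that("sliding-window maps are translation-equivariant at the interior", {
  set.seed(34)
  base <- matrix(rnorm(20 * 20), 20, 20)
  sh <- 3L
  shifted <- base
  shifted[, (1 + sh):20] <- base[, 1:(20 - sh)]
  v1 <- voxel_volume(array(base, dim = c(1, 20, 20)))
  v2 <- voxel_volume(array(shifted, dim = c(1, 20, 20)))
  m <- roi_mask(array(TRUE, dim = c(1, 20, 20)))
  f1 <- first_order_maps(v1, m, 5)
  f2 <- first_order_maps(v2, m, 5)
  for (nm in c("mean", "variance", "entropy")) {
    expect_equal(f2[[nm]][1, 5:16, (5 + sh):(14 + sh)],
                 f1[[nm]][1, 5:16, 5:14], tolerance = 1e-12, info = nm)
  }
})
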