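eig_from_triplets <- function(trip) {
  # trip: n x 3 matrix of sorted eigenvalues -> volumes of shape (1, n, 1)
  n <- nrow(trip)
  mk <- function(k) voxel_volume(array(trip[, k], dim = c(1, n, 1)))
  dti_eigenvalues(mk(1), mk(2), mk(3))
}

map_vals <- function(maps, i) {
  vapply(maps, function(m) m[1, i, 1], numeric(1))
}

test_that("isotropic and stick tensors hit their closed forms", {
  d <- 1.7e-3
  eig <- eig_from_triplets(rbind(c(d, d, d), c(1, 0, 0)))
  maps <- compute_dti_maps(eig, full_mask(eig$lambda1))
  iso <- map_vals(maps, 1)
  expect_equal(iso[["fa"]], 0, tolerance = 1e-12)
  expect_equal(iso[["ra"]], 0, tolerance = 1e-12)
  expect_equal(iso[["vr"]], 1, tolerance = 1e-12)
  expect_equal(iso[["cl"]], 0, tolerance = 1e-12)
  expect_equal(iso[["cp"]], 0, tolerance = 1e-12)
  expect_equal(iso[["cs"]], 1, tolerance = 1e-12)
  expect_equal(iso[["mode"]], 0, tolerance = 1e-12)
  expect_equal(iso[["md"]], d, tolerance = 1e-15)
  expect_equal(iso[["rd"]], d, tolerance = 1e-15)
  expect_equal(iso[["d12"]], 0)
  expect_equal(iso[["d23"]], 0)
  expect_equal(iso[["vd"]], d^3, tolerance = 1e-12)
  expect_equal(iso[["s12"]], d^2, tolerance = 1e-12)

  stick <- map_vals(maps, 2)
  expect_equal(stick[["fa"]], 1, tolerance = 1e-12)
  expect_equal(stick[["vr"]], 0, tolerance = 1e-12)
  expect_equal(stick[["cl"]], 1, tolerance = 1e-12)
  expect_equal(stick[["cp"]], 0, tolerance = 1e-12)
  expect_equal(stick[["cs"]], 0, tolerance = 1e-12)
})

test_that("the reference triplet evaluates to its double-precision values", {
  trip <- matrix(c(2.0, 1.0, 0.5) * 1e-3, nrow = 1)
  maps <- compute_dti_maps(eig_from_triplets(trip),
                           full_mask(voxel_volume(array(0, c(1, 1, 1)))))
  v <- map_vals(maps, 1)
  expect_equal(v[["md"]], 3.5e-3 / 3, tolerance = 1e-12)
  expect_equal(v[["fa"]], sqrt(1 / 3), tolerance = 1e-6)
  expect_equal(v[["fa"]], 0.5774, tolerance = 1e-4)
  expect_equal(v[["rd"]], 0.75e-3, tolerance = 1e-12)
  expect_equal(v[["vd"]], 1.0e-9, tolerance = 1e-15)
  expect_equal(v[["cl"]], 1 / 3.5, tolerance = 1e-12)
  expect_equal(v[["cp"]], 1 / 3.5, tolerance = 1e-12)
  expect_equal(v[["cs"]], 1.5 / 3.5, tolerance = 1e-12)
  expect_equal(v[["cs"]], 0.4286, tolerance = 1e-4)
})

test_that("the 20 map names are fixed and complete", {
  expect_length(dti_map_names(), 20)
  trip <- matrix(c(2, 1, 0.5) * 1e-3, nrow = 1)
  maps <- compute_dti_maps(eig_from_triplets(trip),
                           full_mask(voxel_volume(array(0, c(1, 1, 1)))))
  expect_identical(names(maps), dti_map_names())
})

test_that("anisotropy measures are scale-invariant, diffusivities covariant", {
  set.seed(12)
  n <- 50
  raw <- matrix(runif(3 * n, 0.1e-3, 3e-3), n, 3)
  trip <- t(apply(raw, 1, sort, decreasing = TRUE))
  s <- 2.9
  m1 <- compute_dti_maps(eig_from_triplets(trip),
                         full_mask(voxel_volume(array(0, c(1, n, 1)))))
  m2 <- compute_dti_maps(eig_from_triplets(s * trip),
                         full_mask(voxel_volume(array(0, c(1, n, 1)))))
  for (nm in c("fa", "ra", "vr", "cl", "cp", "cs", "mode", "ac")) {
    expect_equal(as.numeric(m2[[nm]]), as.numeric(m1[[nm]]), tolerance = 1e-9,
                 info = nm)
  }
  for (nm in c("md", "rd", "lambda1", "lambda2", "lambda3", "d12", "d13",
               "d23")) {
    expect_equal(as.numeric(m2[[nm]]), s * as.numeric(m1[[nm]]),
                 tolerance = 1e-9, info = nm)
  }
  expect_equal(as.numeric(m2$vd), s^3 * as.numeric(m1$vd), tolerance = 1e-9)
  for (nm in c("s12", "s13", "s23")) {
    expect_equal(as.numeric(m2[[nm]]), s^2 * as.numeric(m1[[nm]]),
                 tolerance = 1e-9, info = nm)
  }
})

test_that("Westin measures sum to one wherever the trace is positive", {
  set.seed(13)
  n <- 200
  trip <- t(apply(matrix(runif(3 * n, 0, 3e-3), n, 3), 1, sort,
                  decreasing = TRUE))
  maps <- compute_dti_maps(eig_from_triplets(trip),
                           full_mask(voxel_volume(array(0, c(1, n, 1)))))
  s <- as.numeric(maps$cl) + as.numeric(maps$cp) + as.numeric(maps$cs)
  expect_true(all(abs(s - 1) < 1e-12))
  expect_true(all(as.numeric(maps$fa) >= 0 & as.numeric(maps$fa) <= 1 + 1e-12))
  expect_true(all(as.numeric(maps$vr) >= 0 & as.numeric(maps$vr) <= 1 + 1e-9))
  expect_true(all(abs(as.numeric(maps$mode)) <= 1 + 1e-9))
})

test_that("FA matches an independent full-tensor matrix-norm oracle", {
  set.seed(14)
  n <- 1000
  trip <- t(apply(matrix(runif(3 * n, 0, 3e-3), n, 3), 1, sort,
                  decreasing = TRUE))
  maps <- compute_dti_maps(eig_from_triplets(trip),
                           full_mask(voxel_volume(array(0, c(1, n, 1)))))
  want <- vapply(seq_len(n), function(i) {
    oracle_fa_tensor(trip[i, 1], trip[i, 2], trip[i, 3])
  }, numeric(1))
  expect_lt(max(abs(as.numeric(maps$fa) - want)), 1e-12)
})

test_that("ingest sorts eigenvalues and clamps negatives", {
  l1 <- voxel_volume(array(c(0.5e-3, -1e-4), dim = c(1, 2, 1)))
  l2 <- voxel_volume(array(c(2e-3, 1e-3), dim = c(1, 2, 1)))
  l3 <- voxel_volume(array(c(1e-3, 2e-3), dim = c(1, 2, 1)))
  eig <- dti_eigenvalues(l1, l2, l3)
  expect_equal(eig$lambda1[1, 1, 1], 2e-3)
  expect_equal(eig$lambda3[1, 1, 1], 0.5e-3)
  expect_equal(eig$lambda3[1, 2, 1], 0)  # clamped
  expect_equal(attr(eig, "n_clamped"), 1)
})

test_that("zero trace yields zero ratio maps, and empty masks error", {
  trip <- matrix(0, 1, 3)
  maps <- compute_dti_maps(eig_from_triplets(trip),
                           full_mask(voxel_volume(array(0, c(1, 1, 1)))))
  v <- map_vals(maps, 1)
  for (nm in c("fa", "ra", "vr", "cl", "cp", "cs", "ac", "mode")) {
    expect_equal(v[[nm]], 0, info = nm)
  }
  empty <- roi_mask(array(FALSE, c(1, 1, 1)))
  expect_error(compute_dti_maps(eig_from_triplets(trip), empty), "no voxels")
})
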