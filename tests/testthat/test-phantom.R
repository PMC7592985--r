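test_that("generation is deterministic given spec and seed", {
  spec <- tiny_spec(seed = 81)
  c1 <- generate_patient(spec, patient_seed = 101)
  c2 <- generate_patient(spec, patient_seed = 101)
  expect_identical(as.numeric(c1$t2w), as.numeric(c2$t2w))
  expect_identical(as.numeric(c1$adc), as.numeric(c2$adc))
  expect_identical(as.logical(c1$rater_masks$rater2[[1]]),
                   as.logical(c2$rater_masks$rater2[[1]]))
  coh1 <- generate_cohort(tiny_spec(n_patients = 3, seed = 5), prepare = FALSE)
  coh2 <- generate_cohort(tiny_spec(n_patients = 3, seed = 5), prepare = FALSE)
  expect_identical(as.numeric(coh1[[2]]$t2w), as.numeric(coh2[[2]]$t2w))
})

test_that("cohorts have distinct patient ids and differing volumes", {
  coh <- generate_cohort(tiny_spec(n_patients = 16, seed = 2), prepare = FALSE)
  ids <- vapply(coh, function(x) x$patient_id, character(1))
  expect_length(unique(ids), 16)
  expect_false(identical(as.numeric(coh[[1]]$t2w), as.numeric(coh[[2]]$t2w)))
})

test_that("noiseless contrast separates lesion and background per channel", {
  spec <- tiny_spec(seed = 83, noise_sd = list(t2 = 0, hb = 0, adc = 0, eig = 0),
                    bias_amplitude = 0)
  case <- prepare_case(generate_patient(spec, patient_seed = 11))
  d <- dim(case$t2w)
  shift2d <- function(m, dr, dc) {
    ci <- function(i, n) pmin(pmax(i, 1L), n)
    out <- m
    for (s in seq_len(d[1])) out[s, , ] <- m[s, ci(seq_len(d[2]) - dr, d[2]),
                                             ci(seq_len(d[3]) - dc, d[3])]
    out
  }
  les <- as.logical(case$rater_masks$rater1[[1]])
  dim(les) <- d
  # erode/dilate by 2 in-plane voxels to step past the upsampling
  # interpolation ring at the lesion boundary
  core <- les; halo <- les
  for (dr in -2:2) for (dc in -2:2) {
    core <- core & shift2d(les, dr, dc)
    halo <- halo | shift2d(les, dr, dc)
  }
  bg <- as.logical(case$pz) & !halo
  expect_gt(sum(core), 0)
  for (ch in c("t2w", "dwi_highb", "adc")) {
    v <- as.numeric(case[[ch]])
    lo <- range(v[core]); hi <- range(v[bg])
    disjoint <- lo[2] < hi[1] || hi[2] < lo[1]
    expect_true(disjoint, info = ch)
  }
})

test_that("null phantom has identical lesion and background distributions", {
  spec <- tiny_spec(seed = 84, contrast = 0,
                    noise_sd = list(t2 = 0, hb = 0, adc = 0, eig = 0),
                    bias_amplitude = 0)
  case <- generate_patient(spec, patient_seed = 12)
  les <- as.logical(case$rater_masks$rater1[[1]])
  pz <- as.logical(case$pz)
  v <- as.numeric(case$t2w)
  expect_equal(unique(v[les]), unique(v[pz & !les]))
})

test_that("eigenvalue fields are sorted and positive within the PZ", {
  case <- generate_patient(tiny_spec(seed = 85), patient_seed = 13)
  pz_lo <- pzrad:::pz_membership(dim(case$adc), vox_spacing(case$adc),
                                 dim(case$t2w), vox_spacing(case$t2w))
  l1 <- as.numeric(case$eigenvalues$lambda1)[pz_lo]
  l2 <- as.numeric(case$eigenvalues$lambda2)[pz_lo]
  l3 <- as.numeric(case$eigenvalues$lambda3)[pz_lo]
  expect_true(all(l1 >= l2 & l2 >= l3))
  expect_true(all(l3 >= 0))
  expect_true(all(l1 > 0))
})

test_that("reference summaries differ across patients then standardize to 1", {
  coh <- generate_cohort(tiny_spec(n_patients = 3, seed = 86))
  pre <- preprocess_cohort(coh)
  expect_gt(stats::sd(pre$reference$median_plus_iqr), 0)
  for (case in pre$cohort) {
    expect_equal(reference_summary(case$t2w, case$reference_tissue), 1,
                 tolerance = 1e-12)
  }
})

test_that("mask perturbation is identity at radius 0 and degrades with radius", {
  case <- generate_patient(tiny_spec(seed = 87), patient_seed = 14)
  les <- case$rater_masks$rater1[[1]]
  expect_equal(dice(les, perturb_mask(les, 0, seed = 1)), 1)
  mean_dice <- function(r) {
    mean(vapply(1:30, function(i) {
      dice(les, perturb_mask(les, r, seed = 500 + i))
    }, numeric(1)))
  }
  d1 <- mean_dice(1); d3 <- mean_dice(3); d6 <- mean_dice(6)
  expect_gt(d1, d3)
  expect_gt(d3, d6)
  expect_lt(d6, 0.5)  # displaced past most of the lesion diameter
})

test_that("the default rater radius lands in the calibrated Dice band", {
  spec <- phantom_spec(seed = 1)
  case <- generate_patient(spec, patient_seed = 1234)
  les <- case$rater_masks$rater1[[1]]
  ds <- vapply(1:50, function(i) {
    dice(les, perturb_mask(les, spec$rater_radius, seed = 1000 + i))
  }, numeric(1))
  expect_gte(mean(ds), 0.70)
  expect_lte(mean(ds), 0.85)
})

test_that("cohorts round-trip through the NIfTI directory layout", {
  coh <- generate_cohort(tiny_spec(n_patients = 2, seed = 88), prepare = FALSE)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(coh, dir)
  back <- read_cohort(dir, prepare = FALSE)
  expect_length(back, 2)
  expect_equal(as.numeric(back[[1]]$t2w), as.numeric(coh[[1]]$t2w),
               tolerance = 1e-12)
  expect_identical(as.logical(back[[2]]$pz), as.logical(coh[[2]]$pz))
  expect_length(back[[1]]$rater_masks$rater1,
                length(coh[[1]]$rater_masks$rater1))
  unlink(dir, recursive = TRUE)
})
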