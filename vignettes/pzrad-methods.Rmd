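---
title: "Voxel-wise PZ cancer classification: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise PZ cancer classification: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pzrad)
```

pzrad classifies individual MRI voxels of the prostate peripheral zone (PZ)
as cancerous or noncancerous from noncontrast multiparametric MRI: a
T2-weighted volume, a high-b-value diffusion-weighted volume, an ADC map,
and the three eigenvalue volumes of the diffusion tensor. This vignette is
the package's own account of the science: the processing model, every
tunable that matters, what the synthetic phantom does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made.

## The processing model

The pipeline assumes its inputs are already bias-corrected, co-registered,
and (for DTI) tensor-fitted; those steps belong to upstream tools. From
there:

1. **Grid harmonization.** DWI and DTI maps are acquired at coarser
   in-plane resolution and are upsampled to the T2WI matrix
   (`resample_to_grid()`, trilinear for intensity maps, nearest for masks).
   Grids are aligned at their corners with cell-centered voxels; resampling
   changes grid density, never pose. Eigenvalue triplets are re-sorted
   voxelwise after interpolation.
2. **Preprocessing.** The T2WI is median-filtered (3 x 3, per axial slice,
   edge replication) and divided by a per-patient reference-tissue summary:
   the median plus interquartile range of the intensities inside a
   reference mask. The reference tissue is the candidate with the lowest
   inter-patient coefficient of variation of that summary
   (`choose_reference_tissue()`); in the clinical setting this selects the
   ischioanal fossa over urine, bone marrow, and muscle. Standardization
   removes per-patient global scale exactly: the standardized volume's own
   reference summary is 1. Quantitative maps (ADC, eigenvalues) stay in
   native units.
3. **Feature extraction.** 57 per-voxel maps per scalar channel — the
   intensity itself, 15 first-order window statistics, 19 gray-level
   co-occurrence (GLCM) statistics, 6 binary edge maps, and 16 directional
   gradient maps — plus 20 DTI scalar maps, for 191 features in the full
   configuration (57/114/77/171 for the T2-only, DWI-pair, T2+DTI and
   T2+DWI configurations).
4. **Labels.** Cancer voxels are the voxelwise intersection of two raters'
   lesion outlines, matched by spatial overlap; unmatched lesions are
   excluded and reported. The rest of the PZ is noncancer. This favours
   label certainty over completeness: the discordant ring around each
   lesion is deliberately labeled noncancer.
5. **Learning.** Per training set: min–max normalization to [0, 1]
   (fitted on training rows; test rows are clipped), correlation-based
   feature selection (CFS) by best-first search, Gaussian-process Bayesian
   optimization of the RBF-SVM's `C` and `gamma` on `[1e-4, 1e3]` by mean
   cross-validated AUROC, a class-weighted SVM fit, and Platt sigmoid
   calibration of the decision values.
6. **Validation.** Leave-one-patient-out: every training-side statistic —
   normalization extrema, CFS correlations, optimizer objective, SVM, and
   Platt parameters — is computed from the remaining patients only. Each
   fold records its training patient ids so this can be audited.
7. **Maps.** For a new patient, every PZ voxel receives a calibrated
   probability `P = 1/(1 + exp(A f + B))` and a binary label; voxels
   outside the PZ carry `NA`.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| texture window | 9 x 9 | voxels | a mid-sized window: large enough for meaningful statistics, small enough to localize lesion boundaries; the established choice for prostate texture on MRI |
| median filter | 3 x 3 | voxels | minimal salt-and-pepper suppression without blurring lesion margins |
| GLCM gray levels | 32 | levels | quantization over the window's own range; 32 levels keep a 9 x 9 window's co-occurrence matrix meaningfully populated |
| first-order histogram bins | 64 | bins | used only by entropy/energy/mode |
| CFS patience | 5 | expansions | best-first stops after five consecutive non-improving expansions |
| optimizer budget | 30 evaluations, 10-fold CV | — | Gaussian-process expected improvement over `log10 C, log10 gamma` on `[1e-4, 1e3]^2` |
| training cap | 300 voxels/class/patient | voxels | stratified subsample bounding the quadratic SVM cost; held-out patients are always evaluated on every voxel |

All of these live in `pz_config()` and every stochastic step derives from
its single `seed`.

## Numerical conventions

These are places where the literature admits several definitions; each is a
config-level constant, fixed as follows:

* **Quantiles** use linear interpolation between order statistics (type 7)
  everywhere — the reference summary, window percentiles, and IQR all
  depend on this.
* **First-order moments**: variance and SD use the sample (n−1)
  denominator; skewness is `m3/m2^1.5` and kurtosis `m4/m2^2` (not excess);
  all degenerate moments on a constant window are defined as 0, energy
  as 1. The inter-patient CV uses the sample SD, the small-cohort
  convention.
* **GLCM**: one symmetric matrix accumulated over the four unit offsets at
  distance 1, normalized after accumulation; correlation-type statistics
  are 0 when a marginal SD is 0; entropies are in bits. The 19-name feature
  list contains two classically identical pairs (contrast/inertia,
  variance/sum-of-squares); the package disambiguates them by computing
  `inertia` and `sum_of_squares` from the raw co-occurrence counts while
  `contrast` and `glcm_variance` use normalized probabilities, so both the
  count and the names are preserved.
* **Edge operators**: Roberts/Prewitt/Sobel threshold the squared gradient
  magnitude at 4x its slice mean; LoG (sigma 2) and zero-cross (plain
  Laplacian) mark sign changes whose jump exceeds 0.75x the mean absolute
  response; Canny uses Gaussian smoothing (sigma sqrt(2)), non-maximum
  suppression, and hysteresis at the 70th magnitude percentile with a low
  threshold at 0.4x that. The classical edge-operator set lists six
  operators; zero-cross completes it alongside Roberts, Prewitt, Sobel,
  Canny and LoG.
* **Gradient partition**: Sobel/Prewitt/Roberts x {x, y, diagonal,
  magnitude} (12) plus central- and forward-difference x/y (4). x runs
  along columns, y along rows.
* **Westin anisotropies** use the trace denominator, so `Cl + Cp + Cs = 1`
  identically. The `lambda1` denominator variant exists in the literature;
  the trace form was chosen for this sum-to-one property.
* **Attenuation coefficient (AC)**: no standard formula exists under this
  name. The package implements the axial-to-radial ratio
  `AC = lambda1 / RD` (0 where RD = 0) and exposes `ac_fun` in
  `compute_dti_maps()` so another convention can be plugged in. Results
  involving AC and tensor mode are convention-sensitive.
* **Degenerate inputs**: eigenvalues are sorted on ingest and negative
  values clamped to 0 (count recorded); zero-trace voxels give 0 for every
  ratio map; constant feature columns map to 0 under min–max
  normalization; Dice of two empty masks is 1.
* **Kernel**: the Gaussian RBF `exp(-gamma ||x - x'||^2)`. An unsquared
  variant sometimes appears in print; the squared form is the standard
  kernel that `gamma` bounds of `[1e-4, 1e3]` presume.

## Open design choices

**Binary operating point.** The SVM's raw `sign(f)` threshold and the
calibrated-probability threshold at 0.5 coincide only when the Platt
intercept `B` is 0. In near-flat regions of the AUROC objective the libsvm
intercept can drift while ranking quality is unaffected, making raw
`sign(f)` an unreliable operating point. The package thresholds at the
fitted sigmoid's 0.5 crossing, `f = -B/A` — the calibrated version of the
same rule, identical to `sign(f)` for balanced calibrations.

**Optimizer tie-break.** The optimization objective is mean cross-validated
AUROC, with folds grouped by patient so no patient straddles the objective's
train/validation split (stricter than voxel-level folds). Among evaluations
within 0.005 of the best AUROC — indistinguishable at these fold sizes — the
incumbent is the one with the best cross-validated balanced accuracy at the
calibrated threshold. This keeps hyperparameter selection aligned with the
operating point without changing the objective.

**Class imbalance.** Noncancer voxels outnumber cancer voxels severalfold;
the SVM uses inverse-frequency class weights, without which specificity
trivially dominates.

**Platt calibration data.** The sigmoid is fitted to the training-set
decision values with Platt's smoothed targets. Fitting to cross-validated
decision values would be less optimistic; with the training cap in place
the practical difference on the phantom is negligible, and the simpler
choice keeps each fold's model self-contained.

**Standardization order.** The reference summary is computed on the
median-filtered T2WI and the filtered volume is standardized — filtering
first means the divisor is robust to impulse noise.

**CFS on pure noise.** The CFS merit `k r_cf / sqrt(k + k(k-1) r_ff)`
strictly increases when mutually uncorrelated features with nonzero sample
class correlation are added, so on label-free data the search aggregates
noise features at near-zero merit. The meaningful null signature is the
merit value, not the subset size, and the tests assert it that way.

## What the phantom emulates — and what it does not

`phantom_spec()` builds a seeded cohort with the statistical structure the
pipeline assumes: a posterior annular PZ on a 64 x 64 x 8 grid at
0.8 x 0.8 x 4 mm; ellipsoidal lesions of 0.5–1.5 cc; channel contrasts in
the clinically observed directions (lesions dark on T2WI and ADC, bright on
high-b DWI; reduced mean diffusivity and raised anisotropy on DTI, with ADC
around 1.6 vs 0.8 x 10^-3 mm^2/s); a smooth multiplicative intensity field;
Gaussian noise; coarser native DWI/DTI grids; a reference-tissue region
outside the PZ; and two raters, the second a bounded random perturbation of
the first whose radius (2 voxels) is calibrated so cohort-mean inter-rater
Dice falls near 0.78.

Deliberate simplifications, and what they imply about the tests:

* The per-patient global intensity scale multiplies the **signal** channels
  (T2WI, high-b DWI) only. ADC and eigenvalues are quantitative maps in
  mm^2/s whose units do not vary with scanner gain; scaling them would
  misrepresent what standardization must fix.
* The PZ surroundings share the PZ background intensity, so the PZ boundary
  itself carries no intensity signal. Without this, window statistics leak
  "distance to PZ boundary", which correlates with the noncancer label for
  purely geometric reasons and biases the zero-contrast control above
  chance. Real anatomy does have such boundary structure, so real-data
  performance estimates contain a geometric component the phantom
  deliberately excludes.
* T2 lesion contrast (−25 of ~500, under a ±10% bias field) is set below
  the patient-level variability, while diffusion contrasts are strong —
  the clinical situation in which adding DWI/DTI to T2WI helps. This is
  what makes the configuration-ordering check meaningful rather than a
  tie at ceiling.
* Lesions are smooth blobs, noise is Gaussian (a Rician option would matter
  only at very low SNR), and rater disagreement is a translation plus
  one-step morphological jitter. Passing tests therefore demonstrate the
  pipeline's correctness and leakage-freedom, not clinical accuracy on
  real anatomy.

## Problem sizes used by the checks

The verification suite runs the full pipeline at reduced budgets chosen as
the smallest sizes at which each property is stable: 6-patient cohorts
(8 for the zero-contrast control), 3-fold optimizer CV with 6–8
evaluations, up to 15 CFS features, and 100–120 training voxels per class
per patient. The optimizer's published-scale defaults (10-fold, 30
evaluations) remain the package defaults. The label-permutation control
uses 20 permutations with fixed hyperparameters, isolating the leakage
question from optimizer variance; held-out AUROC under permutation centres
on 0.5. (Training-side AUROC of a flexible kernel machine on permuted
labels exceeds 0.5 by memorization and is not a useful control.)

## Known limitations

* No DICOM ingestion, registration, bias-field correction, or tensor
  fitting — inputs must arrive preprocessed and co-registered.
* 2-D (in-slice) windows throughout, matching slice-wise delineation; no
  3-D texture, wavelet, or shape features.
* The AC and mode maps depend on conventions that vary across the
  literature (see above).
* Phantom-based performance numbers characterize the implementation, not
  clinical performance; a 16-patient clinical cohort of this design
  reports held-out AUROC near 0.93 for the full configuration, which the
  phantom reproduces only qualitatively (full > T2-only).

## A worked example

```{r example}
library(pzrad)

spec <- phantom_spec(n_patients = 6, seed = 7)
cohort <- generate_cohort(spec)

config <- pz_config(configuration = "full", folds = 3, iterations = 8,
                    max_train_per_class = 120, seed = 7)
report <- run_pipeline(cohort, config)

glance(report)    # aggregate mean/SD of AUROC, sensitivity, specificity, ...
tidy(report)      # one row per held-out patient
autoplot(report)  # per-fold metric boxplot

case <- preprocess_cohort(cohort)$cohort[[1]]
maps <- predict_maps(report$models[[case$patient_id]], case)
plot_slice(maps$probability, slice = 4, masks = list(pz = case$pz))
```
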