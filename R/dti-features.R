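#' Names of the 20 DTI scalar maps
#'
#' Eight anisotropy measures (FA, RA, VR, Westin linear/planar/spherical,
#' attenuation coefficient, tensor-shape mode) and twelve diffusivity
#' measures (MD, the three eigenvalues, RD, the three pairwise eigenvalue
#' differences, volume diffusivity, and the three surface diffusivities).
#'
#' @return Character vector of length 20.
#' @export
dti_map_names <- function() {
  c("fa", "ra", "vr", "cl", "cp", "cs", "ac", "mode",
    "md", "lambda1", "lambda2", "lambda3", "rd",
    "d12", "d13", "d23", "vd", "s12", "s13", "s23")
}

#' Compute the 20 DTI scalar maps from sorted eigenvalues
#'
#' Per-voxel formulas (lambda1 >= lambda2 >= lambda3, trace tr = sum of
#' eigenvalues):
#' \itemize{
#'   \item MD = tr/3; RD = (lambda2+lambda3)/2; trace alias = 3 MD
#'   \item FA = sqrt(3/2) sqrt(sum (lambda_i - MD)^2) / sqrt(sum lambda_i^2)
#'   \item RA = sqrt(sum (lambda_i - MD)^2 / 3) / MD
#'   \item VR = lambda1 lambda2 lambda3 / MD^3
#'   \item Westin: Cl = (l1-l2)/tr, Cp = 2(l2-l3)/tr, Cs = 3 l3/tr
#'     (trace denominator, so Cl+Cp+Cs = 1)
#'   \item mode = 3 sqrt(6) det(D~)/||D~||^3 with D~ the deviatoric triplet
#'   \item AC = lambda1 / RD (axial-to-radial ratio; 0 where RD = 0) —
#'     a documented anisotropy ratio, replaceable via `ac_fun`
#'   \item differences d12, d13, d23; VD = l1 l2 l3; surfaces S12, S13, S23
#' }
#' Voxels with tr = 0 yield 0 for every ratio quantity; voxels outside the
#' mask are `NA` in every map.
#'
#' @param eig a [dti_eigenvalues()] triplet (sorted, non-negative in mask).
#' @param mask [roi_mask()] of voxels to evaluate; must be non-empty.
#' @param ac_fun optional function `(l1, l2, l3) -> numeric` overriding the
#'   attenuation-coefficient formula.
#' @return A named list of 20 `voxel_volume`s (see [dti_map_names()]).
#' @export
compute_dti_maps <- function(eig, mask, ac_fun = NULL) {
  stopifnot(inherits(eig, "dti_eigenvalues"))
  stopifnot_same_grid(eig$lambda1, mask, "eigenvalues and mask")
  sel <- as.logical(mask)
  if (!any(sel)) stop("mask selects no voxels", call. = FALSE)
  l1 <- as.numeric(eig$lambda1)[sel]
  l2 <- as.numeric(eig$lambda2)[sel]
  l3 <- as.numeric(eig$lambda3)[sel]

  tr <- l1 + l2 + l3
  md <- tr / 3
  dev1 <- l1 - md; dev2 <- l2 - md; dev3 <- l3 - md
  dev_ss <- dev1^2 + dev2^2 + dev3^2
  ss <- l1^2 + l2^2 + l3^2
  pos <- tr > 0

  safe_div <- function(num, den) ifelse(pos & den > 0, num / ifelse(den > 0, den, 1), 0)

  fa <- ifelse(ss > 0, sqrt(1.5) * sqrt(dev_ss) / sqrt(ifelse(ss > 0, ss, 1)), 0)
  ra <- safe_div(sqrt(dev_ss / 3), md)
  vr <- safe_div(l1 * l2 * l3, md^3)
  cl <- safe_div(l1 - l2, tr)
  cp <- safe_div(2 * (l2 - l3), tr)
  cs <- safe_div(3 * l3, tr)
  dev_norm <- sqrt(dev_ss)
  mode <- ifelse(dev_norm > 0,
                 3 * sqrt(6) * (dev1 * dev2 * dev3) /
                   ifelse(dev_norm > 0, dev_norm, 1)^3,
                 0)
  rd <- (l2 + l3) / 2
  ac <- if (is.null(ac_fun)) safe_div(l1, rd) else ac_fun(l1, l2, l3)

  vals <- list(
    fa = fa, ra = ra, vr = vr, cl = cl, cp = cp, cs = cs, ac = ac, mode = mode,
    md = md, lambda1 = l1, lambda2 = l2, lambda3 = l3, rd = rd,
    d12 = l1 - l2, d13 = l1 - l3, d23 = l2 - l3,
    vd = l1 * l2 * l3, s12 = l1 * l2, s13 = l1 * l3, s23 = l2 * l3
  )
  template <- eig$lambda1
  lapply(vals, function(v) {
    arr <- rep(NA_real_, length(sel))
    arr[sel] <- v
    vol_like(arr, template)
  })
}

#' @rdname compute_dti_maps
#' @details `dti_trace_map()` exposes trace = 3 MD as an alias map; it is not
#'   one of the 20 features but is occasionally reported alongside them.
#' @export
dti_trace_map <- function(eig, mask) {
  maps <- compute_dti_maps(eig, mask)
  vol_like(3 * as.numeric(maps$md), eig$lambda1)
}
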