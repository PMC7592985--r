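# Independent brute-force oracles used to check the fast implementations.
# All of these enumerate directly from definitions; none call the package's
# feature code.

# replicated-edge window values around (r, c) of a matrix
oracle_window <- function(img, r, c, w) {
  h <- w %/% 2
  nr <- nrow(img); nc <- ncol(img)
  vals <- matrix(0, w, w)
  for (i in -h:h) for (j in -h:h) {
    vals[i + h + 1, j + h + 1] <-
      img[min(max(r + i, 1), nr), min(max(c + j, 1), nc)]
  }
  vals
}

# the 15 first-order statistics, straight from their formulas
oracle_first_order <- function(vals, nbins = 64) {
  v <- as.numeric(vals)
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2); m3 <- mean((v - m)^3); m4 <- mean((v - m)^4)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  mn <- min(v); mx <- max(v)
  if (mx > mn) {
    bw <- (mx - mn) / nbins
    b <- pmin(floor((v - mn) / bw), nbins - 1)
    counts <- tabulate(b + 1, nbins)
    p <- counts / n
    nz <- p > 0
    entropy <- -sum(p[nz] * log2(p[nz]))
    energy <- sum(p^2)
    mode <- mn + (which.max(counts) - 0.5) * bw
  } else {
    entropy <- 0; energy <- 1; mode <- mn
  }
  c(mean = m, p25 = q[1], p75 = q[3],
    variance = if (n > 1) m2 * n / (n - 1) else 0,
    sd = sqrt(if (n > 1) m2 * n / (n - 1) else 0),
    median = q[2], iqr = q[3] - q[1], mode = mode, min = mn, max = mx,
    range = mx - mn,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    entropy = entropy, energy = energy)
}

oracle_quantize <- function(vals, levels) {
  mn <- min(vals); mx <- max(vals)
  if (mx == mn) return(array(0L, dim = dim(vals)))
  q <- floor((vals - mn) / (mx - mn) * levels)
  array(as.integer(pmin(q, levels - 1)), dim = dim(vals))
}

# symmetric GLCM counts by exhaustive enumeration of every voxel pair
oracle_glcm_counts <- function(win, levels,
                               offsets = list(c(0, 1), c(-1, 1),
                                              c(-1, 0), c(-1, -1))) {
  lev <- oracle_quantize(win, levels)
  counts <- matrix(0, levels, levels)
  nr <- nrow(win); nc <- ncol(win)
  for (off in offsets) {
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      a2 <- a + off[1]; b2 <- b + off[2]
      if (a2 < 1 || a2 > nr || b2 < 1 || b2 > nc) next
      i <- lev[a, b] + 1; j <- lev[a2, b2] + 1
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  counts
}

# the 19 GLCM statistics from a count matrix, independent R implementation
oracle_glcm_stats <- function(counts) {
  N <- sum(counts)
  L <- nrow(counts)
  P <- counts / N
  i <- row(P) - 1; j <- col(P) - 1
  px <- rowSums(P)
  mu <- sum((0:(L - 1)) * px)
  sdx <- sqrt(sum(((0:(L - 1)) - mu)^2 * px))
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  contrast <- sum((i - j)^2 * P)
  f4 <- sum((i - mu)^2 * P)
  correlation <- if (sdx > 0) sum((i - mu) * (j - mu) * P) / sdx^2 else 0
  # p_{x+y}, p_{|x-y|}
  psum <- vapply(0:(2 * L - 2), function(k) sum(P[i + j == k]), numeric(1))
  pdiff <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  sum_avg <- sum((0:(2 * L - 2)) * psum)
  sum_var <- sum(((0:(2 * L - 2)) - sum_avg)^2 * psum)
  sum_ent <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  mu_d <- sum((0:(L - 1)) * pdiff)
  diff_var <- sum(((0:(L - 1)) - mu_d)^2 * pdiff)
  diff_ent <- -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0]))
  mcc <- 0
  if (sdx > 0) {
    keep <- which(px > 0)
    if (length(keep) >= 2) {
      Q <- matrix(0, length(keep), length(keep))
      for (a in seq_along(keep)) for (b in seq_along(keep)) {
        Q[a, b] <- sum(P[keep[a], keep] * P[keep[b], keep] /
                         (px[keep[a]] * px[keep]))
      }
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      mcc <- sqrt(min(max(ev[2], 0), 1))
    }
  }
  c(contrast = contrast,
    inertia = contrast * N,
    energy = sum(P^2),
    entropy = entropy,
    correlation = correlation,
    mcc = mcc,
    homogeneity = sum(P / (1 + abs(i - j))),
    inverse = sum(P / (1 + (i - j)^2)),
    dissimilarity = sum(abs(i - j) * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    sum_average = sum_avg,
    sum_variance = sum_var,
    sum_entropy = sum_ent,
    sum_of_squares = f4 * N,
    difference_variance = diff_var,
    difference_entropy = diff_ent,
    maximum_probability = max(P),
    glcm_variance = f4,
    glcm_sd = sqrt(f4))
}

# FA from the full diagonal tensor via matrix norms
oracle_fa_tensor <- function(l1, l2, l3) {
  D <- diag(c(l1, l2, l3))
  Dev <- D - sum(diag(D)) / 3 * diag(3)
  nD <- norm(D, "F")
  if (nD == 0) return(0)
  sqrt(3 / 2) * norm(Dev, "F") / nD
}

# pair-counting AUROC with half credit for ties
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels > 0]; neg <- scores[labels <= 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# small constant volume helper
const_vol <- function(value, dim = c(2, 10, 10), spacing = c(1, 1, 1)) {
  voxel_volume(array(value, dim = dim), spacing)
}

full_mask <- function(vol, label = "pz") {
  roi_mask(array(TRUE, dim = dim(vol)), vox_spacing(vol), label = label)
}

# small fast phantom used across tests
tiny_spec <- function(n_patients = 4L, ...) {
  phantom_spec(shape = c(6, 48, 48), spacing = c(4, 0.8, 0.8),
               n_patients = n_patients, lesion_count_range = c(1L, 1L),
               lesion_volume_cc = c(0.4, 0.8), ...)
}
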