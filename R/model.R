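#' RBF-SVM hyperparameters
#'
#' Regularization `C` and Gaussian kernel width `gamma`, both searched on
#' `[1e-4, 1e3]`.
#'
#' @param C,gamma positive numbers within `bounds`.
#' @param bounds inclusive search interval, default `c(1e-4, 1e3)`.
#' @return An object of class `svm_hyperparams`.
#' @export
svm_hyperparams <- function(C, gamma, bounds = c(1e-4, 1e3)) {
  stopifnot(C > 0, gamma > 0)
  if (C < bounds[1] || C > bounds[2] || gamma < bounds[1] || gamma > bounds[2]) {
    stop("hyperparameters must lie within the search bounds", call. = FALSE)
  }
  structure(list(C = C, gamma = gamma, bounds = bounds),
            class = "svm_hyperparams")
}

#' @export
print.svm_hyperparams <- function(x, ...) {
  cat(sprintf("<svm_hyperparams> C = %.4g, gamma = %.4g\n", x$C, x$gamma))
  invisible(x)
}

#' Train a soft-margin RBF-SVM on a normalized feature matrix
#'
#' Gaussian kernel `K(x, x') = exp(-gamma ||x - x'||^2)` with regularization
#' `C`. Class imbalance (noncancer voxels greatly outnumber cancer voxels)
#' is handled with inverse-frequency class weights. The stored decision
#' function is oriented so that larger values mean more cancer-like.
#'
#' @param matrix feature-matrix tibble with `label` +1/-1 and features
#'   scaled to `[0, 1]`.
#' @param hp an [svm_hyperparams()].
#' @param features optional character vector restricting the feature columns
#'   used (e.g. a CFS selection).
#' @param class_weights `"inverse"` (default) or `NULL` for unweighted.
#' @return An object of class `rbf_svm` with a [decision_values()] method.
#' @export
train_rbf_svm <- function(matrix, hp, features = NULL,
                          class_weights = "inverse") {
  feat <- features %||% feature_columns(matrix)
  y <- matrix$label
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to train", call. = FALSE)
  }
  X <- as.matrix(matrix[feat])
  yf <- factor(ifelse(y > 0, "cancer", "noncancer"),
               levels = c("cancer", "noncancer"))
  cw <- NULL
  if (identical(class_weights, "inverse")) {
    tab <- table(yf)
    cw <- as.numeric(length(yf) / (2 * tab))
    names(cw) <- names(tab)
  }
  fit <- e1071::svm(x = X, y = yf, scale = FALSE, kernel = "radial",
                    cost = hp$C, gamma = hp$gamma, class.weights = cw,
                    probability = FALSE)
  dv <- as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                        "decision.values"))
  # libsvm orients the decision function by first-seen class; normalize so
  # positives (cancer) score high
  sgn <- if (mean(dv[y > 0]) >= mean(dv[y <= 0])) 1 else -1
  structure(list(fit = fit, hyperparams = hp, features = feat, sign = sgn),
            class = "rbf_svm")
}

#' @rdname train_rbf_svm
#' @param model an `rbf_svm`.
#' @param newdata tibble (or matrix) containing the model's feature columns.
#' @return `decision_values()`: numeric vector, positive = cancer side.
#' @export
decision_values <- function(model, newdata) {
  X <- as.matrix(newdata[model$features])
  dv <- as.numeric(attr(stats::predict(model$fit, X, decision.values = TRUE),
                        "decision.values"))
  model$sign * dv
}

#' @export
print.rbf_svm <- function(x, ...) {
  cat(sprintf("<rbf_svm> %d SV(s), %d feature(s), C = %.4g, gamma = %.4g\n",
              x$fit$tot.nSV, length(x$features),
              x$hyperparams$C, x$hyperparams$gamma))
  invisible(x)
}

#' Platt sigmoid calibration of SVM decision values
#'
#' Fits `P(y = 1 | f) = 1 / (1 + exp(A f + B))` by minimizing the regularized
#' negative log-likelihood with Platt's smoothed targets
#' `t+ = (N+ + 1)/(N+ + 2)`, `t- = 1/(N- + 2)`, using Newton's method with
#' backtracking (the robust model-trust variant). `A < 0` whenever positives
#' have larger decision values.
#'
#' @param decision_values numeric vector of SVM decision values.
#' @param labels vector of +1/-1 labels.
#' @return Named numeric `c(A =, B =)`.
#' @export
platt_calibrate <- function(decision_values, labels) {
  f <- as.numeric(decision_values)
  y <- as.numeric(labels)
  n_pos <- sum(y > 0); n_neg <- sum(y <= 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to calibrate", call. = FALSE)
  }
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y > 0, hi, lo)

  nll <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  fval <- nll(A, B)
  sigma <- 1e-12
  for (it in seq_len(100L)) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newA <- A + step * dA; newB <- B + step * dB
      newf <- nll(newA, newB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
  }
  c(A = A, B = B)
}

#' @rdname platt_calibrate
#' @param f decision values to convert.
#' @param AB the fitted `c(A, B)`.
#' @return `platt_probability()`: probabilities in (0, 1).
#' @export
platt_probability <- function(f, AB) {
  z <- AB[["A"]] * f + AB[["B"]]
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

#' AUROC and thresholded classification metrics
#'
#' AUROC is the Mann-Whitney pair statistic (probability a random positive
#' outscores a random negative, half credit for ties), computed from ranks.
#' Sensitivity, specificity and accuracy use the sign rule: predicted
#' positive where `score > 0`.
#'
#' @param scores numeric decision values (or any monotone score).
#' @param labels vector of +1/-1.
#' @param threshold decision threshold, default 0.
#' @return One-row tibble: `auroc`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0) {
  y <- as.numeric(labels) > 0
  if (all(y) || !any(y)) {
    stop("both classes must be present to compute metrics", call. = FALSE)
  }
  tibble::tibble(
    auroc = auroc(scores, labels),
    sensitivity = mean(scores[y] > threshold),
    specificity = mean(scores[!y] <= threshold),
    accuracy = mean((scores > threshold) == y)
  )
}

#' @rdname compute_metrics
#' @export
auroc <- function(scores, labels) {
  y <- as.numeric(labels) > 0
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUROC", call. = FALSE)
  }
  r <- rank(scores)  # average ranks give half credit for ties
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Dice similarity index between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b [roi_mask()]s on the same grid.
#' @return Number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot_same_grid(a, b, "masks")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}
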