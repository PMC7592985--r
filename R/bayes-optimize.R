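# Run code with a private, restorable RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# Cross-validation folds for the optimizer objective: grouped by patient
# (no within-patient leakage) when several patients are present, otherwise
# stratified by class at the voxel level.
make_cv_folds <- function(matrix, folds) {
  n <- nrow(matrix)
  pats <- unique(matrix$patient_id)
  if (length(pats) >= 2L) {
    k <- min(folds, length(pats))
    assign_pat <- sample(rep(seq_len(k), length.out = length(pats)))
    fold_of_pat <- stats::setNames(assign_pat, pats)
    unname(fold_of_pat[matrix$patient_id])
  } else {
    k <- folds
    fold <- integer(n)
    for (cls in unique(matrix$label)) {
      idx <- which(matrix$label == cls)
      if (length(idx) < k) {
        stop("fold count exceeds the minority-class size", call. = FALSE)
      }
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    fold
  }
}

# mean CV AUROC (the optimization objective) plus mean balanced accuracy at
# the sign threshold, used only to break ties between equal-AUROC incumbents
cv_objective <- function(matrix, hp, folds_id, features = NULL) {
  aucs <- c(); baccs <- c()
  for (k in unique(folds_id)) {
    tr <- matrix[folds_id != k, , drop = FALSE]
    te <- matrix[folds_id == k, , drop = FALSE]
    if (length(unique(tr$label)) < 2L || length(unique(te$label)) < 2L) next
    model <- train_rbf_svm(tr, hp, features = features)
    dv <- decision_values(model, te)
    aucs <- c(aucs, auroc(dv, te$label))
    pos <- te$label > 0
    baccs <- c(baccs, (mean(dv[pos] > 0) + mean(dv[!pos] <= 0)) / 2)
  }
  if (length(aucs) == 0L) return(c(auroc = NA_real_, bacc = NA_real_))
  c(auroc = mean(aucs), bacc = mean(baccs))
}

# squared-exponential GP posterior at candidate points
gp_posterior <- function(X, y, Xs, lengthscale, noise = 1e-4) {
  sf2 <- max(stats::var(y), 1e-8)
  sqd <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  }
  K <- sf2 * exp(-pmax(sqd(X, X), 0) / (2 * lengthscale^2)) +
    diag(noise + 1e-8, nrow(X))
  Ks <- sf2 * exp(-pmax(sqd(Xs, X), 0) / (2 * lengthscale^2))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y - mean(y)))
  mu <- mean(y) + Ks %*% alpha
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(sf2 - colSums(v^2), 1e-12)
  list(mu = as.numeric(mu), sd = sqrt(s2))
}

gp_loglik <- function(X, y, lengthscale, noise = 1e-4) {
  sf2 <- max(stats::var(y), 1e-8)
  sqd <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  K <- sf2 * exp(-pmax(sqd, 0) / (2 * lengthscale^2)) +
    diag(noise + 1e-8, nrow(X))
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  yc <- y - mean(y)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  -0.5 * sum(yc * alpha) - sum(log(diag(L))) - 0.5 * length(y) * log(2 * pi)
}

#' Bayesian optimization of RBF-SVM hyperparameters
#'
#' Gaussian-process expected-improvement search over `log10(C)` and
#' `log10(gamma)` on the box `[1e-4, 1e3]^2`, maximizing the mean
#' cross-validated AUROC. A space-filling Latin-hypercube design seeds the
#' surrogate; each subsequent evaluation maximizes expected improvement
#' over a candidate set. Cross-validation folds are grouped by patient when
#' patient ids are present (stricter than voxel-level folds: no
#' within-patient leakage into the objective). Reproducible under a fixed
#' seed.
#'
#' @param matrix normalized feature-matrix tibble.
#' @param folds CV folds for the objective, default 10.
#' @param iterations total objective evaluations, default 30.
#' @param seed integer seed controlling the design, folds, and candidates.
#' @param bounds search interval for both parameters, default `c(1e-4, 1e3)`.
#' @param features optional feature subset (e.g. from [cfs_search()]).
#' @param n_init initial design size, default `min(8, iterations)`.
#' @return An [svm_hyperparams()] with an extra `trace` tibble
#'   (`iteration`, `C`, `gamma`, `cv_auroc`).
#' @export
bayes_optimize <- function(matrix, folds = 10L, iterations = 30L, seed = 1L,
                           bounds = c(1e-4, 1e3), features = NULL,
                           n_init = NULL) {
  lb <- log10(bounds[1]); ub <- log10(bounds[2])
  n_init <- n_init %||% min(8L, iterations)
  with_local_seed(seed, {
    folds_id <- make_cv_folds(matrix, folds)
    X <- lhs::randomLHS(n_init, 2)  # unit square; scaled to log10 bounds
    evals <- apply(X, 1, function(x) {
      hp <- svm_hyperparams(10^(lb + x[1] * (ub - lb)),
                            10^(lb + x[2] * (ub - lb)), bounds)
      cv_objective(matrix, hp, folds_id, features)
    })
    keep <- !is.na(evals["auroc", ])
    X <- X[keep, , drop = FALSE]
    y <- evals["auroc", keep]
    bacc <- evals["bacc", keep]
    while (length(y) < iterations) {
      ls_grid <- c(0.15, 0.25, 0.4, 0.6)
      ll <- vapply(ls_grid, function(l) gp_loglik(X, y, l), numeric(1))
      lengthscale <- ls_grid[which.max(ll)]
      cand <- rbind(lhs::randomLHS(256, 2),
                    pmin(pmax(matrix(rep(X[which.max(y), ], 32), ncol = 2,
                                     byrow = TRUE) +
                                matrix(stats::rnorm(64, 0, 0.05), ncol = 2),
                              0), 1))
      post <- gp_posterior(X, y, cand, lengthscale)
      best <- max(y)
      z <- (post$mu - best - 1e-4) / post$sd
      ei <- (post$mu - best - 1e-4) * stats::pnorm(z) + post$sd * stats::dnorm(z)
      xn <- cand[which.max(ei), , drop = FALSE]
      hp <- svm_hyperparams(10^(lb + xn[1] * (ub - lb)),
                            10^(lb + xn[2] * (ub - lb)), bounds)
      yn <- cv_objective(matrix, hp, folds_id, features)
      if (!is.na(yn[["auroc"]])) {
        X <- rbind(X, xn); y <- c(y, yn[["auroc"]]); bacc <- c(bacc, yn[["bacc"]])
      } else break
    }
    # incumbent: best AUROC; among near-ties (within half a percent, i.e.
    # statistically indistinguishable at these fold sizes), the evaluation
    # whose sign-threshold balanced accuracy is best
    tied <- which(y >= max(y) - 5e-3)
    i_best <- tied[which.max(bacc[tied])]
    out <- svm_hyperparams(10^(lb + X[i_best, 1] * (ub - lb)),
                           10^(lb + X[i_best, 2] * (ub - lb)), bounds)
    out$cv_auroc <- y[i_best]
    out$trace <- tibble::tibble(
      iteration = seq_along(y),
      C = 10^(lb + X[, 1] * (ub - lb)),
      gamma = 10^(lb + X[, 2] * (ub - lb)),
      cv_auroc = y
    )
    out
  })
}
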