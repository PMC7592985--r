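#' Merit of a feature subset (correlation-based feature selection)
#'
#' The CFS heuristic from test theory: for a subset of `k` features with
#' mean absolute feature-class correlation `r_cf` and mean absolute
#' feature-feature correlation `r_ff`,
#' `merit = k * r_cf / sqrt(k + k (k - 1) * r_ff)`.
#' A good subset is class-predictive (large `r_cf`) but internally
#' uncorrelated (small `r_ff`).
#'
#' @param k subset size, >= 1.
#' @param mean_feature_class_corr mean absolute feature-class correlation.
#' @param mean_feature_feature_corr mean absolute pairwise feature
#'   correlation (ignored for k = 1).
#' @return The merit value.
#' @export
cfs_merit <- function(k, mean_feature_class_corr,
                      mean_feature_feature_corr = 0) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  rcf <- abs(mean_feature_class_corr)
  rff <- abs(mean_feature_feature_corr)
  denom <- k + k * (k - 1) * rff
  if (denom <= 0) {
    stop("degenerate subset: non-positive merit denominator", call. = FALSE)
  }
  k * rcf / sqrt(denom)
}

#' Best-first CFS search over a labeled feature matrix
#'
#' Forward best-first search maximizing [cfs_merit()], with Pearson
#' feature-feature correlations and point-biserial feature-class
#' correlations (Pearson against the numeric +1/-1 label). The search keeps
#' a frontier of evaluated subsets, repeatedly expands the best unexpanded
#' one by each remaining feature, and stops after `patience` consecutive
#' expansions that fail to improve the best merit. Deterministic given the
#' input column order.
#'
#' @param matrix feature-matrix tibble with a `label` column of +1/-1 (see
#'   [assemble_feature_matrix()]).
#' @param patience consecutive non-improving expansions before stopping,
#'   default 5.
#' @param max_features optional cap on subset size.
#' @return An object of class `cfs_result`: list with `selected` (feature
#'   names, in selection order), `merit`, and `search_trace` (tibble of
#'   subset size and merit per accepted improvement).
#' @export
cfs_search <- function(matrix, patience = 5L, max_features = Inf) {
  feat <- feature_columns(matrix)
  if (length(feat) < 2L) stop("need at least two features", call. = FALSE)
  y <- matrix$label
  if (length(unique(y)) < 2L) {
    stop("both classes must be present for feature selection", call. = FALSE)
  }
  X <- as.matrix(matrix[feat])
  sds <- apply(X, 2, stats::sd)
  rcf <- abs(suppressWarnings(as.numeric(stats::cor(X, y))))
  rcf[sds == 0 | !is.finite(rcf)] <- 0
  rff <- abs(suppressWarnings(stats::cor(X)))
  rff[!is.finite(rff)] <- 0
  diag(rff) <- 1

  p <- length(feat)
  merit_of <- function(idx) {
    k <- length(idx)
    mrcf <- mean(rcf[idx])
    mrff <- if (k > 1) mean(rff[idx, idx][upper.tri(matrix(0, k, k))]) else 0
    cfs_merit(k, mrcf, mrff)
  }

  key <- function(idx) paste(sort(idx), collapse = ",")
  start <- which.max(rcf)
  frontier <- list(list(idx = start, merit = merit_of(start)))
  seen <- new.env(parent = emptyenv())
  assign(key(start), TRUE, envir = seen)
  best <- frontier[[1]]
  trace <- list(list(size = 1L, merit = best$merit))
  stale <- 0L

  while (length(frontier) > 0L && stale < patience) {
    merits <- vapply(frontier, function(n) n$merit, numeric(1))
    at <- which.max(merits)
    node <- frontier[[at]]
    frontier[[at]] <- NULL
    improved <- FALSE
    if (length(node$idx) < max_features) {
      for (j in setdiff(seq_len(p), node$idx)) {
        idx <- c(node$idx, j)
        k <- key(idx)
        if (exists(k, envir = seen)) next
        assign(k, TRUE, envir = seen)
        m <- merit_of(idx)
        frontier[[length(frontier) + 1L]] <- list(idx = idx, merit = m)
        if (m > best$merit + 1e-12) {
          best <- list(idx = idx, merit = m)
          trace[[length(trace) + 1L]] <- list(size = length(idx), merit = m)
          improved <- TRUE
        }
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }

  structure(
    list(
      selected = feat[best$idx],
      merit = best$merit,
      search_trace = dplyr::bind_rows(lapply(trace, tibble::as_tibble))
    ),
    class = "cfs_result"
  )
}

#' @export
print.cfs_result <- function(x, ...) {
  cat(sprintf("<cfs_result> %d feature(s), merit %.4f\n",
              length(x$selected), x$merit))
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
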