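#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a leave-one-patient-out evaluation report
#'
#' @param x a `pz_eval_report`.
#' @param ... unused.
#' @return One row per held-out patient with its metrics and chosen
#'   hyperparameters.
#' @export
tidy.pz_eval_report <- function(x, ...) {
  dplyr::select(x$folds, -dplyr::any_of(c("selected", "train_patients")))
}

#' @rdname tidy.pz_eval_report
#' @return `glance()`: one row of aggregate mean/SD metrics.
#' @export
glance.pz_eval_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$aggregate, names_from = "metric",
                             values_from = c("mean", "sd"),
                             names_glue = "{metric}_{.value}")
  dplyr::bind_cols(
    tibble::tibble(configuration = x$config$configuration,
                   n_folds = nrow(x$folds)),
    wide
  )
}

#' @rdname tidy.pz_eval_report
#' @export
tidy.pz_model <- function(x, ...) {
  tibble::tibble(
    feature = x$selection$selected,
    merit = x$selection$merit,
    C = x$hyperparams$C,
    gamma = x$hyperparams$gamma,
    platt_A = x$platt[["A"]],
    platt_B = x$platt[["B"]]
  )
}

#' @rdname tidy.pz_eval_report
#' @export
glance.pz_model <- function(x, ...) {
  tibble::tibble(
    configuration = x$config$configuration,
    n_features = length(x$selection$selected),
    merit = x$selection$merit,
    C = x$hyperparams$C,
    gamma = x$hyperparams$gamma,
    cv_auroc = x$hyperparams$cv_auroc %||% NA_real_,
    n_train_patients = length(x$train_patients)
  )
}

#' Plot per-fold metrics of an evaluation report
#'
#' Boxplot of the held-out AUROC, sensitivity, specificity, accuracy and
#' Dice across leave-one-patient-out folds.
#'
#' @param object a `pz_eval_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pz_eval_report <- function(object, ...) {
  metric_cols <- c("auroc", "sensitivity", "specificity", "accuracy", "dice")
  long <- tidyr::pivot_longer(object$folds[metric_cols], dplyr::everything(),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Held-out performance (%s configuration)",
                      object$config$configuration)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a volume with optional mask overlays
#'
#' @param vol a [voxel_volume()].
#' @param slice slice index.
#' @param masks optional named list of [roi_mask()]s drawn as contours.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, slice = 1L, masks = NULL) {
  d <- dim(vol)
  df <- tibble::tibble(
    row = rep(seq_len(d[2]), times = d[3]),
    col = rep(seq_len(d[3]), each = d[2]),
    value = as.numeric(vol[slice, , ])
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(masks)) {
    for (nm in names(masks)) {
      m <- masks[[nm]]
      mdf <- tibble::tibble(
        row = rep(seq_len(d[2]), times = d[3]),
        col = rep(seq_len(d[3]), each = d[2]),
        inside = as.numeric(m[slice, , ])
      )
      p <- p + ggplot2::geom_contour(
        data = mdf,
        ggplot2::aes(z = .data$inside, colour = !!nm),
        breaks = 0.5, linewidth = 0.4
      )
    }
    p <- p + ggplot2::labs(colour = "mask")
  }
  p
}
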