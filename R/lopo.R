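#' Pipeline configuration
#'
#' Defaults reproduce the published analysis settings: 9 x 9 texture
#' windows, 3 x 3 median filter, 32 GLCM gray levels, CFS patience 5,
#' tenfold cross-validation with 30 Bayesian-optimization evaluations on
#' `[1e-4, 1e3]`. `max_train_per_class` caps the training voxels drawn per
#' patient and class (stratified subsample; the held-out patient is always
#' evaluated on every voxel), keeping the quadratic-cost SVM fits tractable.
#'
#' @param configuration channel configuration: `"t2"`, `"dwi"`, `"t2_dwi"`,
#'   `"t2_dti"`, or `"full"`.
#' @param window sliding-window width for first-order and GLCM features.
#' @param nbins histogram bins for first-order entropy/energy/mode.
#' @param glcm_levels GLCM gray levels.
#' @param median_window median-filter width.
#' @param cfs_patience best-first stopping patience.
#' @param cfs_max_features cap on the CFS subset size.
#' @param folds,iterations,bounds Bayesian-optimization settings.
#' @param max_train_per_class training-voxel cap per patient per class.
#' @param seed master seed for every stochastic step.
#' @return An object of class `pz_config`.
#' @export
pz_config <- function(configuration = "full", window = 9L, nbins = 64L,
                      glcm_levels = 32L, median_window = 3L,
                      cfs_patience = 5L, cfs_max_features = 25L,
                      folds = 10L, iterations = 30L, bounds = c(1e-4, 1e3),
                      max_train_per_class = 300L, seed = 42L) {
  config_channels(configuration)  # validates the name
  structure(as.list(environment()), class = "pz_config")
}

#' @export
print.pz_config <- function(x, ...) {
  cat(sprintf(
    "<pz_config> %s (%d features), window %d, GLCM levels %d, %d-fold CV x %d evals, seed %d\n",
    x$configuration, expected_feature_count(x$configuration), x$window,
    x$glcm_levels, x$folds, x$iterations, x$seed))
  invisible(x)
}

# labeled feature tables + curated masks for every case
cohort_feature_tables <- function(cohort, config) {
  lapply(cohort, function(case) {
    lab <- curate_reference_labels(case$rater_masks$rater1,
                                   case$rater_masks$rater2, case$pz)
    maps <- extract_case_features(case, config$configuration,
                                  mask = case$pz, window = config$window,
                                  nbins = config$nbins,
                                  levels = config$glcm_levels)
    tab <- assemble_feature_matrix(maps, lab$cancer, lab$noncancer,
                                   case$patient_id)
    list(patient_id = case$patient_id, table = tab, labels = lab,
         pz = case$pz)
  })
}

subsample_training <- function(tab, per_class, seed) {
  with_local_seed(seed, {
    dplyr::slice_sample(
      dplyr::group_by(tab, .data$patient_id, .data$label),
      n = per_class
    ) |> dplyr::ungroup()
  })
}

#' Fit the full training-side pipeline on one training table
#'
#' Min-max normalization, CFS feature selection, Bayesian hyperparameter
#' optimization, final RBF-SVM fit and Platt calibration — everything
#' learned from the supplied rows only.
#'
#' @param train_tab labeled feature tibble (training rows only).
#' @param config a [pz_config()].
#' @param seed seed for the optimizer.
#' @return An object of class `pz_model`.
#' @export
fit_pipeline_model <- function(train_tab, config, seed = config$seed) {
  norm <- minmax_fit_apply(train_tab)
  sel <- cfs_search(norm$matrix, patience = config$cfs_patience,
                    max_features = config$cfs_max_features)
  hp <- bayes_optimize(norm$matrix, folds = config$folds,
                       iterations = config$iterations, seed = seed,
                       bounds = config$bounds, features = sel$selected)
  model <- train_rbf_svm(norm$matrix, hp, features = sel$selected)
  platt <- platt_calibrate(decision_values(model, norm$matrix),
                           norm$matrix$label)
  # operating point for binary maps: the decision value where the fitted
  # sigmoid crosses probability 0.5 (equals 0 for a balanced calibration)
  crossing <- if (platt[["A"]] < 0) -platt[["B"]] / platt[["A"]] else 0
  structure(
    list(svm = model, platt = platt, crossing = crossing, selection = sel,
         normalization = norm$state, hyperparams = hp, config = config,
         train_patients = unique(train_tab$patient_id)),
    class = "pz_model"
  )
}

#' @export
print.pz_model <- function(x, ...) {
  cat(sprintf(
    "<pz_model> %s: %d CFS feature(s), C = %.4g, gamma = %.4g, Platt A = %.3f B = %.3f\n",
    x$config$configuration, length(x$selection$selected),
    x$hyperparams$C, x$hyperparams$gamma, x$platt[["A"]], x$platt[["B"]]))
  cat(sprintf("  trained on %d patient(s)\n", length(x$train_patients)))
  invisible(x)
}

# decision values + calibrated probabilities on a raw (unnormalized) table
predict_pipeline <- function(model, tab) {
  norm <- minmax_fit_apply(tab, state = model$normalization)
  dv <- decision_values(model$svm, norm$matrix)
  tibble::tibble(decision = dv, probability = platt_probability(dv, model$platt))
}

#' Voxel-wise probability and binary cancer maps for one patient
#'
#' Applies a fitted [fit_pipeline_model()] to every peripheral-zone voxel
#' of a prepared case: probability is the Platt-calibrated sigmoid of the
#' decision function; the binary map thresholds the decision function at the
#' sigmoid's probability-0.5 crossing (0 for a balanced calibration).
#' Voxels outside the PZ carry `NA`.
#'
#' @param model a `pz_model`.
#' @param case a prepared [patient_case()] with the channels the model's
#'   configuration requires.
#' @return List with `probability` and `binary` `voxel_volume`s and the
#'   per-voxel `table`.
#' @export
predict_maps <- function(model, case) {
  config <- model$config
  ch <- config_channels(config$configuration)
  for (v in ch$scalar) {
    if (is.null(case[[v]])) {
      stop(sprintf("case %s lacks channel '%s' required by the model",
                   case$patient_id, v), call. = FALSE)
    }
  }
  if (ch$dti && is.null(case$eigenvalues)) {
    stop(sprintf("case %s lacks DTI eigenvalues required by the model",
                 case$patient_id), call. = FALSE)
  }
  maps <- extract_case_features(case, config$configuration, mask = case$pz,
                                window = config$window, nbins = config$nbins,
                                levels = config$glcm_levels)
  tab <- features_at_mask(maps, case$pz)
  feat <- setdiff(names(tab), c("slice", "row", "col"))
  ok <- stats::complete.cases(tab[feat])
  pred <- predict_pipeline(model, tab[ok, , drop = FALSE])
  prob <- array(NA_real_, dim = dim(case$pz))
  bin <- array(NA_real_, dim = dim(case$pz))
  idx <- as.matrix(tab[ok, c("slice", "row", "col")])
  prob[idx] <- pred$probability
  bin[idx] <- as.numeric(pred$decision > model$crossing)
  list(
    probability = vol_like(prob, case$t2w),
    binary = vol_like(bin, case$t2w),
    table = dplyr::bind_cols(tab[ok, c("slice", "row", "col")], pred)
  )
}

#' Leave-one-patient-out validation of the full pipeline
#'
#' For each held-out patient, normalization, feature selection,
#' hyperparameter optimization, the SVM and Platt calibration are fitted on
#' the remaining patients only, then evaluated on every labeled voxel of
#' the held-out patient. No held-out voxel influences any training-side
#' statistic; each fold records its training patient ids so that can be
#' audited.
#'
#' @param cohort list of prepared [patient_case()]s (>= 3).
#' @param config a [pz_config()].
#' @param feature_tables optional precomputed [cohort_feature_tables()]
#'   output (reused across configurations).
#' @return An object of class `pz_eval_report`: `folds` tibble (per-patient
#'   metrics, hyperparameters, selected features, train-patient audit),
#'   `aggregate` (mean and SD of each metric), `config`, and per-fold
#'   `models`.
#' @export
lopo_run <- function(cohort, config, feature_tables = NULL) {
  if (length(cohort) < 3L) stop("need at least 3 patients", call. = FALSE)
  tabs <- feature_tables %||% cohort_feature_tables(cohort, config)
  ids <- vapply(tabs, function(x) x$patient_id, character(1))
  folds <- list(); models <- list()
  for (i in seq_along(tabs)) {
    test <- tabs[[i]]
    if (length(unique(test$table$label)) < 2L) {
      warning(sprintf("patient %s has single-class voxels; fold skipped",
                      test$patient_id), call. = FALSE)
      next
    }
    train_tab <- dplyr::bind_rows(lapply(tabs[-i], function(x) x$table))
    if (length(unique(train_tab$label)) < 2L) {
      warning(sprintf("training side of fold %s is single-class; fold skipped",
                      test$patient_id), call. = FALSE)
      next
    }
    fold_seed <- (config$seed + 131L * i) %% .Machine$integer.max
    train_tab <- subsample_training(train_tab, config$max_train_per_class,
                                    fold_seed)
    model <- fit_pipeline_model(train_tab, config, seed = fold_seed)
    pred <- predict_pipeline(model, test$table)
    met <- compute_metrics(pred$decision, test$table$label,
                           threshold = model$crossing)
    # predicted lesion mask vs curated cancer mask
    bin <- array(FALSE, dim = dim(test$pz))
    idx <- as.matrix(test$table[c("slice", "row", "col")])
    bin[idx] <- pred$decision > model$crossing
    d <- dice(mask_like(bin, test$pz, "cancer"), test$labels$cancer)
    folds[[length(folds) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(patient_id = test$patient_id),
      met,
      tibble::tibble(
        dice = d,
        C = model$hyperparams$C, gamma = model$hyperparams$gamma,
        n_selected = length(model$selection$selected),
        selected = list(model$selection$selected),
        train_patients = list(model$train_patients)
      )
    )
    models[[test$patient_id]] <- model
  }
  folds <- dplyr::bind_rows(folds)
  metric_cols <- c("auroc", "sensitivity", "specificity", "accuracy", "dice")
  aggregate <- tidyr::pivot_longer(folds[metric_cols], dplyr::everything(),
                                   names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(folds = folds, aggregate = aggregate, config = config,
                 models = models),
            class = "pz_eval_report")
}

#' @export
print.pz_eval_report <- function(x, ...) {
  cat(sprintf("<pz_eval_report> %s, %d fold(s)\n",
              x$config$configuration, nrow(x$folds)))
  for (i in seq_len(nrow(x$aggregate))) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", x$aggregate$metric[i],
                x$aggregate$mean[i], x$aggregate$sd[i]))
  }
  invisible(x)
}

#' Run the complete workflow on a cohort
#'
#' Preprocess (median filter + T2WI standardization), extract features,
#' leave-one-patient-out selection/optimization/training/calibration, and
#' optionally write probability and binary maps plus JSON/CSV reports.
#'
#' @param cohort list of prepared [patient_case()]s.
#' @param config a [pz_config()].
#' @param output_dir optional directory for NIfTI maps and reports.
#' @return The [lopo_run()] evaluation report (invisibly when writing).
#' @export
run_pipeline <- function(cohort, config = pz_config(), output_dir = NULL) {
  pre <- preprocess_cohort(cohort, median_window = config$median_window)
  report <- lopo_run(pre$cohort, config)
  report$reference <- pre$reference
  report$inter_cv_percent <- pre$inter_cv_percent
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(pre$cohort)) {
      case <- pre$cohort[[i]]
      model <- report$models[[case$patient_id]]
      if (is.null(model)) next
      maps <- predict_maps(model, case)
      write_volume(maps$probability,
                   file.path(output_dir,
                             sprintf("%s_probability.nii.gz", case$patient_id)))
      write_volume(maps$binary,
                   file.path(output_dir,
                             sprintf("%s_binary.nii.gz", case$patient_id)))
    }
    readr_safe_csv(report$folds, file.path(output_dir, "folds.csv"))
    jsonlite::write_json(
      list(
        configuration = config$configuration,
        seed = config$seed,
        aggregate = report$aggregate,
        reference = report$reference,
        inter_cv_percent = report$inter_cv_percent
      ),
      file.path(output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    return(invisible(report))
  }
  report
}

readr_safe_csv <- function(tab, path) {
  tab <- dplyr::mutate(tab, dplyr::across(
    dplyr::where(is.list),
    ~ vapply(.x, function(v) paste(v, collapse = ";"), character(1))
  ))
  utils::write.csv(tab, path, row.names = FALSE)
}
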