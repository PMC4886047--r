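# End-to-end pipeline drivers: preprocess -> average profiles -> peak
# pick/align/filter -> peak matrix -> RFE -> SVM tuning -> repeated CV
# (training), and average-profile scoring of a held-out cohort (validation).

#' Pipeline configuration
#'
#' Nested configuration mirroring each stage of the workflow.
#'
#' @param preprocess A [preprocess_config()].
#' @param peaks A [peak_pick_config()].
#' @param tolerance_ppm Peak alignment tolerance (ppm). Default 2000.
#' @param min_presence Presence-filter fraction. Default 0.25.
#' @param rfe_sizes Candidate subset sizes for [rfe()]; `NULL` for the
#'   default grid.
#' @param pls_components PLS components used to score RFE subsets.
#' @param folds,repeats Cross-validation scheme used for RFE, tuning and the
#'   reliability estimate.
#' @param tuning_grid Data frame of cost/gamma candidates; `NULL` for
#'   [default_tuning_grid()].
#' @param svm_scale Standardise features inside the SVM?
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Optional directory where artifacts (model JSON, peak
#'   matrix, CV report, predictions) are persisted.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            peaks = peak_pick_config(),
                            tolerance_ppm = 2000,
                            min_presence = 0.25,
                            rfe_sizes = NULL,
                            pls_components = 3L,
                            folds = 10L,
                            repeats = 2L,
                            tuning_grid = NULL,
                            svm_scale = TRUE,
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(peaks, "peak_pick_config"),
            tolerance_ppm > 0, min_presence > 0, min_presence <= 1)
  structure(list(preprocess = preprocess, peaks = peaks,
                 tolerance_ppm = as.numeric(tolerance_ppm),
                 min_presence = as.numeric(min_presence),
                 rfe_sizes = rfe_sizes,
                 pls_components = as.integer(pls_components),
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 tuning_grid = tuning_grid, svm_scale = isTRUE(svm_scale),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognised top-level sections: `preprocess`, `peaks` (each holding their
#' config's fields) and the scalar fields of [pipeline_config()]. Unknown
#' keys are an error.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()  # empty file: all defaults
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- raw
  if (!is.null(raw$preprocess)) {
    args$preprocess <- do.call(preprocess_config, raw$preprocess)
  }
  if (!is.null(raw$peaks)) {
    args$peaks <- do.call(peak_pick_config, raw$peaks)
  }
  if (!is.null(raw$tuning_grid)) {
    args$tuning_grid <- as.data.frame(raw$tuning_grid)
  }
  do.call(pipeline_config, args)
}

# Average profiles and their peak lists for every patient in the metadata.
.patient_profiles <- function(ds, config) {
  patients <- ds$metadata$patient_id
  present <- unique(spectra_patient_ids(ds))
  profiles <- list()
  skipped <- character(0)
  for (p in patients) {
    if (!(p %in% present)) {
      skipped <- c(skipped, p)
      next
    }
    profiles[[p]] <- average_patient_profile(ds, p)
  }
  if (length(skipped) > 0L) {
    warning("patients without spectra excluded: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  profiles
}

#' Train the full classification pipeline
#'
#' Executes, on a raw training dataset: per-spectrum preprocessing,
#' per-patient average profiles, peak picking on the profiles, ppm alignment
#' and presence filtering across patients, peak-matrix construction (with
#' spectrum backfill), PLS-scored recursive feature elimination, SVM grid
#' tuning, final SVM training, and a repeated cross-validation reliability
#' estimate. Training labels use the histological truth where present,
#' otherwise the THY2 -> Ben, THY4/THY5 -> PTC cytology mapping.
#'
#' @param ds A raw [msi_dataset()] (or a cohort directory path readable by
#'   [read_msi_cohort()]).
#' @param config A [pipeline_config()].
#' @return A list of class `training_result`: `classifier` (with full
#'   provenance), `cv_report`, `rfe`, `tuning`, `peak_matrix`, `labels`.
#'   When `config$out_dir` is set, artifacts are also written there.
#' @export
run_training <- function(ds, config = pipeline_config()) {
  if (is.character(ds)) ds <- read_msi_cohort(ds)
  stopifnot(inherits(ds, "msi_dataset"),
            inherits(config, "pipeline_config"))
  n_patients <- nrow(ds$metadata)
  if (config$folds > n_patients) {
    stop("more folds (", config$folds, ") than patients (", n_patients,
         "); reduce `folds`", call. = FALSE)
  }
  labels_all <- training_labels(ds$metadata)

  pp <- preprocess_dataset(ds, config$preprocess)
  profiles <- .patient_profiles(pp, config)
  labels <- labels_all[names(profiles)]
  if (length(unique(labels)) < 2L) {
    stop("training cohort must contain both classes", call. = FALSE)
  }

  peak_lists <- lapply(names(profiles), function(p) {
    pick_peaks(profiles[[p]], config$peaks, source_id = p)
  })
  ap <- align_peaks(peak_lists, config$tolerance_ppm)
  ap <- filter_peaks(ap, config$min_presence)
  if (length(ap$reference_mz) == 0L) {
    stop("no reference peaks survive the presence filter", call. = FALSE)
  }
  pm <- build_peak_matrix(ap, spectra = profiles, backfill = TRUE)

  rfe_res <- rfe(pm$values, labels, sizes = config$rfe_sizes,
                 k = config$folds, repeats = config$repeats,
                 seed = config$seed, n_components = config$pls_components)
  X_sel <- pm$values[, rfe_res$selected, drop = FALSE]

  tuned <- tune_svm(X_sel, labels, grid = config$tuning_grid,
                    k = config$folds, repeats = config$repeats,
                    seed = config$seed, scale = config$svm_scale)
  clf <- train_svm(X_sel, labels, tuned)
  cv_report <- cross_validate(X_sel, labels, tuned, k = config$folds,
                              repeats = config$repeats, seed = config$seed)

  prov_config <- list(tolerance_ppm = config$tolerance_ppm,
                      min_presence = config$min_presence,
                      preprocess = unclass(config$preprocess),
                      peaks = unclass(config$peaks),
                      folds = config$folds, repeats = config$repeats,
                      seed = config$seed)
  clf$provenance <- list(
    tolerance_ppm = config$tolerance_ppm,
    min_presence = config$min_presence,
    preprocess = config$preprocess,
    peaks = config$peaks,
    references = ap$reference_mz,
    seed = config$seed,
    config_hash = .hash_config(prov_config),
    tuning = tuned$tuning,
    rfe_size = rfe_res$size,
    cv_profile = rfe_res$cv_profile)

  result <- structure(list(classifier = clf, cv_report = cv_report,
                           rfe = rfe_res, tuning = tuned$tuning,
                           peak_matrix = pm, labels = labels),
                      class = "training_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_classifier(clf, file.path(config$out_dir, "model.json"))
    write_peak_matrix(pm, file.path(config$out_dir, "peak_matrix.csv"))
    jsonlite::write_json(
      list(selected_mz = rfe_res$selected_mz,
           size = rfe_res$size,
           cv_profile = as.list(rfe_res$cv_profile),
           ranking = as.list(rfe_res$ranking),
           seed = rfe_res$seed,
           config_hash = clf$provenance$config_hash),
      file.path(config$out_dir, "rfe.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      c(as.list(metrics_vector(cv_report)),
        list(n = cv_report$n, seed = config$seed,
             config_hash = clf$provenance$config_hash)),
      file.path(config$out_dir, "cv_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.training_result <- function(x, ...) {
  cat("Training result\n")
  print(x$classifier)
  cat(sprintf("RFE: %d features selected of %d\n",
              length(x$rfe$selected), ncol(x$peak_matrix$values)))
  cat("Cross-validation (pooled):\n")
  print(x$cv_report)
  invisible(x)
}

#' Validate a trained classifier on a held-out cohort
#'
#' Each validation patient's pixels are preprocessed with the training
#' configuration, averaged into a profile, peak-picked, aligned to the
#' model's features and scored. Patients without spectra are excluded with a
#' warning.
#'
#' @param clf A classifier with provenance (from [run_training()] or
#'   [read_classifier()]).
#' @param ds A raw [msi_dataset()] of the validation cohort (or a cohort
#'   directory path).
#' @param out_dir Optional directory for the predictions table and report.
#' @return A list of class `validation_result`: `report` (a
#'   [compute_metrics()] performance report, positive class Ben) and
#'   `predictions` (per-patient predicted/true table with decision values).
#' @export
run_validation <- function(clf, ds, out_dir = NULL) {
  if (is.character(ds)) ds <- read_msi_cohort(ds)
  stopifnot(inherits(clf, "trained_classifier"),
            inherits(ds, "msi_dataset"))
  prov <- clf$provenance
  if (is.null(prov)) {
    stop("classifier carries no provenance; cannot preprocess raw data",
         call. = FALSE)
  }
  if (length(ds$spectra) == 0L) {
    stop("validation dataset is empty", call. = FALSE)
  }
  pp <- preprocess_dataset(ds, prov$preprocess)
  profiles <- .patient_profiles(pp, NULL)
  if (length(profiles) == 0L) {
    stop("no validation patients with spectra", call. = FALSE)
  }
  # undetected model features are backfilled from the profile spectrum
  # within the tolerance window, exactly as the training matrix was built;
  # zero-filling them instead would bias validation features downward
  # relative to training
  features <- t(vapply(names(profiles), function(p) {
    prof <- profiles[[p]]
    pl <- pick_peaks(prof, prov$peaks, source_id = p)
    .backfill_features(align_to_model(pl, clf), prof, clf$selected_mz,
                       prov$tolerance_ppm %||% 2000)
  }, numeric(length(clf$feature_names))))
  pred <- predict(clf, features)
  truth <- ds$metadata$histological_class[
    match(names(profiles), ds$metadata$patient_id)]
  predictions <- data.frame(sample_id = names(profiles),
                            predicted = pred$label,
                            true = truth,
                            decision = pred$decision,
                            stringsAsFactors = FALSE)
  report <- if (all(!is.na(truth))) {
    compute_metrics(pred$label, truth, decision_values = pred$decision)
  } else {
    NULL
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_predictions(predictions, file.path(out_dir, "predictions.csv"))
    if (!is.null(report)) {
      jsonlite::write_json(
        c(as.list(metrics_vector(report)),
          list(n = report$n, config_hash = prov$config_hash)),
        file.path(out_dir, "validation_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  structure(list(report = report, predictions = predictions),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("Validation result\n")
  print(x$predictions)
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
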