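# Radial-kernel SVM training, grid tuning, repeated cross-validation and
# model serialisation. The quadratic-programming core is delegated to
# e1071::svm; everything around it (tuning, CV, metrics, provenance,
# portable decision function) lives here.

#' SVM configuration
#'
#' @param cost Soft-margin cost parameter (> 0).
#' @param gamma RBF kernel width parameter (> 0).
#' @param epsilon Recorded for fidelity with the original toolchain's tuning
#'   record but inert: epsilon parametrises regression SVMs, not
#'   C-classification.
#' @param kernel Only `"radial"` is supported.
#' @param scale Standardise features before fitting (stored and re-applied at
#'   prediction time)? Default `TRUE`.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(cost = 10, gamma = 0.11, epsilon = 0.1,
                       kernel = "radial", scale = TRUE) {
  kernel <- match.arg(kernel, "radial")
  if (cost <= 0 || gamma <= 0) {
    stop("cost and gamma must be > 0", call. = FALSE)
  }
  structure(list(cost = as.numeric(cost), gamma = as.numeric(gamma),
                 epsilon = as.numeric(epsilon), kernel = kernel,
                 scale = isTRUE(scale)),
            class = "svm_config")
}

#' Default tuning grid
#'
#' Cost in \{0.1, 1, 10, 100\} crossed with gamma in
#' \{0.01, 0.11, 1.11, 1/n_features\}.
#'
#' @param n_features Number of features (adds `1/n_features` to the gamma
#'   candidates).
#' @return Data frame with columns `cost` and `gamma`.
#' @export
default_tuning_grid <- function(n_features) {
  expand.grid(cost = c(0.1, 1, 10, 100),
              gamma = sort(unique(c(0.01, 0.11, 1.11, 1 / n_features))))
}

.as_class_factor <- function(y) {
  y <- as.character(y)
  bad <- !(y %in% c("Ben", "PTC"))
  if (any(bad)) {
    stop("labels outside the Ben/PTC vocabulary: ",
         paste(unique(y[bad]), collapse = ", "), call. = FALSE)
  }
  factor(y, levels = c("Ben", "PTC"))
}

#' Train an RBF-kernel SVM classifier
#'
#' Fits a soft-margin C-classification SVM at the configured (cost, gamma)
#' and extracts a self-contained decision-function state (support vectors,
#' dual coefficients, offset, feature scaling) so the classifier can be
#' serialised to JSON and restored without the fitting library. Decision
#' values are oriented so positive means Ben.
#'
#' @param X Numeric matrix (samples x features, named columns).
#' @param y Labels in `{"Ben", "PTC"}`, each class at least twice.
#' @param config An [svm_config()].
#' @return An object of class `trained_classifier`. Pipeline callers attach
#'   a `provenance` list (reference m/z, tolerance, preprocessing and peak
#'   configs, seed) needed to score raw data.
#' @export
train_svm <- function(X, y, config = svm_config()) {
  X <- as.matrix(X)
  y <- .as_class_factor(y)
  if (any(table(y) < 2L)) {
    stop("each class needs at least two training samples", call. = FALSE)
  }
  fit <- e1071::svm(x = X, y = y, type = "C-classification",
                    kernel = "radial", cost = config$cost,
                    gamma = config$gamma, scale = config$scale)
  dv <- attr(stats::predict(fit, X, decision.values = TRUE),
             "decision.values")
  # e1071 orients the decision value towards the first label in its
  # internal ordering; normalise so positive always means Ben
  flip <- if (identical(colnames(dv), "PTC/Ben")) -1 else 1

  center <- scl <- NULL
  if (!is.null(fit$x.scale)) {
    center <- fit$x.scale$`scaled:center`
    scl <- fit$x.scale$`scaled:scale`
  }
  state <- list(sv = unname(as.matrix(fit$SV)),
                dual_coefs = as.numeric(fit$coefs) * flip,
                rho = as.numeric(fit$rho) * flip,
                gamma = config$gamma,
                center = center, scale = scl)

  structure(list(svm = fit, flip = flip, state = state, config = config,
                 levels = levels(y),
                 feature_names = colnames(X),
                 selected_mz = suppressWarnings(as.numeric(colnames(X))),
                 provenance = NULL),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf(
    "<trained_classifier> RBF SVM on %d features (cost %g, gamma %g)\n",
    length(x$feature_names), x$config$cost, x$config$gamma))
  invisible(x)
}

# decision function from the serialisable state (positive -> Ben)
.svm_decision <- function(state, X) {
  X <- as.matrix(X)
  if (!is.null(state$center)) {
    X <- sweep(X, 2L, state$center)
    X <- sweep(X, 2L, ifelse(state$scale == 0, 1, state$scale), `/`)
  }
  sv <- state$sv
  d2 <- outer(rowSums(X^2), rowSums(sv^2), `+`) - 2 * tcrossprod(X, sv)
  K <- exp(-state$gamma * pmax(d2, 0))
  drop(K %*% state$dual_coefs) - state$rho
}

#' Predict classes and decision values
#'
#' @param object A [train_svm()] classifier.
#' @param newdata Matrix whose columns match the training features (a
#'   dimension mismatch is an error naming the missing m/z values).
#' @param ... Unused.
#' @return Data frame with columns `label` and `decision` (positive
#'   decision values favour Ben).
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_names)) {
    stop("feature dimension mismatch: model expects ",
         length(object$feature_names), " features, got ", ncol(newdata),
         call. = FALSE)
  }
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing) > 0L) {
      stop("newdata is missing model features (m/z): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  dec <- if (!is.null(object$svm)) {
    dv <- attr(stats::predict(object$svm, newdata, decision.values = TRUE),
               "decision.values")
    as.numeric(dv) * object$flip
  } else {
    .svm_decision(object$state, newdata)
  }
  data.frame(label = ifelse(dec >= 0, "Ben", "PTC"), decision = dec,
             stringsAsFactors = FALSE)
}

#' Serialise a trained classifier to a JSON artifact
#'
#' Stores the selected feature m/z values, the full decision-function state
#' (support vectors, dual coefficients, offset, feature scaling), the tuning
#' configuration and the provenance block. [read_classifier()] restores a
#' classifier whose predictions match the original to numerical precision.
#'
#' @param clf A [train_svm()] classifier.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "trained_classifier"))
  prov <- clf$provenance
  if (!is.null(prov$preprocess)) prov$preprocess <- unclass(prov$preprocess)
  if (!is.null(prov$peaks)) prov$peaks <- unclass(prov$peaks)
  obj <- list(format = "msiclass_classifier",
              version = 1L,
              levels = clf$levels,
              feature_names = clf$feature_names,
              selected_mz = clf$selected_mz,
              config = unclass(clf$config),
              state = clf$state,
              provenance = prov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Restore a classifier written by [write_classifier()]
#'
#' @param path JSON path.
#' @return A `trained_classifier` backed by the stored decision-function
#'   state.
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "msiclass_classifier")) {
    stop(path, " is not an msiclass classifier artifact", call. = FALSE)
  }
  state <- obj$state
  state$sv <- as.matrix(state$sv)
  cfg <- do.call(svm_config, obj$config[c("cost", "gamma", "epsilon",
                                          "kernel", "scale")])
  prov <- obj$provenance
  if (!is.null(prov$preprocess)) {
    prov$preprocess <- do.call(preprocess_config, prov$preprocess)
  }
  if (!is.null(prov$peaks)) {
    prov$peaks <- do.call(peak_pick_config, prov$peaks)
  }
  structure(list(svm = NULL, flip = 1, state = state, config = cfg,
                 levels = obj$levels,
                 feature_names = obj$feature_names,
                 selected_mz = obj$selected_mz,
                 provenance = prov),
            class = "trained_classifier")
}

#' Tune an SVM over a (cost, gamma) grid
#'
#' Every grid point is evaluated with the same repeated stratified k-fold
#' folds (drawn once from `seed`) and the point with maximal mean pooled CV
#' accuracy wins; ties go to the smaller cost, then the smaller gamma.
#'
#' @param X,y Training matrix and labels.
#' @param grid Data frame of `cost`/`gamma` candidates; default
#'   [default_tuning_grid()].
#' @param k,repeats,seed Cross-validation scheme.
#' @param scale Passed through to [svm_config()].
#' @return The winning [svm_config()], with the full evaluation attached as
#'   attribute/field `tuning` (a data frame of grid points and accuracies).
#' @export
tune_svm <- function(X, y, grid = NULL, k = 10L, repeats = 2L, seed = 1L,
                     scale = TRUE) {
  X <- as.matrix(X)
  y <- .as_class_factor(y)
  if (is.null(grid)) grid <- default_tuning_grid(ncol(X))
  if (nrow(grid) == 0L) stop("empty tuning grid", call. = FALSE)
  set.seed(seed)
  folds <- lapply(seq_len(repeats), function(r) .stratified_folds(y, k))
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- svm_config(cost = grid$cost[g], gamma = grid$gamma[g],
                      scale = scale)
    hits <- 0L
    total <- 0L
    for (r in seq_len(repeats)) {
      for (fold in seq_len(k)) {
        tr <- folds[[r]] != fold
        if (length(unique(y[tr])) < 2L || !any(!tr)) next
        clf <- suppressWarnings(
          train_svm(X[tr, , drop = FALSE], y[tr], cfg))
        pred <- predict(clf, X[!tr, , drop = FALSE])$label
        hits <- hits + sum(pred == y[!tr])
        total <- total + sum(!tr)
      }
    }
    hits / total
  }, numeric(1))
  ord <- order(-acc, grid$cost, grid$gamma)
  best <- ord[1L]
  out <- svm_config(cost = grid$cost[best], gamma = grid$gamma[best],
                    scale = scale)
  out$tuning <- data.frame(grid, accuracy = acc)
  out
}

#' Repeated stratified cross-validation of an SVM configuration
#'
#' Folds are stratified by class; metrics are pooled over every held-out
#' prediction across all repeats. If stratification still leaves a training
#' fold single-class (possible for tiny classes), folds are redrawn up to 25
#' times before erroring.
#'
#' @param X,y Training matrix and labels.
#' @param config An [svm_config()].
#' @param k,repeats,seed Cross-validation scheme.
#' @return A [compute_metrics()] performance report for the pooled held-out
#'   predictions.
#' @export
cross_validate <- function(X, y, config = svm_config(), k = 10L,
                           repeats = 2L, seed = 1L) {
  X <- as.matrix(X)
  y <- .as_class_factor(y)
  if (nrow(X) < k) {
    stop("fewer samples (", nrow(X), ") than folds (", k, ")", call. = FALSE)
  }
  set.seed(seed)
  pred <- character(0)
  truth <- character(0)
  dec <- numeric(0)
  loo <- k == nrow(X)  # k = n is exactly leave-one-out
  for (r in seq_len(repeats)) {
    folds <- NULL
    if (loo) folds <- seq_len(nrow(X))
    for (attempt in if (loo) integer(0) else seq_len(25L)) {
      cand <- .stratified_folds(y, k)
      ok <- all(vapply(seq_len(k), function(f) {
        length(unique(y[cand != f])) == 2L
      }, logical(1)))
      if (ok) { folds <- cand; break }
    }
    if (is.null(folds)) {
      stop("could not stratify folds with both classes in every training ",
           "split", call. = FALSE)
    }
    for (fold in seq_len(k)) {
      tr <- folds != fold
      if (!any(!tr)) next
      clf <- suppressWarnings(train_svm(X[tr, , drop = FALSE], y[tr], config))
      p <- predict(clf, X[!tr, , drop = FALSE])
      pred <- c(pred, p$label)
      dec <- c(dec, p$decision)
      truth <- c(truth, as.character(y[!tr]))
    }
  }
  compute_metrics(pred, truth, decision_values = dec)
}
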