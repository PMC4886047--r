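# Recursive feature elimination over the training peak matrix, scored by a
# PLS classifier under repeated stratified k-fold cross-validation.

.default_rfe_sizes <- function(p) {
  s <- c(2L, 5L, 10L, 15L, 20L, 25L, 30L, 40L, 60L, 80L, 100L, p)
  sort(unique(s[s >= 1L & s <= p]), decreasing = TRUE)
}

# One elimination path: starting from all features, recursively refit PLS
# and drop the lowest-importance features down to each candidate size
# (block-wise, caret-style). Ties in importance break towards keeping the
# lower m/z (deterministic). Returns the feature set retained at each size
# plus the full elimination order.
.rfe_path <- function(X, y, sizes_desc, n_components) {
  feats <- colnames(X)
  mz <- suppressWarnings(as.numeric(feats))
  if (anyNA(mz)) mz <- seq_along(feats)  # non-m/z names: tie-break by column
  at_size <- vector("list", length(sizes_desc))
  names(at_size) <- as.character(sizes_desc)
  eliminated <- character(0)
  for (si in seq_along(sizes_desc)) {
    s <- sizes_desc[si]
    if (length(feats) > s) {
      fit <- pls_fit(X[, feats, drop = FALSE], y,
                     min(n_components, length(feats)))
      sc <- pls_feature_scores(fit)
      ord <- order(-sc, mz[match(feats, colnames(X))])
      dropped <- feats[ord][(s + 1L):length(feats)]
      eliminated <- c(eliminated, rev(dropped))
      feats <- feats[ord][seq_len(s)]
      feats <- feats[order(match(feats, colnames(X)))]  # keep column order
    }
    at_size[[si]] <- feats
  }
  list(at_size = at_size, eliminated = eliminated)
}

#' Recursive feature elimination with PLS scoring
#'
#' The outer loop runs `repeats` x `k` stratified folds. Within each fold's
#' training part, features are recursively eliminated (refit PLS, drop the
#' lowest-|coefficient| features in one block down to the next candidate
#' size) and each candidate size's held-out accuracy is recorded. The chosen
#' size maximises the mean cross-validated accuracy, ties going to the
#' smallest size; the selected features come from re-running the elimination
#' on the full training set at that size. Fully reproducible for a fixed
#' seed.
#'
#' @param X Numeric matrix (samples x features) with feature names; when the
#'   columns are named by reference m/z the selected m/z values are reported.
#' @param y Labels in `{"Ben", "PTC"}`.
#' @param sizes Candidate subset sizes; default
#'   `{2, 5, 10, 15, 20, 25, 30, 40, 60, 80, 100, p}` clipped to `[1, p]`.
#' @param k Folds (default 10); `n_samples >= k` is required.
#' @param repeats Repetitions of the k-fold split (default 2).
#' @param seed Integer seed for the fold assignments.
#' @param n_components PLS components used for scoring (default 3, clipped
#'   per fit).
#' @return An object of class `rfe_result`: `selected` (feature names),
#'   `selected_mz`, `size`, `cv_profile` (mean accuracy per size), `ranking`
#'   (elimination order over all features, 1 = most important) and `seed`.
#' @export
rfe <- function(X, y, sizes = NULL, k = 10L, repeats = 2L, seed = 1L,
                n_components = 3L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- as.character(seq_len(ncol(X)))
  y <- as.character(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < k) {
    stop("fewer samples (", n, ") than folds (", k, ")", call. = FALSE)
  }
  sizes <- if (is.null(sizes)) .default_rfe_sizes(p)
           else sort(unique(as.integer(sizes)), decreasing = TRUE)
  if (any(sizes < 1L | sizes > p)) {
    stop("candidate sizes must lie in [1, ", p, "]", call. = FALSE)
  }

  set.seed(seed)
  acc <- matrix(NA_real_, length(sizes), repeats * k,
                dimnames = list(as.character(sizes), NULL))
  col <- 0L
  for (r in seq_len(repeats)) {
    folds <- .stratified_folds(y, k)
    for (fold in seq_len(k)) {
      col <- col + 1L
      tr <- folds != fold
      te <- !tr
      if (length(unique(y[tr])) < 2L) next  # fold degenerate; leave NA
      path <- .rfe_path(X[tr, , drop = FALSE], y[tr], sizes, n_components)
      for (si in seq_along(sizes)) {
        feats <- path$at_size[[si]]
        fit <- pls_fit(X[tr, feats, drop = FALSE], y[tr],
                       min(n_components, length(feats)))
        pred <- predict(fit, X[te, feats, drop = FALSE], type = "class")
        acc[si, col] <- mean(pred == y[te])
      }
    }
  }
  cv_profile <- rowMeans(acc, na.rm = TRUE)
  # maximise mean CV accuracy; ties -> smallest size
  sizes_asc <- rev(sizes)
  prof_asc <- cv_profile[as.character(sizes_asc)]
  best_size <- sizes_asc[which.max(prof_asc)]

  full_path <- .rfe_path(X, y, sizes, n_components)
  selected <- full_path$at_size[[as.character(best_size)]]
  final_fit <- pls_fit(X[, selected, drop = FALSE], y,
                       min(n_components, length(selected)))
  sel_scores <- pls_feature_scores(final_fit)
  sel_mz <- suppressWarnings(as.numeric(selected))
  if (anyNA(sel_mz)) sel_mz <- seq_along(selected)
  survivors <- selected[order(-sel_scores, sel_mz)]
  # survivors first (by final importance), then everything else in reverse
  # elimination order; unique() keeps first occurrences so this is a
  # permutation of all features
  ranking_order <- unique(c(survivors, rev(full_path$eliminated),
                            colnames(X)))
  ranking <- stats::setNames(match(colnames(X), ranking_order), colnames(X))

  structure(list(selected = selected,
                 selected_mz = suppressWarnings(as.numeric(selected)),
                 size = best_size,
                 cv_profile = stats::setNames(cv_profile,
                                              as.character(sizes)),
                 ranking = ranking,
                 sizes = sizes,
                 seed = seed),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf(
    "<rfe_result> %d features selected (CV accuracy %.3f at size %d)\n",
    length(x$selected), x$cv_profile[as.character(x$size)], x$size))
  invisible(x)
}
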