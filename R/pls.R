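# Two-class partial least squares (PLS1 / PLS-DA) fitted by NIPALS, used to
# score candidate feature subsets during recursive feature elimination.

.PLS_CODES <- c(Ben = 1, PTC = -1)

.class_code <- function(y) {
  y <- as.character(y)
  bad <- !(y %in% names(.PLS_CODES))
  if (any(bad)) {
    stop("labels outside the Ben/PTC vocabulary: ",
         paste(unique(y[bad]), collapse = ", "), call. = FALSE)
  }
  unname(.PLS_CODES[y])
}

#' Fit a two-class PLS model (NIPALS)
#'
#' Classes are coded Ben = +1, PTC = -1; predictors and the code are
#' mean-centred internally (centring vectors stored). Latent components are
#' extracted by NIPALS with deflation of both blocks, giving mutually
#' orthogonal score vectors; the regression coefficients map centred
#' predictors to the centred class code. The fit is deterministic.
#'
#' @param X Numeric matrix, samples in rows, features in columns.
#' @param y Labels in `{"Ben", "PTC"}` (each class at least twice), or a
#'   numeric code.
#' @param n_components Number of latent components; clipped with a warning to
#'   `min(n_samples - 1, n_features)`. Extraction also stops early if the
#'   residual covariance vanishes.
#' @param scale Autoscale each feature to unit variance (constant features
#'   are left unscaled)? Default `TRUE`: peak intensities span orders of
#'   magnitude, and standardising is what makes the absolute regression
#'   coefficient a scale-free importance ranking. The scaling vector is
#'   stored and re-applied at prediction time; coefficients are reported on
#'   the scaled predictors.
#' @return An object of class `pls_model` with weights, loadings, scores,
#'   the coefficient vector and the centring/scaling information.
#' @export
pls_fit <- function(X, y, n_components = 2L, scale = TRUE) {
  X <- as.matrix(X)
  code <- if (is.numeric(y)) as.numeric(y) else .class_code(y)
  if (length(unique(code)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  stopifnot(nrow(X) == length(code))
  max_comp <- min(nrow(X) - 1L, ncol(X))
  if (n_components > max_comp) {
    warning("n_components reduced from ", n_components, " to ", max_comp,
            call. = FALSE)
    n_components <- max_comp
  }
  x_center <- colMeans(X)
  y_center <- mean(code)
  E <- sweep(X, 2L, x_center)
  x_scale <- rep(1, ncol(X))
  if (isTRUE(scale)) {
    s <- apply(E, 2L, stats::sd)
    x_scale <- ifelse(is.na(s) | s == 0, 1, s)
    E <- sweep(E, 2L, x_scale, `/`)
  }
  f <- code - y_center

  p <- ncol(X)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(X), n_components)
  q <- numeric(n_components)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24) break
    pl <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pl)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
    a_used <- a
  }
  if (a_used == 0L) {
    stop("no usable covariance between predictors and class code",
         call. = FALSE)
  }
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  coefficients <- drop(W %*% solve(crossprod(P, W), q))
  names(coefficients) <- colnames(X)
  structure(list(n_components = a_used, weights = W, loadings = P,
                 scores = Tm, q = q, coefficients = coefficients,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object A [pls_fit()] model.
#' @param newdata Matrix with the same feature columns used at fit time.
#' @param type `"code"` for the numeric class code, `"class"` for hard labels
#'   (threshold 0: non-negative predicts Ben).
#' @param ... Unused.
#' @return Numeric codes or a character vector of labels.
#' @export
predict.pls_model <- function(object, newdata,
                              type = c("code", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  Z <- sweep(sweep(newdata, 2L, object$x_center), 2L, object$x_scale, `/`)
  code <- drop(Z %*% object$coefficients) + object$y_center
  if (type == "code") code else ifelse(code >= 0, "Ben", "PTC")
}

#' Per-feature importance of a PLS model
#'
#' The absolute regression coefficient of each feature: a scale-free ranking
#' used to decide elimination order during RFE.
#'
#' @param m A [pls_fit()] model.
#' @return Named non-negative numeric vector.
#' @export
pls_feature_scores <- function(m) {
  stopifnot(inherits(m, "pls_model"))
  abs(m$coefficients)
}
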