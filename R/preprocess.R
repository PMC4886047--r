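# Per-spectrum signal conditioning: Savitzky-Golay smoothing, TopHat
# (morphological opening) baseline subtraction, and total-ion-current
# normalisation, applied in that fixed order.

#' Preprocessing configuration
#'
#' All windows are expressed in points (index space), not m/z units: MALDI
#' linear-TOF spectra are near-uniformly sampled and the morphological and
#' polynomial operators act on the sampled sequence.
#'
#' @param tophat_half_window Half-width (points) of the flat structuring
#'   element used for the morphological opening; the element spans
#'   `2 * tophat_half_window + 1` points and must be wider than any real peak
#'   so that peaks survive baseline removal. Default 75.
#' @param savgol_half_window Half-width (points) of the Savitzky-Golay
#'   window. Default 10 (a 21-point window).
#' @param savgol_polyorder Polynomial order of the Savitzky-Golay local fit;
#'   must be smaller than the window length. Default 3.
#' @param tic_target Total ion current every spectrum is scaled to. Default 1
#'   (each spectrum integrates to unit area).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(tophat_half_window = 75L,
                              savgol_half_window = 10L,
                              savgol_polyorder = 3L,
                              tic_target = 1) {
  tophat_half_window <- as.integer(tophat_half_window)
  savgol_half_window <- as.integer(savgol_half_window)
  savgol_polyorder <- as.integer(savgol_polyorder)
  if (tophat_half_window < 1L) {
    stop("tophat_half_window must be >= 1", call. = FALSE)
  }
  if (savgol_polyorder < 0L ||
      2L * savgol_half_window + 1L <= savgol_polyorder) {
    stop("Savitzky-Golay window (2 * half_window + 1) must exceed the ",
         "polynomial order, which must be >= 0", call. = FALSE)
  }
  if (!is.numeric(tic_target) || tic_target <= 0) {
    stop("tic_target must be a positive number", call. = FALSE)
  }
  structure(list(tophat_half_window = tophat_half_window,
                 savgol_half_window = savgol_half_window,
                 savgol_polyorder = savgol_polyorder,
                 tic_target = as.numeric(tic_target)),
            class = "preprocess_config")
}

# Central Savitzky-Golay convolution weights for a full window.
.sg_weights <- function(half_window, polyorder) {
  x <- seq.int(-half_window, half_window)
  A <- outer(x, 0:polyorder, `^`)
  # first row of (A'A)^{-1} A' evaluates the fitted polynomial at the centre
  solve(crossprod(A), t(A))[1L, ]
}

# Least-squares polynomial fit over an arbitrary (possibly truncated) window,
# evaluated at index `at` within the window's own coordinates.
.ls_poly_eval <- function(y, positions, polyorder, at = 0) {
  A <- outer(positions, 0:polyorder, `^`)
  beta <- solve(crossprod(A), crossprod(A, y))
  drop(outer(at, 0:polyorder, `^`) %*% beta)
}

#' Savitzky-Golay smoothing
#'
#' Replaces each intensity by the value at the window centre of a local
#' least-squares polynomial fit. Interior points use the full symmetric
#' window; within `half_window` points of either edge the polynomial is
#' fitted on the truncated window and evaluated in place, so there are no
#' padding artefacts. Negative outputs are permitted at this stage (baseline
#' subtraction clips the final result).
#'
#' @param s A [mass_spectrum()].
#' @param cfg A [preprocess_config()].
#' @return The smoothed spectrum (m/z axis unchanged).
#' @export
smooth_savitzky_golay <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "mass_spectrum"))
  hw <- cfg$savgol_half_window
  p <- cfg$savgol_polyorder
  n <- length(s$intensity)
  if (n <= 2L * hw + 1L) {
    stop("Savitzky-Golay window (", 2L * hw + 1L,
         " points) is not shorter than the spectrum (", n, " points)",
         call. = FALSE)
  }
  w <- .sg_weights(hw, p)
  sm <- stats::filter(s$intensity, w, sides = 2)
  sm <- as.numeric(sm)
  for (i in seq_len(hw)) {
    idx <- 1L:(i + hw)
    sm[i] <- .ls_poly_eval(s$intensity[idx], idx - i, p)
    jdx <- (n - i - hw + 1L):n
    j <- n - i + 1L
    sm[j] <- .ls_poly_eval(s$intensity[jdx], jdx - j, p)
  }
  s$intensity <- sm
  s
}

#' TopHat baseline subtraction
#'
#' Estimates the baseline as the grey-scale morphological opening of the
#' intensity sequence (erosion then dilation with a flat structuring element
#' of width `2 * tophat_half_window + 1` points) and subtracts it, clipping
#' at zero. Opening is anti-extensive (baseline never exceeds the signal) and
#' idempotent, so a second pass changes nothing.
#'
#' @inheritParams smooth_savitzky_golay
#' @return The baseline-subtracted spectrum.
#' @export
subtract_baseline_tophat <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "mass_spectrum"))
  hw <- cfg$tophat_half_window
  n <- length(s$intensity)
  if (n <= 2L * hw + 1L) {
    stop("structuring element (", 2L * hw + 1L,
         " points) is not narrower than the spectrum (", n, " points)",
         call. = FALSE)
  }
  eroded <- .running_extreme(s$intensity, hw, pmin)
  baseline <- .running_extreme(eroded, hw, pmax)
  residual <- s$intensity - baseline
  # snap rounding crumbs (e.g. a smoothed constant minus its own opening)
  # to exact zero so downstream zero-TIC detection works
  tiny <- 64 * .Machine$double.eps * pmax(abs(s$intensity), abs(baseline))
  residual[residual <= tiny] <- 0
  s$intensity <- pmax(residual, 0)
  s
}

#' Total ion current normalisation
#'
#' Scales the intensities so their sum equals `tic_target`, giving every
#' spectrum the same integrated area. A spectrum whose total ion current is
#' not strictly positive cannot be normalised and raises a degenerate-spectrum
#' error (condition class `msiclass_degenerate_spectrum`), which pixel-wise
#' callers may catch to skip the pixel.
#'
#' @inheritParams smooth_savitzky_golay
#' @return The normalised spectrum.
#' @export
normalize_tic <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "mass_spectrum"))
  tot <- sum(s$intensity)
  if (!is.finite(tot) || tot <= 0) {
    stop(structure(
      class = c("msiclass_degenerate_spectrum", "error", "condition"),
      list(message = sprintf(
             "degenerate spectrum at pixel (%d, %d): total ion current %g",
             s$x, s$y, tot),
           call = NULL)))
  }
  s$intensity <- s$intensity * (cfg$tic_target / tot)
  s
}

#' Full per-spectrum preprocessing pipeline
#'
#' Applies, in this fixed order: Savitzky-Golay smoothing, TopHat baseline
#' subtraction, TIC normalisation. Smoothing before the opening keeps noise
#' spikes from distorting the morphological baseline. Coordinates and patient
#' id are preserved.
#'
#' @inheritParams smooth_savitzky_golay
#' @return The preprocessed spectrum; its intensities are non-negative and
#'   sum to `cfg$tic_target`.
#' @export
preprocess_spectrum <- function(s, cfg = preprocess_config()) {
  normalize_tic(subtract_baseline_tophat(smooth_savitzky_golay(s, cfg), cfg),
                cfg)
}

#' Preprocess every spectrum of a dataset
#'
#' @param ds An [msi_dataset()].
#' @param cfg A [preprocess_config()].
#' @param on_degenerate What to do with pixels whose total ion current
#'   vanishes after baseline removal: `"error"` (default) aborts, `"drop"`
#'   removes them with a warning.
#' @return The preprocessed dataset.
#' @export
preprocess_dataset <- function(ds, cfg = preprocess_config(),
                               on_degenerate = c("error", "drop")) {
  stopifnot(inherits(ds, "msi_dataset"))
  on_degenerate <- match.arg(on_degenerate)
  out <- vector("list", length(ds$spectra))
  keep <- logical(length(ds$spectra))
  for (i in seq_along(ds$spectra)) {
    res <- tryCatch(preprocess_spectrum(ds$spectra[[i]], cfg),
                    msiclass_degenerate_spectrum = function(e) e)
    if (inherits(res, "msiclass_degenerate_spectrum")) {
      if (on_degenerate == "error") stop(res)
      keep[i] <- FALSE
    } else {
      out[[i]] <- res
      keep[i] <- TRUE
    }
  }
  if (!all(keep)) {
    warning(sum(!keep), " degenerate spectra dropped during preprocessing",
            call. = FALSE)
  }
  msi_dataset(out[keep], ds$metadata)
}
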