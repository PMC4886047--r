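# Feature extraction: MAD noise estimation, S/N peak picking, ppm-tolerance
# alignment, presence filtering, peak-matrix construction, and per-patient
# average profiles.

#' Peak picking configuration
#'
#' @param snr_threshold Signal-to-noise ratio a local maximum must reach
#'   (inclusive) to be kept as a peak. Default 3.
#' @param halfwindow_local_max Half-width (points) of the window within which
#'   a peak must be the unique maximum. Default 20.
#' @param mad_scale Consistency constant multiplying the median absolute
#'   deviation; 1.4826 makes the estimate unbiased for Gaussian noise.
#' @return An object of class `peak_pick_config`.
#' @export
peak_pick_config <- function(snr_threshold = 3,
                             halfwindow_local_max = 20L,
                             mad_scale = 1.4826) {
  if (!is.numeric(snr_threshold) || snr_threshold <= 0) {
    stop("snr_threshold must be > 0", call. = FALSE)
  }
  halfwindow_local_max <- as.integer(halfwindow_local_max)
  if (halfwindow_local_max < 1L) {
    stop("halfwindow_local_max must be >= 1", call. = FALSE)
  }
  structure(list(snr_threshold = as.numeric(snr_threshold),
                 halfwindow_local_max = halfwindow_local_max,
                 mad_scale = as.numeric(mad_scale)),
            class = "peak_pick_config")
}

#' MAD noise estimate for a spectrum
#'
#' One global noise level per spectrum:
#' `mad_scale * median(|intensity - median(intensity)|)`.
#'
#' @param s A [mass_spectrum()].
#' @param cfg A [peak_pick_config()].
#' @return A non-negative scalar in intensity units.
#' @export
estimate_noise_mad <- function(s, cfg = peak_pick_config()) {
  stopifnot(inherits(s, "mass_spectrum"))
  stats::mad(s$intensity, constant = cfg$mad_scale)
}

#' Construct a peak list
#' @param source_id Identifier of the originating sample or pixel.
#' @param mz,intensity Peak coordinates, ascending in m/z.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(source_id, mz = numeric(), intensity = numeric()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 1L && is.unsorted(mz, strictly = TRUE)) {
    stop("peak m/z values must be strictly increasing", call. = FALSE)
  }
  structure(list(source_id = as.character(source_id), mz = mz,
                 intensity = intensity),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %s: %d peaks\n", x$source_id, length(x$mz)))
  invisible(x)
}

#' Pick peaks from a preprocessed spectrum
#'
#' A peak is a point that is the unique maximum within
#' `halfwindow_local_max` points on either side, is strictly positive, and
#' whose intensity is at least `snr_threshold` times the spectrum's MAD noise
#' level (threshold inclusive). An empty peak list is legal.
#'
#' @inheritParams estimate_noise_mad
#' @param source_id Identifier attached to the resulting peak list; defaults
#'   to the spectrum's pixel identity (`patient_id:x:y`). Patient-profile
#'   callers pass the patient id instead.
#' @return A [peak_list()].
#' @export
pick_peaks <- function(s, cfg = peak_pick_config(),
                       source_id = spectrum_source_id(s)) {
  stopifnot(inherits(s, "mass_spectrum"))
  noise <- estimate_noise_mad(s, cfg)
  int <- s$intensity
  n <- length(int)
  hw <- min(cfg$halfwindow_local_max, n - 1L)
  rmax <- .running_extreme(int, hw, pmax)
  cand <- which(int == rmax & int > 0 & int >= cfg$snr_threshold * noise)
  if (length(cand) > 0L) {
    unique_max <- vapply(cand, function(i) {
      w <- max(1L, i - hw):min(n, i + hw)
      sum(int[w] == int[i]) == 1L
    }, logical(1))
    cand <- cand[unique_max]
  }
  peak_list(source_id, s$mz[cand], int[cand])
}

#' Canonical source identifier of a spectrum
#' @param s A [mass_spectrum()].
#' @return `"<patient_id>:<x>:<y>"`.
#' @export
spectrum_source_id <- function(s) {
  sprintf("%s:%d:%d", s$patient_id, s$x, s$y)
}

# Recursively split a pooled-peak group until no source contributes twice:
# the split point is the largest internal m/z gap.
.split_same_source <- function(mz, src, int, idx) {
  if (length(idx) < 2L || !anyDuplicated(src[idx])) return(list(idx))
  gaps <- diff(mz[idx])
  cut <- which.max(gaps)
  c(.split_same_source(mz, src, int, idx[seq_len(cut)]),
    .split_same_source(mz, src, int, idx[(cut + 1L):length(idx)]))
}

#' Align peak lists across spectra within a ppm tolerance
#'
#' Pools all peaks, sorts them by m/z and partitions them greedily: a new
#' reference group starts whenever the gap to the previous peak exceeds
#' `tolerance_ppm * 1e-6 * mz` (evaluated at the incoming peak). Groups that
#' end up containing two peaks from the same source are split at their
#' largest internal gap, recursively, until every group holds at most one
#' peak per source. Each group's reference m/z is the intensity-weighted mean
#' of its members.
#'
#' @param lists A list of [peak_list()] objects (one per spectrum or patient
#'   profile). Sources with zero peaks still count towards the presence
#'   denominator.
#' @param tolerance_ppm Alignment tolerance in parts per million. Default
#'   2000.
#' @return An object of class `aligned_peaks`: reference m/z values, their
#'   per-source support, and every pooled peak labelled with its reference.
#' @export
align_peaks <- function(lists, tolerance_ppm = 2000) {
  if (inherits(lists, "peak_list")) lists <- list(lists)
  stopifnot(length(lists) > 0L,
            all(vapply(lists, inherits, logical(1), "peak_list")),
            tolerance_ppm > 0)
  source_ids <- vapply(lists, `[[`, character(1), "source_id")
  if (anyDuplicated(source_ids)) {
    stop("duplicated source ids across peak lists", call. = FALSE)
  }
  mz <- unlist(lapply(lists, `[[`, "mz"), use.names = FALSE)
  int <- unlist(lapply(lists, `[[`, "intensity"), use.names = FALSE)
  src <- rep(source_ids, vapply(lists, function(l) length(l$mz), integer(1)))

  empty <- function() {
    structure(list(reference_mz = numeric(), support = integer(),
                   n_sources = length(lists), source_ids = source_ids,
                   peaks = data.frame(source = character(),
                                      ref = integer(), mz = numeric(),
                                      intensity = numeric(),
                                      stringsAsFactors = FALSE),
                   tolerance_ppm = tolerance_ppm),
              class = "aligned_peaks")
  }
  if (length(mz) == 0L) return(empty())

  o <- order(mz, src, int)
  mz <- mz[o]; int <- int[o]; src <- src[o]

  gap_new <- c(TRUE, diff(mz) > tolerance_ppm * 1e-6 * mz[-1L])
  grp <- cumsum(gap_new)
  idx_groups <- split(seq_along(mz), grp)
  idx_groups <- unlist(lapply(idx_groups, function(idx) {
    .split_same_source(mz, src, int, idx)
  }), recursive = FALSE)
  # restore ascending order of groups after the splits
  first_mz <- vapply(idx_groups, function(idx) mz[idx[1L]], numeric(1))
  idx_groups <- idx_groups[order(first_mz)]

  reference_mz <- unname(vapply(idx_groups, function(idx) {
    w <- int[idx]
    if (sum(w) > 0) sum(mz[idx] * w) / sum(w) else mean(mz[idx])
  }, numeric(1)))
  support <- unname(vapply(idx_groups, function(idx) {
    length(unique(src[idx]))
  }, integer(1)))
  ref_of_peak <- integer(length(mz))
  for (g in seq_along(idx_groups)) ref_of_peak[idx_groups[[g]]] <- g

  structure(list(reference_mz = reference_mz, support = support,
                 n_sources = length(lists), source_ids = source_ids,
                 peaks = data.frame(source = src, ref = ref_of_peak, mz = mz,
                                    intensity = int,
                                    stringsAsFactors = FALSE),
                 tolerance_ppm = tolerance_ppm),
            class = "aligned_peaks")
}

#' @export
print.aligned_peaks <- function(x, ...) {
  cat(sprintf("<aligned_peaks> %d references from %d sources (%g ppm)\n",
              length(x$reference_mz), x$n_sources, x$tolerance_ppm))
  invisible(x)
}

#' Filter aligned references by presence across sources
#'
#' Keeps references detected in at least `min_presence` of the sources
#' (boundary inclusive: a reference present in exactly 25 of 100 sources
#' survives `min_presence = 0.25`). This removes false-positive peaks that
#' S/N picking produces from noise, which do not replicate across spectra.
#'
#' @param ap An [align_peaks()] result.
#' @param min_presence Minimum fraction of sources, in (0, 1].
#' @return A filtered `aligned_peaks` object (possibly with no references).
#' @export
filter_peaks <- function(ap, min_presence = 0.25) {
  stopifnot(inherits(ap, "aligned_peaks"),
            min_presence > 0, min_presence <= 1)
  keep <- ap$support / ap$n_sources >= min_presence
  new_index <- cumsum(keep)
  peaks <- ap$peaks[keep[ap$peaks$ref], , drop = FALSE]
  peaks$ref <- new_index[peaks$ref]
  rownames(peaks) <- NULL
  ap$reference_mz <- ap$reference_mz[keep]
  ap$support <- ap$support[keep]
  ap$peaks <- peaks
  ap
}

#' Build the peak-list matrix
#'
#' One row per source, one column per aligned reference; cells hold the
#' detected peak intensity. Where a source has no detected peak at a
#' reference, the cell is 0 (`backfill` off) or the source spectrum's maximum
#' intensity within the ppm tolerance window around the reference
#' (`backfill` on); either way the presence mask records that no peak was
#' detected there.
#'
#' @param ap A (typically filtered) [align_peaks()] result.
#' @param spectra Named list of preprocessed [mass_spectrum()] objects keyed
#'   by source id; required when `backfill = TRUE`.
#' @param backfill Fill undetected cells from the underlying spectrum?
#' @return An object of class `peak_matrix` with fields `values`, `presence`,
#'   `reference_mz`, `sample_ids`.
#' @export
build_peak_matrix <- function(ap, spectra = NULL,
                              backfill = !is.null(spectra)) {
  stopifnot(inherits(ap, "aligned_peaks"))
  nr <- length(ap$source_ids)
  nc <- length(ap$reference_mz)
  values <- matrix(0, nr, nc,
                   dimnames = list(ap$source_ids,
                                   sprintf("%.4f", ap$reference_mz)))
  presence <- matrix(FALSE, nr, nc, dimnames = dimnames(values))
  if (nc > 0L && nrow(ap$peaks) > 0L) {
    ri <- match(ap$peaks$source, ap$source_ids)
    ij <- cbind(ri, ap$peaks$ref)
    values[ij] <- pmax(values[ij], ap$peaks$intensity)
    presence[ij] <- TRUE
  }
  if (backfill && nc > 0L) {
    tol <- ap$tolerance_ppm * 1e-6
    for (i in seq_len(nr)) {
      miss <- which(!presence[i, ])
      if (length(miss) == 0L) next
      s <- spectra[[ap$source_ids[i]]]
      if (is.null(s)) {
        stop("backfill requested but no spectrum supplied for source ",
             ap$source_ids[i], call. = FALSE)
      }
      for (j in miss) {
        ref <- ap$reference_mz[j]
        lo <- findInterval(ref * (1 - tol), s$mz) + 1L
        hi <- findInterval(ref * (1 + tol), s$mz)
        if (hi >= lo) values[i, j] <- max(s$intensity[lo:hi])
      }
    }
  }
  structure(list(values = values, presence = presence,
                 reference_mz = ap$reference_mz,
                 sample_ids = ap$source_ids),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d samples x %d reference peaks\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Average (representative) spectrum of one patient
#'
#' Pointwise mean of the patient's pixel intensities. Spectra sharing a
#' common axis are averaged directly; otherwise each is linearly interpolated
#' onto the patient's first axis (values outside a spectrum's range
#' contribute 0). Run [pick_peaks()] on the result to obtain the patient's
#' peak list.
#'
#' @param ds An [msi_dataset()] of (typically preprocessed) spectra.
#' @param patient_id Patient to average.
#' @return A [mass_spectrum()] with coordinates (0, 0) marking it as a
#'   profile rather than a pixel.
#' @export
average_patient_profile <- function(ds, patient_id) {
  stopifnot(inherits(ds, "msi_dataset"))
  sel <- ds$spectra[spectra_patient_ids(ds) == patient_id]
  if (length(sel) == 0L) {
    stop("no spectra for patient ", patient_id, call. = FALSE)
  }
  axis <- sel[[1L]]$mz
  acc <- numeric(length(axis))
  for (s in sel) {
    acc <- acc + if (identical(s$mz, axis)) {
      s$intensity
    } else {
      stats::approx(s$mz, s$intensity, xout = axis, rule = 1,
                    yleft = 0, yright = 0)$y
    }
  }
  mass_spectrum(axis, acc / length(sel), x = 0L, y = 0L,
                patient_id = patient_id)
}
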