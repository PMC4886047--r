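# Synthetic MSI cohort generator with known ground truth. It emulates the
# statistical structure the analysis pipeline assumes - shared and
# class-discriminative Gaussian peaks on a decaying chemical baseline, with
# multiplicative TIC variation, additive noise, ppm-scale m/z jitter, and
# spatially mixed pixel populations within malignant smears - so every stage
# can be verified end to end without any external data.

#' Specification of a synthetic MSI cohort
#'
#' Defaults mirror the case-versus-control study design the package targets:
#' 14 benign and 18 malignant training patients (the 8 + 10 THY4/THY5 split),
#' with validation cohorts generated separately (see [generate_study()]).
#'
#' @param n_benign,n_malignant Patients per histological class.
#' @param pixels_per_patient Pixel spectra per patient (laid out on a
#'   near-square raster).
#' @param mz_range Acquisition window in Th; default `c(3000, 25000)`.
#' @param mz_step Axis sampling step (Th); 3 Th gives roughly 20 points
#'   across a peak at 10 kTh with the default width.
#' @param n_shared_peaks,n_discriminative_peaks Number of peaks common to
#'   both classes and number carrying class signal.
#' @param effect_size Standardised per-spectrum mean difference on the
#'   discriminative peaks: the class shift in log-amplitude equals
#'   `effect_size * amp_sdlog`. Discriminative peaks alternate direction
#'   (half up, half down in PTC) so total ion current carries no trivial
#'   class signal.
#' @param peak_width_ppm Gaussian peak sigma in ppm of the centre m/z (peak
#'   width grows with m/z, as in linear-TOF data).
#' @param amp_meanlog,amp_sdlog Log-normal peak amplitude distribution
#'   within a patient (pixel-to-pixel variation).
#' @param patient_sdlog Between-patient log-amplitude standard deviation
#'   (per patient and peak). The default (0.6, above the pixel-level 0.4)
#'   reflects the substantial biological and preparation variability of
#'   cytological smears while keeping the meaning of `effect_size`
#'   consistent across levels: a planted per-spectrum effect of `d` standard
#'   deviations yields patient-profile discriminability of comparable order
#'   once pixel averaging and smear mixing are accounted for.
#' @param baseline_amplitude,baseline_decay Exponentially decaying chemical
#'   baseline `amplitude * exp(-(mz - mz_min) / decay)`.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param tic_lognormal_sd Log-normal sigma of the per-spectrum TIC factor.
#' @param mz_jitter_ppm Uniform per-spectrum, per-peak jitter of peak
#'   centres, in ppm.
#' @param malignant_pixel_fraction Fraction of a malignant patient's pixels
#'   that carry the malignant signature; the rest show the benign pattern
#'   (smears are cell mixtures). The malignant pixels form a contiguous
#'   raster block, giving a planted region for pixel-map checks.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_benign = 14L, n_malignant = 18L,
                        pixels_per_patient = 50L,
                        mz_range = c(3000, 25000), mz_step = 3,
                        n_shared_peaks = 30L, n_discriminative_peaks = 10L,
                        effect_size = 3, peak_width_ppm = 1000,
                        amp_meanlog = log(40), amp_sdlog = 0.4,
                        patient_sdlog = 0.6,
                        baseline_amplitude = 30, baseline_decay = 4000,
                        noise_sd = 1, tic_lognormal_sd = 0.3,
                        mz_jitter_ppm = 300,
                        malignant_pixel_fraction = 0.8,
                        seed = 1L) {
  spec <- list(n_benign = as.integer(n_benign),
               n_malignant = as.integer(n_malignant),
               pixels_per_patient = as.integer(pixels_per_patient),
               mz_range = as.numeric(mz_range), mz_step = as.numeric(mz_step),
               n_shared_peaks = as.integer(n_shared_peaks),
               n_discriminative_peaks = as.integer(n_discriminative_peaks),
               effect_size = as.numeric(effect_size),
               peak_width_ppm = as.numeric(peak_width_ppm),
               amp_meanlog = as.numeric(amp_meanlog),
               amp_sdlog = as.numeric(amp_sdlog),
               patient_sdlog = as.numeric(patient_sdlog),
               baseline_amplitude = as.numeric(baseline_amplitude),
               baseline_decay = as.numeric(baseline_decay),
               noise_sd = as.numeric(noise_sd),
               tic_lognormal_sd = as.numeric(tic_lognormal_sd),
               mz_jitter_ppm = as.numeric(mz_jitter_ppm),
               malignant_pixel_fraction = as.numeric(malignant_pixel_fraction),
               seed = as.integer(seed))
  with(spec, {
    if (length(mz_range) != 2L || mz_range[1] >= mz_range[2]) {
      stop("mz_range must be an increasing pair", call. = FALSE)
    }
    if (pixels_per_patient < 1L || n_shared_peaks < 0L ||
        n_discriminative_peaks < 0L) {
      stop("counts must be non-negative (pixels_per_patient >= 1)",
           call. = FALSE)
    }
    if (mz_step <= 0 || peak_width_ppm <= 0 || amp_sdlog <= 0 ||
        patient_sdlog < 0 || baseline_decay <= 0 || noise_sd < 0 ||
        tic_lognormal_sd < 0 || mz_jitter_ppm < 0) {
      stop("scale parameters must be positive", call. = FALSE)
    }
    if (malignant_pixel_fraction < 0 || malignant_pixel_fraction > 1) {
      stop("malignant_pixel_fraction must lie in [0, 1]", call. = FALSE)
    }
  })
  structure(spec, class = "cohort_spec")
}

# Draw the planted peak panel (positions, base amplitudes, which peaks carry
# class signal and in which direction). Consumes the current RNG stream.
# Peak centres keep a generous mutual distance (well beyond the alignment
# tolerance and the local-maximum window) so planted peaks stay resolvable.
.draw_peak_panel <- function(spec) {
  n_peaks <- spec$n_shared_peaks + spec$n_discriminative_peaks
  lo <- spec$mz_range[1] + 1000
  hi <- spec$mz_range[2] - 1000
  centers <- numeric(0)
  attempts <- 0L
  while (length(centers) < n_peaks && attempts < 100000L) {
    attempts <- attempts + 1L
    cand <- stats::runif(1, lo, hi)
    if (length(centers) == 0L ||
        all(abs(cand - centers) >= pmax(300, 0.012 * pmin(cand, centers)))) {
      centers <- c(centers, cand)
    }
  }
  if (length(centers) < n_peaks) {
    stop("could not place ", n_peaks, " separated peaks in the m/z range",
         call. = FALSE)
  }
  centers <- sort(centers)
  base_meanlog <- stats::rnorm(n_peaks, spec$amp_meanlog, 0.5)
  disc <- sort(sample.int(n_peaks, spec$n_discriminative_peaks))
  direction <- numeric(n_peaks)
  direction[disc] <- rep_len(c(1, -1), length(disc))
  effect <- direction * spec$effect_size * spec$amp_sdlog
  list(mz = centers, base_meanlog = base_meanlog,
       discriminative = seq_len(n_peaks) %in% disc,
       effect = effect)
}

.pixel_grid <- function(n) {
  ncol <- ceiling(sqrt(n))
  i <- seq_len(n) - 1L
  data.frame(x = (i %% ncol) + 1L, y = (i %/% ncol) + 1L)
}

.synth_spectrum <- function(axis, panel, meanlog_shift, spec) {
  n_peaks <- length(panel$mz)
  amps <- exp(stats::rnorm(n_peaks, panel$base_meanlog + meanlog_shift,
                           spec$amp_sdlog))
  jitter <- stats::runif(n_peaks, -1, 1) * spec$mz_jitter_ppm * 1e-6
  centers <- panel$mz * (1 + jitter)
  signal <- numeric(length(axis))
  for (j in seq_len(n_peaks)) {
    sigma <- spec$peak_width_ppm * 1e-6 * centers[j]
    lo <- findInterval(centers[j] - 4 * sigma, axis) + 1L
    hi <- findInterval(centers[j] + 4 * sigma, axis)
    if (hi < lo) next
    idx <- lo:hi
    signal[idx] <- signal[idx] +
      amps[j] * exp(-(axis[idx] - centers[j])^2 / (2 * sigma^2))
  }
  baseline <- spec$baseline_amplitude *
    exp(-(axis - spec$mz_range[1]) / spec$baseline_decay)
  noise <- stats::rnorm(length(axis), 0, spec$noise_sd)
  ticf <- stats::rlnorm(1, 0, spec$tic_lognormal_sd)
  pmax(signal + baseline + noise, 0) * ticf
}

#' Generate a synthetic MSI cohort with ground truth
#'
#' Every patient receives `pixels_per_patient` spectra on a shared axis. A
#' pixel spectrum is the sum of Gaussian peaks (shared plus discriminative,
#' amplitudes log-normal around class means separated by `effect_size`), an
#' exponentially decaying baseline and additive Gaussian noise, all scaled
#' by a per-spectrum log-normal TIC factor; peak centres are jittered within
#' `mz_jitter_ppm`. Malignant patients' smears contain a contiguous block of
#' malignant-signature pixels covering `malignant_pixel_fraction` of the
#' raster, the rest showing the benign pattern.
#'
#' @param spec A [cohort_spec()].
#' @param panel Planted peak panel to reuse (so that independently generated
#'   cohorts, e.g. training and validation, share the same molecular
#'   signature); by default a fresh panel is drawn from `spec$seed`.
#' @param cytology `"auto"` assigns THY2 to benign and THY4/THY5
#'   (alternating) to malignant patients; `"THY3"` marks every patient as an
#'   undetermined report, the validation situation.
#' @param prefix Patient-id prefixes for the benign and malignant class.
#' @return A list with elements `dataset` (an [msi_dataset()]), `truth`
#'   (planted peak panel, per-patient classes, per-pixel latent classes) and
#'   `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), panel = NULL,
                            cytology = c("auto", "THY3"),
                            prefix = c("BEN", "MAL")) {
  stopifnot(inherits(spec, "cohort_spec"))
  cytology <- match.arg(cytology)
  set.seed(spec$seed)
  if (is.null(panel)) panel <- .draw_peak_panel(spec)

  axis <- seq(spec$mz_range[1], spec$mz_range[2], by = spec$mz_step)
  n_pat <- spec$n_benign + spec$n_malignant
  classes <- rep(c("Ben", "PTC"), c(spec$n_benign, spec$n_malignant))
  ids <- c(sprintf("%s%02d", prefix[1], seq_len(spec$n_benign)),
           sprintf("%s%02d", prefix[2], seq_len(spec$n_malignant)))
  cyt <- if (cytology == "THY3") {
    rep("THY3", n_pat)
  } else {
    c(rep("THY2", spec$n_benign),
      rep_len(c("THY4", "THY5"), spec$n_malignant))
  }

  grid <- .pixel_grid(spec$pixels_per_patient)
  spectra <- vector("list", n_pat * spec$pixels_per_patient)
  pixel_truth <- vector("list", n_pat)
  si <- 0L
  for (pi in seq_len(n_pat)) {
    patient_shift <- stats::rnorm(length(panel$mz), 0, spec$patient_sdlog)
    latent <- if (classes[pi] == "PTC") {
      n_mal <- round(spec$malignant_pixel_fraction * spec$pixels_per_patient)
      rep(c("PTC", "Ben"),
          c(n_mal, spec$pixels_per_patient - n_mal))
    } else {
      rep("Ben", spec$pixels_per_patient)
    }
    for (px in seq_len(spec$pixels_per_patient)) {
      shift <- patient_shift +
        if (latent[px] == "PTC") panel$effect else 0
      int <- .synth_spectrum(axis, panel, shift, spec)
      si <- si + 1L
      spectra[[si]] <- mass_spectrum(axis, int, x = grid$x[px],
                                     y = grid$y[px], patient_id = ids[pi])
    }
    pixel_truth[[pi]] <- data.frame(patient_id = ids[pi], x = grid$x,
                                    y = grid$y, latent_class = latent,
                                    stringsAsFactors = FALSE)
  }

  metadata <- data.frame(patient_id = ids, cytological_class = cyt,
                         histological_class = classes,
                         stringsAsFactors = FALSE)
  truth <- list(peaks = data.frame(mz = panel$mz,
                                   discriminative = panel$discriminative,
                                   effect = panel$effect),
                panel = panel,
                patients = metadata[, c("patient_id", "histological_class")],
                pixels = do.call(rbind, pixel_truth))
  list(dataset = msi_dataset(spectra, metadata), truth = truth, spec = spec)
}

#' Generate a complete synthetic study (training + validation cohorts)
#'
#' The two cohorts share one planted peak panel. The training cohort follows
#' `spec`; the validation cohort emulates an undetermined (THY3) batch of
#' `n_validation_benign + n_validation_malignant` patients whose
#' histological truth is recorded in the metadata for scoring. Defaults
#' mirror an 8 benign / 3 malignant THY3 batch.
#'
#' @param spec A [cohort_spec()] for the training cohort.
#' @param n_validation_benign,n_validation_malignant Validation cohort
#'   composition.
#' @return List with `train` and `validation` cohorts (each as returned by
#'   [generate_cohort()]).
#' @export
generate_study <- function(spec = cohort_spec(),
                           n_validation_benign = 8L,
                           n_validation_malignant = 3L) {
  train <- generate_cohort(spec)
  vspec <- spec
  vspec$n_benign <- as.integer(n_validation_benign)
  vspec$n_malignant <- as.integer(n_validation_malignant)
  vspec$seed <- spec$seed + 1000L
  validation <- generate_cohort(vspec, panel = train$truth$panel,
                                cytology = "THY3",
                                prefix = c("VAL_B", "VAL_M"))
  list(train = train, validation = validation)
}

#' The in-package worked example: an 11-patient external validation
#'
#' Returns the predicted and true classes of the 11 undetermined (THY3)
#' patients used as the external validation worked example, packaged as a
#' fixture for metric tests and demonstrations: 8 benign and 3 malignant
#' patients, two of whom are benign cases predicted malignant.
#'
#' @return A data frame with columns `sample_id`, `predicted`, `true`.
#' @export
generate_worked_example <- function() {
  path <- system.file("extdata", "worked_example_validation.csv",
                      package = "msiclass", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(df), c("sample_id", "predicted", "true")))
  df
}
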