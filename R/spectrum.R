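#' Construct a single-pixel mass spectrum
#'
#' A `mass_spectrum` holds one pixel's profile-mode spectrum: a strictly
#' increasing m/z axis (Th), the matching intensity trace, the pixel's raster
#' coordinates and the identifier of the patient the pixel belongs to.
#'
#' @param mz Numeric vector of mass-to-charge values (Th). Must be sortable to
#'   a strictly increasing axis; intensities are reordered along with it.
#' @param intensity Numeric vector of intensities, same length as `mz`. All
#'   values must be finite.
#' @param x,y Integer pixel coordinates (1-based raster units).
#' @param patient_id Character scalar naming the patient (opaque identifier).
#'
#' @return An object of class `mass_spectrum`: a list with elements `mz`,
#'   `intensity`, `x`, `y`, `patient_id`.
#' @export
#' @examples
#' s <- mass_spectrum(c(3000, 3001, 3002), c(0, 5, 1), x = 1, y = 1,
#'                    patient_id = "P01")
#' total_ion_current(s)
mass_spectrum <- function(mz, intensity, x = 1L, y = 1L,
                          patient_id = NA_character_) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("`mz` and `intensity` must have the same length (",
         length(mz), " vs ", length(intensity), ")", call. = FALSE)
  }
  if (length(mz) < 2L) {
    stop("a mass spectrum needs at least two points", call. = FALSE)
  }
  if (any(!is.finite(mz))) stop("m/z values must be finite", call. = FALSE)
  if (any(!is.finite(intensity))) {
    stop("intensity values must be finite", call. = FALSE)
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      stop("m/z axis contains duplicated values and cannot be sorted into ",
           "a strictly increasing axis", call. = FALSE)
    }
  }
  structure(
    list(mz = mz, intensity = intensity, x = as.integer(x), y = as.integer(y),
         patient_id = as.character(patient_id)),
    class = "mass_spectrum"
  )
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf(
    "<mass_spectrum> %d points, m/z %.1f-%.1f, pixel (%d, %d), patient %s\n",
    length(x$mz), min(x$mz), max(x$mz), x$x, x$y, x$patient_id))
  invisible(x)
}

#' Total ion current of a spectrum
#'
#' @param s A [mass_spectrum()].
#' @return The sum of all intensities.
#' @export
total_ion_current <- function(s) {
  stopifnot(inherits(s, "mass_spectrum"))
  sum(s$intensity)
}

#' Assemble an MSI dataset from spectra and patient metadata
#'
#' An `msi_dataset` couples an ordered collection of pixel spectra with the
#' per-patient metadata table (cytological category THY1-THY5 and, where
#' available, the histological truth Ben/PTC).
#'
#' @param spectra List of [mass_spectrum()] objects.
#' @param metadata Data frame with columns `patient_id`, `cytological_class`
#'   and `histological_class`, one row per patient. When `NULL` a stub table
#'   with `NA` classes is derived from the spectra.
#'
#' @return An object of class `msi_dataset` with elements `spectra` and
#'   `metadata`.
#' @export
msi_dataset <- function(spectra, metadata = NULL) {
  if (!is.list(spectra) || length(spectra) == 0L ||
      !all(vapply(spectra, inherits, logical(1), "mass_spectrum"))) {
    stop("`spectra` must be a non-empty list of mass_spectrum objects",
         call. = FALSE)
  }
  pid <- vapply(spectra, `[[`, character(1), "patient_id")
  if (is.null(metadata)) {
    metadata <- data.frame(patient_id = unique(pid),
                           cytological_class = NA_character_,
                           histological_class = NA_character_,
                           stringsAsFactors = FALSE)
  }
  metadata <- validate_metadata(metadata, allow_na = TRUE)
  missing <- setdiff(unique(pid), metadata$patient_id)
  if (length(missing) > 0L) {
    stop("spectra reference patients absent from the metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- paste(pid,
               vapply(spectra, `[[`, integer(1), "x"),
               vapply(spectra, `[[`, integer(1), "y"), sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (patient_id, x, y) pixel coordinates in the dataset",
         call. = FALSE)
  }
  structure(list(spectra = spectra, metadata = metadata),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d spectra from %d patients\n",
              length(x$spectra), nrow(x$metadata)))
  invisible(x)
}

#' Patient identifiers of every spectrum in a dataset
#' @param ds An [msi_dataset()].
#' @return Character vector, one entry per spectrum.
#' @export
spectra_patient_ids <- function(ds) {
  stopifnot(inherits(ds, "msi_dataset"))
  vapply(ds$spectra, `[[`, character(1), "patient_id")
}

#' Subset an MSI dataset to one patient
#' @param ds An [msi_dataset()].
#' @param patient_id Patient to keep.
#' @return An `msi_dataset` containing only that patient's spectra.
#' @export
subset_patient <- function(ds, patient_id) {
  keep <- spectra_patient_ids(ds) == patient_id
  if (!any(keep)) {
    stop("no spectra for patient ", patient_id, call. = FALSE)
  }
  msi_dataset(ds$spectra[keep],
              ds$metadata[ds$metadata$patient_id == patient_id, ,
                          drop = FALSE])
}

#' Combine MSI datasets
#' @param ... `msi_dataset` objects.
#' @return A single `msi_dataset` with concatenated spectra and the union of
#'   the metadata tables.
#' @export
combine_datasets <- function(...) {
  dss <- list(...)
  stopifnot(all(vapply(dss, inherits, logical(1), "msi_dataset")))
  spectra <- do.call(c, lapply(dss, `[[`, "spectra"))
  metadata <- unique(do.call(rbind, lapply(dss, `[[`, "metadata")))
  if (anyDuplicated(metadata$patient_id)) {
    stop("conflicting metadata for the same patient across datasets",
         call. = FALSE)
  }
  msi_dataset(spectra, metadata)
}

.CYTOLOGICAL_CLASSES <- paste0("THY", 1:5)
.HISTOLOGICAL_CLASSES <- c("Ben", "PTC")

#' Validate a patient metadata table
#'
#' Checks column presence, the SIAPEC cytological vocabulary (THY1-THY5) and
#' the histological vocabulary (Ben/PTC), and uniqueness of patient ids.
#'
#' @param metadata Data frame to validate.
#' @param allow_na Accept `NA` class entries (used for datasets whose truth is
#'   withheld, e.g. an unlabelled validation batch)?
#' @return The validated data frame (character columns, row names dropped).
#' @export
validate_metadata <- function(metadata, allow_na = FALSE) {
  required <- c("patient_id", "cytological_class", "histological_class")
  missing <- setdiff(required, names(metadata))
  if (length(missing) > 0L) {
    stop("metadata is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(metadata) == 0L) {
    stop("metadata table is empty", call. = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  for (col in required) metadata[[col]] <- as.character(metadata[[col]])
  if (anyDuplicated(metadata$patient_id)) {
    stop("duplicated patient_id in metadata", call. = FALSE)
  }
  bad_cyt <- !(metadata$cytological_class %in% .CYTOLOGICAL_CLASSES)
  bad_his <- !(metadata$histological_class %in% .HISTOLOGICAL_CLASSES)
  if (allow_na) {
    bad_cyt <- bad_cyt & !is.na(metadata$cytological_class)
    bad_his <- bad_his & !is.na(metadata$histological_class)
  }
  if (any(bad_cyt) || any(bad_his)) {
    rows <- sort(unique(c(which(bad_cyt), which(bad_his))))
    stop("metadata contains unknown class tokens in rows ",
         paste(rows, collapse = ", "),
         " (cytological classes must be THY1-THY5, histological Ben/PTC)",
         call. = FALSE)
  }
  rownames(metadata) <- NULL
  metadata
}

#' Binary training labels from patient metadata
#'
#' Uses the histological truth where available, and otherwise collapses the
#' cytological category: THY2 is taken as benign, THY4 and THY5 as malignant
#' (the case-versus-control framing used to assemble a training set). THY1 and
#' THY3 patients cannot be labelled this way.
#'
#' @param metadata Validated metadata table.
#' @return Named character vector of "Ben"/"PTC", named by patient id.
#' @export
training_labels <- function(metadata) {
  metadata <- validate_metadata(metadata, allow_na = TRUE)
  lab <- metadata$histological_class
  need <- is.na(lab)
  if (any(need)) {
    cyt <- metadata$cytological_class[need]
    mapped <- ifelse(cyt == "THY2", "Ben",
                     ifelse(cyt %in% c("THY4", "THY5"), "PTC", NA))
    if (anyNA(mapped)) {
      stop("cannot derive a training label for patients ",
           paste(metadata$patient_id[need][is.na(mapped)], collapse = ", "),
           ": no histology and cytology is not THY2/THY4/THY5",
           call. = FALSE)
    }
    lab[need] <- mapped
  }
  stats::setNames(lab, metadata$patient_id)
}
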