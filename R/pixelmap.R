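# Pixel-by-pixel classification of an MSI dataset with a trained model, and
# rendering of the resulting class map.

.MAP_COLORS <- list(Ben = c(0, 1, 0), PTC = c(1, 0, 0),
                    unclassified = c(0.5, 0.5, 0.5))

#' Align a peak list to a model's feature set
#'
#' For each of the model's selected reference m/z values the feature vector
#' receives the intensity of the nearest input peak within the model's ppm
#' tolerance window (ties broken towards the higher intensity), and 0 where
#' no peak falls inside the window.
#'
#' @param pl A [peak_list()].
#' @param clf A [train_svm()] classifier whose provenance carries
#'   `tolerance_ppm`.
#' @return Named numeric feature vector of length `length(clf$selected_mz)`.
#' @export
align_to_model <- function(pl, clf) {
  stopifnot(inherits(pl, "peak_list"), inherits(clf, "trained_classifier"))
  tol <- clf$provenance$tolerance_ppm
  if (is.null(tol)) {
    stop("classifier has no alignment tolerance in its provenance",
         call. = FALSE)
  }
  sel <- clf$selected_mz
  v <- numeric(length(sel))
  if (length(pl$mz) > 0L) {
    for (j in seq_along(sel)) {
      d <- abs(pl$mz - sel[j])
      win <- tol * 1e-6 * sel[j]
      ok <- which(d <= win)
      if (length(ok) > 0L) {
        best <- ok[order(d[ok], -pl$intensity[ok])][1L]
        v[j] <- pl$intensity[best]
      }
    }
  }
  stats::setNames(v, clf$feature_names)
}

# Replace zero (undetected) entries of a model feature vector by the
# spectrum's maximum intensity inside the tolerance window, mirroring the
# backfill used when the training matrix was built. Scoring backfilled
# training features against zero-filled new features would shift every new
# sample systematically toward low intensities.
.backfill_features <- function(v, s, reference_mz, tolerance_ppm) {
  tol <- tolerance_ppm * 1e-6
  for (j in which(v == 0)) {
    ref <- reference_mz[j]
    lo <- findInterval(ref * (1 - tol), s$mz) + 1L
    hi <- findInterval(ref * (1 + tol), s$mz)
    if (hi >= lo) v[j] <- max(s$intensity[lo:hi])
  }
  v
}

#' Classify every pixel of an MSI dataset
#'
#' Each pixel's raw spectrum is preprocessed exactly as the training data
#' (using the configurations stored in the classifier's provenance) and its
#' peaks are picked. Before classification, a dataset-wide presence filter at
#' the training `min_presence` is applied across the unknown file's pixels to
#' discard false-positive peaks, and each pixel's surviving peaks are aligned
#' to the model's features. Pixels whose total ion current is degenerate are
#' labelled `unclassified`; pixels with an empty feature vector are still
#' classified (the decision function is defined at the origin, and dropping
#' them would bias area fractions).
#'
#' @param ds A raw [msi_dataset()].
#' @param clf A classifier with full provenance (from [run_training()]).
#' @param min_presence Presence-filter fraction; default the training value
#'   stored in the provenance.
#' @return An object of class `class_map`: a data frame of
#'   `(x, y, patient_id, label, decision)` with class fractions and raster
#'   extents as attributes.
#' @export
classify_pixels <- function(ds, clf, min_presence = NULL) {
  stopifnot(inherits(ds, "msi_dataset"), inherits(clf, "trained_classifier"))
  prov <- clf$provenance
  if (is.null(prov)) {
    stop("classifier has no provenance; train it through run_training()",
         call. = FALSE)
  }
  min_presence <- min_presence %||% prov$min_presence %||% 0.25
  pre_cfg <- prov$preprocess %||% preprocess_config()
  pk_cfg <- prov$peaks %||% peak_pick_config()

  n <- length(ds$spectra)
  status <- character(n)
  lists <- vector("list", n)
  pre <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch(preprocess_spectrum(ds$spectra[[i]], pre_cfg),
                    msiclass_degenerate_spectrum = function(e) e)
    if (inherits(res, "condition")) {
      status[i] <- "degenerate"
    } else {
      status[i] <- "ok"
      pre[[i]] <- res
      lists[[i]] <- pick_peaks(res, pk_cfg)
    }
  }

  ok <- which(status == "ok")
  features <- matrix(0, n, length(clf$feature_names),
                     dimnames = list(NULL, clf$feature_names))
  if (length(ok) > 0L) {
    ap <- align_peaks(lists[ok], prov$tolerance_ppm %||% 2000)
    ap <- filter_peaks(ap, min_presence)
    # surviving peaks per pixel, at their aligned reference m/z
    by_source <- split(ap$peaks, ap$peaks$source)
    for (i in ok) {
      sid <- lists[[i]]$source_id
      pk <- by_source[[sid]]
      pl <- if (is.null(pk)) {
        peak_list(sid)
      } else {
        refs <- ap$reference_mz[pk$ref]
        o <- order(refs)
        peak_list(sid, refs[o], pk$intensity[o])
      }
      features[i, ] <- .backfill_features(align_to_model(pl, clf), pre[[i]],
                                          clf$selected_mz,
                                          prov$tolerance_ppm %||% 2000)
    }
    pred <- predict(clf, features[ok, , drop = FALSE])
  }

  label <- rep("unclassified", n)
  decision <- rep(NA_real_, n)
  if (length(ok) > 0L) {
    label[ok] <- pred$label
    decision[ok] <- pred$decision
  }
  map <- data.frame(
    x = vapply(ds$spectra, `[[`, integer(1), "x"),
    y = vapply(ds$spectra, `[[`, integer(1), "y"),
    patient_id = spectra_patient_ids(ds),
    label = label, decision = decision,
    stringsAsFactors = FALSE)
  fractions <- c(Ben = mean(label == "Ben"),
                 PTC = mean(label == "PTC"),
                 unclassified = mean(label == "unclassified"))
  structure(map, class = c("class_map", "data.frame"),
            fractions = fractions,
            extent = c(xmin = min(map$x), xmax = max(map$x),
                       ymin = min(map$y), ymax = max(map$y)))
}

#' Class fractions of a class map
#' @param cm A [classify_pixels()] result.
#' @return Named vector of the benign, malignant and unclassified fractions
#'   (summing to 1).
#' @export
class_fractions <- function(cm) {
  stopifnot(inherits(cm, "class_map"))
  attr(cm, "fractions")
}

#' Render a class map as a PNG image
#'
#' Green pixels are benign, red malignant, grey unclassified; raster
#' positions without a spectrum are transparent. A sidecar JSON
#' (`<path>.json`) records the legend, the class fractions and the raster
#' extent.
#'
#' @param cm A [classify_pixels()] result.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
render_map <- function(cm, path) {
  stopifnot(inherits(cm, "class_map"), nrow(cm) > 0L)
  ext <- attr(cm, "extent")
  w <- ext[["xmax"]] - ext[["xmin"]] + 1L
  h <- ext[["ymax"]] - ext[["ymin"]] + 1L
  img <- array(0, dim = c(h, w, 4L))
  for (i in seq_len(nrow(cm))) {
    row <- cm$y[i] - ext[["ymin"]] + 1L
    col <- cm$x[i] - ext[["xmin"]] + 1L
    img[row, col, 1:3] <- .MAP_COLORS[[cm$label[i]]]
    img[row, col, 4L] <- 1
  }
  png::writePNG(img, path)
  legend <- lapply(.MAP_COLORS, function(rgbv) {
    grDevices::rgb(rgbv[1], rgbv[2], rgbv[3])
  })
  jsonlite::write_json(
    list(legend = legend,
         fractions = as.list(attr(cm, "fractions")),
         extent = as.list(ext),
         n_pixels = nrow(cm)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
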