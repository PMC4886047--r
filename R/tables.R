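# Tabular artifacts: metadata, peak matrices, predictions. Plain CSV
# throughout so every artifact stays diffable and tool-agnostic.

#' Read a patient metadata table
#'
#' Expects a delimited table with columns `patient_id`, `cytological_class`
#' (THY1-THY5) and `histological_class` (Ben/PTC). Unknown class tokens are a
#' validation error listing the offending rows.
#'
#' @param path CSV file path.
#' @param allow_na Accept `NA` entries in the class columns (for cohorts whose
#'   truth is withheld)?
#' @return A validated data frame.
#' @export
read_metadata <- function(path, allow_na = FALSE) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(md, allow_na = allow_na)
}

#' Write a patient metadata table
#' @param metadata Data frame to write (validated first).
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_metadata <- function(metadata, path) {
  metadata <- validate_metadata(metadata, allow_na = TRUE)
  utils::write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' Write a peak matrix to CSV
#'
#' Columns are the aligned reference m/z values at fixed 4-decimal precision;
#' the first column holds the sample identifiers. The detection mask is
#' written alongside as `<path>.presence.csv` so the matrix round-trips.
#'
#' @param pm A `peak_matrix` (see [build_peak_matrix()]).
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_peak_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "peak_matrix"))
  df <- data.frame(sample_id = pm$sample_ids, pm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  dfp <- data.frame(sample_id = pm$sample_ids, pm$presence,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(dfp, paste0(path, ".presence.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a peak matrix written by [write_peak_matrix()]
#' @param path CSV path.
#' @return A `peak_matrix`.
#' @export
read_peak_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  ppath <- paste0(path, ".presence.csv")
  presence <- if (file.exists(ppath)) {
    dp <- utils::read.csv(ppath, check.names = FALSE)
    pm <- as.matrix(dp[, -1, drop = FALSE]) > 0
    rownames(pm) <- dp$sample_id
    pm
  } else {
    values > 0
  }
  structure(list(values = values, presence = presence,
                 reference_mz = as.numeric(colnames(values)),
                 sample_ids = df$sample_id),
            class = "peak_matrix")
}

#' Write per-sample predictions to CSV
#'
#' @param predictions Data frame with at least `sample_id`, `predicted` and
#'   optionally `true` and `decision` columns.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}
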