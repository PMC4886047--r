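# imzML 1.1 input/output.
#
# imzML stores the mzML-style metadata in an XML file and the numeric arrays
# in a companion binary ".ibd" file addressed by byte offsets. Continuous
# mode shares one m/z axis across all pixels (stored once); processed mode
# stores a private m/z axis per pixel. Only uncompressed 32/64-bit IEEE
# floats are supported; anything else is rejected loudly.

.IMZML_ACC <- list(
  continuous = "IMS:1000030",
  processed = "IMS:1000031",
  uuid = "IMS:1000080",
  pos_x = "IMS:1000050",
  pos_y = "IMS:1000051",
  ext_offset = "IMS:1000102",
  ext_len = "IMS:1000103",
  ext_enc_len = "IMS:1000104",
  mz_array = "MS:1000514",
  int_array = "MS:1000515",
  f32 = "MS:1000521",
  f64 = "MS:1000523"
)

.ibd_path <- function(path) {
  cand <- c(sub("\\.imzML$", ".ibd", path, ignore.case = TRUE),
            paste0(path, ".ibd"))
  hit <- cand[file.exists(cand)]
  if (length(hit) > 0L) hit[1L] else cand[1L]
}

.format_uuid <- function(hex32) {
  paste(substr(hex32, 1, 8), substr(hex32, 9, 12), substr(hex32, 13, 16),
        substr(hex32, 17, 20), substr(hex32, 21, 32), sep = "-")
}

#' Write an MSI dataset to an imzML file pair
#'
#' Writes `path` (XML) plus the companion `.ibd` binary. Continuous mode is
#' used when every spectrum shares one identical m/z axis, processed mode
#' otherwise. Both arrays are stored as uncompressed little-endian 64-bit
#' floats, so a write/read cycle is the identity on m/z, intensities and
#' coordinates. The ibd UUID is derived from an md5 of the array payload, so
#' writing is fully deterministic and consumes no random numbers.
#'
#' Patient identity is not representable in imzML; the convention used
#' throughout this package is one file per patient with a sidecar metadata
#' table (see [write_msi_cohort()]).
#'
#' @param dataset An [msi_dataset()] or a list of [mass_spectrum()] objects.
#' @param path Output path, conventionally ending in `.imzML`.
#' @return Invisibly, the path written.
#' @export
write_imzml <- function(dataset, path) {
  spectra <- if (inherits(dataset, "msi_dataset")) dataset$spectra else dataset
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("cannot write an empty dataset", call. = FALSE)
  }
  stopifnot(all(vapply(spectra, inherits, logical(1), "mass_spectrum")))
  ibd <- .ibd_path(path)

  axis0 <- spectra[[1L]]$mz
  continuous <- all(vapply(spectra, function(s) identical(s$mz, axis0),
                           logical(1)))

  # serialise payload first (offsets are known up front: uuid block is 16
  # bytes); uuid = md5 of the payload for a deterministic file
  payload <- tempfile(fileext = ".bin")
  con <- file(payload, "wb")
  offsets <- vector("list", length(spectra))
  pos <- 16L
  put <- function(v) {
    writeBin(as.double(v), con, size = 8L, endian = "little")
    start <- pos
    pos <<- pos + 8L * length(v)
    c(offset = start, len = length(v), enc = 8L * length(v))
  }
  if (continuous) {
    mz_ref <- put(axis0)
    for (i in seq_along(spectra)) {
      offsets[[i]] <- list(mz = mz_ref, int = put(spectra[[i]]$intensity))
    }
  } else {
    for (i in seq_along(spectra)) {
      offsets[[i]] <- list(mz = put(spectra[[i]]$mz),
                           int = put(spectra[[i]]$intensity))
    }
  }
  close(con)

  uuid_hex <- unname(tools::md5sum(payload))
  con <- file(ibd, "wb")
  writeBin(as.raw(strtoi(substring(uuid_hex, seq(1, 31, 2), seq(2, 32, 2)),
                         16L)), con)
  pcon <- file(payload, "rb")
  repeat {
    chunk <- readBin(pcon, "raw", n = 1048576L)
    if (length(chunk) == 0L) break
    writeBin(chunk, con)
  }
  close(pcon)
  close(con)
  unlink(payload)

  xs <- vapply(spectra, `[[`, integer(1), "x")
  ys <- vapply(spectra, `[[`, integer(1), "y")
  mode_acc <- if (continuous) .IMZML_ACC$continuous else .IMZML_ACC$processed
  mode_name <- if (continuous) "continuous" else "processed"

  spec_xml <- vapply(seq_along(spectra), function(i) {
    o <- offsets[[i]]
    sprintf(paste0(
      '      <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n',
      '        <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>\n',
      '        <scanList count="1">\n',
      '          <cvParam cvRef="MS" accession="MS:1000795" name="no combination"/>\n',
      '          <scan>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
      '          </scan>\n',
      '        </scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="mzArray"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="intensityArray"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n',
      '      </spectrum>'),
      i - 1L, i, length(spectra[[i]]$intensity), xs[i], ys[i],
      o$mz[["len"]], o$mz[["enc"]], o$mz[["offset"]],
      o$int[["len"]], o$int[["enc"]], o$int[["offset"]])
  }, character(1))

  xml <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '  <cvList count="3">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>\n',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription>\n',
    '    <fileContent>\n',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>\n',
    '      <cvParam cvRef="IMS" accession="%s" name="%s"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n',
    '    </fileContent>\n',
    '  </fileDescription>\n',
    '  <referenceableParamGroupList count="2">\n',
    '    <referenceableParamGroup id="mzArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '    <referenceableParamGroup id="intensityArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '  </referenceableParamGroupList>\n',
    '  <softwareList count="1">\n',
    '    <software id="msiclass" version="0.1.0"/>\n',
    '  </softwareList>\n',
    '  <scanSettingsList count="1">\n',
    '    <scanSettings id="scansettings1">\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n',
    '    </scanSettings>\n',
    '  </scanSettingsList>\n',
    '  <instrumentConfigurationList count="1">\n',
    '    <instrumentConfiguration id="IC1"/>\n',
    '  </instrumentConfigurationList>\n',
    '  <dataProcessingList count="1">\n',
    '    <dataProcessing id="export">\n',
    '      <processingMethod order="1" softwareRef="msiclass">\n',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>\n',
    '      </processingMethod>\n',
    '    </dataProcessing>\n',
    '  </dataProcessingList>\n',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '    <spectrumList count="%d" defaultDataProcessingRef="export">\n',
    '%s\n',
    '    </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n'),
    mode_acc, mode_name, .format_uuid(uuid_hex), max(xs), max(ys),
    length(spectra), paste(spec_xml, collapse = "\n"))

  writeLines(xml, path, sep = "")
  invisible(path)
}

.cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) NA_character_ else xml2::xml_attr(p, "value")
}

.has_cv <- function(node, accession) {
  !inherits(xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession)), "xml_missing")
}

#' Read an imzML file pair into an MSI dataset
#'
#' Supports both continuous and processed dialects; in processed mode each
#' pixel keeps its private m/z axis (no resampling is performed at I/O time).
#' Arrays may be 32- or 64-bit uncompressed floats. Spectra are returned
#' sorted by (y, x), with each m/z axis sorted ascending if the file stored
#' it unsorted.
#'
#' @param path Path to the `.imzML` XML file; the companion `.ibd` must sit
#'   next to it.
#' @param patient_id Patient identifier to stamp on every spectrum; defaults
#'   to the file's base name (the one-file-per-patient convention).
#' @param metadata Optional per-patient metadata table to attach.
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path, patient_id = NULL, metadata = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ibd <- .ibd_path(path)
  if (!file.exists(ibd)) {
    stop("missing companion binary file: expected ", ibd, " next to ", path,
         call. = FALSE)
  }
  if (is.null(patient_id)) {
    patient_id <- sub("\\.imzML$", "", basename(path), ignore.case = TRUE)
  }

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  # byte width per referenceable param group, and which group is m/z
  groups <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  group_size <- list()
  group_kind <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    size <- if (.has_cv(g, .IMZML_ACC$f64)) 8L
            else if (.has_cv(g, .IMZML_ACC$f32)) 4L
            else NA_integer_
    kind <- if (.has_cv(g, .IMZML_ACC$mz_array)) "mz"
            else if (.has_cv(g, .IMZML_ACC$int_array)) "intensity"
            else NA_character_
    group_size[[id]] <- size
    group_kind[[id]] <- kind
  }

  spec_nodes <- xml2::xml_find_all(doc, "//run//spectrum")
  if (length(spec_nodes) == 0L) {
    stop("no spectra found in ", path, call. = FALSE)
  }

  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  read_array <- function(offset, n, size) {
    seek(con, where = offset, origin = "start")
    readBin(con, "double", n = n, size = size, endian = "little")
  }

  spectra <- lapply(spec_nodes, function(sn) {
    scan <- xml2::xml_find_first(sn, ".//scan")
    x <- as.integer(.cv_value(scan, .IMZML_ACC$pos_x))
    y <- as.integer(.cv_value(scan, .IMZML_ACC$pos_y))
    arrays <- list()
    for (bda in xml2::xml_find_all(sn, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "referenceableParamGroupRef"), "ref")
      kind <- group_kind[[ref]] %||% NA_character_
      size <- group_size[[ref]] %||% NA_integer_
      # allow inline (non-group) declarations as a fallback
      if (is.na(kind)) {
        kind <- if (.has_cv(bda, .IMZML_ACC$mz_array)) "mz"
                else if (.has_cv(bda, .IMZML_ACC$int_array)) "intensity"
                else NA_character_
      }
      if (is.na(size)) {
        size <- if (.has_cv(bda, .IMZML_ACC$f64)) 8L
                else if (.has_cv(bda, .IMZML_ACC$f32)) 4L
                else NA_integer_
      }
      if (is.na(kind)) next
      if (is.na(size)) {
        stop("unsupported binary encoding in ", path,
             " (only 32- and 64-bit floats are supported)", call. = FALSE)
      }
      offset <- as.numeric(.cv_value(bda, .IMZML_ACC$ext_offset))
      n <- as.integer(.cv_value(bda, .IMZML_ACC$ext_len))
      if (is.na(offset) || is.na(n)) {
        stop("binary array without external offset/length in ", path,
             call. = FALSE)
      }
      arrays[[kind]] <- read_array(offset, n, size)
    }
    if (is.null(arrays$mz) || is.null(arrays$intensity)) {
      stop("spectrum without both m/z and intensity arrays in ", path,
           call. = FALSE)
    }
    mass_spectrum(arrays$mz, arrays$intensity, x = x, y = y,
                  patient_id = patient_id)
  })

  ord <- order(vapply(spectra, `[[`, integer(1), "y"),
               vapply(spectra, `[[`, integer(1), "x"))
  msi_dataset(spectra[ord], metadata)
}

#' Write a multi-patient cohort as per-patient imzML files plus metadata
#'
#' @param dataset An [msi_dataset()].
#' @param dir Output directory (created if needed). One
#'   `<patient_id>.imzML`/`.ibd` pair per patient plus `metadata.csv`.
#' @return Invisibly, the directory.
#' @export
write_msi_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "msi_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pid <- spectra_patient_ids(dataset)
  for (p in unique(pid)) {
    write_imzml(dataset$spectra[pid == p],
                file.path(dir, paste0(p, ".imzML")))
  }
  write_metadata(dataset$metadata, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_msi_cohort()]
#'
#' @param dir Directory holding `<patient>.imzML` files and `metadata.csv`.
#' @return An [msi_dataset()] covering every patient listed in the metadata.
#' @export
read_msi_cohort <- function(dir) {
  md <- read_metadata(file.path(dir, "metadata.csv"))
  dss <- lapply(md$patient_id, function(p) {
    read_imzml(file.path(dir, paste0(p, ".imzML")), patient_id = p,
               metadata = md[md$patient_id == p, , drop = FALSE])
  })
  do.call(combine_datasets, dss)
}
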