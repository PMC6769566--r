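#' @title imzML input/output
#' @description Minimal but standard-conformant reading and writing of
#'   imzML 1.1 mass spectrometry imaging files (paired `.imzML` XML and
#'   `.ibd` binary). Both storage modes are supported: `"continuous"` (one
#'   shared m/z axis, stored once) and `"processed"` (per-pixel axes).
#'   m/z values are stored as 64-bit floats and intensities as 32-bit
#'   floats, without compression.
#' @name imzml_io
NULL

ibd_path_for <- function(path) {
  paste0(sub("\\.[iI][mM][zZ][mM][lL]$", "", path), ".ibd")
}

# Deterministic pseudo-UUID derived from dataset content, so that identical
# datasets produce byte-identical files (full-pipeline reproducibility).
content_uuid <- function(dataset) {
  tot <- vapply(dataset$spectra, function(s) sum(s$intensity), numeric(1))
  bytes <- as.integer(writeBin(c(as.double(length(dataset$spectra)),
                                 as.double(length(dataset$spectra[[1]]$mz)),
                                 sum(tot), tot[1]),
                               raw(), size = 8))
  acc <- integer(16)
  h <- 5381L
  for (i in seq_along(bytes)) {
    h <- (h * 33L + bytes[i]) %% 16777216L
    j <- (i - 1L) %% 16L + 1L
    acc[j] <- bitwXor(acc[j], h %% 256L)
  }
  paste(sprintf("%02x", acc), collapse = "")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write an MSI dataset as imzML
#'
#' @param dataset An [msi_dataset].
#' @param path Output `.imzML` path; the binary companion is written next to
#'   it with extension `.ibd`.
#' @param mode `"continuous"` (requires a shared m/z axis across pixels) or
#'   `"processed"`; defaults to the dataset's own mode.
#' @return `path`, invisibly.
#' @details Specimen metadata (specimen id, patient id, cytology class,
#'   origin) is carried in `userParam` elements of the file description, so
#'   that [read_imzml()] round-trips it. Intensities are written as 32-bit
#'   floats; round-trips preserve them to float32 precision.
#' @export
write_imzml <- function(dataset, path, mode = dataset$mode) {
  stopifnot(inherits(dataset, "msi_dataset"))
  mode <- match.arg(mode, c("continuous", "processed"))
  spectra <- dataset$spectra
  if (length(spectra) == 0L) stop("empty dataset")
  if (mode == "continuous") {
    ax <- spectra[[1]]$mz
    same <- vapply(spectra, function(s) {
      length(s$mz) == length(ax) && all(s$mz == ax)
    }, logical(1))
    if (!all(same)) {
      stop("continuous mode requires a shared m/z axis; use mode = \"processed\"")
    }
  }
  uuid <- content_uuid(dataset)
  ibd <- ibd_path_for(path)
  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(strtoi(substring(uuid, seq(1, 31, 2), seq(2, 32, 2)),
                         base = 16L)), con)
  offset <- 16
  n <- length(spectra)
  mz_off <- numeric(n); mz_len <- integer(n)
  int_off <- numeric(n); int_len <- integer(n)
  if (mode == "continuous") {
    ax <- spectra[[1]]$mz
    writeBin(ax, con, size = 8, endian = "little")
    mz_off[] <- offset; mz_len[] <- length(ax)
    offset <- offset + 8 * length(ax)
    for (i in seq_len(n)) {
      writeBin(as.double(spectra[[i]]$intensity), con, size = 4,
               endian = "little")
      int_off[i] <- offset; int_len[i] <- length(spectra[[i]]$intensity)
      offset <- offset + 4 * int_len[i]
    }
  } else {
    for (i in seq_len(n)) {
      writeBin(spectra[[i]]$mz, con, size = 8, endian = "little")
      mz_off[i] <- offset; mz_len[i] <- length(spectra[[i]]$mz)
      offset <- offset + 8 * mz_len[i]
      writeBin(as.double(spectra[[i]]$intensity), con, size = 4,
               endian = "little")
      int_off[i] <- offset; int_len[i] <- length(spectra[[i]]$intensity)
      offset <- offset + 4 * int_len[i]
    }
  }

  xs <- vapply(spectra, function(s) s$x, integer(1))
  ys <- vapply(spectra, function(s) s$y, integer(1))
  mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '  <cvList count="3">',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '  </cvList>',
    '  <fileDescription>',
    '    <fileContent>',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>',
    sprintf('      <cvParam cvRef="IMS" accession="%s" name="%s"/>',
            mode_acc, mode),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>',
            uuid),
    sprintf('      <userParam name="specimen_id" value="%s"/>',
            xml_escape(dataset$specimen_id)),
    sprintf('      <userParam name="patient_id" value="%s"/>',
            xml_escape(dataset$patient_id)),
    sprintf('      <userParam name="cytology_class" value="%s"/>',
            dataset$cytology_class),
    sprintf('      <userParam name="origin" value="%s"/>', dataset$origin),
    '    </fileContent>',
    '  </fileDescription>',
    '  <referenceableParamGroupList count="2">',
    '    <referenceableParamGroup id="mzArray">',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '    <referenceableParamGroup id="intensityArray">',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '  </referenceableParamGroupList>',
    '  <softwareList count="1">',
    '    <software id="msiTriage" version="0.1.0">',
    '      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="msiTriage"/>',
    '    </software>',
    '  </softwareList>',
    '  <scanSettingsList count="1">',
    '    <scanSettings id="scanSettings1">',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', max(xs)),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', max(ys)),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>', dataset$pixel_size_um),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g" unitCvRef="UO" unitAccession="UO:0000017" unitName="micrometer"/>', dataset$pixel_size_um),
    '    </scanSettings>',
    '  </scanSettingsList>',
    '  <instrumentConfigurationList count="1">',
    '    <instrumentConfiguration id="IC1"/>',
    '  </instrumentConfigurationList>',
    '  <dataProcessingList count="1">',
    '    <dataProcessing id="export">',
    '      <processingMethod order="1" softwareRef="msiTriage">',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '      </processingMethod>',
    '    </dataProcessing>',
    '  </dataProcessingList>',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="export">', n)
  )
  spec_xml <- vapply(seq_len(n), function(i) {
    paste0(
      sprintf('      <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">\n',
              i, i - 1L, int_len[i]),
      '        <scanList count="1">\n',
      '          <scan>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n', xs[i]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n', ys[i]),
      '          </scan>\n',
      '        </scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="mzArray"/>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', mz_len[i]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n', 8 * mz_len[i]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n', mz_off[i]),
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="intensityArray"/>\n',
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', int_len[i]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n', 4 * int_len[i]),
      sprintf('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n', int_off[i]),
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n',
      '      </spectrum>')
  }, character(1))
  tail <- c('    </spectrumList>', '  </run>', '</mzML>')
  writeLines(c(head, spec_xml, tail), path)
  invisible(path)
}

cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

#' Read an imzML MSI dataset
#'
#' Parses a paired `.imzML`/`.ibd` file (continuous or processed mode) into
#' an [msi_dataset]. Any pixel whose m/z axis is stored unsorted is sorted,
#' with intensities permuted consistently.
#'
#' @param path Path to the `.imzML` XML file; the `.ibd` binary is expected
#'   next to it.
#' @param specimen_id,patient_id,cytology_class,origin Optional metadata
#'   overrides; defaults come from the file's `userParam` entries when
#'   present (as written by [write_imzml()]), else from the file name.
#' @return An [msi_dataset].
#' @export
read_imzml <- function(path, specimen_id = NULL, patient_id = NULL,
                       cytology_class = NULL, origin = NULL) {
  if (!file.exists(path)) stop(sprintf("imzML file not found: %s", path))
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd)) {
    stop(sprintf("binary companion file not found: %s", ibd))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
  mode <- if (!inherits(xml2::xml_find_first(
    fc, ".//cvParam[@accession='IMS:1000030']"), "xml_missing")) {
    "continuous"
  } else "processed"
  up <- function(name) {
    n <- xml2::xml_find_first(fc, sprintf(".//userParam[@name='%s']", name))
    if (inherits(n, "xml_missing")) NULL else xml2::xml_attr(n, "value")
  }
  if (is.null(specimen_id)) {
    specimen_id <- up("specimen_id")
    if (is.null(specimen_id)) {
      specimen_id <- sub("\\.[iI][mM][zZ][mM][lL]$", "", basename(path))
    }
  }
  if (is.null(patient_id)) patient_id <- up("patient_id") %||% specimen_id
  if (is.null(cytology_class)) cytology_class <- up("cytology_class") %||% "Unknown"
  if (is.null(origin)) origin <- up("origin") %||% "in_vivo"
  px <- cv_value(doc, "IMS:1000046")
  pixel_size <- if (is.na(px)) 50 else as.numeric(px)

  # data types declared in the referenceable param groups (fall back to the
  # standard float64 mz / float32 intensity if a file inlines its cvParams)
  group_type <- function(group_id) {
    g <- xml2::xml_find_first(
      doc, sprintf(".//referenceableParamGroup[@id='%s']", group_id))
    if (inherits(g, "xml_missing")) return(NA_integer_)
    if (!inherits(xml2::xml_find_first(
      g, ".//cvParam[@accession='MS:1000523']"), "xml_missing")) return(8L)
    if (!inherits(xml2::xml_find_first(
      g, ".//cvParam[@accession='MS:1000521']"), "xml_missing")) return(4L)
    NA_integer_
  }
  group_role <- function(group_id) {
    g <- xml2::xml_find_first(
      doc, sprintf(".//referenceableParamGroup[@id='%s']", group_id))
    if (inherits(g, "xml_missing")) return(NA_character_)
    if (!inherits(xml2::xml_find_first(
      g, ".//cvParam[@accession='MS:1000514']"), "xml_missing")) return("mz")
    if (!inherits(xml2::xml_find_first(
      g, ".//cvParam[@accession='MS:1000515']"), "xml_missing")) return("intensity")
    NA_character_
  }

  spectra_nodes <- xml2::xml_find_all(doc, ".//run/spectrumList/spectrum")
  if (length(spectra_nodes) == 0L) stop("empty dataset: imzML lists no pixels")
  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  ibd_size <- file.info(ibd)$size

  read_array <- function(offset, length, size) {
    if (offset + size * length > ibd_size) {
      stop(sprintf("corrupt binary file %s: array at offset %.0f overruns",
                   ibd, offset))
    }
    seek(con, where = offset, origin = "start")
    readBin(con, what = "double", n = length, size = size,
            endian = "little")
  }

  spectra <- vector("list", length(spectra_nodes))
  for (i in seq_along(spectra_nodes)) {
    sp <- spectra_nodes[[i]]
    x <- as.integer(cv_value(sp, "IMS:1000050"))
    y <- as.integer(cv_value(sp, "IMS:1000051"))
    if (is.na(x) || is.na(y)) stop("spectrum without pixel position")
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- NULL; intensity <- NULL
    for (arr in arrays) {
      ref <- xml2::xml_find_first(arr, ".//referenceableParamGroupRef")
      role <- NA_character_; size <- NA_integer_
      if (!inherits(ref, "xml_missing")) {
        gid <- xml2::xml_attr(ref, "ref")
        role <- group_role(gid); size <- group_type(gid)
      }
      if (is.na(role)) {
        role <- if (!inherits(xml2::xml_find_first(
          arr, ".//cvParam[@accession='MS:1000514']"), "xml_missing")) "mz"
        else "intensity"
      }
      if (is.na(size)) {
        size <- if (!inherits(xml2::xml_find_first(
          arr, ".//cvParam[@accession='MS:1000523']"), "xml_missing")) 8L
        else 4L
      }
      off <- as.numeric(cv_value(arr, "IMS:1000102"))
      len <- as.integer(cv_value(arr, "IMS:1000103"))
      if (is.na(off) || is.na(len)) stop("binary array without external offset")
      vals <- read_array(off, len, size)
      if (role == "mz") mz <- vals else intensity <- vals
    }
    if (is.null(mz) || is.null(intensity)) {
      stop("spectrum missing m/z or intensity array")
    }
    spectra[[i]] <- pixel_spectrum(x, y, mz, pmax(0, intensity))
  }
  msi_dataset(specimen_id = specimen_id, patient_id = patient_id,
              spectra = spectra, cytology_class = cytology_class,
              origin = origin, pixel_size_um = pixel_size, mode = mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
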