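#' Construct a single pixel profile spectrum
#'
#' A `pixel_spectrum` is one MALDI-TOF profile spectrum recorded at an
#' integer raster coordinate of an MSI acquisition. Coordinates follow the
#' imzML convention: 1-based, column `x` increasing rightwards, row `y`
#' increasing downwards.
#'
#' @param x,y Integer pixel coordinates (1-based, positive).
#' @param mz Numeric vector of m/z values in Da. If not strictly increasing
#'   it is sorted and `intensity` permuted consistently (acquisition software
#'   variants differ in axis ordering; repairing is safer than rejecting).
#' @param intensity Numeric vector of non-negative intensities (arbitrary
#'   units), same length as `mz`.
#' @return An object of class `pixel_spectrum`: a list with fields `x`, `y`,
#'   `mz`, `intensity`.
#' @examples
#' s <- pixel_spectrum(1, 1, c(3000, 3010, 3020), c(0, 5, 1))
#' s$mz
#' @export
pixel_spectrum <- function(x, y, mz, intensity) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != 1L || length(y) != 1L || is.na(x) || is.na(y) ||
      x < 1L || y < 1L) {
    stop("pixel coordinates must be single positive integers (1-based)")
  }
  mz <- as.double(mz); intensity <- as.double(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length")
  }
  if (length(mz) < 2L) stop("a pixel spectrum needs at least 2 points")
  if (anyNA(mz) || any(!is.finite(mz))) stop("mz values must be finite")
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("intensities must be finite")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (is.unsorted(mz, strictly = TRUE)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (any(diff(mz) == 0)) stop("duplicate m/z values in spectrum")
  }
  structure(list(x = x, y = y, mz = mz, intensity = intensity),
            class = "pixel_spectrum")
}

#' @export
print.pixel_spectrum <- function(x, ...) {
  cat(sprintf("<pixel_spectrum (%d,%d): %d points, m/z %.1f-%.1f>\n",
              x$x, x$y, length(x$mz), x$mz[1], x$mz[length(x$mz)]))
  invisible(x)
}

coord_key <- function(x, y) paste0(x, ",", y)

#' Construct an MSI dataset (one specimen)
#'
#' Bundles all pixel spectra of one specimen with its clinical metadata.
#' In `"continuous"` mode every pixel shares one m/z axis (enforced); in
#' `"processed"` mode each pixel may carry its own axis.
#'
#' @param specimen_id,patient_id Identifier strings. One patient can
#'   contribute several specimens (e.g. an in vivo FNA and an ex vivo wash).
#' @param spectra List of [pixel_spectrum] objects; duplicate coordinates are
#'   an error.
#' @param cytology_class One of `"Thy2"`, `"Thy3"`, `"Thy4"`, `"Thy5"`,
#'   `"Metastasis"`, `"Unknown"` (the SIAPEC reporting tiers plus the
#'   lymph-node and unlabeled cases).
#' @param origin `"in_vivo"` (needle wash) or `"ex_vivo"` (post-surgical).
#' @param pixel_size_um Raster pitch in micrometres (default 50).
#' @param mode `"continuous"` or `"processed"`.
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(specimen_id, patient_id, spectra,
                        cytology_class = "Unknown",
                        origin = "in_vivo",
                        pixel_size_um = 50,
                        mode = "continuous") {
  cytology_class <- match.arg(cytology_class,
                              c("Thy2", "Thy3", "Thy4", "Thy5",
                                "Metastasis", "Unknown"))
  origin <- match.arg(origin, c("in_vivo", "ex_vivo"))
  mode <- match.arg(mode, c("continuous", "processed"))
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be positive")
  }
  if (length(spectra) == 0L) stop("empty dataset: no pixel spectra")
  ok <- vapply(spectra, inherits, logical(1), "pixel_spectrum")
  if (!all(ok)) stop("spectra must all be pixel_spectrum objects")
  keys <- vapply(spectra, function(s) coord_key(s$x, s$y), character(1))
  if (anyDuplicated(keys)) stop("duplicate pixel coordinates in dataset")
  names(spectra) <- keys
  if (mode == "continuous") {
    ax <- spectra[[1]]$mz
    same <- vapply(spectra, function(s) {
      length(s$mz) == length(ax) && all(s$mz == ax)
    }, logical(1))
    if (!all(same)) {
      stop("continuous mode requires a shared m/z axis across all pixels")
    }
  }
  structure(list(specimen_id = as.character(specimen_id),
                 patient_id = as.character(patient_id),
                 cytology_class = cytology_class,
                 origin = origin,
                 pixel_size_um = pixel_size_um,
                 mode = mode,
                 spectra = spectra),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset %s (patient %s, %s, %s): %d pixels, %s mode>\n",
              x$specimen_id, x$patient_id, x$cytology_class, x$origin,
              length(x$spectra), x$mode))
  invisible(x)
}

#' Coordinates of all pixels in a dataset
#'
#' @param dataset An [msi_dataset].
#' @return Data frame with integer columns `x`, `y`, one row per pixel.
#' @export
dataset_coords <- function(dataset) {
  stopifnot(inherits(dataset, "msi_dataset"))
  data.frame(
    x = vapply(dataset$spectra, function(s) s$x, integer(1)),
    y = vapply(dataset$spectra, function(s) s$y, integer(1)),
    row.names = NULL)
}

#' Construct a region-of-interest annotation
#'
#' An ROI is the pathologist's selection of pixels covering thyrocyte
#' clusters within one specimen. ROIs can be as small as a single pixel.
#' Optional cytomorphology metadata (`cell_cluster_count`,
#' `cells_per_cluster_min`) supports the SIAPEC adequacy rule
#' (see [adequacy_check()]).
#'
#' @param roi_id,specimen_id Identifier strings.
#' @param pixels Two-column matrix or data frame of (x, y) pixel
#'   coordinates; duplicates are removed.
#' @param cell_cluster_count Optional non-negative integer: number of
#'   thyrocyte clusters the ROI contains.
#' @param cells_per_cluster_min Optional non-negative integer: smallest
#'   cell count among those clusters.
#' @return An object of class `roi_annotation`; `pixels` is an integer
#'   matrix with columns `x`, `y`.
#' @export
roi_annotation <- function(roi_id, specimen_id, pixels,
                           cell_cluster_count = NULL,
                           cells_per_cluster_min = NULL) {
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L || nrow(pixels) < 1L) {
    stop("pixels must be a non-empty two-column (x, y) matrix")
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 1L)) {
    stop("ROI pixel coordinates must be positive integers")
  }
  colnames(pixels) <- c("x", "y")
  pixels <- unique(pixels)
  chk_count <- function(v, what) {
    if (!is.null(v)) {
      v <- as.integer(v)
      if (length(v) != 1L || is.na(v) || v < 0L) {
        stop(what, " must be a single non-negative integer or NULL")
      }
    }
    v
  }
  structure(list(roi_id = as.character(roi_id),
                 specimen_id = as.character(specimen_id),
                 pixels = pixels,
                 cell_cluster_count = chk_count(cell_cluster_count,
                                                "cell_cluster_count"),
                 cells_per_cluster_min = chk_count(cells_per_cluster_min,
                                                   "cells_per_cluster_min")),
            class = "roi_annotation")
}

#' @export
print.roi_annotation <- function(x, ...) {
  cat(sprintf("<roi_annotation %s (%s): %d pixels>\n",
              x$roi_id, x$specimen_id, nrow(x$pixels)))
  invisible(x)
}

#' Validate that an ROI lies on its dataset's pixel grid
#'
#' @param roi An [roi_annotation].
#' @param dataset The [msi_dataset] the ROI refers to.
#' @return `roi`, invisibly, if every ROI pixel exists in the dataset;
#'   otherwise an error naming the offending coordinates.
#' @export
validate_roi <- function(roi, dataset) {
  stopifnot(inherits(roi, "roi_annotation"), inherits(dataset, "msi_dataset"))
  if (!identical(roi$specimen_id, dataset$specimen_id)) {
    stop(sprintf("ROI '%s' refers to specimen '%s', not '%s'",
                 roi$roi_id, roi$specimen_id, dataset$specimen_id))
  }
  keys <- coord_key(roi$pixels[, "x"], roi$pixels[, "y"])
  missing <- setdiff(keys, names(dataset$spectra))
  if (length(missing)) {
    stop(sprintf("ROI '%s' has %d pixel(s) outside the dataset grid: %s",
                 roi$roi_id, length(missing),
                 paste(utils::head(missing, 5), collapse = " ")))
  }
  invisible(roi)
}

#' Extract the spectra under an ROI
#'
#' @inheritParams validate_roi
#' @return List of [pixel_spectrum] objects, in ROI pixel order.
#' @export
roi_spectra <- function(roi, dataset) {
  validate_roi(roi, dataset)
  keys <- coord_key(roi$pixels[, "x"], roi$pixels[, "y"])
  dataset$spectra[keys]
}
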