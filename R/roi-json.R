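#' Read ROI annotations from JSON
#'
#' The package stores the pathologist's regions of interest in a plain JSON
#' format: one file per specimen, with explicit pixel lists —
#' `{"specimen_id": str, "rois": [{"roi_id": str, "pixels": [[x, y], ...],
#' "cell_cluster_count": int|null, "cells_per_cluster_min": int|null}]}`.
#' Duplicate coordinates within one ROI are deduplicated. Validation against
#' the pixel grid of the referenced dataset happens on first use (see
#' [validate_roi()]), not at read time, so annotations can be read before
#' their imzML file.
#'
#' @param path Path to a ROI JSON file.
#' @return List of [roi_annotation] objects.
#' @export
read_roi_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("ROI file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$specimen_id) || is.null(j$rois)) {
    stop("ROI JSON must have 'specimen_id' and 'rois' fields")
  }
  if (length(j$rois) == 0L) stop("ROI JSON lists no ROIs")
  lapply(j$rois, function(r) {
    if (is.null(r$roi_id)) stop("ROI without roi_id")
    if (is.null(r$pixels) || length(r$pixels) == 0L) {
      stop(sprintf("ROI '%s' has an empty pixel list", r$roi_id))
    }
    px <- do.call(rbind, lapply(r$pixels, function(p) {
      if (length(p) != 2L) stop("each pixel must be an [x, y] pair")
      c(as.integer(p[[1]]), as.integer(p[[2]]))
    }))
    roi_annotation(roi_id = r$roi_id,
                   specimen_id = j$specimen_id,
                   pixels = px,
                   cell_cluster_count = r$cell_cluster_count,
                   cells_per_cluster_min = r$cells_per_cluster_min)
  })
}

#' Write ROI annotations to JSON
#'
#' @param rois List of [roi_annotation] objects, all for one specimen.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_annotations <- function(rois, path) {
  stopifnot(length(rois) >= 1L,
            all(vapply(rois, inherits, logical(1), "roi_annotation")))
  sid <- unique(vapply(rois, function(r) r$specimen_id, character(1)))
  if (length(sid) != 1L) stop("all ROIs must belong to one specimen")
  payload <- list(
    specimen_id = jsonlite::unbox(sid),
    rois = lapply(rois, function(r) {
      list(roi_id = jsonlite::unbox(r$roi_id),
           pixels = lapply(seq_len(nrow(r$pixels)),
                           function(i) as.integer(r$pixels[i, ])),
           cell_cluster_count =
             if (is.null(r$cell_cluster_count)) NULL
             else jsonlite::unbox(r$cell_cluster_count),
           cells_per_cluster_min =
             if (is.null(r$cells_per_cluster_min)) NULL
             else jsonlite::unbox(r$cells_per_cluster_min))
    }))
  jsonlite::write_json(payload, path, null = "null", digits = NA)
  invisible(path)
}
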