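#' Construct a feature matrix
#'
#' Observations (pixels, ROI means, or ROI-group means) by aligned m/z
#' features. Intensities of undetected features are imputed as 0, but the
#' binary `detected` mask is kept alongside because the prevalence filters
#' are defined on detection, not on intensity.
#'
#' @param observation_ids Character vector, one id per row.
#' @param feature_mz Ascending numeric vector of feature m/z values (Da).
#' @param intensities Numeric matrix, observations x features, >= 0.
#' @param detected Binary matrix of the same shape; `detected == 0` entries
#'   must have intensity 0.
#' @param labels Optional per-observation class labels (`"benign"` /
#'   `"malignant"`, or `NA`).
#' @param patient_of Optional per-observation patient id.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(observation_ids, feature_mz, intensities, detected,
                           labels = NULL, patient_of = NULL) {
  observation_ids <- as.character(observation_ids)
  feature_mz <- as.double(feature_mz)
  intensities <- as.matrix(intensities)
  detected <- as.matrix(detected)
  storage.mode(detected) <- "integer"
  n <- length(observation_ids); p <- length(feature_mz)
  if (!all(dim(intensities) == c(n, p)) || !all(dim(detected) == c(n, p))) {
    stop("intensities/detected shape must be observations x features")
  }
  if (is.unsorted(feature_mz, strictly = TRUE)) {
    stop("feature_mz must be strictly ascending")
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (any(intensities[detected == 0L] != 0)) {
    stop("undetected entries must have intensity 0")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    stopifnot(length(labels) == n)
  }
  if (!is.null(patient_of)) {
    patient_of <- as.character(patient_of)
    stopifnot(length(patient_of) == n)
  }
  rownames(intensities) <- observation_ids
  colnames(intensities) <- sprintf("%.2f", feature_mz)
  dimnames(detected) <- dimnames(intensities)
  structure(list(observation_ids = observation_ids,
                 feature_mz = feature_mz,
                 intensities = intensities,
                 detected = detected,
                 labels = labels,
                 patient_of = patient_of),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d observations x %d features%s>\n",
              length(x$observation_ids), length(x$feature_mz),
              if (!is.null(x$labels)) ", labelled" else ""))
  invisible(x)
}

#' Restrict a feature matrix to a subset of features
#'
#' @param fm A [feature_matrix].
#' @param keep_mz Feature m/z values to keep (matched exactly against
#'   `fm$feature_mz`).
#' @return The restricted [feature_matrix].
#' @export
subset_features <- function(fm, keep_mz) {
  stopifnot(inherits(fm, "feature_matrix"))
  idx <- match(keep_mz, fm$feature_mz)
  if (anyNA(idx)) stop("keep_mz contains m/z values not in the matrix")
  idx <- sort(idx)
  feature_matrix(fm$observation_ids, fm$feature_mz[idx],
                 fm$intensities[, idx, drop = FALSE],
                 fm$detected[, idx, drop = FALSE],
                 labels = fm$labels, patient_of = fm$patient_of)
}

#' Write a feature matrix to CSV (+ JSON detection mask)
#'
#' @param fm A [feature_matrix].
#' @param path CSV output path; the detection mask goes to the same path
#'   with extension `.mask.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(observation_id = fm$observation_ids,
                   fm$intensities, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  mask_path <- paste0(sub("\\.csv$", "", path), ".mask.json")
  jsonlite::write_json(
    list(feature_mz = fm$feature_mz,
         observation_ids = fm$observation_ids,
         detected = fm$detected),
    mask_path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
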