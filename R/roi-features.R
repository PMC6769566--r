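#' Mean processed profile of one ROI
#'
#' Each ROI pixel is processed through the profile chain (baseline
#' subtraction, smoothing, TIC normalization) and the processed profiles
#' are averaged pointwise. Peaks are picked on the mean, not per pixel, so
#' averaging happens at the profile stage where noise cancels. Pixels
#' flagged empty (zero total ion current) are excluded from the mean.
#'
#' @param dataset An [msi_dataset]; its pixels must share one m/z axis.
#' @param roi An [roi_annotation] on that dataset.
#' @param params A [preprocessing_params()] list.
#' @return A [pixel_spectrum]-shaped mean profile (coordinate set to (1,1);
#'   attributes `roi_id` and `n_pixels` record provenance). If every ROI
#'   pixel is empty a classed condition `msiTriage_inadequate_roi` is
#'   signalled.
#' @export
roi_mean_spectrum <- function(dataset, roi, params = preprocessing_params()) {
  spectra <- roi_spectra(roi, dataset)
  profiles <- list()
  for (s in spectra) {
    p <- tryCatch(process_profile(s, params),
                  msiTriage_empty_pixel = function(e) NULL)
    if (!is.null(p)) profiles[[length(profiles) + 1L]] <- p
  }
  if (length(profiles) == 0L) {
    stop(inadequate_roi_error(
      sprintf("inadequate ROI '%s': all %d pixels are empty",
              roi$roi_id, length(spectra))))
  }
  ax <- profiles[[1]]$mz
  for (p in profiles[-1]) {
    if (!identical(length(p$mz), length(ax)) || any(p$mz != ax)) {
      stop("ROI pixels do not share one m/z axis")
    }
  }
  mean_int <- Reduce(`+`, lapply(profiles, `[[`, "intensity")) /
    length(profiles)
  out <- pixel_spectrum(1L, 1L, ax, mean_int)
  attr(out, "roi_id") <- roi$roi_id
  attr(out, "n_pixels") <- length(profiles)
  out
}

#' Partition a patient's ROIs into equivalent groups
#'
#' Patients contribute very different numbers of ROIs and pixels; to give
#' every training observation comparable spectral support, each patient's
#' ROIs are partitioned into a fixed number of groups of balanced total
#' pixel count (5 groups per benign patient, 4 per malignant in the default
#' design). ROIs are sorted by pixel count descending and dealt greedily to
#' the group with the smallest running pixel total among groups still below
#' the 7-ROI cap; exact ties are broken by a seeded draw, so the partition
#' is deterministic given the seed.
#'
#' @param rois List of [roi_annotation] objects (one patient).
#' @param n_groups Number of groups; reduced (with a message) to
#'   `length(rois)` when the patient has fewer ROIs than groups.
#' @param seed Integer seed for tie-breaking.
#' @return List of `roi_group` objects: `group_id`, `roi_ids` (1-7 each),
#'   `pixel_total`. Groups partition the input exactly.
#' @export
make_equivalent_groups <- function(rois, n_groups, seed = 1L) {
  stopifnot(length(rois) >= 1L,
            all(vapply(rois, inherits, logical(1), "roi_annotation")))
  n_groups <- as.integer(n_groups)
  if (n_groups < 1L) stop("n_groups must be >= 1")
  n <- length(rois)
  if (n < n_groups) {
    message(sprintf("only %d ROIs for %d groups; using %d groups", n,
                    n_groups, n))
    n_groups <- n
  }
  if (n > 7L * n_groups) {
    stop(sprintf("%d ROIs cannot fit %d groups of at most 7 ROIs each",
                 n, n_groups))
  }
  counts <- vapply(rois, function(r) nrow(r$pixels), integer(1))
  set.seed(seed)
  ord <- order(-counts, stats::runif(n))
  assign <- integer(n)
  totals <- numeric(n_groups)
  sizes <- integer(n_groups)
  for (i in ord) {
    open <- which(sizes < 7L)
    best <- open[totals[open] == min(totals[open])]
    g <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
    assign[i] <- g
    totals[g] <- totals[g] + counts[i]
    sizes[g] <- sizes[g] + 1L
  }
  lapply(seq_len(n_groups), function(g) {
    member <- which(assign == g)
    structure(list(group_id = sprintf("g%02d", g),
                   roi_ids = vapply(rois[member], function(r) r$roi_id,
                                    character(1)),
                   pixel_total = sum(counts[member])),
              class = "roi_group")
  })
}

#' @export
print.roi_group <- function(x, ...) {
  cat(sprintf("<roi_group %s: %d ROIs, %d pixels>\n",
              x$group_id, length(x$roi_ids), x$pixel_total))
  invisible(x)
}

#' Group-mean observations for one specimen
#'
#' Averages the member-ROI mean profiles of each equivalent group, picks
#' peaks on the group mean, and projects them onto a feature grid. With the
#' default design (9 benign patients x 5 groups, 9 malignant x 4 groups)
#' the cohort yields 45 + 36 observations.
#'
#' @param dataset An [msi_dataset].
#' @param rois The specimen's [roi_annotation] list.
#' @param groups Output of [make_equivalent_groups()] for those ROIs.
#' @param grid A [feature_grid] to project onto.
#' @param params A [preprocessing_params()] list.
#' @param label Optional class label attached to every observation.
#' @return A [feature_matrix] with one observation per group
#'   (`<specimen>_<group>` ids, `patient_of` filled in).
#' @export
group_mean_observations <- function(dataset, rois, groups, grid,
                                    params = preprocessing_params(),
                                    label = NULL) {
  stopifnot(length(groups) >= 1L)
  roi_by_id <- stats::setNames(rois, vapply(rois, function(r) r$roi_id,
                                            character(1)))
  means <- lapply(rois, roi_mean_spectrum, dataset = dataset, params = params)
  names(means) <- names(roi_by_id)
  nf <- length(grid$features)
  intens <- matrix(0, nrow = length(groups), ncol = nf)
  det <- matrix(0L, nrow = length(groups), ncol = nf)
  obs_ids <- character(length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    member <- means[g$roi_ids]
    prof <- member[[1]]
    if (length(member) > 1L) {
      prof$intensity <- Reduce(`+`, lapply(member, `[[`, "intensity")) /
        length(member)
    }
    pl <- pick_peaks(prof, snr_min = params$snr_min)
    pl <- filter_low_intensity(pl, params$intensity_threshold,
                               params$intensity_rule)
    proj <- project_onto_grid(pl, grid)
    intens[gi, ] <- proj$intensity
    det[gi, ] <- proj$detected
    obs_ids[gi] <- paste0(dataset$specimen_id, "_", g$group_id)
  }
  feature_matrix(observation_ids = obs_ids,
                 feature_mz = grid$features,
                 intensities = intens,
                 detected = det,
                 labels = if (is.null(label)) NULL
                          else rep(label, length(groups)),
                 patient_of = rep(dataset$patient_id, length(groups)))
}

#' Intra-patient prevalence filter
#'
#' For each patient independently, a feature counts as present in that
#' patient iff it was detected in at least `min_fraction` of the patient's
#' ROIs (boundary inclusive: 1 detection out of 4 ROIs passes at 0.25).
#' The per-ROI detail is reduced to a patient-level binary presence
#' profile, which is what the inter-patient filter consumes.
#'
#' @param fm A [feature_matrix] whose observations are per-ROI mean spectra
#'   (not grouped), with `patient_of` set.
#' @param min_fraction Minimum detection fraction (default 0.25).
#' @return List with `patients`, `feature_mz`, and `presence` (binary
#'   patients x features matrix).
#' @export
intra_patient_filter <- function(fm, min_fraction = 0.25) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$patient_of)) stop("feature matrix lacks patient_of")
  patients <- unique(fm$patient_of)
  presence <- matrix(0L, nrow = length(patients),
                     ncol = length(fm$feature_mz),
                     dimnames = list(patients, colnames(fm$detected)))
  for (p in patients) {
    rows <- fm$patient_of == p
    if (!any(rows)) stop(sprintf("patient %s has zero ROIs", p))
    frac <- colMeans(fm$detected[rows, , drop = FALSE])
    presence[p, ] <- as.integer(frac >= min_fraction)
  }
  list(patients = patients, feature_mz = fm$feature_mz, presence = presence)
}

#' Inter-patient prevalence filter
#'
#' Keeps the features that are class-representative: present (after the
#' intra-patient filter) in at least `min_fraction` of the benign patients
#' or in at least `min_fraction` of the malignant patients. The default
#' `"union"` reading returns two class-specific representative sets merged;
#' `"intersection"` instead requires both classes to reach the threshold.
#'
#' @param patient_presence Output of [intra_patient_filter()].
#' @param benign_ids,malignant_ids Patient ids of the two classes
#'   (non-empty, subsets of `patient_presence$patients`).
#' @param min_fraction Minimum fraction of patients per class (default 0.25).
#' @param mode `"union"` (default) or `"intersection"`.
#' @return Ascending vector of retained feature m/z values; an error if the
#'   filter leaves no representative feature.
#' @export
inter_patient_filter <- function(patient_presence, benign_ids, malignant_ids,
                                 min_fraction = 0.25,
                                 mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(length(benign_ids) >= 1L, length(malignant_ids) >= 1L)
  pres <- patient_presence$presence
  miss <- setdiff(c(benign_ids, malignant_ids), rownames(pres))
  if (length(miss)) {
    stop("unknown patient ids: ", paste(miss, collapse = ", "))
  }
  frac_b <- colMeans(pres[benign_ids, , drop = FALSE])
  frac_m <- colMeans(pres[malignant_ids, , drop = FALSE])
  keep <- if (mode == "union") {
    frac_b >= min_fraction | frac_m >= min_fraction
  } else {
    frac_b >= min_fraction & frac_m >= min_fraction
  }
  out <- sort(unique(patient_presence$feature_mz[keep]))
  if (length(out) == 0L) {
    stop("no representative features survive the inter-patient filter")
  }
  out
}

#' SIAPEC specimen adequacy check
#'
#' A satisfactory FNA specimen should contain at least `min_clusters`
#' groups of `min_cells` thyrocytes. ROIs whose metadata records clusters
#' of at least `min_cells` cells contribute their cluster counts; the
#' specimen is adequate when the contributed clusters reach `min_clusters`.
#'
#' @param rois List of [roi_annotation] objects for one specimen.
#' @param min_clusters Minimum number of qualifying clusters (default 6).
#' @param min_cells Minimum cells per cluster (default 10).
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate) when metadata is absent
#'   from some ROI and the remaining ROIs do not already reach the
#'   threshold — missing data must not read as inadequacy.
#' @export
adequacy_check <- function(rois, min_clusters = 6L, min_cells = 10L) {
  stopifnot(length(rois) >= 1L)
  has_meta <- vapply(rois, function(r) {
    !is.null(r$cell_cluster_count) && !is.null(r$cells_per_cluster_min)
  }, logical(1))
  known <- rois[has_meta]
  clusters <- sum(vapply(known, function(r) {
    if (r$cell_cluster_count >= 1L && r$cells_per_cluster_min >= min_cells) {
      r$cell_cluster_count
    } else 0L
  }, integer(1)))
  if (clusters >= min_clusters) return(TRUE)
  if (any(!has_meta)) {
    message("adequacy indeterminate: some ROIs lack cytomorphology metadata")
    return(NA)
  }
  FALSE
}
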