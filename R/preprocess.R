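#' @title Per-spectrum preprocessing chain
#' @description Linear-mode MALDI-TOF profile spectra carry a chemical
#'   baseline, point-to-point detector noise and arbitrary per-pixel
#'   intensity scale. The chain applied here, in fixed order, is:
#'   median baseline subtraction, moving-average smoothing, total ion
#'   current (TIC) normalization, peak picking at a signal-to-noise
#'   threshold, and removal of peaks below an absolute post-TIC intensity
#'   floor. See [process_spectrum()] for the composed operator.
#' @name preprocessing
NULL

empty_pixel_error <- function(msg = "empty pixel: total ion current is zero") {
  structure(class = c("msiTriage_empty_pixel", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

inadequate_roi_error <- function(msg) {
  structure(class = c("msiTriage_inadequate_roi", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

is_empty_pixel_condition <- function(e) inherits(e, "msiTriage_empty_pixel")

replace_intensity <- function(s, intensity) {
  s$intensity <- intensity
  s
}

# median of a sorted vector; even lengths interpolate via mean() of the two
# middle values, matching stats::median exactly
sorted_median <- function(s) {
  m <- length(s)
  if (m %% 2L == 1L) s[(m + 1L) %/% 2L] else mean(s[m %/% 2L + 0:1])
}

# Median of intensities over [i - hw, i + hw], truncated at the edges.
# Interior windows (odd length 2*hw+1) come from stats::runmed, whose
# medians are exact order statistics; truncated edge windows (possibly of
# even length, where the median interpolates) grow by one point per
# position, so each edge maintains one incrementally sorted window instead
# of re-sorting per position.
running_median <- function(x, hw) {
  n <- length(x)
  k <- 2L * hw + 1L
  base <- as.vector(stats::runmed(x, k = k, endrule = "keep"))
  s <- sort(x[1:(hw + 1L)])
  base[1L] <- sorted_median(s)
  for (i in 1L + seq_len(hw - 1L)) {
    v <- x[i + hw]
    s <- append(s, v, after = findInterval(v, s))
    base[i] <- sorted_median(s)
  }
  s <- sort(x[(n - hw):n])
  base[n] <- sorted_median(s)
  for (i in n - seq_len(hw - 1L)) {
    v <- x[i - hw]
    s <- append(s, v, after = findInterval(v, s))
    base[i] <- sorted_median(s)
  }
  base
}

#' Subtract a running-median baseline
#'
#' The baseline at point i is the median intensity over the window
#' `[i - half_window_points, i + half_window_points]`, truncated at the
#' spectrum edges. Output intensities are clamped at zero.
#'
#' @param s A [pixel_spectrum].
#' @param half_window_points Half window width in points (>= 1). The default
#'   of 50 points spans roughly 200 Da on the package's default 4000-point
#'   axis, wide relative to linear-TOF protein peaks so that peak apexes
#'   survive subtraction.
#' @return A [pixel_spectrum] with the baseline removed; m/z unchanged.
#' @export
subtract_baseline <- function(s, half_window_points = 50L) {
  stopifnot(inherits(s, "pixel_spectrum"))
  hw <- as.integer(half_window_points)
  if (is.na(hw) || hw < 1L) stop("half_window_points must be >= 1")
  n <- length(s$intensity)
  if (n < 2L * hw + 1L) {
    stop(sprintf("spectrum too short (%d points) for half window %d", n, hw))
  }
  baseline <- running_median(s$intensity, hw)
  replace_intensity(s, pmax(0, s$intensity - baseline))
}

# Truncated-window moving average via shifted accumulation. Summation order
# over each window matches a left-to-right sum so the result agrees with a
# brute-force sum(window)/length(window) to within one rounding of sum().
running_mean <- function(x, hw) {
  n <- length(x)
  xp <- c(numeric(hw), x, numeric(hw))
  acc <- numeric(n)
  for (j in 0:(2L * hw)) acc <- acc + xp[(1L + j):(n + j)]
  i <- seq_len(n)
  cnt <- pmin(i + hw, n) - pmax(i - hw, 1L) + 1L
  acc / cnt
}

#' Smooth a spectrum with an unweighted moving average
#'
#' @param s A [pixel_spectrum].
#' @param half_window_points Half window width in points (>= 1). Default 2,
#'   i.e. a 5-point window: the nearest integer realization of a half window
#'   width of 2.5, exposed so users can trade noise suppression against peak
#'   broadening.
#' @return Smoothed [pixel_spectrum]; windows are truncated at the edges so
#'   the total signal is preserved up to edge effects.
#' @export
smooth_spectrum <- function(s, half_window_points = 2L) {
  stopifnot(inherits(s, "pixel_spectrum"))
  hw <- as.integer(half_window_points)
  if (is.na(hw) || hw < 1L) stop("half_window_points must be >= 1")
  if (length(s$intensity) < 2L * hw + 1L) {
    stop(sprintf("spectrum too short (%d points) for half window %d",
                 length(s$intensity), hw))
  }
  replace_intensity(s, running_mean(s$intensity, hw))
}

#' Total ion current normalization
#'
#' Divides every intensity by the spectrum's summed intensity so that the
#' output sums to one, removing the per-pixel intensity scale.
#'
#' @param s A [pixel_spectrum].
#' @return Normalized [pixel_spectrum].
#' @section Empty pixels: a spectrum whose intensities sum to zero carries no
#'   signal to normalize; a classed condition `msiTriage_empty_pixel` is
#'   signalled so that callers can mask the pixel rather than score it.
#' @export
tic_normalize <- function(s) {
  stopifnot(inherits(s, "pixel_spectrum"))
  tic <- sum(s$intensity)
  if (tic <= 0) stop(empty_pixel_error())
  replace_intensity(s, s$intensity / tic)
}

#' Robust noise level of a profile spectrum
#'
#' Scaled median absolute deviation (MAD, consistency constant 1.4826) of
#' the intensities. Intended for baseline-subtracted spectra, where the
#' median level is near zero and peaks are sparse enough not to inflate a
#' median-based scale estimate.
#'
#' @param s A [pixel_spectrum] (>= 16 points).
#' @return Single non-negative noise level in the spectrum's intensity
#'   units; exactly 0 for an identically-zero spectrum.
#' @export
estimate_noise <- function(s) {
  stopifnot(inherits(s, "pixel_spectrum"))
  if (length(s$intensity) < 16L) stop("need at least 16 points")
  stats::mad(s$intensity, constant = 1.4826)
}

# Local maxima with plateau handling: run-length encode, keep interior runs
# strictly above both neighbouring runs, apex = leftmost point of the run.
local_maxima <- function(x) {
  r <- rle(x)
  nr <- length(r$values)
  if (nr < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- 2:(nr - 1L)
  keep <- r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]
  starts[i][keep]
}

#' Pick peaks at a signal-to-noise threshold
#'
#' Finds local maxima (strictly greater than both neighbours; flat-topped
#' plateaus are assigned to their leftmost point) and keeps those whose apex
#' intensity divided by the noise level is at least `snr_min`. The boundary
#' is inclusive: apex / noise exactly equal to `snr_min` is kept.
#'
#' @param s A processed [pixel_spectrum] (baseline-subtracted, smoothed,
#'   TIC-normalized).
#' @param snr_min Minimum signal-to-noise ratio (default 6).
#' @param noise Noise level to use; `NULL` (default) estimates it from `s`
#'   via [estimate_noise()]. When the estimate is zero (noise-free signal)
#'   every positive local maximum is kept.
#' @return A `peak_list`: list with `source` (observation id, here the
#'   coordinate key), and `peaks`, a data frame with columns `mz`,
#'   `intensity`, `snr` sorted by ascending m/z.
#' @export
pick_peaks <- function(s, snr_min = 6, noise = NULL) {
  stopifnot(inherits(s, "pixel_spectrum"))
  if (is.null(noise)) noise <- estimate_noise(s)
  if (!is.numeric(noise) || length(noise) != 1L || noise < 0) {
    stop("noise must be a single non-negative number")
  }
  apex <- local_maxima(s$intensity)
  if (noise > 0) {
    snr <- s$intensity[apex] / noise
    keep <- snr >= snr_min
    apex <- apex[keep]
    snr <- snr[keep]
  } else {
    apex <- apex[s$intensity[apex] > 0]
    snr <- rep(Inf, length(apex))
  }
  peak_list(source = coord_key(s$x, s$y),
            mz = s$mz[apex],
            intensity = s$intensity[apex],
            snr = snr)
}

#' Construct a peak list
#'
#' @param source Observation identifier the peaks came from.
#' @param mz,intensity,snr Equal-length numeric vectors; reordered to
#'   ascending m/z.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(source, mz, intensity, snr = rep(NA_real_, length(mz))) {
  stopifnot(length(mz) == length(intensity), length(mz) == length(snr))
  if (any(intensity < 0)) stop("peak intensities must be non-negative")
  o <- order(mz)
  peaks <- structure(
    list(mz = as.double(mz)[o], intensity = as.double(intensity)[o],
         snr = as.double(snr)[o]),
    class = "data.frame", row.names = c(NA_integer_, -length(mz)))
  structure(list(source = as.character(source), peaks = peaks),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list %s: %d peaks>\n", x$source, nrow(x$peaks)))
  invisible(x)
}

#' Filter peaks by absolute post-TIC intensity
#'
#' Applies the absolute intensity cut of 0.0003 (TIC-normalized units) used
#' to separate real protein signal from residual noise peaks. The default
#' rule retains peaks at or above the threshold (the noise-floor reading);
#' `rule = "below"` retains peaks strictly below it instead, for users who
#' want the opposite convention.
#'
#' @param pl A `peak_list` with TIC-normalized intensities.
#' @param threshold Absolute intensity threshold (default 0.0003).
#' @param rule `"above"` (default: keep intensity >= threshold) or
#'   `"below"` (keep intensity < threshold).
#' @return Filtered `peak_list`, order preserved.
#' @export
filter_low_intensity <- function(pl, threshold = 0.0003,
                                 rule = c("above", "below")) {
  stopifnot(inherits(pl, "peak_list"))
  rule <- match.arg(rule)
  keep <- if (rule == "above") pl$peaks$intensity >= threshold
          else pl$peaks$intensity < threshold
  pl$peaks <- pl$peaks[keep, , drop = FALSE]
  rownames(pl$peaks) <- NULL
  pl
}

#' Construct a feature grid
#'
#' @param features Ascending numeric vector of reference m/z values (Da).
#' @param tolerance_ppm Matching tolerance in parts per million.
#' @return An object of class `feature_grid`.
#' @export
feature_grid <- function(features, tolerance_ppm) {
  features <- as.double(features)
  if (length(features) < 1L) stop("feature grid must be non-empty")
  if (is.unsorted(features, strictly = TRUE)) stop("features must be ascending")
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0) {
    stop("tolerance_ppm must be positive")
  }
  structure(list(features = features, tolerance_ppm = tolerance_ppm),
            class = "feature_grid")
}

#' @export
print.feature_grid <- function(x, ...) {
  cat(sprintf("<feature_grid: %d features, m/z %.1f-%.1f, tol %g ppm>\n",
              length(x$features), min(x$features), max(x$features),
              x$tolerance_ppm))
  invisible(x)
}

#' Align peak lists onto a common feature grid
#'
#' Pools all peak m/z values, sorts them, and cuts the sorted sequence into
#' clusters wherever the gap between adjacent values exceeds the relative
#' tolerance (single-linkage binning). Each cluster becomes one feature at
#' the intensity-weighted mean m/z. Linear-TOF protein peaks are broad, so
#' the default tolerance (2000 ppm, i.e. +/- 0.2%) is far wider than the
#' +/- 30 ppm calibration accuracy and is governed by peak width, not mass
#' accuracy.
#'
#' @param peaklists List of `peak_list` objects (at least one non-empty).
#' @param tolerance_ppm Gap threshold in ppm of the lower m/z (default 2000).
#' @return List with `grid` (a [feature_grid]) and `matrix` (a
#'   [feature_matrix]): per observation, the summed intensity of its peaks in
#'   each cluster (0 when absent) plus a binary `detected` mask.
#' @export
align_peaks <- function(peaklists, tolerance_ppm = 2000) {
  stopifnot(is.list(peaklists), length(peaklists) >= 1L)
  counts <- vapply(peaklists, function(p) nrow(p$peaks), integer(1))
  if (sum(counts) == 0L) stop("no features: all peak lists are empty")
  obs_ids <- vapply(peaklists, function(p) p$source, character(1))
  if (anyDuplicated(obs_ids)) stop("duplicate peak list source ids")
  all_mz <- unlist(lapply(peaklists, function(p) p$peaks$mz))
  all_int <- unlist(lapply(peaklists, function(p) p$peaks$intensity))
  all_obs <- rep(seq_along(peaklists), counts)
  o <- order(all_mz)
  all_mz <- all_mz[o]; all_int <- all_int[o]; all_obs <- all_obs[o]
  gap_ppm <- diff(all_mz) / all_mz[-length(all_mz)] * 1e6
  cluster <- cumsum(c(1L, as.integer(gap_ppm > tolerance_ppm)))
  nclus <- cluster[length(cluster)]
  w <- all_int
  # guard against all-zero clusters: fall back to unweighted mean
  feat_mz <- vapply(seq_len(nclus), function(k) {
    idx <- which(cluster == k)
    if (sum(w[idx]) > 0) stats::weighted.mean(all_mz[idx], w[idx])
    else mean(all_mz[idx])
  }, numeric(1))
  intensities <- matrix(0, nrow = length(peaklists), ncol = nclus)
  detected <- matrix(0L, nrow = length(peaklists), ncol = nclus)
  for (i in seq_along(all_mz)) {
    r <- all_obs[i]; k <- cluster[i]
    intensities[r, k] <- intensities[r, k] + all_int[i]
    detected[r, k] <- 1L
  }
  grid <- feature_grid(feat_mz, tolerance_ppm)
  fm <- feature_matrix(observation_ids = obs_ids,
                       feature_mz = feat_mz,
                       intensities = intensities,
                       detected = detected)
  list(grid = grid, matrix = fm)
}

#' Project a peak list onto an existing feature grid
#'
#' Each peak is matched to the nearest grid feature; matches within the
#' grid's ppm tolerance contribute their intensity (summed if several peaks
#' hit one feature), peaks matching no feature are dropped, and absent
#' features are 0. This is the prediction-time counterpart of
#' [align_peaks()].
#'
#' @param pl A `peak_list`.
#' @param grid A [feature_grid].
#' @return List with `intensity` and `detected` vectors, one entry per grid
#'   feature.
#' @export
project_onto_grid <- function(pl, grid) {
  stopifnot(inherits(pl, "peak_list"), inherits(grid, "feature_grid"))
  nf <- length(grid$features)
  out_i <- numeric(nf); out_d <- integer(nf)
  if (nrow(pl$peaks) > 0L) {
    idx <- findInterval(pl$peaks$mz, grid$features)
    for (j in seq_len(nrow(pl$peaks))) {
      cand <- unique(pmin(pmax(c(idx[j], idx[j] + 1L), 1L), nf))
      d <- abs(grid$features[cand] - pl$peaks$mz[j])
      k <- cand[which.min(d)]
      if (abs(grid$features[k] - pl$peaks$mz[j]) / grid$features[k] * 1e6 <=
          grid$tolerance_ppm) {
        out_i[k] <- out_i[k] + pl$peaks$intensity[j]
        out_d[k] <- 1L
      }
    }
  }
  list(intensity = out_i, detected = out_d)
}

#' Default preprocessing parameters
#'
#' @param baseline_half_window Points, for [subtract_baseline()] (default 50).
#' @param smooth_half_window Points, for [smooth_spectrum()] (default 2).
#' @param snr_min Signal-to-noise threshold for [pick_peaks()] (default 6).
#' @param intensity_threshold Post-TIC absolute floor for
#'   [filter_low_intensity()] (default 0.0003).
#' @param intensity_rule `"above"` or `"below"`, see [filter_low_intensity()].
#' @param tolerance_ppm Alignment tolerance for [align_peaks()] (default 2000).
#' @return Named list of parameters.
#' @export
preprocessing_params <- function(baseline_half_window = 50L,
                                 smooth_half_window = 2L,
                                 snr_min = 6,
                                 intensity_threshold = 0.0003,
                                 intensity_rule = "above",
                                 tolerance_ppm = 2000) {
  list(baseline_half_window = as.integer(baseline_half_window),
       smooth_half_window = as.integer(smooth_half_window),
       snr_min = snr_min,
       intensity_threshold = intensity_threshold,
       intensity_rule = intensity_rule,
       tolerance_ppm = tolerance_ppm)
}

#' Baseline-subtract, smooth and TIC-normalize a spectrum
#'
#' The profile part of the processing chain, kept separate from peak
#' picking because ROI- and group-mean spectra are averaged at the profile
#' stage before peaks are picked on the mean.
#'
#' @param s A raw [pixel_spectrum].
#' @param params A [preprocessing_params()] list.
#' @return Processed [pixel_spectrum] whose intensities sum to 1, or a
#'   `msiTriage_empty_pixel` condition if the pixel carries no signal.
#' @export
process_profile <- function(s, params = preprocessing_params()) {
  s <- subtract_baseline(s, params$baseline_half_window)
  s <- smooth_spectrum(s, params$smooth_half_window)
  tic_normalize(s)
}

#' Full per-spectrum processing: profile chain then peak picking
#'
#' Applies, in order: baseline subtraction, smoothing, TIC normalization,
#' S/N peak picking, low-intensity filtering.
#'
#' @inheritParams process_profile
#' @return A `peak_list`; propagates the empty-pixel condition for
#'   signal-free pixels.
#' @export
process_spectrum <- function(s, params = preprocessing_params()) {
  p <- process_profile(s, params)
  pl <- pick_peaks(p, snr_min = params$snr_min)
  filter_low_intensity(pl, threshold = params$intensity_threshold,
                       rule = params$intensity_rule)
}
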