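#' @title Synthetic FNA cytospin MSI cohorts
#' @description Generates imzML-compatible datasets with known ground truth
#'   that emulate the statistical structure the triage analysis assumes:
#'   per-pixel linear-TOF protein profile spectra (m/z 3000-20,000) built
#'   from Gaussian peak panels, a decaying-exponential chemical baseline,
#'   multiplicative per-pixel TIC variation, additive truncated Gaussian
#'   noise, a small per-patient mass miscalibration, non-thyrocyte
#'   background pixels with their own broad low-mass spectral family, and
#'   the challenge scenarios seen in routine thyroid cytopathology
#'   (paucicellular, heterogeneous benign/malignant mixture, colloid-rich).
#' @name synthetic_data
NULL

#' Construct a peak panel
#'
#' Defines the spectral populations planted in thyrocyte pixels: peaks
#' shared by both classes, plus class-specific discriminant peaks that are
#' up-regulated in their class (full `mean_height` there) and attenuated by
#' `fold_change` in the other class — discriminant proteins are over- or
#' under-expressed, not absent.
#'
#' @param shared_peaks,benign_peaks,malignant_peaks Two-column matrices (or
#'   data frames) with columns `mz` (Da, within 3000-20,000) and `height`
#'   (mean apex height, arbitrary units, > 0). Benign and malignant m/z
#'   lists must be disjoint.
#' @param peak_fwhm_da Full width at half maximum of every peak, in Da
#'   (default 40: broad linear-TOF protein peaks).
#' @param fold_change Up-regulation factor of class-specific peaks in their
#'   own class relative to the other (default 4).
#' @return An object of class `peak_panel`.
#' @export
peak_panel <- function(shared_peaks, benign_peaks, malignant_peaks,
                       peak_fwhm_da = 40, fold_change = 4) {
  as_pk <- function(m, what) {
    m <- as.matrix(as.data.frame(m))
    if (ncol(m) != 2L) stop(what, " must have columns mz, height")
    colnames(m) <- c("mz", "height")
    if (any(m[, "mz"] < 3000 | m[, "mz"] > 20000)) {
      stop(what, " m/z must lie within [3000, 20000]")
    }
    if (any(m[, "height"] <= 0)) stop(what, " heights must be positive")
    m
  }
  shared_peaks <- as_pk(shared_peaks, "shared_peaks")
  benign_peaks <- as_pk(benign_peaks, "benign_peaks")
  malignant_peaks <- as_pk(malignant_peaks, "malignant_peaks")
  if (length(intersect(benign_peaks[, "mz"], malignant_peaks[, "mz"]))) {
    stop("benign and malignant peak m/z lists must be disjoint")
  }
  if (peak_fwhm_da <= 0) stop("peak_fwhm_da must be positive")
  if (fold_change < 1) stop("fold_change must be >= 1")
  structure(list(shared_peaks = shared_peaks,
                 benign_peaks = benign_peaks,
                 malignant_peaks = malignant_peaks,
                 peak_fwhm_da = peak_fwhm_da,
                 fold_change = fold_change),
            class = "peak_panel")
}

#' Default peak panel
#'
#' Fifteen shared protein peaks spread over the acquisition range, two
#' benign-up and three malignant-up discriminant peaks (five discriminant
#' m/z in total), all separated by at least ~250 Da so that alignment at
#' the default 2000 ppm tolerance never merges distinct peaks.
#'
#' @return A [peak_panel].
#' @export
default_peak_panel <- function() {
  shared <- cbind(
    mz = c(3372, 4153, 4965, 5425, 6115, 6891, 7782, 8452, 9133, 10092,
           11310, 12872, 14044, 15127, 16952),
    height = c(120, 90, 140, 70, 60, 50, 45, 55, 40, 65, 35, 30, 40, 30, 25))
  benign <- cbind(mz = c(5810, 8705), height = c(85, 75))
  malignant <- cbind(mz = c(6570, 9422, 11022), height = c(90, 80, 70))
  peak_panel(shared, benign, malignant, peak_fwhm_da = 40, fold_change = 4)
}

#' Configuration of a synthetic cohort
#'
#' Defaults mirror the cohort statistics of the study design this package
#' models: 9 benign + 9 malignant training patients; ROIs per patient
#' drawn log-uniformly within 5-22 (benign) and 4-19 (malignant); pixels
#' per ROI log-uniformly within 3-39 (benign) and 3-162 (malignant), so
#' the medians land near the reported skewed summaries; per-patient mass
#' miscalibration uniform within +/- 30 ppm (the instrument's external
#' calibration accuracy).
#'
#' @param n_benign_patients,n_malignant_patients Positive integers
#'   (default 9 each).
#' @param rois_per_patient_range Optional `(min, max)` override applied to
#'   both classes; default `NULL` uses the per-class ranges above.
#' @param pixels_per_roi_range Optional `(min, max)` override applied to
#'   both classes; default `NULL` uses the per-class ranges above.
#' @param panel A [peak_panel] (default [default_peak_panel()]).
#' @param baseline_amplitude Amplitude (a.u.) of the decaying-exponential
#'   chemical baseline (default 20).
#' @param noise_sd Standard deviation of the additive Gaussian point noise,
#'   truncated at zero (default 2).
#' @param tic_variation_cv Coefficient of variation of the lognormal
#'   per-pixel intensity multiplier (default 0.3).
#' @param mass_jitter_ppm Half-width of the uniform per-patient mass-axis
#'   scaling error, in ppm; must be within +/- 30 (default 30).
#' @param background_fraction Fraction of non-thyrocyte (colloid/blood)
#'   pixels in each specimen (default 0.2).
#' @param peak_height_cv Per-patient lognormal coefficient of variation of
#'   panel peak heights — the biological between-patient variability that
#'   makes single features imperfect classifiers (default 0.5).
#' @param n_private_peaks Number of patient-idiosyncratic peaks planted per
#'   patient (contamination heterogeneity; these are exactly what the
#'   inter-patient prevalence filter is meant to remove; default 2).
#' @param scenario `"standard"`, `"paucicellular"`,
#'   `"heterogeneous_mixture"` or `"colloid_rich"`.
#' @param axis_points Number of points of the shared profile axis
#'   (default 4000 over `mz_range`, resolving the 40-Da peak FWHM with
#'   ~9 points).
#' @param mz_range Acquisition m/z range (default `c(3000, 20000)`).
#' @param seed Integer RNG seed; every draw derives from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_benign_patients = 9L,
                             n_malignant_patients = 9L,
                             rois_per_patient_range = NULL,
                             pixels_per_roi_range = NULL,
                             panel = default_peak_panel(),
                             baseline_amplitude = 20,
                             noise_sd = 2,
                             tic_variation_cv = 0.3,
                             mass_jitter_ppm = 30,
                             background_fraction = 0.2,
                             peak_height_cv = 0.5,
                             n_private_peaks = 2L,
                             scenario = "standard",
                             axis_points = 4000L,
                             mz_range = c(3000, 20000),
                             seed = 1L) {
  scenario <- match.arg(scenario, c("standard", "paucicellular",
                                    "heterogeneous_mixture", "colloid_rich"))
  chk_range <- function(r, what) {
    if (!is.null(r)) {
      r <- as.integer(r)
      if (length(r) != 2L || anyNA(r) || r[1] < 1L || r[1] > r[2]) {
        stop(what, " must be a valid (min, max) pair")
      }
    }
    r
  }
  rois_per_patient_range <- chk_range(rois_per_patient_range,
                                      "rois_per_patient_range")
  pixels_per_roi_range <- chk_range(pixels_per_roi_range,
                                    "pixels_per_roi_range")
  stopifnot(inherits(panel, "peak_panel"))
  if (n_benign_patients < 1L || n_malignant_patients < 1L) {
    stop("patient counts must be positive")
  }
  if (abs(mass_jitter_ppm) > 30) {
    stop("mass_jitter_ppm must be within +/- 30 ppm")
  }
  for (f in c(tic_variation_cv, background_fraction)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  if (noise_sd < 0 || baseline_amplitude < 0 || peak_height_cv < 0) {
    stop("noise_sd, baseline_amplitude and peak_height_cv must be >= 0")
  }
  if (axis_points < 64L) stop("axis_points too small to resolve peaks")
  structure(list(n_benign_patients = as.integer(n_benign_patients),
                 n_malignant_patients = as.integer(n_malignant_patients),
                 rois_per_patient_range = rois_per_patient_range,
                 pixels_per_roi_range = pixels_per_roi_range,
                 panel = panel,
                 baseline_amplitude = baseline_amplitude,
                 noise_sd = noise_sd,
                 tic_variation_cv = tic_variation_cv,
                 mass_jitter_ppm = mass_jitter_ppm,
                 background_fraction = background_fraction,
                 peak_height_cv = peak_height_cv,
                 n_private_peaks = as.integer(n_private_peaks),
                 scenario = scenario,
                 axis_points = as.integer(axis_points),
                 mz_range = as.double(mz_range),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

class_range <- function(config, which, class) {
  override <- config[[which]]
  if (!is.null(override)) return(override)
  if (which == "rois_per_patient_range") {
    if (class == "benign") c(5L, 22L) else c(4L, 19L)
  } else {
    if (class == "benign") c(3L, 39L) else c(3L, 162L)
  }
}

# integer draw, log-uniform over [lo, hi] (right-skewed like ROI/pixel counts)
rlogunif_int <- function(n, lo, hi) {
  pmin(hi, pmax(lo, as.integer(round(exp(stats::runif(n, log(lo), log(hi)))))))
}

# sum of Gaussian peaks evaluated on an axis, each only within +/- 5 sigma
gaussian_mixture <- function(axis, mzs, heights, fwhm) {
  out <- numeric(length(axis))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  for (i in seq_along(mzs)) {
    lo <- findInterval(mzs[i] - 5 * sigma, axis) + 1L
    hi <- findInterval(mzs[i] + 5 * sigma, axis)
    if (hi < lo) next
    idx <- lo:hi
    out[idx] <- out[idx] +
      heights[i] * exp(-(axis[idx] - mzs[i])^2 / (2 * sigma^2))
  }
  out
}

lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# broad low-mass colloid/blood-like bumps for non-thyrocyte pixels
background_template <- function(axis, boost = 1) {
  gaussian_mixture(axis, c(3450, 4700, 6300), boost * c(60, 45, 30),
                   fwhm = 400)
}

# pack ROI pixel blocks onto a grid with 1-pixel gutters; returns a list of
# integer (x, y) matrices, one per ROI
layout_rois <- function(pixel_counts) {
  total <- sum(pixel_counts)
  row_width <- max(8L, ceiling(sqrt(total * 2)))
  blocks <- vector("list", length(pixel_counts))
  cur_x <- 1L; cur_y <- 1L; row_h <- 0L
  for (i in seq_along(pixel_counts)) {
    npx <- pixel_counts[i]
    w <- ceiling(sqrt(npx)); h <- ceiling(npx / w)
    if (cur_x + w > row_width + 1L && cur_x > 1L) {
      cur_x <- 1L
      cur_y <- cur_y + row_h + 1L
      row_h <- 0L
    }
    cells <- cbind(x = cur_x + ((seq_len(npx) - 1L) %% w),
                   y = cur_y + ((seq_len(npx) - 1L) %/% w))
    blocks[[i]] <- cells
    cur_x <- cur_x + w + 1L
    row_h <- max(row_h, h)
  }
  blocks
}

draw_private_peaks <- function(n, panel, mz_range) {
  if (n == 0L) {
    return(cbind(mz = numeric(0), height = numeric(0)))
  }
  known <- c(panel$shared_peaks[, "mz"], panel$benign_peaks[, "mz"],
             panel$malignant_peaks[, "mz"])
  mzs <- numeric(0)
  guard <- 0L
  while (length(mzs) < n && guard < 1000L) {
    cand <- stats::runif(1, mz_range[1] + 200, mz_range[2] - 1000)
    if (all(abs(cand - c(known, mzs)) > 300)) mzs <- c(mzs, cand)
    guard <- guard + 1L
  }
  cbind(mz = mzs, height = stats::runif(length(mzs), 40, 90))
}

# one patient's specimen; `pixel_class` decides the template per thyrocyte
# pixel and is what the challenge scenarios override
simulate_specimen <- function(patient_id, class, config,
                              roi_pixel_counts = NULL,
                              roi_pixel_class = NULL,
                              background_fraction = config$background_fraction,
                              background_n = NULL,
                              background_boost = 1,
                              specimen_suffix = "") {
  panel <- config$panel
  rr <- class_range(config, "rois_per_patient_range", class)
  pr <- class_range(config, "pixels_per_roi_range", class)
  if (is.null(roi_pixel_counts)) {
    n_rois <- rlogunif_int(1, rr[1], rr[2])
    roi_pixel_counts <- rlogunif_int(n_rois, pr[1], pr[2])
  }
  n_rois <- length(roi_pixel_counts)
  blocks <- layout_rois(roi_pixel_counts)
  n_thyro <- sum(roi_pixel_counts)
  # per-class pixel labels inside ROIs (all `class` unless overridden)
  if (is.null(roi_pixel_class)) {
    roi_pixel_class <- lapply(roi_pixel_counts, function(k) rep(class, k))
  }

  # patient-level draws
  jitter <- stats::runif(1, -config$mass_jitter_ppm, config$mass_jitter_ppm)
  axis <- seq(config$mz_range[1], config$mz_range[2],
              length.out = config$axis_points) * (1 + jitter * 1e-6)
  hfac <- function(m) {
    m[, "height"] * lognormal_factor(nrow(m), config$peak_height_cv)
  }
  sh_h <- hfac(panel$shared_peaks)
  be_h <- hfac(panel$benign_peaks)
  ma_h <- hfac(panel$malignant_peaks)
  priv <- draw_private_peaks(config$n_private_peaks, panel, config$mz_range)
  fwhm <- panel$peak_fwhm_da
  base_sig <- gaussian_mixture(axis, panel$shared_peaks[, "mz"], sh_h, fwhm) +
    if (nrow(priv)) gaussian_mixture(axis, priv[, "mz"], priv[, "height"],
                                     fwhm) else 0
  templates <- list(
    benign = base_sig +
      gaussian_mixture(axis, panel$benign_peaks[, "mz"], be_h, fwhm) +
      gaussian_mixture(axis, panel$malignant_peaks[, "mz"],
                       ma_h / panel$fold_change, fwhm),
    malignant = base_sig +
      gaussian_mixture(axis, panel$benign_peaks[, "mz"],
                       be_h / panel$fold_change, fwhm) +
      gaussian_mixture(axis, panel$malignant_peaks[, "mz"], ma_h, fwhm),
    background = background_template(axis, boost = background_boost))
  baseline <- config$baseline_amplitude * exp(-(axis - axis[1]) / 3000)

  # background pixels fill empty cells of the bounding box
  all_cells <- do.call(rbind, blocks)
  n_bg <- if (!is.null(background_n)) {
    as.integer(background_n)
  } else if (background_fraction > 0) {
    round(background_fraction / (1 - background_fraction) * n_thyro)
  } else 0L
  w <- max(all_cells[, "x"]); h <- max(all_cells[, "y"])
  occupied <- coord_key(all_cells[, "x"], all_cells[, "y"])
  while (w * h - n_thyro < n_bg) w <- w + 2L
  grid <- expand.grid(x = seq_len(w), y = seq_len(h))
  free <- grid[!(coord_key(grid$x, grid$y) %in% occupied), , drop = FALSE]
  bg_cells <- if (n_bg > 0) {
    free[sample.int(nrow(free), n_bg), , drop = FALSE]
  } else free[0, , drop = FALSE]

  specimen_id <- paste0(patient_id, specimen_suffix)
  make_spec <- function(x, y, template) {
    t_mult <- lognormal_factor(1, config$tic_variation_cv)
    raw <- t_mult * (template + baseline)
    if (config$noise_sd > 0) {
      raw <- raw + stats::rnorm(length(axis), 0, config$noise_sd)
    }
    pixel_spectrum(x, y, axis, pmax(0, raw))
  }
  spectra <- vector("list", n_thyro + nrow(bg_cells))
  labels <- character(n_thyro + nrow(bg_cells))
  xs <- integer(length(spectra)); ys <- integer(length(spectra))
  k <- 0L
  rois <- vector("list", n_rois)
  for (i in seq_len(n_rois)) {
    cells <- blocks[[i]]
    cls <- roi_pixel_class[[i]]
    for (j in seq_len(nrow(cells))) {
      k <- k + 1L
      spectra[[k]] <- make_spec(cells[j, "x"], cells[j, "y"],
                                templates[[cls[j]]])
      labels[k] <- paste0("thyrocyte_", cls[j])
      xs[k] <- cells[j, "x"]; ys[k] <- cells[j, "y"]
    }
    rois[[i]] <- roi_annotation(
      roi_id = sprintf("%s_roi%02d", specimen_id, i),
      specimen_id = specimen_id,
      pixels = cells,
      cell_cluster_count = sample(1:3, 1),
      cells_per_cluster_min = 10L)
  }
  if (nrow(bg_cells)) {
    for (j in seq_len(nrow(bg_cells))) {
      k <- k + 1L
      spectra[[k]] <- make_spec(bg_cells$x[j], bg_cells$y[j],
                                templates$background)
      labels[k] <- "background"
      xs[k] <- bg_cells$x[j]; ys[k] <- bg_cells$y[j]
    }
  }
  cytology <- if (class == "benign") "Thy2" else "Thy5"
  dataset <- msi_dataset(specimen_id = specimen_id, patient_id = patient_id,
                         spectra = spectra, cytology_class = cytology,
                         origin = "in_vivo", mode = "continuous")
  list(dataset = dataset, rois = rois,
       pixel_labels = data.frame(x = xs, y = ys, label = labels),
       class = class)
}

#' Simulate a full synthetic cohort
#'
#' Generates one standard-scenario specimen per patient for
#' `n_benign_patients` benign and `n_malignant_patients` malignant
#' patients, with pathologist-style ROI annotations over the thyrocyte
#' pixel blocks and a ground-truth record. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [synthetic_config] (`scenario` must be `"standard"`).
#' @return List with `datasets` (list of [msi_dataset]), `rois` (list of
#'   ROI lists, parallel to `datasets`), and `truth`: a list with
#'   `specimen_class` (named vector), `discriminant` (data frame `mz`,
#'   `direction` in `up_benign`/`up_malignant`) and `pixel_labels` (per
#'   specimen, data frame `x`, `y`, `label`).
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$scenario != "standard") {
    stop("simulate_cohort requires scenario = \"standard\"; ",
         "use make_challenge_specimen() for the others")
  }
  set.seed(config$seed)
  ids <- c(sprintf("B%02d", seq_len(config$n_benign_patients)),
           sprintf("M%02d", seq_len(config$n_malignant_patients)))
  classes <- rep(c("benign", "malignant"),
                 c(config$n_benign_patients, config$n_malignant_patients))
  sims <- mapply(function(id, cl) simulate_specimen(id, cl, config),
                 ids, classes, SIMPLIFY = FALSE)
  truth <- list(
    specimen_class = stats::setNames(classes, ids),
    discriminant = rbind(
      data.frame(mz = config$panel$benign_peaks[, "mz"],
                 direction = "up_benign"),
      data.frame(mz = config$panel$malignant_peaks[, "mz"],
                 direction = "up_malignant")),
    pixel_labels = stats::setNames(lapply(sims, `[[`, "pixel_labels"), ids))
  list(datasets = stats::setNames(lapply(sims, `[[`, "dataset"), ids),
       rois = stats::setNames(lapply(sims, `[[`, "rois"), ids),
       truth = truth)
}

#' Simulate a challenge specimen
#'
#' Builds one malignant specimen under a challenge scenario:
#' `"paucicellular"` keeps at most 10% of the standard malignant thyrocyte
#' pixel count; `"heterogeneous_mixture"` interleaves malignant thyrocytes
#' with at least 70% benign thyrocytes inside the same ROIs;
#' `"colloid_rich"` surrounds the thyrocytes with at least 70% background
#' pixels carrying an elevated broad background signal.
#'
#' @param config A [synthetic_config] with `scenario != "standard"`.
#' @param patient_id Identifier (default `"C01"`).
#' @return List with `dataset`, `rois`, `pixel_labels`, and
#'   `standard_thyrocyte_count` (the pre-modification count used by the
#'   paucicellular scaling).
#' @export
make_challenge_specimen <- function(config, patient_id = "C01") {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$scenario == "standard") {
    stop("make_challenge_specimen requires a non-standard scenario")
  }
  set.seed(config$seed)
  rr <- class_range(config, "rois_per_patient_range", "malignant")
  pr <- class_range(config, "pixels_per_roi_range", "malignant")
  n_rois <- rlogunif_int(1, rr[1], rr[2])
  std_counts <- rlogunif_int(n_rois, pr[1], pr[2])
  std_total <- sum(std_counts)

  if (config$scenario == "paucicellular") {
    target <- max(1L, floor(0.1 * std_total))
    counts <- pmax(1L, floor(0.1 * std_counts))
    if (sum(counts) > target) {
      counts <- counts[seq_len(max(1L, min(length(counts), target)))]
      while (sum(counts) > target && any(counts > 1L)) {
        i <- which.max(counts); counts[i] <- counts[i] - 1L
      }
    }
    # a paucicellular aspirate covers the same cytospin footprint as an
    # adequate one: the thyrocyte count collapses but the non-thyrocyte
    # background (blood, inflammation, colloid) stays at its standard
    # absolute level, so background pixels dominate the distribution
    bg_n <- if (config$background_fraction > 0) {
      max(0L, round(std_total / (1 - config$background_fraction)) -
            sum(counts))
    } else NULL
    sim <- simulate_specimen(patient_id, "malignant", config,
                             roi_pixel_counts = counts,
                             background_n = bg_n,
                             specimen_suffix = "_pauci")
  } else if (config$scenario == "heterogeneous_mixture") {
    n_mal <- floor(0.25 * std_total)
    # deal malignant pixels round-robin across ROIs, interleaved within each
    per_roi <- integer(n_rois)
    i <- 1L
    while (sum(per_roi) < n_mal) {
      if (per_roi[i] < std_counts[i]) per_roi[i] <- per_roi[i] + 1L
      i <- i %% n_rois + 1L
    }
    pixel_class <- lapply(seq_len(n_rois), function(i) {
      cls <- rep("benign", std_counts[i])
      if (per_roi[i] > 0L) {
        idx <- unique(round(seq(1, std_counts[i], length.out = per_roi[i])))
        cls[idx] <- "malignant"
      }
      cls
    })
    sim <- simulate_specimen(patient_id, "malignant", config,
                             roi_pixel_counts = std_counts,
                             roi_pixel_class = pixel_class,
                             specimen_suffix = "_hetero")
  } else {  # colloid_rich
    sim <- simulate_specimen(patient_id, "malignant", config,
                             roi_pixel_counts = std_counts,
                             background_fraction = 0.8,
                             background_boost = 3,
                             specimen_suffix = "_colloid")
  }
  list(dataset = sim$dataset, rois = sim$rois,
       pixel_labels = sim$pixel_labels,
       standard_thyrocyte_count = std_total)
}
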