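make_uniform_dataset <- function(n_pixels = 6, n_points = 400, value = NULL,
                                 seed = 501) {
  set.seed(seed)
  axis <- seq(3000, 20000, length.out = n_points)
  base <- if (is.null(value)) abs(rnorm(n_points, 20, 5)) else value
  spectra <- lapply(seq_len(n_pixels), function(i) {
    pixel_spectrum(i, 1, axis, base)
  })
  msi_dataset("U1", "U1", spectra)
}

test_that("the ROI mean of identical pixels equals any member profile", {
  d <- make_uniform_dataset()
  roi <- roi_annotation("r1", "U1", cbind(1:6, 1))
  m <- roi_mean_spectrum(d, roi)
  single <- process_profile(d$spectra[[1]])
  expect_equal(m$intensity, single$intensity, tolerance = 1e-12)
  expect_identical(attr(m, "n_pixels"), 6L)
})

test_that("a two-pixel ROI mean is the pointwise average of the profiles", {
  axis <- seq(3000, 20000, length.out = 300)
  set.seed(502)
  a <- pixel_spectrum(1, 1, axis, abs(rnorm(300, 30, 8)))
  b <- pixel_spectrum(2, 1, axis, abs(rnorm(300, 10, 3)))
  d <- msi_dataset("S1", "P1", list(a, b))
  roi <- roi_annotation("r1", "S1", rbind(c(1, 1), c(2, 1)))
  m <- roi_mean_spectrum(d, roi)
  pa <- process_profile(a); pb <- process_profile(b)
  expect_equal(m$intensity, (pa$intensity + pb$intensity) / 2,
               tolerance = 1e-12)
})

test_that("empty pixels are excluded and all-empty ROIs are inadequate", {
  axis <- seq(3000, 20000, length.out = 300)
  set.seed(503)
  live <- pixel_spectrum(1, 1, axis, abs(rnorm(300, 20, 5)))
  dead <- pixel_spectrum(2, 1, axis, numeric(300))
  d <- msi_dataset("S1", "P1", list(live, dead))
  roi <- roi_annotation("r1", "S1", rbind(c(1, 1), c(2, 1)))
  m <- roi_mean_spectrum(d, roi)
  expect_identical(attr(m, "n_pixels"), 1L)
  expect_equal(m$intensity, process_profile(live)$intensity)
  dead_roi <- roi_annotation("r2", "S1", rbind(c(2, 1)))
  expect_error(roi_mean_spectrum(d, dead_roi),
               class = "msiTriage_inadequate_roi")
})

test_that("averaging replicates reduces residual noise by about sqrt(n)", {
  set.seed(504)
  axis <- seq(3000, 20000, length.out = 1000)
  sigma <- 40 / (2 * sqrt(2 * log(2)))
  clean <- 50 * exp(-(axis - 8000)^2 / (2 * sigma^2))
  make_noisy <- function(i) {
    pixel_spectrum(i, 1, axis, pmax(0, clean + rnorm(1000, 0, 3)))
  }
  d <- msi_dataset("S1", "P1", lapply(1:10, make_noisy))
  roi10 <- roi_annotation("all", "S1", cbind(1:10, 1))
  m10 <- roi_mean_spectrum(d, roi10)
  p1 <- process_profile(d$spectra[[1]])
  ref <- tic_normalize(smooth_spectrum(subtract_baseline(
    pixel_spectrum(1, 1, axis, clean))))
  # off-peak residual noise, single pixel vs 10-pixel mean
  off <- axis < 6000 | axis > 10000
  sd1 <- stats::sd((p1$intensity - ref$intensity)[off])
  sd10 <- stats::sd((m10$intensity - ref$intensity)[off])
  expect_lt(abs(sd1 / sd10 - sqrt(10)) / sqrt(10), 0.2)
})

test_that("equivalent grouping is a balanced, capped, exact partition", {
  mk_rois <- function(counts) {
    lapply(seq_along(counts), function(i) {
      roi_annotation(sprintf("r%02d", i), "S1",
                     cbind(seq_len(counts[i]), i))
    })
  }
  # 5 ROIs into 5 groups: singletons
  g5 <- make_equivalent_groups(mk_rois(rep(4, 5)), 5, seed = 1)
  expect_identical(vapply(g5, function(g) length(g$roi_ids), integer(1)),
                   rep(1L, 5))
  # 9 equal ROIs into 5 groups: sizes 2,2,2,2,1
  g9 <- make_equivalent_groups(mk_rois(rep(3, 9)), 5, seed = 1)
  expect_identical(sort(vapply(g9, function(g) length(g$roi_ids),
                               integer(1))), c(1L, 2L, 2L, 2L, 2L))
  # 22 ROIs into 5 groups: cap respected, exact partition
  set.seed(505)
  counts <- sample(3:40, 22, replace = TRUE)
  rois22 <- mk_rois(counts)
  g22 <- make_equivalent_groups(rois22, 5, seed = 2)
  sizes <- vapply(g22, function(g) length(g$roi_ids), integer(1))
  expect_true(all(sizes >= 1 & sizes <= 7))
  all_ids <- unlist(lapply(g22, `[[`, "roi_ids"))
  expect_setequal(all_ids, vapply(rois22, function(r) r$roi_id, character(1)))
  expect_identical(anyDuplicated(all_ids), 0L)
  # balance: totals within the largest single ROI of each other
  totals <- vapply(g22, `[[`, numeric(1), "pixel_total")
  expect_lte(max(totals) - min(totals), max(counts))
  # determinism given seed
  g22b <- make_equivalent_groups(rois22, 5, seed = 2)
  expect_identical(g22, g22b)
  expect_error(make_equivalent_groups(mk_rois(rep(2, 40)), 5, seed = 1),
               "cannot fit")
  expect_message(make_equivalent_groups(mk_rois(rep(2, 3)), 5, seed = 1),
                 "using 3 groups")
})

test_that("the intra-patient filter matches brute-force counting", {
  set.seed(506)
  for (r in 1:20) {
    n_pat <- sample(3:8, 1)
    rois_per <- sample(2:8, n_pat, replace = TRUE)
    n_obs <- sum(rois_per)
    p <- 30
    detected <- matrix(rbinom(n_obs * p, 1, 0.35), nrow = n_obs)
    intens <- detected * matrix(runif(n_obs * p), nrow = n_obs)
    patient_of <- rep(sprintf("P%02d", seq_len(n_pat)), rois_per)
    fm <- feature_matrix(sprintf("o%03d", seq_len(n_obs)),
                         seq(3000, by = 100, length.out = p),
                         intens, detected, patient_of = patient_of)
    frac <- runif(1, 0.1, 0.6)
    got <- intra_patient_filter(fm, frac)
    expect_identical(unname(got$presence),
                     oracle_intra_filter(detected, patient_of, frac))
  }
})

test_that("intra-patient boundary: 1 detection in 4 ROIs passes at 25%", {
  detected <- rbind(c(1L, 0L), c(0L, 0L), c(0L, 0L), c(0L, 0L))
  fm <- feature_matrix(paste0("o", 1:4), c(5000, 6000),
                       detected * 0.5, detected,
                       patient_of = rep("P1", 4))
  got <- intra_patient_filter(fm, 0.25)
  expect_identical(unname(got$presence[1, ]), c(1L, 0L))
})

test_that("the inter-patient filter implements the union reading", {
  patients <- c(sprintf("B%d", 1:9), sprintf("M%d", 1:9))
  pres <- matrix(0L, nrow = 18, ncol = 3,
                 dimnames = list(patients, NULL))
  pres[1:3, 1] <- 1L            # 3/9 benign (33%), 0 malignant
  pres[c(1:2, 10:11), 2] <- 1L  # 2/9 in each class (22%)
  pres[c(1:5, 10:14), 3] <- 1L  # majority in both
  pp <- list(patients = patients, feature_mz = c(5000, 6000, 7000),
             presence = pres)
  got <- inter_patient_filter(pp, patients[1:9], patients[10:18], 0.25)
  expect_identical(got, c(5000, 7000))
  both <- inter_patient_filter(pp, patients[1:9], patients[10:18], 0.25,
                               mode = "intersection")
  expect_identical(both, 7000)
  all_kept <- inter_patient_filter(pp, patients[1:9], patients[10:18], 0)
  expect_identical(all_kept, c(5000, 6000, 7000))
  pres0 <- pres; pres0[] <- 0L
  pp0 <- list(patients = patients, feature_mz = pp$feature_mz,
              presence = pres0)
  expect_error(inter_patient_filter(pp0, patients[1:9], patients[10:18]),
               "no representative features")
})

test_that("both prevalence filters agree with brute force on random inputs", {
  set.seed(507)
  for (r in 1:20) {
    n_b <- sample(4:10, 1); n_m <- sample(4:10, 1)
    p <- sample(10:40, 1)
    patients <- c(sprintf("B%02d", seq_len(n_b)),
                  sprintf("M%02d", seq_len(n_m)))
    pres <- matrix(rbinom((n_b + n_m) * p, 1, 0.3),
                   nrow = n_b + n_m, dimnames = list(patients, NULL))
    mz <- seq(3000, by = 50, length.out = p)
    pp <- list(patients = patients, feature_mz = mz, presence = pres)
    frac <- runif(1, 0.05, 0.5)
    want_idx <- oracle_inter_filter(pres, seq_len(n_b),
                                    n_b + seq_len(n_m), frac)
    if (length(want_idx) == 0) {
      expect_error(inter_patient_filter(pp, patients[seq_len(n_b)],
                                        patients[n_b + seq_len(n_m)], frac))
    } else {
      got <- inter_patient_filter(pp, patients[seq_len(n_b)],
                                  patients[n_b + seq_len(n_m)], frac)
      expect_identical(got, mz[want_idx])
    }
  }
})

test_that("filters are monotone: raising the threshold never adds features", {
  set.seed(508)
  patients <- sprintf("P%02d", 1:12)
  pres <- matrix(rbinom(12 * 25, 1, 0.4), nrow = 12,
                 dimnames = list(patients, NULL))
  pp <- list(patients = patients, feature_mz = seq_len(25) * 100 + 3000,
             presence = pres)
  kept <- lapply(c(0, 0.1, 0.25, 0.5, 0.8), function(f) {
    tryCatch(inter_patient_filter(pp, patients[1:6], patients[7:12], f),
             error = function(e) numeric(0))
  })
  for (i in seq_along(kept)[-1]) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
})

test_that("the default study design yields 45 benign and 36 malignant observations", {
  cfg <- synthetic_config(rois_per_patient_range = c(5, 9),
                          pixels_per_roi_range = c(3, 8),
                          axis_points = 800, seed = 509)
  sim <- simulate_cohort(cfg)
  tr <- train_cohort(sim$datasets, sim$rois, sim$truth$specimen_class,
                     seed = 509)
  expect_identical(sum(tr$training_matrix$labels == "benign"), 45L)
  expect_identical(sum(tr$training_matrix$labels == "malignant"), 36L)
  # single patient, single group of one ROI: observation equals projection
  one <- sim$datasets[["B01"]]
  roi1 <- sim$rois[["B01"]][[1]]
  g1 <- make_equivalent_groups(list(roi1), 1, seed = 1)
  fm1 <- group_mean_observations(one, list(roi1), g1, tr$grid)
  prof <- roi_mean_spectrum(one, roi1)
  pl <- filter_low_intensity(pick_peaks(prof))
  proj <- project_onto_grid(pl, tr$grid)
  expect_equal(unname(fm1$intensities[1, ]), proj$intensity)
})

test_that("adequacy follows the six-clusters-of-ten rule with NA for missing data", {
  mk <- function(n, clusters = 1L, cells = 10L) {
    lapply(seq_len(n), function(i) {
      roi_annotation(paste0("r", i), "S1", rbind(c(i, 1)),
                     cell_cluster_count = clusters,
                     cells_per_cluster_min = cells)
    })
  }
  expect_true(adequacy_check(mk(6)))
  expect_false(adequacy_check(mk(5)))
  expect_true(adequacy_check(mk(3, clusters = 2L)))
  expect_false(adequacy_check(mk(8, cells = 9L)))
  bare <- lapply(1:6, function(i) {
    roi_annotation(paste0("r", i), "S1", rbind(c(i, 1)))
  })
  expect_true(is.na(suppressMessages(adequacy_check(bare))))
  # metadata-rich ROIs already adequate: missing metadata elsewhere is moot
  expect_true(suppressMessages(adequacy_check(c(mk(6), bare[1]))))
})
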