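test_that("the same seed reproduces a cohort exactly", {
  a <- simulate_cohort(tiny_config(seed = 7))
  b <- simulate_cohort(tiny_config(seed = 7))
  expect_identical(a, b)
  c2 <- simulate_cohort(tiny_config(seed = 8))
  expect_false(identical(a$datasets, c2$datasets))
})

test_that("the noise-free limit makes all same-class pixels identical", {
  cfg <- tiny_config(seed = 9, noise_sd = 0, baseline_amplitude = 0,
                     tic_variation_cv = 0, mass_jitter_ppm = 0,
                     peak_height_cv = 0, n_private_peaks = 0,
                     background_fraction = 0)
  sim <- simulate_cohort(cfg)
  for (id in names(sim$datasets)) {
    ints <- lapply(sim$datasets[[id]]$spectra, `[[`, "intensity")
    for (v in ints[-1]) expect_identical(v, ints[[1]])
  }
  # and across patients of one class (no jitter, no patient effects)
  b1 <- sim$datasets[["B01"]]$spectra[[1]]
  b2 <- sim$datasets[["B02"]]$spectra[[1]]
  expect_identical(b1$intensity, b2$intensity)
  m1 <- sim$datasets[["M01"]]$spectra[[1]]
  expect_false(identical(b1$intensity, m1$intensity))
})

test_that("generated cohorts carry coherent ground truth and metadata", {
  sim <- simulate_cohort(tiny_config(seed = 10))
  expect_identical(length(sim$datasets), 4L)
  expect_identical(unname(sim$truth$specimen_class[c("B01", "M01")]),
                   c("benign", "malignant"))
  panel <- tiny_config()$panel
  expect_setequal(sim$truth$discriminant$mz,
                  c(panel$benign_peaks[, "mz"], panel$malignant_peaks[, "mz"]))
  for (id in names(sim$datasets)) {
    d <- sim$datasets[[id]]
    expect_identical(d$cytology_class,
                     if (startsWith(id, "B")) "Thy2" else "Thy5")
    labs <- sim$truth$pixel_labels[[id]]
    expect_identical(nrow(labs), length(d$spectra))
    # every ROI pixel exists in the dataset and is a thyrocyte
    for (roi in sim$rois[[id]]) {
      expect_silent(validate_roi(roi, d))
      keys <- paste(roi$pixels[, 1], roi$pixels[, 2])
      lab <- labs$label[match(keys, paste(labs$x, labs$y))]
      expect_true(all(startsWith(lab, "thyrocyte")))
    }
  }
})

test_that("every generated dataset survives an imzML round-trip", {
  sim <- simulate_cohort(tiny_config(seed = 11))
  dir <- withr::local_tempdir()
  d <- sim$datasets[[1]]
  path <- file.path(dir, "b01.imzML")
  write_imzml(d, path)
  d2 <- read_imzml(path)
  expect_setequal(names(d2$spectra), names(d$spectra))
  k <- names(d$spectra)[5]
  expect_equal(d2$spectra[[k]]$intensity, d$spectra[[k]]$intensity,
               tolerance = 1e-6)
})

test_that("planted class peaks are detected in nearly all pixels of their class", {
  cfg <- synthetic_config(n_benign_patients = 3, n_malignant_patients = 3,
                          rois_per_patient_range = c(3, 5),
                          pixels_per_roi_range = c(3, 10),
                          axis_points = 2000, seed = 12)
  sim <- simulate_cohort(cfg)
  panel <- cfg$panel
  for (cls in c("benign", "malignant")) {
    own <- if (cls == "benign") panel$benign_peaks[, "mz"]
           else panel$malignant_peaks[, "mz"]
    ids <- names(sim$truth$specimen_class)[sim$truth$specimen_class == cls]
    hit <- 0L; tot <- 0L
    for (id in ids) {
      d <- sim$datasets[[id]]
      labs <- sim$truth$pixel_labels[[id]]
      thy <- labs[startsWith(labs$label, "thyrocyte"), ]
      for (i in seq_len(nrow(thy))) {
        s <- d$spectra[[paste0(thy$x[i], ",", thy$y[i])]]
        pl <- process_spectrum(s)
        tot <- tot + length(own)
        hit <- hit + sum(vapply(own, function(m) {
          any(abs(pl$peaks$mz - m) / m * 1e6 <= 2000)
        }, logical(1)))
      }
    }
    expect_gte(hit / tot, 0.95)
  }
})

test_that("challenge scenarios meet their construction contracts", {
  base <- tiny_config(seed = 13)

  pc <- synthetic_config(n_benign_patients = 2, n_malignant_patients = 2,
                         rois_per_patient_range = c(3, 4),
                         pixels_per_roi_range = c(8, 20),
                         axis_points = 800, seed = 13,
                         scenario = "paucicellular")
  ch <- make_challenge_specimen(pc)
  n_mal <- sum(ch$pixel_labels$label == "thyrocyte_malignant")
  expect_lte(n_mal, 0.1 * ch$standard_thyrocyte_count)
  expect_gte(n_mal, 1L)

  hc <- synthetic_config(n_benign_patients = 2, n_malignant_patients = 2,
                         rois_per_patient_range = c(3, 4),
                         pixels_per_roi_range = c(8, 20),
                         axis_points = 800, seed = 13,
                         scenario = "heterogeneous_mixture")
  hh <- make_challenge_specimen(hc)
  thy <- hh$pixel_labels[startsWith(hh$pixel_labels$label, "thyrocyte"), ]
  frac_mal <- mean(thy$label == "thyrocyte_malignant")
  expect_lte(frac_mal, 0.3)
  expect_gte(mean(thy$label == "thyrocyte_benign"), 0.7)

  cc <- synthetic_config(n_benign_patients = 2, n_malignant_patients = 2,
                         rois_per_patient_range = c(3, 4),
                         pixels_per_roi_range = c(8, 20),
                         axis_points = 800, seed = 13,
                         scenario = "colloid_rich")
  cr <- make_challenge_specimen(cc)
  expect_gte(mean(cr$pixel_labels$label == "background"), 0.7)

  expect_error(make_challenge_specimen(base), "non-standard")
  expect_error(simulate_cohort(pc), "standard")
})

test_that("noise-free cohorts are linearly separable in the planted features", {
  cfg <- synthetic_config(n_benign_patients = 3, n_malignant_patients = 3,
                          rois_per_patient_range = c(4, 5),
                          pixels_per_roi_range = c(3, 6),
                          axis_points = 1200, seed = 14,
                          noise_sd = 0, baseline_amplitude = 0,
                          tic_variation_cv = 0, mass_jitter_ppm = 0,
                          peak_height_cv = 0, n_private_peaks = 0)
  sim <- simulate_cohort(cfg)
  filters <- default_pipeline_config()$filters
  filters$groups_benign <- 3L
  filters$groups_malignant <- 3L
  tr <- suppressWarnings(
    train_cohort(sim$datasets, sim$rois, sim$truth$specimen_class,
                 filters = filters,
                 model_opts = list(cv_folds = 3L), seed = 14))
  # tiny penalty: refit at a small fixed lambda and check training accuracy 1
  small <- suppressWarnings(
    fit_lasso_logistic(tr$training_matrix, lambda = 1e-4, seed = 14))
  probs <- apply(tr$training_matrix$intensities, 1, function(v) {
    predict_probability(small$model, unname(v))
  })
  truth <- as.integer(tr$training_matrix$labels == "malignant")
  expect_identical(as.integer(probs > 0.5), truth)
})

test_that("raising the noise floor does not improve pixel-level separability", {
  skip_if_not_installed("pROC")
  aucs <- vapply(c(2, 30, 120), function(ns) {
    cfg <- synthetic_config(n_benign_patients = 3, n_malignant_patients = 3,
                            rois_per_patient_range = c(3, 4),
                            pixels_per_roi_range = c(4, 8),
                            axis_points = 1200, seed = 15, noise_sd = ns)
    sim <- simulate_cohort(cfg)
    tr <- suppressWarnings(
      train_cohort(sim$datasets, sim$rois, sim$truth$specimen_class,
                   filters = within(default_pipeline_config()$filters, {
                     groups_benign <- 3L; groups_malignant <- 3L
                   }),
                   model_opts = list(cv_folds = 3L), seed = 15))
    scores <- numeric(0); labels <- integer(0)
    for (id in names(sim$datasets)) {
      labs <- sim$truth$pixel_labels[[id]]
      thy <- labs[startsWith(labs$label, "thyrocyte"), ]
      d <- sim$datasets[[id]]
      for (i in seq_len(nrow(thy))) {
        s <- d$spectra[[paste0(thy$x[i], ",", thy$y[i])]]
        pl <- tryCatch(process_spectrum(s),
                       msiTriage_empty_pixel = function(e) NULL)
        if (is.null(pl)) next
        scores <- c(scores, predict_probability(
          tr$model, project_onto_grid(pl, tr$model$grid)))
        labels <- c(labels,
                    as.integer(thy$label[i] == "thyrocyte_malignant"))
      }
    }
    as.numeric(suppressMessages(pROC::auc(labels, scores, quiet = TRUE)))
  }, numeric(1))
  expect_true(all(diff(aucs) <= 1e-6))
  expect_gt(aucs[1], 0.99)
})
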