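test_that("baseline subtraction matches the brute-force running median", {
  set.seed(101)
  for (r in 1:25) {
    n <- sample(120:600, 1)
    hw <- sample(1:40, 1)
    if (n < 2 * hw + 1) hw <- (n - 1) %/% 2
    x <- abs(rnorm(n, 50, 20))
    s <- pixel_spectrum(1, 1, seq(3000, 9000, length.out = n), x)
    out <- subtract_baseline(s, hw)
    expect_identical(out$intensity, pmax(0, x - oracle_running_median(x, hw)))
    expect_identical(out$mz, s$mz)
  }
})

test_that("constant spectra have zero signal after baseline subtraction", {
  s <- pixel_spectrum(1, 1, seq(3000, 4000, length.out = 200), rep(7.5, 200))
  expect_true(all(subtract_baseline(s, 10)$intensity == 0))
})

test_that("a narrow peak on a constant offset survives a wide baseline window", {
  s <- planted_spectrum(mzs = 8000, heights = 100, fwhm = 40, n = 2000,
                        offset = 30)
  out <- subtract_baseline(s, 100)
  expect_gt(max(out$intensity), 99)  # apex preserved within 1%
  expect_lt(abs(max(out$intensity) - 100), 1)
})

test_that("baseline subtraction rejects spectra shorter than the window", {
  s <- pixel_spectrum(1, 1, seq(3000, 3100, length.out = 20), rnorm(20)^2)
  expect_error(subtract_baseline(s, 15), "too short")
})

test_that("smoothing equals the brute-force truncated moving average", {
  set.seed(102)
  for (r in 1:25) {
    n <- sample(50:500, 1)
    hw <- sample(1:8, 1)
    if (n < 2 * hw + 1) hw <- 1L
    x <- abs(rnorm(n, 10, 5))
    s <- pixel_spectrum(1, 1, seq(3000, 8000, length.out = n), x)
    expect_equal(smooth_spectrum(s, hw)$intensity, oracle_moving_average(x, hw),
                 tolerance = 1e-12)
  }
})

test_that("smoothing leaves constants unchanged and flattens an impulse to 1/5", {
  s <- pixel_spectrum(1, 1, seq(3000, 4000, length.out = 100), rep(3, 100))
  expect_equal(smooth_spectrum(s, 2)$intensity, rep(3, 100))
  imp <- numeric(101); imp[51] <- 1
  si <- pixel_spectrum(1, 1, seq(3000, 4000, length.out = 101), imp)
  sm <- smooth_spectrum(si, 2)$intensity
  expect_equal(sm[49:53], rep(1 / 5, 5))
  expect_equal(sm[48], 0)
})

test_that("TIC normalization scales to unit sum and flags empty pixels", {
  s <- pixel_spectrum(1, 1, c(3000, 3010, 3020), c(2, 3, 5))
  expect_equal(tic_normalize(s)$intensity, c(0.2, 0.3, 0.5))
  set.seed(103)
  r <- pixel_spectrum(1, 1, seq(3000, 5000, length.out = 300),
                      abs(rnorm(300)))
  expect_equal(sum(tic_normalize(r)$intensity), 1, tolerance = 1e-12)
  z <- pixel_spectrum(1, 1, c(3000, 3010, 3020), c(0, 0, 0))
  expect_error(tic_normalize(z), class = "msiTriage_empty_pixel")
})

test_that("noise estimation is a scaled MAD: calibrated, robust, zero on silence", {
  set.seed(104)
  x <- rnorm(4000)
  s <- pixel_spectrum(1, 1, seq(3000, 20000, length.out = 4000), abs(x))
  s$intensity <- x  # bypass non-negativity for the pure-noise check
  est <- estimate_noise(s)
  expect_gt(est, 0.9); expect_lt(est, 1.1)
  expect_identical(est, oracle_mad_noise(x))
  spiked <- x; spiked[2000] <- 1e6
  s2 <- s; s2$intensity <- spiked
  expect_lt(abs(estimate_noise(s2) - est) / est, 0.05)
  z <- pixel_spectrum(1, 1, seq(3000, 3100, length.out = 20), numeric(20))
  expect_identical(estimate_noise(z), 0)
})

test_that("peak picking matches a brute-force scan, including plateaus", {
  set.seed(105)
  for (r in 1:30) {
    n <- sample(60:400, 1)
    # coarse rounding forces plateaus and ties
    x <- round(abs(rnorm(n, 5, 3)), sample(0:1, 1))
    s <- pixel_spectrum(1, 1, seq(3000, 9000, length.out = n), x)
    noise <- 1.0
    got <- pick_peaks(s, snr_min = 3, noise = noise)
    want <- oracle_pick_peaks(x, noise, 3)
    expect_identical(got$peaks$mz, s$mz[want])
    expect_identical(got$peaks$intensity, x[want])
  }
})

test_that("the S/N threshold is inclusive at the boundary", {
  # two isolated triangular peaks with apexes 5.9 and 6.0 over unit noise
  x <- numeric(101)
  x[20 + (-1:1)] <- c(3, 5.9, 3)
  x[70 + (-1:1)] <- c(3, 6.0, 3)
  s <- pixel_spectrum(1, 1, seq(3000, 4000, length.out = 101), x)
  pl <- pick_peaks(s, snr_min = 6, noise = 1)
  expect_identical(nrow(pl$peaks), 1L)
  expect_equal(pl$peaks$intensity, 6.0)
  expect_equal(pl$peaks$snr, 6.0)
})

test_that("noise-free planted spectra yield exactly the planted peaks", {
  mzs <- c(4000, 6500, 9000, 12000, 16000)
  s <- planted_spectrum(mzs, heights = c(5, 8, 4, 7, 6))
  pl <- pick_peaks(s)  # noise estimate is 0 -> all positive maxima
  expect_identical(nrow(pl$peaks), 5L)
  expect_true(all(abs(pl$peaks$mz - mzs) < 15))
  z <- pixel_spectrum(1, 1, seq(3000, 3200, length.out = 50), numeric(50))
  expect_identical(nrow(pick_peaks(z, noise = 1)$peaks), 0L)
})

test_that("low-intensity filtering keeps the boundary and honors both rules", {
  pl <- peak_list("a", mz = c(5000, 6000, 7000),
                  intensity = c(0.0001, 0.0003, 0.0005))
  kept <- filter_low_intensity(pl)
  expect_equal(kept$peaks$intensity, c(0.0003, 0.0005))
  expect_equal(filter_low_intensity(pl, threshold = 0)$peaks$intensity,
               pl$peaks$intensity)
  literal <- filter_low_intensity(pl, rule = "below")
  expect_equal(literal$peaks$intensity, 0.0001)
  empty <- peak_list("b", numeric(0), numeric(0))
  expect_identical(nrow(filter_low_intensity(empty)$peaks), 0L)
})

test_that("alignment matches the brute-force gap clustering on random inputs", {
  set.seed(106)
  for (r in 1:25) {
    k <- sample(2:6, 1)
    mz_list <- lapply(seq_len(k), function(i) {
      sort(runif(sample(3:25, 1), 3000, 20000))
    })
    int_list <- lapply(mz_list, function(m) runif(length(m), 0.1, 5))
    tol <- sample(c(300, 1000, 2000, 5000), 1)
    pls <- lapply(seq_len(k), function(i) {
      peak_list(paste0("o", i), mz_list[[i]], int_list[[i]])
    })
    got <- align_peaks(pls, tolerance_ppm = tol)
    want <- oracle_align(mz_list, int_list, tol)
    expect_equal(got$grid$features, want$centers, tolerance = 1e-12)
    expect_equal(unname(got$matrix$intensities), want$matrix,
                 tolerance = 1e-12)
    expect_identical(unname(got$matrix$detected), want$detected)
  }
})

test_that("alignment splits or merges peaks according to the ppm tolerance", {
  pls <- list(peak_list("a", 8000.0, 2), peak_list("b", 8008.0, 6))
  expect_identical(length(align_peaks(pls, 500)$grid$features), 2L)
  merged <- align_peaks(pls, 2000)
  expect_identical(length(merged$grid$features), 1L)
  expect_equal(merged$grid$features, (8000 * 2 + 8008 * 6) / 8)
  single <- align_peaks(list(peak_list("a", c(5000, 9000), c(1, 2))), 2000)
  expect_equal(single$grid$features, c(5000, 9000))
  expect_equal(unname(single$matrix$intensities[1, ]), c(1, 2))
  expect_error(align_peaks(list(peak_list("a", numeric(0), numeric(0))), 2000),
               "no features")
})

test_that("alignment feature count is non-increasing in tolerance", {
  set.seed(107)
  pls <- lapply(1:5, function(i) {
    m <- sort(runif(20, 3000, 20000))
    peak_list(paste0("o", i), m, runif(20, 0.5, 2))
  })
  counts <- vapply(c(100, 500, 1000, 2000, 5000, 20000), function(tol) {
    length(align_peaks(pls, tol)$grid$features)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the full chain finds planted peaks and propagates empty pixels", {
  s <- planted_spectrum(c(5000, 8000, 12000), heights = c(60, 90, 40),
                        n = 2000, offset = 10)
  pl <- process_spectrum(s)
  hits <- vapply(c(5000, 8000, 12000), function(m) {
    any(abs(pl$peaks$mz - m) / m * 1e6 <= 2000)
  }, logical(1))
  expect_true(all(hits))
  expect_true(all(pl$peaks$intensity >= 0.0003))
  z <- pixel_spectrum(1, 1, seq(3000, 20000, length.out = 2000),
                      numeric(2000))
  expect_error(process_spectrum(z), class = "msiTriage_empty_pixel")
})

test_that("no processing operator produces negatives or NaN", {
  set.seed(108)
  for (r in 1:10) {
    s <- planted_spectrum(runif(3, 4000, 18000), heights = runif(3, 20, 80),
                          n = 600, noise_sd = 3, offset = 15)
    p <- process_profile(s)
    expect_false(any(p$intensity < 0))
    expect_false(anyNA(p$intensity))
    expect_equal(sum(p$intensity), 1, tolerance = 1e-12)
  }
})
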