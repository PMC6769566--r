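# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

oracle_running_median <- function(x, hw) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - hw):min(n, i + hw)])
  }, numeric(1))
}

oracle_moving_average <- function(x, hw) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - hw):min(n, i + hw)]
    sum(w) / length(w)
  }, numeric(1))
}

oracle_mad_noise <- function(x) {
  1.4826 * stats::median(abs(x - stats::median(x)))
}

# local maxima with plateaus resolved to their leftmost point, by scanning
oracle_local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

oracle_pick_peaks <- function(x, noise, snr_min) {
  idx <- oracle_local_maxima(x)
  if (noise > 0) idx[x[idx] / noise >= snr_min] else idx[x[idx] > 0]
}

# single-linkage gap clustering of pooled peaks, naive loop
oracle_align <- function(mz_list, int_list, tolerance_ppm) {
  obs <- rep(seq_along(mz_list), lengths(mz_list))
  mz <- unlist(mz_list); it <- unlist(int_list)
  o <- order(mz)
  mz <- mz[o]; it <- it[o]; obs <- obs[o]
  cl <- integer(length(mz))
  cl[1] <- 1L
  for (i in seq_along(mz)[-1]) {
    cl[i] <- if ((mz[i] - mz[i - 1]) / mz[i - 1] * 1e6 > tolerance_ppm) {
      cl[i - 1] + 1L
    } else cl[i - 1]
  }
  nf <- max(cl)
  centers <- vapply(seq_len(nf), function(k) {
    idx <- cl == k
    if (sum(it[idx]) > 0) sum(mz[idx] * it[idx]) / sum(it[idx])
    else mean(mz[idx])
  }, numeric(1))
  m <- matrix(0, nrow = length(mz_list), ncol = nf)
  d <- matrix(0L, nrow = length(mz_list), ncol = nf)
  for (i in seq_along(mz)) {
    m[obs[i], cl[i]] <- m[obs[i], cl[i]] + it[i]
    d[obs[i], cl[i]] <- 1L
  }
  list(centers = centers, matrix = m, detected = d)
}

oracle_intra_filter <- function(detected, patient_of, min_fraction) {
  patients <- unique(patient_of)
  unname(t(vapply(patients, function(p) {
    rows <- which(patient_of == p)
    counts <- integer(ncol(detected))
    for (r in rows) counts <- counts + detected[r, ]
    as.integer(counts / length(rows) >= min_fraction)
  }, integer(ncol(detected)))))
}

oracle_inter_filter <- function(presence, b_rows, m_rows, min_fraction,
                                union = TRUE) {
  keep <- logical(ncol(presence))
  for (j in seq_len(ncol(presence))) {
    fb <- sum(presence[b_rows, j]) / length(b_rows)
    fm <- sum(presence[m_rows, j]) / length(m_rows)
    keep[j] <- if (union) fb >= min_fraction || fm >= min_fraction
               else fb >= min_fraction && fm >= min_fraction
  }
  which(keep)
}

# FISTA proximal-gradient solver for the lasso-logistic objective
#   (1/n) * sum(log(1 + exp(-(2y-1) * (b0 + X b)))) + lambda * sum(|b|)
# with an unpenalized intercept; independent of glmnet.
oracle_lasso_logistic <- function(x, y, lambda, max_iter = 30000) {
  # centering the features is an exact reparameterization (the L1 term only
  # involves beta, which is unchanged); it decorrelates the intercept from
  # the features so the proximal gradient converges quickly
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  n <- nrow(x); p <- ncol(x)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  xa <- cbind(1, x)
  L <- max(eigen(crossprod(xa), symmetric = TRUE,
                 only.values = TRUE)$values) / (4 * n)
  step <- 1 / L
  beta <- numeric(p); b0 <- 0
  zb <- beta; zb0 <- b0; tk <- 1
  # FISTA is not monotone in the objective, so no early stopping: a fixed
  # iteration budget at this problem size converges far past 1e-6
  for (it in seq_len(max_iter)) {
    eta <- zb0 + drop(x %*% zb)
    pr <- 1 / (1 + exp(-eta))
    g <- (pr - y) / n
    b0_new <- zb0 - step * sum(g)
    beta_new <- soft(zb - step * drop(crossprod(x, g)), step * lambda)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zb0 <- b0_new + (tk - 1) / t_new * (b0_new - b0)
    zb <- beta_new + (tk - 1) / t_new * (beta_new - beta)
    b0 <- b0_new; beta <- beta_new; tk <- t_new
  }
  list(intercept = b0 - sum(mu * beta), beta = beta)
}

# quick synthetic profile with planted Gaussian peaks on a clean axis
planted_spectrum <- function(mzs, heights, fwhm = 40, n = 1200,
                             range = c(3000, 20000), noise_sd = 0,
                             offset = 0, x = 1, y = 1) {
  axis <- seq(range[1], range[2], length.out = n)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  sig <- offset + numeric(n)
  for (i in seq_along(mzs)) {
    sig <- sig + heights[i] * exp(-(axis - mzs[i])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) sig <- pmax(0, sig + stats::rnorm(n, 0, noise_sd))
  pixel_spectrum(x, y, axis, sig)
}

# small fast cohort configuration used across tests (not the study-scale
# default; unit tests only need structure, not power)
tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_benign_patients = 2, n_malignant_patients = 2,
                   rois_per_patient_range = c(3, 4),
                   pixels_per_roi_range = c(3, 6),
                   axis_points = 800, seed = seed, ...)
}
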