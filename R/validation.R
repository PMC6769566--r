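#' @title Specimen scoring and triage
#' @description A fitted malignancy model is applied to a new specimen in
#'   three modes: per-ROI (mean spectrum of each pathologist-selected ROI),
#'   whole-average (mean of every non-empty pixel, ignoring the
#'   morphological selection), and pixel-by-pixel. Each mode yields a set
#'   of probabilities summarized by quartiles; the triage call compares the
#'   3rd quartile against a benign and a malignant threshold, with an
#'   explicit indeterminate "alert" band between them rather than a forced
#'   binary call.
#' @name validation
NULL

#' Quartile summary of malignancy probabilities
#'
#' Quartiles use linear interpolation between order statistics (the common
#' "type 7" rule, R's default); the rule is exposed because threshold
#' statistics quoted on these summaries depend on it.
#'
#' @param probs Non-empty numeric vector of probabilities in \[0, 1\].
#' @param mode `"roi"`, `"whole_average"` or `"pixel"`.
#' @param specimen_id Optional specimen identifier carried in the summary.
#' @param type Quantile algorithm type passed to [stats::quantile()]
#'   (default 7).
#' @return An object of class `quartile_summary`: `n`, `q1`, `median`,
#'   `q3`, `mean`, `sd`, `mode`, `specimen_id`.
#' @export
summarize_quartiles <- function(probs, mode = c("roi", "whole_average",
                                                "pixel"),
                                specimen_id = NA_character_, type = 7) {
  mode <- match.arg(mode)
  if (length(probs) == 0L) stop("cannot summarize an empty probability list")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  q <- unname(stats::quantile(probs, c(0.25, 0.5, 0.75), type = type))
  structure(list(n = length(probs), q1 = q[1], median = q[2], q3 = q[3],
                 mean = mean(probs),
                 sd = if (length(probs) > 1L) stats::sd(probs) else NA_real_,
                 mode = mode, specimen_id = as.character(specimen_id)),
            class = "quartile_summary")
}

#' @export
print.quartile_summary <- function(x, ...) {
  cat(sprintf(
    "<quartile_summary %s [%s]: n = %d, q1 = %.4f, median = %.4f, q3 = %.4f>\n",
    x$specimen_id, x$mode, x$n, x$q1, x$median, x$q3))
  invisible(x)
}

#' Triage call from a quartile summary
#'
#' `q3 < low` calls the specimen benign, `q3 > high` malignant, and the
#' band in between raises `alert_indeterminate` — a signal that the
#' specimen needs pathologist review rather than an automated call. The
#' defaults (7% and 28%) are the observed training gap between the classes,
#' not a prescribed rule; they are configurable, and the raw q3 is always
#' reported alongside the call.
#'
#' @param summary A [summarize_quartiles()] result.
#' @param low,high Decision thresholds, `low < high` (defaults 0.07, 0.28).
#' @return An object of class `triage_decision`: `specimen_id`, `mode`,
#'   `call`, `q3`, `thresholds`.
#' @export
triage <- function(summary, low = 0.07, high = 0.28) {
  stopifnot(inherits(summary, "quartile_summary"))
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    stop("invalid thresholds: need low < high")
  }
  call <- if (summary$q3 < low) "benign"
          else if (summary$q3 > high) "malignant"
          else "alert_indeterminate"
  structure(list(specimen_id = summary$specimen_id,
                 mode = summary$mode,
                 call = call,
                 q3 = summary$q3,
                 thresholds = c(low = low, high = high)),
            class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("<triage %s [%s]: %s (q3 = %.4f; thresholds %.2f/%.2f)>\n",
              x$specimen_id, x$mode, x$call, x$q3,
              x$thresholds["low"], x$thresholds["high"]))
  invisible(x)
}

obs_probability <- function(model, profile, params) {
  pl <- pick_peaks(profile, snr_min = params$snr_min)
  pl <- filter_low_intensity(pl, params$intensity_threshold,
                             params$intensity_rule)
  predict_probability(model, project_onto_grid(pl, model$grid))
}

#' Score a specimen per ROI
#'
#' One probability per ROI, from its mean processed profile projected onto
#' the model's feature grid. ROIs whose pixels are all empty are skipped
#' with a warning; if every ROI is inadequate an error is raised.
#'
#' @param model A `malignancy_model`.
#' @param dataset An [msi_dataset].
#' @param rois List of [roi_annotation] objects on the dataset.
#' @param params A [preprocessing_params()] list.
#' @return List with `probabilities` (named by roi_id) and `summary`
#'   (a [summarize_quartiles()] over them, mode `"roi"`).
#' @export
classify_by_roi <- function(model, dataset, rois,
                            params = preprocessing_params()) {
  stopifnot(length(rois) >= 1L)
  probs <- numeric(0)
  for (roi in rois) {
    prof <- tryCatch(roi_mean_spectrum(dataset, roi, params),
                     msiTriage_inadequate_roi = function(e) {
                       warning(conditionMessage(e), call. = FALSE)
                       NULL
                     })
    if (is.null(prof)) next
    probs[roi$roi_id] <- obs_probability(model, prof, params)
  }
  if (length(probs) == 0L) {
    stop("all ROIs are inadequate: no pixels with signal")
  }
  list(probabilities = probs,
       summary = summarize_quartiles(probs, "roi",
                                     specimen_id = dataset$specimen_id))
}

#' Score a specimen by its whole-average spectrum
#'
#' Averages the processed profiles of every non-empty pixel — irrespective
#' of the pathologist's ROI selection — and scores the single mean
#' spectrum.
#'
#' @inheritParams classify_by_roi
#' @return A single probability of malignancy.
#' @export
classify_whole_average <- function(model, dataset,
                                   params = preprocessing_params()) {
  stopifnot(inherits(dataset, "msi_dataset"))
  acc <- NULL; n_ok <- 0L; ax <- NULL
  for (s in dataset$spectra) {
    p <- tryCatch(process_profile(s, params),
                  msiTriage_empty_pixel = function(e) NULL)
    if (is.null(p)) next
    if (is.null(acc)) {
      acc <- p$intensity; ax <- p$mz
    } else {
      if (length(p$mz) != length(ax) || any(p$mz != ax)) {
        stop("whole-average requires a shared m/z axis")
      }
      acc <- acc + p$intensity
    }
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L) stop("no non-empty pixels in specimen")
  prof <- pixel_spectrum(1L, 1L, ax, acc / n_ok)
  obs_probability(model, prof, params)
}

#' Score a specimen pixel by pixel
#'
#' Every non-empty pixel is processed and scored independently; pixels
#' without signal (zero total ion current) are masked, never scored — a
#' zero-probability score for an empty pixel would bias the specimen's
#' quartiles towards benign.
#'
#' @inheritParams classify_by_roi
#' @return List with `map` (a [probability_map]) and `summary`
#'   (a [summarize_quartiles()] over scored pixels, mode `"pixel"`).
#' @export
classify_pixelwise <- function(model, dataset,
                               params = preprocessing_params()) {
  stopifnot(inherits(dataset, "msi_dataset"))
  n <- length(dataset$spectra)
  xs <- integer(n); ys <- integer(n); ps <- numeric(n)
  ok <- logical(n)
  i <- 0L
  for (s in dataset$spectra) {
    i <- i + 1L
    xs[i] <- s$x; ys[i] <- s$y
    pl <- tryCatch(process_spectrum(s, params),
                   msiTriage_empty_pixel = function(e) NULL)
    if (is.null(pl)) next
    ps[i] <- predict_probability(model, project_onto_grid(pl, model$grid))
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("no non-empty pixels in specimen")
  map <- probability_map(
    dataset$specimen_id,
    entries = data.frame(x = xs[ok], y = ys[ok], probability = ps[ok]),
    masked = cbind(x = xs[!ok], y = ys[!ok]))
  list(map = map,
       summary = summarize_quartiles(ps[ok], "pixel",
                                     specimen_id = dataset$specimen_id))
}

#' Cohort-level triage report
#'
#' Collects per-specimen triage decisions and quartile summaries into one
#' table, adds confusion counts against the true classes when provided,
#' and reports per-class mean and sd of the 3rd quartiles.
#'
#' @param decisions List of [triage()] decisions.
#' @param summaries List of [summarize_quartiles()] results, parallel to
#'   `decisions`.
#' @param truth Optional named character vector mapping specimen_id to
#'   `"benign"`/`"malignant"`; when absent the report omits accuracy and
#'   confusion counts.
#' @return An object of class `cohort_report`: `table` (data frame
#'   specimen_id, mode, n, q3, call, truth), `q3_by_class` (per-class and
#'   per-mode mean/sd of q3), `confusion` and `accuracy` (when truth is
#'   given; calls of `alert_indeterminate` count as incorrect for accuracy
#'   but are tallied separately).
#' @export
cohort_report <- function(decisions, summaries, truth = NULL) {
  stopifnot(length(decisions) >= 1L, length(decisions) == length(summaries))
  tab <- do.call(rbind, lapply(seq_along(decisions), function(i) {
    d <- decisions[[i]]; s <- summaries[[i]]
    data.frame(specimen_id = d$specimen_id, mode = d$mode, n = s$n,
               q3 = d$q3, call = d$call, stringsAsFactors = FALSE)
  }))
  tab$truth <- if (is.null(truth)) NA_character_
               else unname(truth[tab$specimen_id])
  by_class <- NULL
  if (!is.null(truth)) {
    agg <- stats::aggregate(q3 ~ truth + mode, data = tab,
                            FUN = function(v) c(mean = mean(v),
                                                sd = stats::sd(v)))
    by_class <- data.frame(truth = agg$truth, mode = agg$mode,
                           mean_q3 = agg$q3[, "mean"], sd_q3 = agg$q3[, "sd"])
  }
  confusion <- NULL; accuracy <- NA_real_
  if (!is.null(truth)) {
    confusion <- table(truth = tab$truth, call = tab$call)
    accuracy <- mean(tab$call == tab$truth)
  }
  structure(list(table = tab, q3_by_class = by_class,
                 confusion = confusion, accuracy = accuracy),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort triage report\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$q3_by_class)) {
    cat("\n3rd-quartile statistics by class and mode:\n")
    print(x$q3_by_class, row.names = FALSE)
    cat(sprintf("\nAccuracy (exact call vs truth): %.3f\n", x$accuracy))
  }
  invisible(x)
}
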