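#' @title Pipeline orchestration
#' @description One configuration object drives the whole workflow:
#'   simulate (or read) a cohort, preprocess, build ROI features, filter,
#'   fit the malignancy model, validate in three modes, and report. Every
#'   random draw derives from the configured seed, so two runs with the
#'   same configuration produce byte-identical outputs.
#' @name pipeline_cli
NULL

#' Default pipeline configuration
#'
#' @param seed Master seed for the run (default 1).
#' @return Nested named list with blocks `paths` (input imzML directory,
#'   ROI JSON directory, output directory; all `NULL` for in-memory runs),
#'   `preprocessing` (see [preprocessing_params()]), `filters`
#'   (intra/inter fractions 0.25, inter mode `"union"`, 5 benign / 4
#'   malignant equivalent groups), `model` (5 CV folds), `triage`
#'   (thresholds 0.07 / 0.28), `adequacy` (policy `"flag"` or
#'   `"exclude"`), `validation` (5 + 5 standard synthetic specimens) and
#'   `synthetic` (a [synthetic_config]; set to `NULL` to read data from
#'   `paths` instead).
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(paths = list(input_dir = NULL, roi_dir = NULL, out_dir = NULL),
       preprocessing = preprocessing_params(),
       filters = list(intra_min_fraction = 0.25,
                      inter_min_fraction = 0.25,
                      inter_mode = "union",
                      groups_benign = 5L,
                      groups_malignant = 4L),
       model = list(cv_folds = 5L),
       triage = list(low = 0.07, high = 0.28),
       adequacy = list(policy = "flag"),
       validation = list(n_benign = 5L, n_malignant = 5L),
       synthetic = synthetic_config(seed = as.integer(seed)),
       seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_pipeline_config()] values.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  seed <- if (!is.null(user$seed)) as.integer(user$seed) else 1L
  cfg <- default_pipeline_config(seed = seed)
  merge_block <- function(base, over) {
    for (nm in names(over)) base[[nm]] <- over[[nm]]
    base
  }
  for (block in c("paths", "preprocessing", "filters", "model", "triage",
                  "adequacy", "validation")) {
    if (!is.null(user[[block]])) {
      cfg[[block]] <- merge_block(cfg[[block]], user[[block]])
    }
  }
  if (!is.null(user$synthetic)) {
    syn <- user$synthetic
    if (isFALSE(syn) || identical(syn, "none")) {
      cfg$synthetic <- NULL
    } else {
      syn$seed <- syn$seed %||% seed
      cfg$synthetic <- do.call(synthetic_config, syn)
    }
  }
  cfg
}

cytology_to_class <- function(cls) {
  switch(cls,
         Thy2 = "benign",
         Thy5 = "malignant",
         Metastasis = "malignant",
         NA_character_)
}

load_cohort_from_paths <- function(paths) {
  if (is.null(paths$input_dir) || is.null(paths$roi_dir)) {
    stop("config has no synthetic block and no input/ROI paths")
  }
  files <- sort(list.files(paths$input_dir, pattern = "\\.imzML$",
                           full.names = TRUE, ignore.case = TRUE))
  if (length(files) == 0L) stop("no imzML files in ", paths$input_dir)
  datasets <- lapply(files, read_imzml)
  ids <- vapply(datasets, function(d) d$specimen_id, character(1))
  names(datasets) <- ids
  rois <- lapply(ids, function(id) {
    rp <- file.path(paths$roi_dir, paste0(id, ".roi.json"))
    if (!file.exists(rp)) stop("no ROI file for specimen ", id)
    read_roi_annotations(rp)
  })
  names(rois) <- ids
  list(datasets = datasets, rois = rois, truth = NULL)
}

#' Train the malignancy model on a cohort
#'
#' The full training computation on in-memory data: per-ROI mean spectra,
#' peak alignment across all ROIs, intra- then inter-patient prevalence
#' filters, equivalent-group mean observations on the filtered grid, and
#' the cross-validated Lasso-logistic fit. Exposed separately from
#' [run_training()] so programmatic callers can skip file I/O.
#'
#' @param datasets Named list of [msi_dataset] objects (training
#'   specimens).
#' @param rois Named list (parallel to `datasets`) of ROI lists.
#' @param labels Named character vector specimen_id -> `"benign"` /
#'   `"malignant"`; every training specimen must be labelled.
#' @param params A [preprocessing_params()] list.
#' @param filters,model_opts,seed Blocks from the pipeline configuration
#'   (see [default_pipeline_config()]).
#' @return List with `model`, `cv`, `grid` (filtered training grid),
#'   `funnel` (feature counts: total aligned, after filters, selected),
#'   `roi_matrix` (per-ROI [feature_matrix]), `training_matrix` (the
#'   group-mean observations), and `groups` (per-specimen group
#'   assignments).
#' @export
train_cohort <- function(datasets, rois, labels,
                         params = preprocessing_params(),
                         filters = default_pipeline_config()$filters,
                         model_opts = list(cv_folds = 5L),
                         seed = 1L) {
  ids <- names(datasets)
  stopifnot(length(ids) >= 2L, identical(sort(ids), sort(names(rois))))
  if (is.null(labels) || anyNA(labels[ids])) {
    stop("every training specimen needs a benign/malignant label")
  }
  # per-ROI peak lists for alignment + filters
  peaklists <- list()
  roi_patient <- character(0)
  roi_label <- character(0)
  for (id in ids) {
    d <- datasets[[id]]
    for (roi in rois[[id]]) {
      prof <- roi_mean_spectrum(d, roi, params)
      pl <- pick_peaks(prof, snr_min = params$snr_min)
      pl <- filter_low_intensity(pl, params$intensity_threshold,
                                 params$intensity_rule)
      pl$source <- roi$roi_id
      peaklists[[roi$roi_id]] <- pl
      roi_patient[roi$roi_id] <- d$patient_id
      roi_label[roi$roi_id] <- labels[[id]]
    }
  }
  aligned <- align_peaks(unname(peaklists), tolerance_ppm = params$tolerance_ppm)
  fm_roi <- aligned$matrix
  fm_roi$patient_of <- unname(roi_patient[fm_roi$observation_ids])
  fm_roi$labels <- unname(roi_label[fm_roi$observation_ids])

  presence <- intra_patient_filter(fm_roi, filters$intra_min_fraction)
  pat_label <- vapply(presence$patients, function(p) {
    fm_roi$labels[match(p, fm_roi$patient_of)]
  }, character(1))
  kept_mz <- inter_patient_filter(
    presence,
    benign_ids = presence$patients[pat_label == "benign"],
    malignant_ids = presence$patients[pat_label == "malignant"],
    min_fraction = filters$inter_min_fraction,
    mode = filters$inter_mode)
  grid <- feature_grid(kept_mz, params$tolerance_ppm)

  # group-mean training observations on the filtered grid
  group_sets <- list()
  fms <- list()
  for (id in ids) {
    d <- datasets[[id]]
    n_groups <- if (labels[[id]] == "benign") filters$groups_benign
                else filters$groups_malignant
    groups <- make_equivalent_groups(rois[[id]], n_groups, seed = seed)
    group_sets[[id]] <- groups
    fms[[id]] <- group_mean_observations(d, rois[[id]], groups, grid,
                                         params, label = labels[[id]])
  }
  training <- feature_matrix(
    observation_ids = unlist(lapply(fms, `[[`, "observation_ids"),
                             use.names = FALSE),
    feature_mz = grid$features,
    intensities = do.call(rbind, lapply(fms, `[[`, "intensities")),
    detected = do.call(rbind, lapply(fms, `[[`, "detected")),
    labels = unlist(lapply(fms, `[[`, "labels"), use.names = FALSE),
    patient_of = unlist(lapply(fms, `[[`, "patient_of"), use.names = FALSE))

  fit <- fit_lasso_logistic(training, cv_folds = model_opts$cv_folds,
                            seed = seed, grid = grid)
  funnel <- c(total = length(aligned$grid$features),
              filtered = length(kept_mz),
              selected = nrow(fit$model$coefficients))
  list(model = fit$model, cv = fit$cv, grid = grid, funnel = funnel,
       roi_matrix = fm_roi, training_matrix = training,
       groups = group_sets)
}

write_pipeline_outputs <- function(out_dir, model, funnel, report, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_model(model, file.path(out_dir, "model.json"))
  jsonlite::write_json(as.list(funnel), file.path(out_dir, "funnel.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$table, file.path(out_dir, "decisions.csv"),
                   row.names = FALSE)
  cfg <- config
  if (!is.null(cfg$synthetic)) {
    syn <- unclass(cfg$synthetic)
    syn$panel <- NULL  # matrices do not serialize usefully to YAML
    cfg$synthetic <- syn
  }
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
}

#' Run the training stage of the pipeline
#'
#' Obtains the training cohort (from the configuration's synthetic block,
#' or from imzML + ROI JSON files under `config$paths`), checks specimen
#' adequacy, trains the Lasso-logistic model, and re-scores every training
#' specimen pixel-by-pixel with triage calls. When
#' `config$paths$out_dir` is set, persists the model JSON, the feature
#' funnel counts, the per-specimen decision table and a frozen copy of the
#' resolved configuration.
#'
#' @param config A pipeline configuration (see
#'   [default_pipeline_config()]).
#' @return List with `model`, `cv`, `funnel`, `report` (a
#'   [cohort_report()] over the training specimens, pixel mode),
#'   `adequacy` (per-specimen flag), and `cohort` (the data used).
#' @export
run_training <- function(config = default_pipeline_config()) {
  cohort <- if (!is.null(config$synthetic)) {
    simulate_cohort(config$synthetic)
  } else {
    load_cohort_from_paths(config$paths)
  }
  ids <- names(cohort$datasets)
  labels <- if (!is.null(cohort$truth)) {
    cohort$truth$specimen_class[ids]
  } else {
    vapply(cohort$datasets,
           function(d) cytology_to_class(d$cytology_class), character(1))
  }
  if (anyNA(labels)) {
    stop("missing labels: training specimens must be Thy2 or Thy5")
  }

  adequacy <- vapply(ids, function(id) adequacy_check(cohort$rois[[id]]),
                     logical(1))
  if (identical(config$adequacy$policy, "exclude") &&
      any(!is.na(adequacy) & !adequacy)) {
    drop <- ids[!is.na(adequacy) & !adequacy]
    message("excluding inadequate specimens: ", paste(drop, collapse = ", "))
    ids <- setdiff(ids, drop)
  }

  trained <- train_cohort(cohort$datasets[ids], cohort$rois[ids],
                          labels[ids],
                          params = config$preprocessing,
                          filters = config$filters,
                          model_opts = config$model,
                          seed = config$seed)

  summaries <- list(); decisions <- list()
  for (id in ids) {
    px <- classify_pixelwise(trained$model, cohort$datasets[[id]],
                             config$preprocessing)
    summaries[[id]] <- px$summary
    decisions[[id]] <- triage(px$summary, config$triage$low,
                              config$triage$high)
  }
  report <- cohort_report(decisions, summaries, truth = labels[ids])

  if (!is.null(config$paths$out_dir)) {
    write_pipeline_outputs(config$paths$out_dir, trained$model,
                           trained$funnel, report, config)
  }
  list(model = trained$model, cv = trained$cv, funnel = trained$funnel,
       report = report, adequacy = adequacy, cohort = cohort,
       trained = trained)
}

#' Run the validation stage of the pipeline
#'
#' Scores each validation specimen with all three approaches (per-ROI,
#' whole-average, pixel-by-pixel) against a fitted model. Validation is
#' blind by construction: true labels are consumed only by the final
#' report, and only when supplied.
#'
#' @param config A pipeline configuration.
#' @param model A `malignancy_model` (e.g. from [run_training()] or
#'   [read_model()]).
#' @param datasets,rois Optional named lists of validation specimens; when
#'   `NULL` and the configuration has a synthetic block, a standard
#'   validation cohort (`config$validation$n_benign` +
#'   `config$validation$n_malignant` specimens) is simulated with seed
#'   `config$seed + 1`.
#' @param truth Optional named truth vector for the report; `NULL` omits
#'   confusion counts.
#' @return List with `report` (a [cohort_report()]), `summaries` and
#'   `decisions` (one entry per specimen and mode), and `maps`
#'   (pixel-mode [probability_map]s).
#' @export
run_validation <- function(config, model, datasets = NULL, rois = NULL,
                           truth = NULL) {
  stopifnot(inherits(model, "malignancy_model"))
  if (is.null(datasets)) {
    if (is.null(config$synthetic)) {
      stop("no validation specimens: supply datasets or a synthetic block")
    }
    syn <- config$synthetic
    syn$n_benign_patients <- as.integer(config$validation$n_benign)
    syn$n_malignant_patients <- as.integer(config$validation$n_malignant)
    syn$seed <- config$seed + 1L
    sim <- simulate_cohort(syn)
    datasets <- sim$datasets
    rois <- sim$rois
    if (is.null(truth)) truth <- sim$truth$specimen_class
  }
  ids <- names(datasets)
  rng <- range(unlist(lapply(datasets[[1]]$spectra[1], function(s) s$mz)))
  if (any(model$grid$features < rng[1] - 1 | model$grid$features > rng[2] + 1)) {
    stop("model/data version mismatch: model features outside the data's m/z range")
  }
  summaries <- list(); decisions <- list(); maps <- list()
  for (id in ids) {
    d <- datasets[[id]]
    roi_res <- classify_by_roi(model, d, rois[[id]], config$preprocessing)
    whole_p <- classify_whole_average(model, d, config$preprocessing)
    px <- classify_pixelwise(model, d, config$preprocessing)
    s <- list(roi = roi_res$summary,
              whole_average = summarize_quartiles(whole_p, "whole_average",
                                                  specimen_id = id),
              pixel = px$summary)
    for (m in names(s)) {
      key <- paste0(id, ".", m)
      summaries[[key]] <- s[[m]]
      decisions[[key]] <- triage(s[[m]], config$triage$low,
                                 config$triage$high)
    }
    maps[[id]] <- px$map
  }
  report <- cohort_report(decisions, summaries, truth = truth)
  list(report = report, summaries = summaries, decisions = decisions,
       maps = maps)
}
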