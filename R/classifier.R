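#' @title Lasso-penalized logistic malignancy model
#' @description The training observations (ROI-group mean spectra on the
#'   filtered feature grid) are few and the features many and correlated,
#'   so the malignancy model is an L1-penalized logistic regression: it
#'   minimizes the binomial negative log-likelihood plus
#'   `lambda * sum(|beta_j|)` along a descending lambda path and selects
#'   the penalty by cross-validated deviance. Malignant is coded 1, so the
#'   predicted success probability is the probability of malignancy.
#' @name classifier
NULL

# Patient-grouped, class-stratified fold assignment: all observations of a
# patient share a fold (their ROI groups are not independent), and each
# class's patients are dealt round-robin so every fold sees both classes.
patient_folds <- function(patient_of, labels, cv_folds, seed) {
  patients <- unique(patient_of)
  pat_label <- vapply(patients,
                      function(p) labels[match(p, patient_of)], character(1))
  per_class_n <- table(pat_label)
  k <- min(cv_folds, min(per_class_n))
  if (k < cv_folds) {
    message(sprintf("fewer patients (%d) than folds (%d); using %d folds",
                    min(per_class_n), cv_folds, k))
  }
  if (k < 3L) {
    stop("need at least 3 patients per class for cross-validated penalty ",
         "selection; fit with a fixed lambda instead")
  }
  set.seed(seed)
  pat_fold <- integer(length(patients))
  names(pat_fold) <- patients
  for (cl in unique(pat_label)) {
    ids <- sample(patients[pat_label == cl])
    pat_fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  list(foldid = unname(pat_fold[patient_of]), nfolds = k)
}

#' Fit the Lasso-logistic malignancy model
#'
#' Fits an L1-penalized logistic regression of class (malignant = 1) on the
#' feature intensities via `glmnet`, with features standardized internally
#' (constant features dropped) and coefficients reported on the original
#' intensity scale. The penalty is chosen as the minimizer of the mean
#' cross-validated binomial deviance over folds that are stratified by
#' class and grouped by patient — all ROI groups of one patient land in
#' one fold, preventing within-patient leakage.
#'
#' @param fm A labelled [feature_matrix] (labels `"benign"`/`"malignant"`,
#'   `patient_of` set, both classes present).
#' @param cv_folds Number of CV folds (default 5); reduced with a message
#'   when a class has fewer patients than folds.
#' @param seed Integer seed controlling fold assignment (the only source of
#'   randomness; the fit is deterministic given the folds).
#' @param grid Optional [feature_grid] recording the alignment tolerance of
#'   the training features; defaults to the matrix's m/z at 2000 ppm.
#' @param lambda Optional fixed penalty (single value): skips
#'   cross-validation and fits at exactly this lambda (used for oracle
#'   comparisons and analytic-limit checks).
#' @param standardize Standardize features internally (default `TRUE`).
#' @return List with `model` (a `malignancy_model`: intercept, nonzero
#'   coefficients by feature m/z, chosen penalty, training grid,
#'   standardization constants) and `cv` (a `cv_result`: lambda path,
#'   per-lambda mean/sd CV deviance, chosen lambda, fold assignments;
#'   `NULL` when `lambda` was fixed).
#' @export
fit_lasso_logistic <- function(fm, cv_folds = 5L, seed = 1L, grid = NULL,
                               lambda = NULL, standardize = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$labels)) stop("feature matrix lacks class labels")
  y <- as.integer(fm$labels == "malignant")
  if (length(unique(y)) < 2L) {
    stop("training data must contain both benign and malignant observations")
  }
  if (is.null(grid)) grid <- feature_grid(fm$feature_mz, 2000)
  x <- fm$intensities
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all features are constant")
  x_fit <- x[, keep, drop = FALSE]
  mz_fit <- fm$feature_mz[keep]

  if (!is.null(lambda) && length(lambda) == 1L) {
    # warm-start down a short path ending exactly at the requested lambda
    fit <- glmnet::glmnet(x_fit, y, family = "binomial", alpha = 1,
                          standardize = standardize, thresh = 1e-10,
                          lambda = c(lambda * 8, lambda * 4, lambda * 2,
                                     lambda))
    cf <- as.matrix(stats::coef(fit, s = lambda))
    chosen <- lambda
    cv <- NULL
    folds_used <- NA_integer_
  } else {
    if (is.null(fm$patient_of)) stop("feature matrix lacks patient_of")
    pf <- patient_folds(fm$patient_of, fm$labels, cv_folds, seed)
    set.seed(seed)
    cvfit <- glmnet::cv.glmnet(x_fit, y, family = "binomial", alpha = 1,
                               foldid = pf$foldid,
                               type.measure = "deviance",
                               standardize = standardize)
    chosen <- cvfit$lambda.min
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
    cv <- structure(list(lambda_path = cvfit$lambda,
                         cv_mean = cvfit$cvm,
                         cv_sd = cvfit$cvsd,
                         lambda_chosen = chosen,
                         foldid = pf$foldid,
                         nfolds = pf$nfolds,
                         fit = cvfit),
                    class = "cv_result")
    folds_used <- pf$nfolds
  }
  beta <- cf[-1, 1]
  nz <- which(beta != 0)
  model <- structure(
    list(intercept = unname(cf[1, 1]),
         coefficients = data.frame(mz = mz_fit[nz],
                                   coefficient = unname(beta[nz])),
         penalty = chosen,
         cv_folds = folds_used,
         grid = grid,
         standardization = data.frame(mz = mz_fit,
                                      mean = unname(colMeans(x_fit)),
                                      sd = unname(sds[keep])),
         seed = as.integer(seed)),
    class = "malignancy_model")
  list(model = model, cv = cv)
}

#' @export
print.malignancy_model <- function(x, ...) {
  cat(sprintf(
    "<malignancy_model: %d/%d nonzero features, lambda = %.5g, intercept = %.3f>\n",
    nrow(x$coefficients), length(x$grid$features), x$penalty, x$intercept))
  invisible(x)
}

#' Predict the probability of malignancy for one observation
#'
#' `p = 1 / (1 + exp(-(b0 + sum_j beta_j x_j)))` over the model's nonzero
#' coefficients. The observation must be expressed on the model's training
#' feature grid (absent features = 0, the same convention as training; see
#' [project_onto_grid()]).
#'
#' @param model A `malignancy_model`.
#' @param observation Numeric vector of feature intensities, one entry per
#'   grid feature, or the list returned by [project_onto_grid()].
#' @return Probability in (0, 1).
#' @export
predict_probability <- function(model, observation) {
  stopifnot(inherits(model, "malignancy_model"))
  if (is.list(observation) && !is.null(observation$intensity)) {
    observation <- observation$intensity
  }
  nf <- length(model$grid$features)
  if (length(observation) != nf) {
    stop(sprintf("observation has %d features; model grid has %d",
                 length(observation), nf))
  }
  eta <- model$intercept
  if (nrow(model$coefficients)) {
    idx <- match(model$coefficients$mz, model$grid$features)
    eta <- eta + sum(model$coefficients$coefficient * observation[idx])
  }
  stats::plogis(eta)
}

#' Features selected by the model
#'
#' @param model A `malignancy_model`.
#' @return Data frame with columns `mz` (ascending) and `coefficient`, the
#'   nonzero-coefficient features only.
#' @export
select_features <- function(model) {
  stopifnot(inherits(model, "malignancy_model"))
  out <- model$coefficients[order(model$coefficients$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a malignancy model to JSON
#'
#' @param model A `malignancy_model`.
#' @param path Output path.
#' @return `path`, invisibly. Reloading with [read_model()] reproduces
#'   identical predictions.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "malignancy_model"))
  payload <- list(
    intercept = jsonlite::unbox(model$intercept),
    coefficients = model$coefficients,
    penalty = jsonlite::unbox(model$penalty),
    cv_folds = jsonlite::unbox(model$cv_folds),
    grid = list(features = model$grid$features,
                tolerance_ppm = jsonlite::unbox(model$grid$tolerance_ppm)),
    standardization = model$standardization,
    seed = jsonlite::unbox(model$seed))
  # I(17) significant digits: lossless decimal round-trip for float64
  jsonlite::write_json(payload, path, digits = I(17), na = "null")
  invisible(path)
}

#' Read a malignancy model from JSON
#'
#' @param path Path written by [write_model()].
#' @return A `malignancy_model`.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- as.data.frame(j$coefficients)
  if (nrow(cf) == 0L) cf <- data.frame(mz = numeric(0),
                                       coefficient = numeric(0))
  structure(
    list(intercept = j$intercept,
         coefficients = cf,
         penalty = j$penalty,
         cv_folds = j$cv_folds,
         grid = feature_grid(j$grid$features, j$grid$tolerance_ppm),
         standardization = as.data.frame(j$standardization),
         seed = as.integer(j$seed)),
    class = "malignancy_model")
}
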