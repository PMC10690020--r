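#' Square-root transform of non-negative pathology measures
#'
#' Applied to immunohistochemistry-based neuropathology measures (per cent
#' area, tangle densities) to improve normality before covariate adjustment.
#' PET SUVR z-scores are used as-is and do not pass through this transform.
#'
#' @param values numeric vector or matrix of non-negative measures; matrix
#'   columns are biomarkers.
#' @return elementwise square root, same shape.
#' @export
sqrt_transform <- function(values) {
  if (any(is.na(values)))
    stop("missing values in measures")
  if (any(values < 0)) {
    if (is.matrix(values) && !is.null(colnames(values))) {
      bad <- colnames(values)[apply(values < 0, 2, any)]
      stop("negative values in biomarker(s): ",
           paste(bad, collapse = ", "))
    }
    stop("negative values cannot be square-root transformed")
  }
  sqrt(values)
}

#' Fit control-cohort covariate adjustment models
#'
#' Fits one ordinary least-squares regression per biomarker against the
#' stated covariates (default age, sex, education years) in a control
#' population, and stores the mean and standard deviation of the control
#' residuals for later z-scoring.
#'
#' @param controls data.frame of control subjects containing the biomarker
#'   and covariate columns.
#' @param biomarkers character vector of biomarker column names.
#' @param covariates character vector of covariate column names.
#' @param sd_floor minimum admissible residual SD; a degenerate (exactly
#'   collinear) control set produces an error rather than divide-by-zero
#'   z-scores downstream.
#' @return object of class \code{adjustment_model}: per-biomarker
#'   coefficients and control residual mean/SD.
#' @export
fit_control_adjustment <- function(controls,
                                   biomarkers,
                                   covariates = c("age", "sex",
                                                  "education"),
                                   sd_floor = 1e-6) {
  p <- length(covariates)
  miss_cov <- stats::complete.cases(controls[, covariates, drop = FALSE])
  controls <- controls[miss_cov, , drop = FALSE]
  if (nrow(controls) < p + 2L)
    stop("need at least ", p + 2L, " control subjects with complete ",
         "covariates; got ", nrow(controls))
  X <- stats::model.matrix(
    stats::reformulate(covariates),
    data = controls[, covariates, drop = FALSE])
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient covariate design in controls")
  coefs <- list(); res_mean <- numeric(0); res_sd <- numeric(0)
  for (b in biomarkers) {
    if (!b %in% names(controls)) stop("missing biomarker column: ", b)
    fit <- stats::lm.fit(X, controls[[b]])
    r <- fit$residuals
    s <- stats::sd(r)
    if (s < sd_floor)
      stop("control residual SD below floor (", sd_floor,
           ") for biomarker ", b,
           ": values are (near-)exact functions of the covariates")
    coefs[[b]] <- fit$coefficients
    res_mean[b] <- mean(r)
    res_sd[b] <- s
  }
  structure(list(biomarkers = biomarkers, covariates = covariates,
                 coefficients = coefs, residual_mean = res_mean,
                 residual_sd = res_sd, n_controls = nrow(controls),
                 sd_floor = sd_floor),
            class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("Control covariate-adjustment model: ", length(x$biomarkers),
      " biomarkers ~ ", paste(x$covariates, collapse = " + "),
      " (n = ", x$n_controls, " controls)\n", sep = "")
  invisible(x)
}

adjust_design <- function(cohort, model) {
  miss <- !stats::complete.cases(cohort[, model$covariates, drop = FALSE])
  if (any(miss))
    stop("missing covariates for subject(s): ",
         paste(utils::head(cohort$subject_id[miss], 10), collapse = ", "))
  stats::model.matrix(stats::reformulate(model$covariates),
                      data = cohort[, model$covariates, drop = FALSE])
}

#' Residualize biomarkers against a control adjustment model
#'
#' Subtracts each biomarker's predicted value (from the control-fitted
#' regression) from its observed value, for all subjects — not only
#' controls.
#'
#' @param cohort data.frame containing the model's biomarker and covariate
#'   columns.
#' @param model an \code{\link{fit_control_adjustment}} model.
#' @return the cohort with biomarker columns replaced by residuals.
#' @export
residualize <- function(cohort, model) {
  X <- adjust_design(cohort, model)
  for (b in model$biomarkers)
    cohort[[b]] <- cohort[[b]] - as.numeric(X %*% model$coefficients[[b]])
  cohort
}

#' Control-standardized z-scores
#'
#' Residualizes a raw cohort against the control adjustment model, then
#' standardizes each biomarker by the control residual mean and SD:
#' z = (residual - control mean) / control SD. A z of 0 is the control
#' expectation; z = 2, 5, 10 are the mild/moderate/severe event thresholds
#' of the z-score progression model.
#'
#' @param cohort raw (unresidualized) cohort data.frame.
#' @param model an \code{\link{fit_control_adjustment}} model.
#' @return n x B matrix of z-scores (columns = biomarkers), with subject ids
#'   as rownames when available.
#' @export
compute_zscores <- function(cohort, model) {
  if (any(model$residual_sd <= model$sd_floor))
    stop("control residual SD at or below floor; refit the adjustment")
  res <- residualize(cohort, model)
  Z <- sapply(model$biomarkers, function(b)
    (res[[b]] - model$residual_mean[[b]]) / model$residual_sd[[b]])
  Z <- matrix(Z, nrow = nrow(cohort),
              dimnames = list(cohort$subject_id, model$biomarkers))
  Z
}

#' Volume-weighted composite regions
#'
#' Combines adjacent regions into composites by volume-weighted averaging:
#' sum(v_i x_i) / sum(v_i).
#'
#' @param values n x regions matrix (columns named by region).
#' @param volumes named positive vector of region volumes.
#' @param mapping named list: composite name -> character vector of member
#'   regions.
#' @return n x composites matrix.
#' @export
composite_regions <- function(values, volumes, mapping) {
  if (is.null(dim(values)))
    values <- matrix(values, nrow = 1, dimnames = list(NULL, names(values)))
  if (any(volumes <= 0)) stop("volumes must be positive")
  out <- matrix(0, nrow(values), length(mapping),
                dimnames = list(rownames(values), names(mapping)))
  for (k in seq_along(mapping)) {
    regs <- mapping[[k]]
    if (length(regs) == 0L) stop("empty composite: ", names(mapping)[k])
    if (!all(regs %in% colnames(values)))
      stop("missing region(s) for composite ", names(mapping)[k], ": ",
           paste(setdiff(regs, colnames(values)), collapse = ", "))
    if (!all(regs %in% names(volumes)))
      stop("missing volume(s) for composite ", names(mapping)[k])
    v <- volumes[regs]
    out[, k] <- as.numeric(values[, regs, drop = FALSE] %*% v) / sum(v)
  }
  out
}

#' Complete-case filter on modelling biomarkers
#'
#' Drops subjects missing any modelling biomarker, with a message recording
#' the excluded count (cohort-flow logging).
#'
#' @param cohort data.frame.
#' @param biomarkers biomarker columns that must be complete.
#' @return filtered cohort.
#' @export
complete_cases <- function(cohort, biomarkers) {
  keep <- stats::complete.cases(cohort[, biomarkers, drop = FALSE])
  if (any(!keep))
    message("complete-case rule: dropped ", sum(!keep), " of ",
            nrow(cohort), " subjects missing modelling biomarkers")
  cohort[keep, , drop = FALSE]
}
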