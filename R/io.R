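#' Read a cohort table from CSV
#'
#' UTF-8, comma-separated, header required. Validates required columns and
#' unique subject ids; extra columns are preserved as passthrough.
#'
#' @param path CSV file path.
#' @param required character vector of required column names (always
#'   includes \code{subject_id}).
#' @return data.frame, one row per subject.
#' @export
read_cohort_csv <- function(path, required = character(0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- union("subject_id", required)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop("duplicate subject_id(s): ",
         paste(unique(utils::head(dup, 10)), collapse = ", "))
  df
}

#' Write a cohort or results table to CSV
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_cohort_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Stores sequences (event-id lists with labels), fractions, event spec,
#' fitting configuration and seed; MCMC samples are summarized by the
#' positional variance diagrams rather than stored raw.
#'
#' @param model fitted \code{\link{fit_sustain}} model.
#' @param path output JSON path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(kind = model$kind,
              n_subtypes = model$n_subtypes,
              biomarkers = model$spec$biomarkers,
              pathology = as.list(model$spec$pathology),
              levels = model$spec$levels,
              sequences = model$sequences,
              sequence_labels = lapply(model$sequences, function(s)
                model$spec$events$label[s]),
              fractions = model$fractions,
              loglik = model$loglik,
              pvd = lapply(seq_len(model$n_subtypes), function(c)
                unname(positional_variance(model$samples[[c]]))),
              config = model$config,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export positional variance diagrams as CSV
#'
#' One matrix per subtype, events ordered by their MAP position.
#'
#' @param model fitted model.
#' @param dir output directory.
#' @return paths of the written CSVs.
#' @export
export_pvd <- function(model, dir = ".") {
  if (is.null(model$samples)) stop("model has no MCMC samples")
  paths <- character(model$n_subtypes)
  for (c in seq_len(model$n_subtypes)) {
    pvd <- positional_variance(model$samples[[c]], model$spec)
    pvd <- pvd[model$sequences[[c]], , drop = FALSE]
    p <- file.path(dir, sprintf("pvd_subtype%d.csv", c))
    utils::write.csv(data.frame(event = rownames(pvd), pvd,
                                check.names = FALSE),
                     p, row.names = FALSE)
    paths[c] <- p
  }
  paths
}

#' Pipeline configuration
#'
#' Collects the choices the end-to-end pipeline needs: model kind, event
#' levels, covariates, number of subtypes (or a CV range), MCMC settings and
#' seeds.
#'
#' @param kind "zscore" or "ordinal".
#' @param covariates covariate column names for control adjustment.
#' @param event_levels z thresholds per biomarker (z-score kind).
#' @param n_subtypes number of subtypes to fit; if \code{cv_max_subtypes} is
#'   set, CVIC selects the count in 1..cv_max_subtypes instead.
#' @param cv_max_subtypes optional upper bound for CVIC model selection.
#' @param n_folds CV folds.
#' @param n_restarts,mcmc fitting settings (see \code{\link{fit_sustain}}).
#' @param seed integer seed used for all pipeline randomness.
#' @param output_dir where \code{\link{run_pipeline}} writes artifacts.
#' @return classed list.
#' @export
pipeline_config <- function(kind = c("zscore", "ordinal"),
                            covariates = c("age", "sex", "education"),
                            event_levels = c(2, 5, 10),
                            n_subtypes = 2L, cv_max_subtypes = NULL,
                            n_folds = 10L, n_restarts = 25L,
                            mcmc = list(n_iter = 1e5, burn_in = 1e4),
                            seed = 1L, output_dir = tempfile("sustain_")) {
  kind <- match.arg(kind)
  structure(list(kind = kind, covariates = covariates,
                 event_levels = event_levels, n_subtypes = n_subtypes,
                 cv_max_subtypes = cv_max_subtypes, n_folds = n_folds,
                 n_restarts = n_restarts, mcmc = mcmc,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full subtyping pipeline
#'
#' Orchestrates preprocessing, model fitting (with optional CVIC model
#' selection), subject placement, early-window group construction and the
#' cross-sectional comparison scheme, writing all artifacts (model JSON,
#' PVD CSVs, placements, group stats, manifest with checksums) to the
#' configured output directory.
#'
#' @param cohort cohort data.frame (raw biomarker values, covariates,
#'   \code{apoe_e4}).
#' @param controls control cohort data.frame used to fit the covariate
#'   adjustment.
#' @param biomarkers biomarker column names.
#' @param pathology pathology class per biomarker.
#' @param config a \code{\link{pipeline_config}}.
#' @param global_labels for the ordinal kind: list with \code{cerad} and
#'   \code{braak} column names and \code{mtl_regions} (regions scored with
#'   the MTL Braak grouping).
#' @return list: adjustment model, fitted model, placements, windows, group
#'   labels, group-comparison tables, cvic table (if selected by CV),
#'   manifest.
#' @export
run_pipeline <- function(cohort, controls, biomarkers, pathology,
                         config, global_labels = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  cohort <- step("preprocess", complete_cases(cohort, biomarkers))

  if (config$kind == "zscore") {
    adj <- step("preprocess",
                fit_control_adjustment(controls, biomarkers,
                                       config$covariates))
    data <- step("preprocess", compute_zscores(cohort, adj))
    spec <- event_spec(biomarkers, pathology, config$event_levels,
                       kind = "zscore")
  } else {
    if (is.null(global_labels))
      stop("[score] ordinal pipeline requires global_labels ",
           "(cerad/braak columns and mtl_regions)")
    sq <- cohort
    sq[biomarkers] <- step("score",
                           sqrt_transform(as.matrix(cohort[biomarkers])))
    ctrl_sq <- controls
    ctrl_sq[biomarkers] <- sqrt_transform(as.matrix(controls[biomarkers]))
    adj <- step("preprocess",
                fit_control_adjustment(ctrl_sq, biomarkers,
                                       config$covariates))
    res <- step("preprocess", residualize(sq, adj))
    amy <- biomarkers[pathology == "amyloid"]
    tau <- biomarkers[pathology == "tau"]
    cerad_score <- step("score", map_cerad(cohort[[global_labels$cerad]]))
    mixtures_a <- step("score", lapply(amy, function(r)
      fit_kde_mixture(res[[r]], cerad_score, region = r, K = 4L)))
    ta <- step("score", score_probabilities(
      as.matrix(res[amy]), mixtures_a))
    mixtures_t <- step("score", lapply(tau, function(r) {
      cls <- if (r %in% global_labels$mtl_regions) "MTL" else "neocortical"
      fit_kde_mixture(res[[r]],
                      map_braak(cohort[[global_labels$braak]], cls),
                      region = r, K = 4L)
    }))
    tt <- step("score", score_probabilities(as.matrix(res[tau]),
                                            mixtures_t))
    dimnames(ta)[[2]] <- amy; dimnames(tt)[[2]] <- tau
    data <- step("score", assemble_ordinal_input(ta, tt))
    spec <- event_spec_from_tensor(data)
  }

  cvic <- NULL
  n_subtypes <- config$n_subtypes
  if (!is.null(config$cv_max_subtypes)) {
    cvic <- step("cv", cross_validate_cvic(
      data, spec, max_subtypes = config$cv_max_subtypes,
      n_folds = config$n_folds, seed = config$seed,
      n_restarts = config$n_restarts))
    n_subtypes <- cvic$n_subtypes[which.min(cvic$cvic)]
  }
  model <- step("fit", fit_sustain(data, spec, n_subtypes = n_subtypes,
                                   n_restarts = config$n_restarts,
                                   mcmc = config$mcmc,
                                   seed = config$seed))
  placements <- step("place", assign_subjects(model, data,
                                              subject_id =
                                                cohort$subject_id))
  windows <- step("groups", lapply(seq_len(model$n_subtypes), function(c)
    early_stage_window(model, c)))
  groups <- step("groups", define_groups(placements, windows,
                                         cohort$apoe_e4))
  prop <- step("stats", tryCatch(proportion_test(groups, cohort$apoe_e4),
                                 error = function(e) NULL))

  out_dir <- config$output_dir
  files <- character(0)
  f <- file.path(out_dir, "model.json")
  write_model_json(model, f); files <- c(files, f)
  files <- c(files, export_pvd(model, out_dir))
  f <- file.path(out_dir, "placements.csv")
  write_cohort_csv(cbind(placements, group = as.character(groups)), f)
  files <- c(files, f)
  if (!is.null(cvic)) {
    f <- file.path(out_dir, "cvic.csv"); write_cohort_csv(cvic, f)
    files <- c(files, f)
  }
  manifest <- list(files = lapply(files, function(p)
    list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    seed = config$seed, kind = config$kind,
    n_subtypes = model$n_subtypes,
    n_subjects = nrow(cohort),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  list(adjustment = if (exists("adj")) adj else NULL, model = model,
       placements = placements, windows = windows, groups = groups,
       proportion_test = prop, cvic = cvic,
       manifest = manifest, output_dir = out_dir)
}
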