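#' Place follow-up visits under a frozen model
#'
#' Applies the baseline covariate-adjustment model and the fitted
#' subtype-and-stage model to each visit of a longitudinal table — no
#' refitting — so baseline and follow-up placements are directly
#' comparable.
#'
#' @param model a fitted \code{\link{fit_sustain}} model (z-score kind).
#' @param visits long-format data.frame: \code{subject_id},
#'   \code{time_years}, covariate and biomarker columns.
#' @param adjustment the baseline \code{\link{fit_control_adjustment}} model.
#' @return data.frame of per-visit placements: subject_id, time_years, and
#'   the \code{\link{assign_subjects}} columns.
#' @export
assign_followups <- function(model, visits, adjustment) {
  miss <- setdiff(model$spec$biomarkers, names(visits))
  if (length(miss))
    stop("visit table is missing model biomarkers: ",
         paste(miss, collapse = ", "))
  Z <- compute_zscores(visits, adjustment)
  pl <- assign_subjects(model, Z, subject_id = visits$subject_id)
  out <- cbind(subject_id = visits$subject_id,
               time_years = visits$time_years,
               pl[, c("map_subtype", "subtype_label", "map_stage",
                      "stage_zero", "entropy")])
  rownames(out) <- NULL
  out
}

#' Subtype consistency confusion matrix
#'
#' Cross-tabulates baseline versus follow-up MAP subtype for paired
#' subjects. Subjects whose MAP stage is 0 at either visit are excluded:
#' at stage 0 no event has occurred and the subtype is undefined.
#'
#' @param baseline,followup placement data.frames containing
#'   \code{subject_id}, \code{map_subtype} and \code{map_stage}.
#' @param subset optional logical/indices selecting baseline subjects (e.g.
#'   an APOE stratum) before pairing.
#' @return square contingency table (baseline subtype x follow-up subtype).
#' @export
consistency_matrix <- function(baseline, followup, subset = NULL) {
  if (!is.null(subset)) baseline <- baseline[subset, , drop = FALSE]
  m <- merge(baseline[, c("subject_id", "map_subtype", "map_stage")],
             followup[, c("subject_id", "map_subtype", "map_stage")],
             by = "subject_id", suffixes = c("_bl", "_fu"))
  m <- m[m$map_stage_bl > 0 & m$map_stage_fu > 0, , drop = FALSE]
  if (nrow(m) == 0) stop("no paired subjects with non-zero stage")
  lev <- sort(unique(c(m$map_subtype_bl, m$map_subtype_fu)))
  table(baseline = factor(m$map_subtype_bl, levels = lev),
        followup = factor(m$map_subtype_fu, levels = lev))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact hypergeometric test with fixed margins; the two-sided
#' p-value sums the probabilities of all tables at least as extreme as the
#' observed one (sum-of-smaller-point-probabilities convention).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative counts")
  if (!all(dim(table) == 2L)) stop("a 2x2 table is required")
  stats::fisher.test(table)$p.value
}

#' Annual rate of stage change and group comparison
#'
#' Per-subject rate = (last stage - baseline stage) / elapsed years (the
#' first-to-last convention; a per-visit OLS slope is available as an
#' option), compared across groups with a one-way ANOVA.
#'
#' @param placements long placement data.frame: \code{subject_id},
#'   \code{time_years}, \code{map_stage}.
#' @param groups named vector/factor of group labels per subject_id, or a
#'   data.frame with columns subject_id and group.
#' @param method \code{"first_last"} or \code{"ols"}.
#' @return list: \code{rates} (per-subject data.frame), \code{group_stats}
#'   (mean and SD per group), \code{anova} (F statistic, dof, p).
#' @export
stage_rate <- function(placements, groups = NULL,
                       method = c("first_last", "ols")) {
  method <- match.arg(method)
  sp <- split(placements, placements$subject_id)
  rates <- vapply(sp, function(d) {
    d <- d[order(d$time_years), , drop = FALSE]
    if (nrow(d) < 2L) return(NA_real_)
    dt <- d$time_years[nrow(d)] - d$time_years[1]
    if (dt <= 0) stop("zero elapsed time for subject ", d$subject_id[1])
    if (method == "first_last")
      (d$map_stage[nrow(d)] - d$map_stage[1]) / dt
    else
      unname(stats::coef(stats::lm(map_stage ~ time_years, data = d))[2])
  }, 0)
  out <- data.frame(subject_id = names(rates), rate = unname(rates),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$rate), , drop = FALSE]
  res <- list(rates = out)
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      g <- groups$group[match(out$subject_id, groups$subject_id)]
    } else {
      g <- groups[out$subject_id]
    }
    g <- factor(g)
    res$group_stats <- do.call(rbind, lapply(levels(g), function(l) {
      r <- out$rate[g == l]
      data.frame(group = l, n = length(r), mean = mean(r), sd = stats::sd(r))
    }))
    av <- stats::anova(stats::aov(out$rate ~ g))
    res$anova <- list(F = av$`F value`[1], dof = av$Df,
                      p = av$`Pr(>F)`[1])
  }
  res
}

#' Longitudinal trajectory linear mixed-effects model
#'
#' Maximum-likelihood LME of an outcome with fixed effects of baseline age,
#' sex, education years, optionally intracranial volume (ICV), time in years
#' since baseline, group main effects and group x time interactions, plus
#' per-subject random intercepts and random time slopes with unstructured
#' covariance. The reference level of \code{group} should be the stage-zero
#' (e4-) normal-ageing group. ICV is included only for imaging outcomes
#' (\code{include_icv = TRUE}); cognition models exclude it.
#'
#' Singular random-effects covariances trigger a warning and a refit with
#' independent (diagonal) random effects; non-convergence is an error.
#' p-values use the normal approximation to the t statistics.
#'
#' @param table long-format data.frame with \code{subject_id},
#'   \code{time_years}, covariates (\code{age}, \code{sex},
#'   \code{education}, optionally \code{icv}) and the outcome column.
#' @param outcome name of the outcome column.
#' @param groups factor (or vector) of group labels, one per row of
#'   \code{table}; the first factor level is the reference.
#' @param include_icv include ICV as a fixed effect.
#' @return list: \code{coefficients} (estimate, se, t, p per fixed effect),
#'   \code{fit} (the lmer object), \code{singular} flag.
#' @export
fit_lme <- function(table, outcome, groups, include_icv = FALSE) {
  df <- table
  df$.group <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  df$.y <- df[[outcome]]
  fixed <- c("age", "sex", "education", if (include_icv) "icv",
             "time_years * .group")
  form <- stats::as.formula(paste(".y ~", paste(fixed, collapse = " + "),
                                  "+ (1 + time_years | subject_id)"))
  fit <- tryCatch(
    lme4::lmer(form, data = df, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) stop("LME fit failed: ", conditionMessage(e)))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    warning("singular random-effects covariance; refitting with ",
            "independent random intercept and slope")
    form2 <- stats::as.formula(paste(".y ~",
                                     paste(fixed, collapse = " + "),
                                     "+ (1 + time_years || subject_id)"))
    fit <- lme4::lmer(form2, data = df, REML = FALSE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore",
                        calc.derivs = FALSE))
  }
  cc <- stats::coef(summary(fit))
  out <- data.frame(term = rownames(cc), estimate = cc[, "Estimate"],
                    se = cc[, "Std. Error"], t = cc[, "t value"],
                    p = 2 * stats::pnorm(-abs(cc[, "t value"])),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$term <- gsub("\\.group", "group:", out$term)
  list(coefficients = out, fit = fit, singular = singular)
}
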