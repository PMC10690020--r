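#' Early-stage window of a subtype
#'
#' The early window of a subtype is the inclusive stage range [1, w] in
#' which the subtype shows abnormality in only one pathology class: w is the
#' position of the first event whose pathology class differs from the
#' subtype's leading class, minus one. Restricting group comparisons to this
#' window avoids the mid-sequence "crossing problem" where subtypes imply
#' indistinguishable biomarker patterns.
#'
#' @param model a fitted \code{\link{fit_sustain}} model.
#' @param subtype subtype index.
#' @param leading_class optional pathology class the subtype is regarded as
#'   leading with; defaults to the class of the first event. If the first
#'   event belongs to the other class the window is empty (c(1, 0)).
#' @return list with \code{subtype}, \code{leading_class} ("amyloid" or
#'   "tau"), \code{window} = c(1, w) (c(1, 0) when the first event already
#'   belongs to the other class), and \code{first_other_pos}.
#' @export
early_stage_window <- function(model, subtype, leading_class = NULL) {
  spec <- model$spec
  seqn <- model$sequences[[subtype]]
  classes <- spec$events$pathology[seqn]
  leading <- if (is.null(leading_class)) classes[1] else leading_class
  other <- which(classes != leading)
  if (!length(other)) {
    warning("all events of subtype ", subtype, " share pathology class '",
            leading, "'; early window spans the full stage range")
    return(list(subtype = subtype, leading_class = leading,
                window = c(1L, spec$n_events),
                first_other_pos = NA_integer_))
  }
  w <- other[1] - 1L
  list(subtype = subtype, leading_class = leading,
       window = c(1L, w), first_other_pos = other[1])
}

#' Construct the five analysis groups
#'
#' Partitions placed subjects into: \code{stage_zero} (MAP stage 0 in either
#' subtype, the normal-ageing reference), early amyloid-first and early
#' tau-first groups split by APOE e4 carriage (>= 1 allele = e4+), and
#' \code{other} (outside any early window, or missing APOE).
#'
#' @param placements a \code{\link{assign_subjects}} result.
#' @param windows list of \code{\link{early_stage_window}} results, one per
#'   subtype.
#' @param apoe_e4 APOE e4 allele count per subject (0/1/2 or NA).
#' @return factor of group labels with levels \code{stage_zero},
#'   \code{earlyA_e4neg}, \code{earlyA_e4pos}, \code{earlyT_e4neg},
#'   \code{earlyT_e4pos}, \code{other}.
#' @export
define_groups <- function(placements, windows, apoe_e4) {
  n <- nrow(placements)
  if (length(apoe_e4) != n)
    stop("apoe_e4 must match the number of placed subjects")
  lab <- rep("other", n)
  e4pos <- !is.na(apoe_e4) & apoe_e4 >= 1
  n_missing <- sum(is.na(apoe_e4))
  by_subtype <- lapply(windows, function(w) w)
  for (j in seq_len(n)) {
    if (placements$stage_zero[j]) { lab[j] <- "stage_zero"; next }
    c <- placements$map_subtype[j]
    w <- by_subtype[[c]]
    s <- placements$map_stage[j]
    if (s >= w$window[1] && s <= w$window[2] && !is.na(apoe_e4[j])) {
      cls <- if (w$leading_class == "amyloid") "earlyA" else "earlyT"
      lab[j] <- paste0(cls, if (e4pos[j]) "_e4pos" else "_e4neg")
    }
  }
  if (n_missing > 0L)
    message(n_missing, " subjects with missing APOE assigned to 'other'")
  factor(lab, levels = c("stage_zero", "earlyA_e4neg", "earlyA_e4pos",
                         "earlyT_e4neg", "earlyT_e4pos", "other"))
}

scheme_subset <- function(groups,
                          scheme = c("all_vs_stage_zero", "within_earlyA",
                                     "within_earlyT")) {
  scheme <- match.arg(scheme)
  lev <- switch(scheme,
    all_vs_stage_zero = c("stage_zero", "earlyA_e4neg", "earlyA_e4pos",
                          "earlyT_e4neg", "earlyT_e4pos"),
    within_earlyA = c("earlyA_e4neg", "earlyA_e4pos"),
    within_earlyT = c("earlyT_e4neg", "earlyT_e4pos"))
  keep <- groups %in% lev
  g <- factor(groups[keep], levels = lev)
  counts <- table(g)
  if (any(counts == 0))
    stop("empty group(s) under scheme ", scheme, ": ",
         paste(names(counts)[counts == 0], collapse = ", "))
  list(keep = keep, groups = g, reference = lev[1])
}

#' Group-difference linear regressions
#'
#' The three-regression comparison scheme: (1) all five groups with
#' stage-zero as reference; (2) within the early amyloid-first groups (e4+
#' vs e4-); (3) within the early tau-first groups. Each regression models
#' the outcome on the stated covariates plus group indicators (OLS), and
#' reports the group contrasts. No multiple-testing correction is applied;
#' p-values are nominal.
#'
#' @param outcome numeric outcome per subject.
#' @param groups factor from \code{\link{define_groups}}.
#' @param covariates data.frame of adjustment covariates (e.g. sex and
#'   education for pathology/age outcomes; age and sex for education).
#' @param scheme one of \code{"all_vs_stage_zero"}, \code{"within_earlyA"},
#'   \code{"within_earlyT"}.
#' @return data.frame: contrast, estimate, se, t, p (two-sided).
#' @export
group_regression <- function(outcome, groups, covariates, scheme) {
  ss <- scheme_subset(groups, scheme)
  df <- data.frame(.y = outcome[ss$keep],
                   covariates[ss$keep, , drop = FALSE],
                   .group = ss$groups)
  fit <- stats::lm(stats::reformulate(c(names(covariates), ".group"),
                                      response = ".y"), data = df)
  tab <- summary(fit)$coefficients
  rows <- grep("^\\.group", rownames(tab))
  data.frame(contrast = paste0(sub("^\\.group", "", rownames(tab)[rows]),
                               " vs ", ss$reference),
             estimate = tab[rows, 1], se = tab[rows, 2],
             t = tab[rows, 3], p = tab[rows, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chi-squared test of group proportions across APOE strata
#'
#' Pearson chi-squared test (no continuity correction) of the distribution
#' of early amyloid-first, early tau-first and stage-zero membership within
#' APOE e4- and e4+ participants. Early groups are collapsed over their e4
#' strata.
#'
#' @param groups factor from \code{\link{define_groups}}.
#' @param apoe_e4 allele counts per subject.
#' @return list: statistic, dof, p, and the contingency table.
#' @export
proportion_test <- function(groups, apoe_e4) {
  coarse <- as.character(groups)
  coarse[coarse %in% c("earlyA_e4neg", "earlyA_e4pos")] <- "earlyA"
  coarse[coarse %in% c("earlyT_e4neg", "earlyT_e4pos")] <- "earlyT"
  keep <- coarse %in% c("stage_zero", "earlyA", "earlyT") & !is.na(apoe_e4)
  tab <- table(factor(coarse[keep],
                      levels = c("stage_zero", "earlyA", "earlyT")),
               factor(ifelse(apoe_e4[keep] >= 1, "e4pos", "e4neg"),
                      levels = c("e4neg", "e4pos")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in group x APOE table")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), dof = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Group-difference logistic regressions
#'
#' Logistic analogue of \code{\link{group_regression}} for binary outcomes
#' (e.g. sex): maximum-likelihood fit of outcome on covariates plus group
#' indicators; reports odds ratios per contrast.
#'
#' @param outcome binary (0/1) outcome.
#' @param groups,covariates,scheme as in \code{\link{group_regression}}.
#' @return data.frame: contrast, estimate (log-odds), or, se, z, p.
#' @export
logistic_group_test <- function(outcome, groups, covariates, scheme) {
  ss <- scheme_subset(groups, scheme)
  df <- data.frame(.y = outcome[ss$keep],
                   covariates[ss$keep, , drop = FALSE],
                   .group = ss$groups)
  fit <- stats::glm(stats::reformulate(c(names(covariates), ".group"),
                                       response = ".y"),
                    family = stats::binomial(), data = df)
  if (!fit$converged || any(abs(stats::coef(fit)) > 15))
    stop("logistic fit did not converge (possible perfect separation); ",
         "consider an exact or penalized fit")
  tab <- summary(fit)$coefficients
  rows <- grep("^\\.group", rownames(tab))
  data.frame(contrast = paste0(sub("^\\.group", "", rownames(tab)[rows]),
                               " vs ", ss$reference),
             estimate = tab[rows, 1], or = exp(tab[rows, 1]),
             se = tab[rows, 2], z = tab[rows, 3], p = tab[rows, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}
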