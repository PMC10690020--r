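#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model the analysis assumes: latent progression
#' subtypes with distinct event orderings, a latent stage per subject with a
#' stage-zero mass, Gaussian biomarker noise around piecewise-linear z
#' trajectories, covariate (age/sex/education) nuisance effects on the raw
#' scale, an APOE e4-subtype association, and (optionally) longitudinal
#' visits with group-specific accumulation rates.
#'
#' The default configuration has two subtypes over 6 biomarkers (3 amyloid,
#' 3 tau) with three z events each (z = 2, 5, 10): subtype 1
#' ("amyloid-first") orders all amyloid events before any tau event; subtype
#' 2 ("tau-first") interleaves mild tau events before amyloid events.
#' Fractions are 0.6/0.4, P(e4+ | subtype) = 0.45/0.15, and the stage
#' distribution puts 20% mass at stage 0 with the remainder uniform. These
#' defaults are generator conventions for validation studies, not estimates
#' from any cohort.
#'
#' @param n_subjects number of subjects.
#' @param biomarkers biomarker names.
#' @param pathology pathology class per biomarker ("amyloid"/"tau").
#' @param event_levels z thresholds per biomarker.
#' @param n_subtypes number of latent subtypes.
#' @param subtype_fractions simplex weights over subtypes.
#' @param sequences list of ground-truth event orderings (integer
#'   permutations over the event spec); \code{NULL} builds the default
#'   amyloid-first / tau-first pair.
#' @param stage_distribution probability vector over stages 0..N.
#' @param noise_sd per-biomarker Gaussian noise sd on the z scale.
#' @param apoe_model P(e4 carrier | subtype), one value per subtype.
#' @param covariate_model list with \code{intercept} and slopes \code{age}
#'   (per year), \code{sex} (0 = male, 1 = female), \code{education}
#'   (per year) applied additively on the raw measure scale.
#' @param longitudinal list: \code{times} (visit times in years, must start
#'   at 0), \code{stage_rate} (stages/year per subtype),
#'   \code{slope} (per-subtype linear biomarker drift per year),
#'   \code{advance} ("poisson" for stochastic integer advance or
#'   "deterministic"), and \code{lme} (generative linear mixed-effects
#'   parameters for the outcome column: \code{group_time} per subtype,
#'   random-effect sds, residual sd).
#' @param neuropath list for the neuropathology generator: amyloid/tau
#'   region names (entorhinal and hippocampus are treated as MTL),
#'   \code{K} score levels, sqrt-scale \code{base}, severity separation
#'   \code{sep}, noise \code{sd}, global-label \code{misclass} rate, and
#'   \code{region_lag} (probability a region trails its expected severity by
#'   one level).
#' @param seed integer seed; all generators are deterministic given the
#'   config.
#' @return object of class \code{synth_config}.
#' @export
synth_config <- function(n_subjects = 600L,
                         biomarkers = c("A1", "A2", "A3", "T1", "T2", "T3"),
                         pathology = c("amyloid", "amyloid", "amyloid",
                                       "tau", "tau", "tau"),
                         event_levels = c(2, 5, 10),
                         n_subtypes = 2L,
                         subtype_fractions = NULL,
                         sequences = NULL,
                         stage_distribution = NULL,
                         noise_sd = 1,
                         apoe_model = NULL,
                         covariate_model = list(intercept = 0, age = 0.02,
                                                sex = 0.3,
                                                education = -0.05),
                         longitudinal = list(),
                         neuropath = list(),
                         seed = 1L) {
  spec <- event_spec(biomarkers, pathology, event_levels, kind = "zscore")
  N <- spec$n_events
  if (is.null(subtype_fractions))
    subtype_fractions <- if (n_subtypes == 2L) c(0.6, 0.4)
                         else rep(1 / n_subtypes, n_subtypes)
  if (length(subtype_fractions) != n_subtypes ||
      any(subtype_fractions < 0) ||
      abs(sum(subtype_fractions) - 1) > 1e-8)
    stop("subtype_fractions must be a simplex of length n_subtypes")
  if (is.null(sequences)) sequences <- default_sequences(spec, n_subtypes)
  if (length(sequences) != n_subtypes)
    stop("need one ground-truth sequence per subtype")
  for (s in sequences)
    if (!is_valid_sequence(spec, s))
      stop("a ground-truth sequence is not a valid event permutation")
  if (is.null(stage_distribution))
    stage_distribution <- c(0.2, rep(0.8 / N, N))
  if (length(stage_distribution) != N + 1L ||
      any(stage_distribution < 0) ||
      abs(sum(stage_distribution) - 1) > 1e-8)
    stop("stage_distribution must be a probability vector over stages 0..N")
  if (is.null(apoe_model))
    apoe_model <- if (n_subtypes == 2L) c(0.45, 0.15)
                  else rep(0.3, n_subtypes)
  noise_sd <- rep_len(noise_sd, length(biomarkers))

  long_defaults <- list(times = c(0, 1, 2),
                        stage_rate = rep(1, n_subtypes),
                        slope = rep(0, n_subtypes),
                        advance = "poisson",
                        lme = list(intercept = 1,
                                   time_slope = 0.02,
                                   group_time = c(0, rep(0.05,
                                                         n_subtypes - 1L)),
                                   re_sd = c(0.3, 0.05),
                                   resid_sd = 0.2))
  longitudinal <- utils::modifyList(long_defaults, longitudinal)
  np_defaults <- list(amyloid_regions = c("angular", "midfrontal",
                                          "cingulate", "calcarine"),
                      tau_regions = c("entorhinal", "hippocampus",
                                      "inftemporal", "supfrontal"),
                      K = 4L, base = 2, sep = 2.5, sd = 0.5,
                      misclass = 0.1, region_lag = 0.1)
  neuropath <- utils::modifyList(np_defaults, neuropath)

  structure(list(n_subjects = n_subjects, spec = spec,
                 n_subtypes = n_subtypes,
                 subtype_fractions = subtype_fractions,
                 sequences = sequences,
                 stage_distribution = stage_distribution,
                 noise_sd = noise_sd, apoe_model = apoe_model,
                 covariate_model = covariate_model,
                 longitudinal = longitudinal, neuropath = neuropath,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Default ground-truth orderings: subtype 1 runs amyloid level waves first
# (all z=2, then z=5, then z=10) followed by tau waves; subtype 2 leads with
# the mild tau wave, then alternates class waves by level.
default_sequences <- function(spec, n_subtypes) {
  ev <- spec$events
  wave_ids <- function(class, lvl)
    ev$event_id[ev$pathology == class & ev$level_index == lvl]
  L <- max(ev$level_index)
  s1 <- c(unlist(lapply(seq_len(L), function(l) wave_ids("amyloid", l))),
          unlist(lapply(seq_len(L), function(l) wave_ids("tau", l))))
  s2 <- unlist(lapply(seq_len(L), function(l)
    c(wave_ids("tau", l), wave_ids("amyloid", l))))
  seqs <- list(as.integer(s1), as.integer(s2))
  if (n_subtypes == 1L) return(seqs[1])
  if (n_subtypes == 2L) return(seqs)
  c(seqs, replicate(n_subtypes - 2L, random_sequence(spec),
                    simplify = FALSE))
}

draw_covariates <- function(n) {
  age <- round(pmin(pmax(stats::rnorm(n, 75, 8), 55), 95), 1)
  sex <- stats::rbinom(n, 1, 0.5)
  education <- round(pmin(pmax(stats::rnorm(n, 16, 2.6), 8), 20))
  icv <- round(stats::rnorm(n, 1500, 150))
  data.frame(age = age, sex = sex, education = education, icv = icv)
}

covariate_effect <- function(cm, cov) {
  cm$intercept + cm$age * cov$age + cm$sex * cov$sex +
    cm$education * cov$education
}

#' Generate a cross-sectional synthetic cohort
#'
#' Each subject draws a latent subtype (from the subtype fractions), a latent
#' stage (from the stage distribution), and APOE e4 status (from the
#' per-subtype carrier probability). Biomarker values are the expected
#' piecewise-linear z-trajectory value at the true stage plus Gaussian noise,
#' with linear covariate effects added back on the raw scale.
#'
#' @param config a \code{\link{synth_config}}.
#' @return list with \code{cohort} (one row per subject: identifiers,
#'   covariates, APOE e4 allele count, diagnosis label, biomarker columns)
#'   and \code{truth} (true subtype, stage, APOE carriage per subject plus
#'   the generating sequences and event spec).
#' @export
generate_cross_sectional <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  spec <- config$spec
  N <- spec$n_events
  subtype <- sample.int(config$n_subtypes, n, replace = TRUE,
                        prob = config$subtype_fractions)
  stage <- sample.int(N + 1L, n, replace = TRUE,
                      prob = config$stage_distribution) - 1L
  carrier <- stats::rbinom(n, 1, config$apoe_model[subtype])
  apoe_e4 <- ifelse(carrier == 1,
                    1L + stats::rbinom(n, 1, 0.2), 0L)
  cov <- draw_covariates(n)
  Z <- matrix(0, n, length(spec$biomarkers),
              dimnames = list(NULL, spec$biomarkers))
  for (c in seq_len(config$n_subtypes)) {
    idx <- which(subtype == c)
    if (!length(idx)) next
    E <- trajectory_matrix(spec, config$sequences[[c]])
    Z[idx, ] <- t(E[, stage[idx] + 1L, drop = FALSE])
  }
  Z <- Z + matrix(stats::rnorm(n * ncol(Z)), n, ncol(Z)) %*%
    diag(config$noise_sd, ncol(Z))
  raw <- Z + covariate_effect(config$covariate_model, cov)
  colnames(raw) <- spec$biomarkers
  diagnosis <- ifelse(stage == 0L, "CN",
                      ifelse(stage <= N / 2, "MCI", "AD"))
  cohort <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                       cov, apoe_e4 = apoe_e4, diagnosis = diagnosis,
                       raw, stringsAsFactors = FALSE)
  truth <- list(subjects = data.frame(subject_id = cohort$subject_id,
                                      subtype = subtype, stage = stage,
                                      apoe_pos = carrier == 1,
                                      stringsAsFactors = FALSE),
                sequences = config$sequences, spec = spec,
                config = config)
  list(cohort = cohort, truth = truth)
}

#' Generate a synthetic control cohort
#'
#' Stage-zero subjects only (no abnormal events), with covariate effects
#' present on the raw scale and APOE e4 non-carrier status, mirroring the
#' amyloid-negative, e4-negative, cognitively normal reference populations
#' used to fit covariate-adjustment models.
#'
#' @param config a \code{\link{synth_config}}.
#' @param n number of controls (default 150).
#' @return a cohort data.frame as in \code{\link{generate_cross_sectional}}.
#' @export
generate_controls <- function(config, n = 150L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 101L)
  spec <- config$spec
  cov <- draw_covariates(n)
  Z <- matrix(stats::rnorm(n * length(spec$biomarkers)), n) %*%
    diag(config$noise_sd, length(spec$biomarkers))
  raw <- Z + covariate_effect(config$covariate_model, cov)
  colnames(raw) <- spec$biomarkers
  data.frame(subject_id = sprintf("C%04d", seq_len(n)),
             cov, apoe_e4 = 0L, diagnosis = "CN", raw,
             stringsAsFactors = FALSE)
}

# Representative global labels per severity, chosen so that both the MTL and
# neocortical Braak groupings invert to the generating severity.
braak_label_for_severity <- c("II", "IV", "V", "VI")
cerad_label_for_severity <- c("no AD", "possible AD", "probable AD",
                              "definite AD")

#' Generate a synthetic neuropathology cohort
#'
#' Emulates post-mortem immunohistochemistry data: per-region continuous
#' measures (non-negative, right-skewed) coupled to a latent ordinal severity
#' 0..3 per region, plus a global CERAD-like label (4 levels) and a global
#' Braak-like label driven by the maximum regional severity of each pathology
#' with a configurable misclassification rate. Regional severities follow the
#' subject's latent stage along the subtype's event ordering over an
#' 8-region ordinal event spec (4 amyloid + 4 tau regions, 3 severity steps
#' each); a region may trail its expected severity by one level with
#' probability \code{region_lag}. Measures are generated on the square-root
#' scale as \code{base + sep * severity} plus covariate effects and Gaussian
#' noise, then squared.
#'
#' @param config a \code{\link{synth_config}}; the \code{neuropath} element
#'   controls regions, separation, noise and label misclassification.
#' @return list with \code{cohort} (covariates, global \code{cerad} and
#'   \code{braak} labels, per-region measures), \code{truth} (subtype,
#'   stage, per-region true severities, global severities) and the ordinal
#'   event \code{spec} used.
#' @export
generate_neuropath_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  np <- config$neuropath
  if (np$sep <= 0)
    warning("severity-conditional distributions overlap completely ",
            "(sep <= 0); severity is unidentifiable")
  set.seed(config$seed + 202L)
  regions <- c(np$amyloid_regions, np$tau_regions)
  pathology <- c(rep("amyloid", length(np$amyloid_regions)),
                 rep("tau", length(np$tau_regions)))
  spec <- event_spec(regions, pathology, levels = np$K, kind = "ordinal")
  N <- spec$n_events
  sequences <- default_sequences(spec, config$n_subtypes)
  n <- config$n_subjects
  subtype <- sample.int(config$n_subtypes, n, replace = TRUE,
                        prob = config$subtype_fractions)
  stage <- sample.int(N + 1L, n, replace = TRUE,
                      prob = c(0.2, rep(0.8 / N, N))) - 1L
  carrier <- stats::rbinom(n, 1, config$apoe_model[subtype])
  cov <- draw_covariates(n)

  # staged severities under the subtype sequence define the per-class
  # global severity; regions then sit at that global level, optionally
  # trailing it by one (region_lag), so that at lag 0 the global rating is
  # an exact summary of every region
  sev_staged <- matrix(0L, n, length(regions),
                       dimnames = list(NULL, regions))
  for (c in seq_len(config$n_subtypes)) {
    idx <- which(subtype == c)
    if (!length(idx)) next
    S <- stage_scores(spec, sequences[[c]])
    sev_staged[idx, ] <- t(S[, stage[idx] + 1L, drop = FALSE])
  }
  gsev_a <- apply(sev_staged[, pathology == "amyloid", drop = FALSE],
                  1, max)
  gsev_t <- apply(sev_staged[, pathology == "tau", drop = FALSE], 1, max)
  gsev <- cbind(matrix(gsev_a, n, sum(pathology == "amyloid")),
                matrix(gsev_t, n, sum(pathology == "tau")))
  lag <- matrix(stats::rbinom(n * ncol(gsev), 1, np$region_lag),
                n, ncol(gsev))
  sev_obs <- pmax(gsev - lag, 0L)
  colnames(sev_obs) <- regions

  eff <- covariate_effect(config$covariate_model, cov)
  sq <- np$base + np$sep * sev_obs + eff +
    matrix(stats::rnorm(n * ncol(sev_obs), sd = np$sd), n, ncol(sev_obs))
  measures <- pmax(sq, 0)^2
  colnames(measures) <- regions

  flip <- function(g) {
    do_flip <- stats::rbinom(length(g), 1, np$misclass) == 1
    shift <- ifelse(stats::runif(length(g)) < 0.5, -1L, 1L)
    pmin(pmax(g + ifelse(do_flip, shift, 0L), 0L), np$K - 1L)
  }
  lab_a <- flip(gsev_a)
  lab_t <- flip(gsev_t)
  cohort <- data.frame(subject_id = sprintf("N%04d", seq_len(n)),
                       cov, apoe_e4 = carrier,
                       diagnosis = ifelse(stage == 0L, "CN",
                                          ifelse(stage <= N / 2,
                                                 "MCI", "AD")),
                       cerad = cerad_label_for_severity[lab_a + 1L],
                       braak = braak_label_for_severity[lab_t + 1L],
                       measures, stringsAsFactors = FALSE)
  truth <- list(subjects = data.frame(subject_id = cohort$subject_id,
                                      subtype = subtype, stage = stage,
                                      apoe_pos = carrier == 1,
                                      global_amyloid = gsev_a,
                                      global_tau = gsev_t,
                                      stringsAsFactors = FALSE),
                severity = sev_obs, sequences = sequences, spec = spec)
  list(cohort = cohort, truth = truth, spec = spec)
}

#' Generate longitudinal visits for a baseline cohort
#'
#' Each subject receives visits at the configured times (years since
#' baseline, first visit at 0). The true stage advances at the subtype
#' group's stage rate — stochastically via a Poisson draw on rate x elapsed
#' time (so stages remain integers), or deterministically via rounding —
#' and biomarker values are regenerated from the advanced stage plus a
#' group-specific linear drift. An \code{outcome} column follows a
#' generative linear mixed-effects model with per-subject random intercepts
#' and time slopes and a group x time fixed effect, for trajectory-model
#' validation.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{generate_cross_sectional}}.
#' @param config the same \code{\link{synth_config}}.
#' @return long-format data.frame: subject_id, time_years, covariates (incl.
#'   ICV), true subtype/stage at each visit, biomarker values, outcome.
#' @export
generate_longitudinal <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  lg <- config$longitudinal
  times <- lg$times
  if (any(times < 0)) stop("negative visit times")
  if (times[1] != 0) stop("baseline visit at time 0 is required")
  set.seed(config$seed + 303L)
  spec <- truth$spec
  N <- spec$n_events
  subj <- truth$subjects
  n <- nrow(subj)
  cov <- config$covariate_model
  covdf <- draw_covariates(n)
  lme <- lg$lme
  u0 <- stats::rnorm(n, 0, lme$re_sd[1])
  u1 <- stats::rnorm(n, 0, lme$re_sd[2])
  rows <- list()
  for (v in seq_along(times)) {
    t <- times[v]
    rate <- lg$stage_rate[subj$subtype]
    adv <- if (identical(lg$advance, "deterministic")) round(rate * t)
           else stats::rpois(n, rate * t)
    stage_t <- pmin(subj$stage + adv, N)
    Z <- matrix(0, n, length(spec$biomarkers),
                dimnames = list(NULL, spec$biomarkers))
    for (c in seq_len(config$n_subtypes)) {
      idx <- which(subj$subtype == c)
      if (!length(idx)) next
      E <- trajectory_matrix(spec, truth$sequences[[c]])
      Z[idx, ] <- t(E[, stage_t[idx] + 1L, drop = FALSE])
    }
    Z <- Z + matrix(stats::rnorm(n * ncol(Z)), n, ncol(Z)) %*%
      diag(config$noise_sd, ncol(Z)) + lg$slope[subj$subtype] * t
    raw <- Z + covariate_effect(cov, covdf)
    outcome <- lme$intercept + lme$time_slope * t +
      lme$group_time[subj$subtype] * t + u0 + u1 * t +
      stats::rnorm(n, 0, lme$resid_sd)
    rows[[v]] <- data.frame(subject_id = subj$subject_id,
                            time_years = t, covdf,
                            subtype = subj$subtype,
                            true_stage = stage_t,
                            apoe_pos = subj$apoe_pos,
                            raw, outcome = outcome,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$subject_id, out$time_years), , drop = FALSE]
}
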