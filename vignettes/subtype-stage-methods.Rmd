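---
title: "Modelling amyloid and tau progression subtypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling amyloid and tau progression subtypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sustainr)
```

## The scientific problem

Alzheimer's-related pathology is driven by two protein aggregates —
amyloid-beta plaques and tau neurofibrillary tangles — that accumulate in
spatially distinct patterns and may begin as independent processes. A
long-standing question is whether their joint progression follows a single
canonical ordering (widespread neocortical amyloid preceding the spread of
tau beyond the medial temporal lobe) or whether distinct *subtypes* exist,
including a "tau-first" variant in which mild tau appears in medial temporal
and neocortical regions before substantial amyloid.

`sustainr` implements the data-driven machinery needed to ask that question
from cross-sectional biomarker tables: an event-based subtype-and-stage
model with two data likelihoods (continuous z-scores for PET SUVR-like
inputs, ordinal severity scores for post-mortem neuropathology), the
kernel-density mixture that converts continuous neuropathology measures
into severity-score probabilities anchored to global CERAD/Braak ratings,
cross-validated selection of the number of subtypes, early-stage group
comparisons stratified by APOE e4, and longitudinal consistency and
trajectory analyses. A synthetic-cohort generator with full ground truth
makes every stage of the pipeline testable at desk scale.

## The event-based model

An *event* is a (biomarker, severity level) pair. For the z-score model
each biomarker contributes events at fixed deviations from a control
population — z = 2, 5 and 10, roughly mild, moderate and severe
abnormality. Thresholds this extreme are appropriate because control
variability in PET SUVRs is small, so patient z-scores become large. A
*subtype* is a total ordering (sequence) of all N events, and a subject's
*stage* s in 0..N counts how many events along their subtype's sequence
have occurred; stage 0 is the pre-event, normal-ageing state.

Each biomarker's expected z value is piecewise linear in stage, anchored at
(0, 0), at (position of each of its events, that event's z level), and at
(N, z_max). We set z_max to the top event level + 5 (so 15 for events at
2/5/10): the trajectory needs a terminal anchor beyond the last threshold,
and the exact value matters little because stages beyond the last event are
dominated by other biomarkers' positions. When a biomarker's final event
occupies position N itself, the terminal anchor is dropped rather than
averaged with it. Trajectories are strictly increasing in stage, so every
stage has a distinct expected profile and zero-noise staging is exact.

The stage likelihood of a z-score row is a product of independent Gaussians
around the expected trajectory with sigma = 1 per biomarker — the inputs are
control-standardized, so the unit scale is the control residual SD by
construction. The ordinal likelihood replaces the Gaussians with the
subject's severity-score probabilities: at stage s, region j is expected to
carry score s_j(s) (the number of its events at positions at or before s),
and the likelihood is the product over regions of P(score = s_j(s)).
Subjects enter the model through their *marginal* likelihood, a uniform
average over stages 0..N. The uniform stage prior follows the referenced
model family; no empirical stage distribution is assumed at fit time.

## Fitting: greedy ascent, MCMC, hierarchical subtypes

Sequence fitting maximizes the total log marginal likelihood by relocation
hill-climbing: every event is tried at every position compatible with its
biomarker's internal level order (z = 2 before z = 5 before z = 10), and
moves are accepted only when the likelihood improves, from multiple random
valid restarts. A Metropolis sampler with the same single-event relocation
proposal then quantifies ordering uncertainty; the positional variance
diagram (PVD) summarizes the post-burn-in samples as the frequency with
which each event occupies each position. Within-biomarker order is
maintained by the proposal itself, so every sample is a valid sequence.

Multi-subtype models are built hierarchically: the C-subtype solution is
initialized by splitting each subtype of the (C-1)-subtype solution in turn
— random halves of its hard-assigned members, each half refit — and the
best-likelihood split is refined by EM, alternating soft subject-to-subtype
responsibilities, responsibility-weighted sequence refits (warm-started from
the current sequences) and mixture-fraction updates, until the total
log-likelihood improves by less than `tol` (default 1e-3). Soft assignment
is the default; classification (hard) EM is available via
`hard_assignment = TRUE`. Fractions are floored at 1e-3 to avoid numerical
collapse; separately, a split that leaves any subtype with fewer than
`min_members` (default 5) hard-assigned subjects is rejected, because a
sequence fitted to a handful of subjects is noise.

Defaults of 25 greedy restarts and 1e5 MCMC iterations with 1e4 burn-in are
desk-scale settings chosen so that a 600-subject, 18-event, two-subtype fit
completes in about two minutes on one core; reference implementations of
this model family run substantially longer chains. All settings are
arguments.

## Model selection: CVIC

The number of subtypes is selected by cross-validation: for each candidate
C, the model is fitted on all folds but one and the held-out subjects' log
marginal likelihood under the fitted mixture is accumulated;
CVIC(C) = -2 x (sum of held-out log-likelihoods), lower is better. The
information criterion referenced by the model family's literature is cited
but not printed in closed form there; this -2 x out-of-fold log-likelihood
reading is the package's interpretation and is stated here deliberately.
Folds are a simple random partition (no stratification). When a training
fold cannot support a C-subtype model — every candidate split collapses
below `min_members` — the (C-1)-subtype fit is carried forward with a
warning, so CVIC simply registers no improvement.

One behaviour discovered during validation is worth stating plainly: when
z-scores are *estimated* through the control-adjustment pipeline, the
per-biomarker noise scale is only approximately 1 (the control residual SD
is itself estimated from ~150-500 controls), and on single-subtype data a
second subtype can absorb that slight misspecification, producing a small
but consistent out-of-fold gain (order 0.05 nats/subject). With exactly
standardized inputs CVIC prefers the single-subtype model as expected. The
package's model-selection validation therefore standardizes its synthetic
cohorts on the generator scale, isolating selection behaviour from
adjustment estimation noise; real-data users should expect CVIC differences
of this magnitude to be within the noise floor of the adjustment step.

## Severity scoring for neuropathology (the KDE mixture)

Post-mortem data provide continuous regional measures (percent area of
amyloid staining, tangle densities) but only *global* ordinal ratings: a
CERAD neuritic-plaque rating (no/possible/probable/definite) and a Braak
stage (0..VI). The package converts continuous measures into regional
severity-score probabilities by fitting, per region, one Gaussian-kernel
density to the measures of subjects at each global score level and
normalizing the K densities at a subject's measure:

P(score k | m) = p(m | score = k) / sum_k' p(m | score = k').

Braak stages are grouped into four tau scores, with the grouping depending
on region class: medial temporal regions treat Braak 0/I/II as score 0
(age-related MTL tau is normal in the old), III/IV as mild, V moderate, VI
severe; neocortical regions, which become abnormal later, group 0..III as
score 0 and IV as mild. CERAD ratings are used directly as amyloid scores.

Numerical choices the source methodology leaves open, fixed here and
recorded in the fitted objects: Gaussian kernels with Scott's-rule
bandwidth per level (sd x n^(-1/5)); densities floored at 1e-300 before
normalizing, with a uniform 1/K fallback (and warning) if every level
underflows, so the normalizing denominator is never zero; score levels with
fewer than 5 training subjects are merged into the adjacent level with the
larger count for density fitting only, the score retaining its identity
through the shared density. Scoring operates on square-root transformed,
control-residualized measures, in that order.

## Preprocessing

Covariate adjustment follows the control-residualization scheme: for each
biomarker, an OLS regression on age, sex (0 = male, 1 = female) and
education years is fitted in a control population (stage-zero-like, APOE
e4-negative, amyloid-negative subjects), all subjects are residualized
against its predictions, and — for the z-score path — residuals are
standardized by the control residual mean and SD. A residual-SD floor of
1e-6 guards degenerate controls. Subjects missing any modelling biomarker
are dropped (complete-case rule) with a logged count; subjects missing
covariates are excluded from adjustment fitting only. Composite regions are
volume-weighted averages. The square-root transform applies only to the
neuropathology path; PET-like inputs are used as-is.

## Early-stage groups and cross-sectional comparisons

Mid-sequence stages of different subtypes can imply indistinguishable
biomarker patterns (the "crossing problem"): a subject with mild tau plus
amyloid could belong to either ordering. Group comparisons therefore use
only the *early window* of each subtype — stages [1, w] where w + 1 is the
position of the first event whose pathology class differs from the
subtype's leading class, so the window contains abnormality in one class
only. The window is derived automatically from the fitted sequence rather
than read off a PVD by eye; an optional `leading_class` argument covers the
degenerate case of a sequence that opens with the unexpected class.

Subjects are partitioned into five groups: stage-zero (MAP stage 0 in
either subtype — the normal-ageing reference), early amyloid-first and
early tau-first, each split by APOE e4 carriage (at least one e4 allele).
Comparisons follow a three-regression scheme per outcome: all groups
against the stage-zero reference, then e4+ versus e4- within each early
group, with outcome-appropriate covariates (sex and education for pathology
and age outcomes; age and sex for education). Sex uses the analogous
logistic regressions with odds ratios; group-by-APOE composition uses a
Pearson chi-squared test without continuity correction. No multiple-testing
correction is applied anywhere — reported p-values are nominal, which users
should weigh when scanning many outcomes.

## Longitudinal analyses

Follow-up visits are placed under the *frozen* baseline model and
adjustment (no refitting), making baseline and follow-up subtype/stage
assignments directly comparable. Subtype-consistency confusion matrices
cross-tabulate baseline versus follow-up MAP subtype among subjects staged
above zero at both visits — at stage 0 the subtype is undefined, and such
visits are excluded (the source analyses do not state their handling;
exclusion is this package's documented choice). Two-sided Fisher's exact
tests (sum-of-smaller-point-probabilities convention) compare consistency
between subtypes. Annual stage-change rates use the first-to-last
difference divided by elapsed years — robust with sparse irregular visits —
with a per-visit OLS slope available as an option, and are compared across
groups by one-way ANOVA.

Trajectory models are linear mixed-effects fits (maximum likelihood, via
lme4) with fixed effects of baseline age, sex, education, optionally
intracranial volume (imaging outcomes only), time in years, group main
effects and group-by-time interactions, plus per-subject random intercepts
and time slopes with unstructured covariance. Singular random-effects fits
trigger a warning and a refit with independent random effects;
non-convergence is an error. p-values use the normal approximation to the
t statistics, adequate at the subject counts the package targets (hundreds)
but anti-conservative for very small samples.

## The synthetic cohort generator

The generator emulates exactly the structure the analysis assumes, so that
recovery tests are informative about the estimator rather than about
distributional mismatch: two latent subtypes with distinct orderings
(defaults: an amyloid-first sequence running all amyloid level-waves before
any tau event, and a tau-first sequence leading with the mild-tau wave;
fractions 0.6/0.4), a latent stage with 20% mass at stage 0 and the rest
uniform (providing a usable stage-zero reference group), Gaussian biomarker
noise (sd 1) around the piecewise-linear trajectories, additive linear
age/sex/education effects on the raw scale, APOE e4 carriage probabilities
of 0.45 (amyloid-first) and 0.15 (tau-first), and longitudinal visits whose
stages advance by a Poisson draw on rate x elapsed-time (stages stay
integers; a deterministic rounding mode exists for exact tests) with
group-specific drift and a generative random-intercept/random-slope outcome
for mixed-model validation. These values are generator conventions chosen
once for validation studies — sample sizes and rates in the hundreds-of-
subjects range that the cited cohorts occupy — not estimates of any
published cohort.

The neuropathology generator couples continuous regional measures to a
latent ordinal severity 0..3: measures are built on the square-root scale
as base + separation x severity + covariate effects + Gaussian noise
(defaults 2, 2.5 and sd 0.5) and squared, giving non-negative,
right-skewed raw measures well separated by severity. Global CERAD-like
and Braak-like labels summarize the per-class severity, with a
configurable misclassification rate (default 10%) and a representative
Braak label per severity chosen so both region-class groupings invert to
the generating severity. Regional severities equal the class-global
severity except for a Bernoulli one-level lag per region (default 0.1):
with the lag and misclassification at zero, global ratings are exact
summaries of every region, the condition under which severity recovery is
a clean test of the KDE mixture itself. What the generator does *not*
emulate — spatial correlation between regions beyond the shared stage,
heavy-tailed measurement error, site effects, informative missingness —
bounds what passing tests show about real cohorts.

## Validation scale and reproducibility

The bundled validation (test suite and `scripts/acceptance.R`) runs the
full pipeline at desk scale: 500-600 subjects, 18-24 events, 3-fold
cross-validation with greedy-only fold fits, 1e5-iteration MCMC for the
headline two-subtype fit, and 20-replicate simulation studies for oracle
agreement and mixed-model coverage. These sizes were chosen so the entire
validation completes in minutes on a single core while leaving each check
statistically meaningful; every quantity is recomputed from scratch at run
time under a user-supplied seed, and identical (config, seed) pairs
reproduce byte-identical cohorts and fits.

## Known limitations

* The z-score and ordinal likelihoods assume conditional independence of
  biomarkers given stage; correlated residuals (e.g. shared scanner or
  batch effects) are not modelled.
* CVIC differences smaller than the adjustment-estimation noise floor
  (see above) should not be over-interpreted.
* The early-window rule reproduces by construction the reported-style
  cut-offs when sequences have a clean leading class, but a fitted sequence
  that interleaves classes immediately yields a narrow or empty window, and
  group comparisons then have little power.
* Subtype labels are exchangeable across fits; matching to "amyloid-first"
  / "tau-first" is by inspection of the fitted sequences (the early-window
  derivation reports each subtype's leading class).
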