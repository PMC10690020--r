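# sustainr

Event-based subtype-and-stage modelling of Alzheimer's-related amyloid-beta
and tau pathology progression from cross-sectional biomarker data.

Amyloid plaques and tau tangles accumulate in spatially distinct patterns,
and their joint ordering may differ between people: in an *amyloid-first*
variant widespread neocortical amyloid precedes the spread of tau beyond
the medial temporal lobe, while in a *tau-first* variant mild tau appears
first. `sustainr` is for researchers who want to infer such progression
subtypes from a single cross-sectional table — PET SUVR z-scores or
post-mortem immunohistochemistry with global CERAD/Braak ratings — and then
ask the downstream questions: how do early-stage groups differ by APOE e4,
demographics and pathology load, and are subtype assignments stable over
longitudinal follow-up?

## The model

An event is a (biomarker, severity level) pair; a subtype is a total
ordering sigma of all N events; a subject's stage s in 0..N counts the
events that have occurred. For the z-score likelihood, biomarker b follows
a piecewise-linear expected trajectory E_b(s | sigma) anchored at z = 0
(stage 0), at its event thresholds z = 2, 5, 10 (at their positions in
sigma), and at z_max at stage N, with

P(z | s, sigma) = prod_b Normal(z_b; E_b(s | sigma), 1),
P(z | sigma)    = mean over s of P(z | s, sigma)   (uniform stage prior).

The ordinal likelihood replaces the Gaussians with per-region severity-score
probabilities P(score_{i,j,k}) obtained from a per-region kernel-density
mixture anchored to global ratings:

P(score k | m) = p(m | score = k, region) / sum_k' p(m | score = k', region).

A C-subtype model is a mixture with fractions f_c over per-subtype
sequences, fitted by greedy relocation ascent plus Metropolis MCMC within
an EM loop, grown hierarchically from the (C-1)-subtype solution; the
number of subtypes is chosen by CVIC = -2 x sum of held-out log-likelihoods
under k-fold cross-validation (lower is better). Subjects are placed by
their joint (subtype, stage) posterior; ordering uncertainty is reported as
positional variance diagrams (PVDs).

## Worked example

Simulate a two-subtype cohort with ground truth, z-score it against a
control population, fit a two-subtype model and place subjects:

```r
library(sustainr)

cfg   <- synth_config(n_subjects = 600, seed = 404)
gen   <- generate_cross_sectional(cfg)
ctrl  <- generate_controls(cfg, 200)
adj   <- fit_control_adjustment(ctrl, cfg$spec$biomarkers)
Z     <- compute_zscores(gen$cohort, adj)

model <- fit_sustain(Z, cfg$spec, n_subtypes = 2, n_restarts = 8,
                     mcmc = list(n_iter = 1e5, burn_in = 1e4), seed = 405)
model
#> Subtype-and-stage model (zscore), 2 subtype(s), 18 events, n = 600
#> Total log-likelihood: -6846.09
#> Subtype 1 (fraction 0.392):
#>   T1:2 -> T2:2 -> T3:2 -> A1:2 -> A2:2 -> A3:2 -> T1:5 -> T2:5 -> ...
#> Subtype 2 (fraction 0.608):
#>   A1:2 -> A2:2 -> A3:2 -> A1:5 -> A2:5 -> A3:5 -> A1:10 -> A2:10 -> ...
```

The fitted subtype 2 is the amyloid-first pattern (all amyloid events
before any tau event) and subtype 1 is the tau-first pattern (mild tau wave
leading), matching the generating orderings with Kendall tau 0.99 and 1.00
and fractions 0.61/0.39 against the true 0.6/0.4. Downstream:

```r
pl      <- predict(model, Z)                    # subtype/stage placements
windows <- lapply(1:2, function(c) early_stage_window(model, c))
groups  <- define_groups(pl, windows, gen$cohort$apoe_e4)
proportion_test(groups, gen$cohort$apoe_e4)$p   # APOE-subtype association
plot(model)                                     # PVD heatmaps
```

`early_stage_window()` reports, for example, stages 1–9 for the
amyloid-first subtype: the window before its first tau event, inside which
group membership is unambiguous. Placements at stage 0 form the
normal-ageing reference group.

For the neuropathology path, `generate_neuropath_cohort()`,
`sqrt_transform()`, `residualize()`, `map_cerad()`/`map_braak()`,
`fit_kde_mixture()` and `score_probabilities()` produce the severity-score
tensor consumed by `fit_sustain()` with an ordinal `event_spec`;
`run_pipeline()` orchestrates either path end-to-end and writes model JSON,
PVD CSVs, placements and a checksummed manifest.

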