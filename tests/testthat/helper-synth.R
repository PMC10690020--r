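# Shared fixtures: small configurations and cohorts built in code.

# Tiny z-score spec: two biomarkers, two levels each (N = 4 events).
tiny_spec <- function() {
  event_spec(c("a", "t"), c("amyloid", "tau"), levels = c(2, 5))
}

# Three single-event biomarkers: 6 possible sequences, enumerable.
enum_spec <- function() {
  event_spec(c("b1", "b2", "b3"), "amyloid", levels = list(2, 2, 2))
}

# All permutations of 1..3 (sequences for enum_spec).
perms3 <- function() {
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
}

# Exhaustive maximum-likelihood sequence for enum_spec data: the
# independent oracle for greedy+MCMC fits.
brute_force_ml <- function(Z, spec) {
  ps <- perms3()
  lls <- vapply(ps, function(s) sum(log(subject_marginal(Z, spec, s))), 0)
  list(sequence = ps[[which.max(lls)]], loglik = max(lls))
}

# Simulate z-score data directly from a sequence (no covariates), for
# fitting tests that bypass preprocessing.
simulate_z <- function(spec, sequence, n, noise_sd = 1, seed = 1,
                       stage_probs = NULL) {
  set.seed(seed)
  N <- spec$n_events
  if (is.null(stage_probs)) stage_probs <- rep(1 / (N + 1), N + 1)
  stage <- sample.int(N + 1L, n, replace = TRUE, prob = stage_probs) - 1L
  E <- sustainr:::trajectory_matrix(spec, sequence)
  Z <- t(E[, stage + 1L, drop = FALSE]) +
    matrix(rnorm(n * length(spec$biomarkers), sd = noise_sd), n)
  colnames(Z) <- spec$biomarkers
  attr(Z, "stage") <- stage
  Z
}

# Default small cohort for preprocessing tests.
small_config <- function(n = 300, seed = 42, ...) {
  synth_config(n_subjects = n, seed = seed, ...)
}

# Kendall rank correlation between two sequences (on event positions).
seq_kendall <- function(s1, s2) {
  cor(order(s1), order(s2), method = "kendall")
}
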