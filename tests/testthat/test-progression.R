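# Event-based model core: trajectories, stage likelihoods, sequence fitting.

test_that("expected z trajectory passes through its anchors and interpolates", {
  spec <- event_spec(c("b", "x", "y", "w"), "amyloid",
                     levels = list(c(2, 5), 1, c(1, 2, 3), 1))
  # b's events at positions 2 and 6 of N = 7
  sq <- c(3L, 1L, 4L, 5L, 6L, 2L, 7L)
  expect_equal(expected_zscore(spec, sq, 0, "b"), 0)
  expect_equal(expected_zscore(spec, sq, 2, "b"), 2)
  expect_equal(expected_zscore(spec, sq, 6, "b"), 5)
  # linear interpolation between anchors: 2 + (4-2)/(6-2)*(5-2) = 3.5
  expect_equal(expected_zscore(spec, sq, 4, "b"), 3.5)
  # stage 0 is 0 for every biomarker
  for (b in spec$biomarkers) expect_equal(expected_zscore(spec, sq, 0, b), 0)
  expect_error(expected_zscore(spec, sq, 8, "b"), "out of range")
})

test_that("trajectories are monotone non-decreasing in stage", {
  spec <- tiny_spec()
  set.seed(7)
  for (i in 1:10) {
    sq <- sustainr:::random_sequence(spec)
    E <- sustainr:::trajectory_matrix(spec, sq)
    expect_true(all(diff(t(E)) >= -1e-12))
  }
})

test_that("z-score stage likelihood is Gaussian around the trajectory", {
  spec <- tiny_spec()
  sq <- c(1L, 3L, 2L, 4L)
  B <- length(spec$biomarkers)
  E <- sustainr:::trajectory_matrix(spec, sq)
  z <- E[, 3]  # exactly at stage-2 expectation
  names(z) <- spec$biomarkers
  expect_equal(zscore_stage_likelihood(z, spec, sq, 2), (2 * pi)^(-B / 2))
  # moving one coordinate away strictly decreases the likelihood
  lik <- sapply(c(0, 0.5, 1, 2), function(d) {
    z2 <- z; z2[1] <- z2[1] + d
    zscore_stage_likelihood(z2, spec, sq, 2)
  })
  expect_true(all(diff(lik) < 0))
  expect_error(zscore_stage_likelihood(z, spec, sq, 2, sigma = 0),
               "positive")
})

test_that("single-event biomarker at its threshold favours stage 1 over 0", {
  spec <- event_spec("b", "amyloid", levels = list(2))
  z <- c(b = 2)
  l0 <- zscore_stage_likelihood(z, spec, 1L, 0)
  l1 <- zscore_stage_likelihood(z, spec, 1L, 1)
  expect_gt(l1, l0)
  expect_equal(l1, dnorm(2, 2))
  expect_equal(l0, dnorm(2, 0))
})

test_that("ordinal stage likelihood reproduces the hand-worked product", {
  osp <- event_spec(c("r1", "r2"), "amyloid", levels = 2, kind = "ordinal")
  pr <- rbind(r1 = c(0.2, 0.8), r2 = c(0.7, 0.3))
  lik <- sapply(0:2, function(s) ordinal_stage_likelihood(pr, osp,
                                                          c(1L, 2L), s))
  expect_equal(lik, c(0.14, 0.56, 0.24))
  # uniform rows are stage-uninformative: K^(-R) everywhere
  pu <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(sapply(0:2, function(s)
    ordinal_stage_likelihood(pu, osp, c(1L, 2L), s)), rep(0.25, 3))
  # all mass on the true scores of a stage-1 subject
  p1 <- rbind(c(0, 1), c(1, 0))
  lik1 <- sapply(0:2, function(s) ordinal_stage_likelihood(p1, osp,
                                                           c(1L, 2L), s))
  expect_equal(lik1[2], 1)
  expect_true(all(lik1[-2] < 1))
  expect_error(ordinal_stage_likelihood(rbind(c(0.9, 0.3), c(0.5, 0.5)),
                                        osp, c(1L, 2L), 0), "malformed")
})

test_that("subject marginal averages stage likelihoods uniformly", {
  osp <- event_spec(c("r1", "r2"), "amyloid", levels = 2, kind = "ordinal")
  P <- array(0, c(1, 2, 2))
  P[1, , ] <- rbind(c(0.2, 0.8), c(0.7, 0.3))
  expect_equal(subject_marginal(P, osp, c(1L, 2L)),
               (0.14 + 0.56 + 0.24) / 3)
  P[1, , ] <- 0.5
  expect_equal(subject_marginal(P, osp, c(1L, 2L)), 0.25)
})

test_that("random sequences and MCMC proposals respect level order", {
  spec <- event_spec(c("a", "b"), "amyloid", levels = list(c(2, 5, 10),
                                                           c(1, 3)))
  set.seed(11)
  for (i in 1:25) {
    sq <- sustainr:::random_sequence(spec)
    expect_true(sustainr:::is_valid_sequence(spec, sq))
    from <- sample.int(spec$n_events, 1)
    b <- sustainr:::relocation_bounds(spec, sq, from)
    for (to in seq.int(b[1], b[2]))
      expect_true(sustainr:::is_valid_sequence(
        spec, sustainr:::relocate_event(sq, from, to)))
  }
})

test_that("greedy+MCMC matches the exhaustive ML sequence on enumerable data", {
  spec <- enum_spec()
  set.seed(3)
  for (i in 1:5) {
    truth <- perms3()[[sample.int(6, 1)]]
    Z <- simulate_z(spec, truth, n = 100, noise_sd = 1, seed = 100 + i)
    oracle <- brute_force_ml(Z, spec)
    fit <- fit_single_subtype(Z, spec, n_restarts = 5,
                              mcmc = list(n_iter = 2000, burn_in = 500),
                              seed = 200 + i)
    expect_identical(fit$sequence, oracle$sequence)
    expect_equal(fit$loglik, oracle$loglik)
  }
})

test_that("zero-noise data recovers the generating sequence exactly", {
  spec <- tiny_spec()
  truth <- c(1L, 3L, 2L, 4L)
  Z <- simulate_z(spec, truth, n = 200, noise_sd = 0, seed = 5)
  fit <- fit_single_subtype(Z, spec, n_restarts = 8,
                            mcmc = list(n_iter = 2000, burn_in = 500),
                            seed = 6)
  expect_identical(fit$sequence, truth)
})

test_that("sequence fits are deterministic given data and seed", {
  spec <- tiny_spec()
  Z <- simulate_z(spec, c(1L, 3L, 2L, 4L), n = 80, seed = 9)
  f1 <- fit_single_subtype(Z, spec, n_restarts = 3,
                           mcmc = list(n_iter = 1000, burn_in = 200),
                           seed = 10)
  f2 <- fit_single_subtype(Z, spec, n_restarts = 3,
                           mcmc = list(n_iter = 1000, burn_in = 200),
                           seed = 10)
  expect_identical(f1$sequence, f2$sequence)
  expect_identical(f1$samples, f2$samples)
})

test_that("MCMC samples always respect within-biomarker level order", {
  spec <- event_spec(c("a", "t"), c("amyloid", "tau"),
                     levels = c(2, 5, 10))
  Z <- simulate_z(spec, sustainr:::random_sequence(spec), n = 60, seed = 13)
  fit <- fit_single_subtype(Z, spec, n_restarts = 2,
                            mcmc = list(n_iter = 3000, burn_in = 500,
                                        thin = 5),
                            seed = 14)
  pos_a <- apply(fit$samples, 1, function(s) order(s)[1:3])
  pos_t <- apply(fit$samples, 1, function(s) order(s)[4:6])
  expect_true(all(apply(pos_a, 2, function(p) all(diff(p) > 0))))
  expect_true(all(apply(pos_t, 2, function(p) all(diff(p) > 0))))
})

test_that("greedy ascent never decreases the total log-likelihood", {
  spec <- tiny_spec()
  Z <- simulate_z(spec, c(1L, 3L, 2L, 4L), n = 50, seed = 21)
  ctx <- sustainr:::ll_context(Z, spec)
  set.seed(22)
  s0 <- sustainr:::random_sequence(spec)
  ll0 <- sustainr:::ctx_total(ctx, s0)
  g <- sustainr:::greedy_ascent(ctx, s0)
  expect_gte(g$loglik, ll0)
})

test_that("multi-subtype likelihood is non-decreasing in C (nesting)", {
  cfg0 <- small_config(n = 200, seed = 31,
                       covariate_model = list(intercept = 0, age = 0,
                                              sex = 0, education = 0))
  gen0 <- generate_cross_sectional(cfg0)
  Z <- as.matrix(gen0$cohort[, cfg0$spec$biomarkers])
  m1 <- fit_sustain(Z, cfg0$spec, n_subtypes = 1, n_restarts = 3,
                    mcmc = list(n_iter = 0), seed = 32)
  m2 <- fit_sustain(Z, cfg0$spec, n_subtypes = 2, n_restarts = 3,
                    mcmc = list(n_iter = 0), seed = 32)
  expect_gte(m2$loglik, m1$loglik)
  expect_equal(sum(m2$fractions), 1)
})

test_that("positional variance diagrams summarize sample frequencies", {
  spec <- tiny_spec()
  s1 <- c(1L, 3L, 2L, 4L)
  pvd1 <- positional_variance(matrix(s1, nrow = 1), spec)
  expect_true(all(pvd1 %in% c(0, 1)))
  expect_equal(rowSums(pvd1), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unname(pvd1[cbind(s1, 1:4)]), rep(1, 4))
  # two samples differing by one adjacent transposition split 0.5/0.5
  s2 <- c(3L, 1L, 2L, 4L)
  pvd2 <- positional_variance(rbind(s1, s2), spec)
  expect_equal(rowSums(pvd2), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unname(pvd2[1, 1:2]), c(0.5, 0.5))
  expect_equal(unname(pvd2[3, 1:2]), c(0.5, 0.5))
  expect_error(positional_variance(matrix(integer(0), 0, 4)), "no sequence")
})
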