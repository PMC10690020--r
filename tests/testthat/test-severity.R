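# KDE severity scoring: label maps, mixtures, score probabilities.

test_that("Braak groupings differ between MTL and neocortical regions", {
  expect_equal(map_braak("III", "MTL"), 1L)
  expect_equal(map_braak("III", "neocortical"), 0L)
  expect_equal(map_braak("VI", "MTL"), 3L)
  expect_equal(map_braak("VI", "neocortical"), 3L)
  expect_equal(map_braak(c("0", "I", "II"), "MTL"), rep(0L, 3))
  expect_equal(map_braak("IV", "MTL"), 1L)
  expect_equal(map_braak("IV", "neocortical"), 1L)
  expect_equal(map_braak("V", "MTL"), 2L)
  expect_equal(map_braak(4, "neocortical"), 1L)  # numeric labels accepted
  expect_error(map_braak("VII", "MTL"), "unknown")
})

test_that("CERAD ratings map directly onto scores 0..3", {
  expect_equal(map_cerad(c("no AD", "possible AD", "probable AD",
                           "definite AD")), 0:3)
  expect_equal(map_cerad("Probable Alzheimer's disease"), 2L)
  expect_error(map_cerad("maybe AD"), "unknown")
})

test_that("identical training sets per level give uniform probabilities", {
  set.seed(111)
  x <- rnorm(40)
  mix <- fit_kde_mixture(rep(x, 4), rep(0:3, each = 40), region = "r")
  probs <- score_probabilities(matrix(c(-1, 0, 2), ncol = 1),
                               list(mix))
  expect_equal(unname(probs[, 1, ]),
               matrix(0.25, 3, 4), tolerance = 1e-12)
})

test_that("well-separated levels dominate near their own mode", {
  set.seed(112)
  m <- c(rnorm(200, 0, 0.5), rnorm(200, 10, 0.5))
  s <- rep(0:1, each = 200)
  mix <- fit_kde_mixture(m, s, region = "r", K = 2)
  d <- kde_density(mix, 0)
  expect_gt(d[1, 1] / d[1, 2], 1e3)
  # normalization: Eq. 1 slices sum to 1
  probs <- score_probabilities(matrix(seq(-1, 11, by = 0.5), ncol = 1),
                               list(mix))
  expect_true(all(abs(apply(probs, c(1, 2), sum) - 1) < 1e-9))
})

test_that("halving the bandwidth raises the training-set likelihood", {
  # the KDE overfitting property: a narrower bandwidth concentrates mass
  # on the training sample, raising its mean log density (pointwise
  # monotonicity does not hold for individual training points)
  set.seed(113)
  x <- rnorm(60)
  mix <- fit_kde_mixture(x, rep(0:1, each = 30), region = "r", K = 2)
  for (k in 1:2) {
    d <- mix$densities[[k]]
    at_train <- sustainr:::gauss_kde(d$train, d$train, d$h)
    at_half <- sustainr:::gauss_kde(d$train, d$train, d$h / 2)
    expect_gt(mean(log(at_half)), mean(log(at_train)))
  }
})

test_that("score probabilities follow the density ratio analytically", {
  # single-kernel densities: one training point per level, bandwidth 1;
  # densities at m = 0 are dnorm(0) and dnorm(x), giving an exact ratio
  mix <- structure(list(region = "r", K = 2,
                        densities = list(list(train = 0, h = 1),
                                         list(train = sqrt(2 * log(3)),
                                              h = 1)),
                        counts = c(1L, 1L), groups = 1:2,
                        bandwidths = c(1, 1), min_count = 1L),
                   class = "kde_mixture")
  probs <- score_probabilities(matrix(0), list(mix))
  expect_equal(unname(probs[1, 1, ]), c(0.75, 0.25), tolerance = 1e-12)
  # equidistant between two symmetric kernels: exactly (0.5, 0.5)
  mix$densities <- list(list(train = -1, h = 1), list(train = 1, h = 1))
  probs2 <- score_probabilities(matrix(0), list(mix))
  expect_equal(unname(probs2[1, 1, ]), c(0.5, 0.5))
  expect_error(score_probabilities(matrix(NA_real_), list(mix)), "NaN|NA")
})

test_that("sparse score levels are merged into a neighbouring density", {
  set.seed(114)
  m <- c(rnorm(50, 0), rnorm(3, 5), rnorm(50, 10))
  s <- c(rep(0, 50), rep(1, 3), rep(2, 50))
  mix <- fit_kde_mixture(m, s, region = "r", K = 3)
  expect_equal(mix$counts, c(50L, 3L, 50L))
  # level 1 shares a density with one of its neighbours
  expect_true(mix$groups[2] %in% c(mix$groups[1], mix$groups[3]))
  expect_error(fit_kde_mixture(rnorm(6), rep(0:2, each = 2), "r", K = 3,
                               min_count = 10), "fewer than")
})

test_that("argmax score recovers severity on separated synthetic data", {
  cfg <- small_config(n = 300, seed = 115,
                      neuropath = list(misclass = 0, region_lag = 0))
  np <- generate_neuropath_cohort(cfg)
  regions <- colnames(np$truth$severity)
  # pipeline order: sqrt, residualize against label-defined controls, KDE
  cohort_sq <- np$cohort
  cohort_sq[regions] <- sqrt_transform(as.matrix(np$cohort[, regions]))
  ctrl <- cohort_sq[np$cohort$cerad == "no AD" &
                      np$cohort$diagnosis == "CN", ]
  adj <- fit_control_adjustment(ctrl, regions)
  res <- residualize(cohort_sq, adj)
  sq <- as.matrix(res[, regions])
  mixtures <- lapply(seq_along(regions), function(i) {
    cls <- np$spec$pathology[regions[i]]
    score <- if (cls == "amyloid") map_cerad(np$cohort$cerad)
             else map_braak(np$cohort$braak,
                            if (regions[i] %in% c("entorhinal",
                                                  "hippocampus"))
                              "MTL" else "neocortical")
    fit_kde_mixture(sq[, i], score, region = regions[i], K = 4)
  })
  probs <- score_probabilities(sq, mixtures)
  expect_true(all(abs(apply(probs, c(1, 2), sum) - 1) < 1e-9))
  hit <- 0; tot <- 0
  for (i in seq_along(regions)) {
    pred <- max.col(probs[, i, ]) - 1L
    hit <- hit + sum(pred == np$truth$severity[, i])
    tot <- tot + nrow(np$cohort)
  }
  expect_gte(hit / tot, 0.95)
})

test_that("P(top score) is monotone when training levels are ordered", {
  set.seed(116)
  m <- c(rnorm(100, 0, 1), rnorm(100, 4, 1), rnorm(100, 8, 1))
  s <- rep(0:2, each = 100)
  mix <- fit_kde_mixture(m, s, region = "r", K = 3)
  grid <- seq(min(m), max(m), length.out = 80)
  probs <- score_probabilities(matrix(grid, ncol = 1), list(mix))
  ptop <- probs[, 1, 3]
  expect_true(all(diff(ptop) > -1e-6))
})

test_that("tensor assembly concatenates regions and preserves slices", {
  set.seed(117)
  mk <- function(R, prefix) {
    a <- array(runif(10 * R * 4), c(10, R, 4))
    a <- a / rep(apply(a, c(1, 2), sum), times = 4)
    dimnames(a) <- list(paste0("s", 1:10), paste0(prefix, 1:R),
                        paste0("score", 0:3))
    a
  }
  ta <- mk(8, "amy"); tt <- mk(8, "tau")
  out <- assemble_ordinal_input(ta, tt)
  expect_equal(dim(out), c(10, 16, 4))
  expect_true(all(abs(apply(out, c(1, 2), sum) - 1) < 1e-9))
  expect_equal(attr(out, "pathology"),
               rep(c("amyloid", "tau"), each = 8))
  # no second tensor: identity with pathology attribute
  solo <- assemble_ordinal_input(ta)
  expect_equal(unname(solo[, , ]), unname(ta[, , ]))
  bad <- mk(8, "tau")[1:5, , ]
  expect_error(assemble_ordinal_input(ta, bad), "mismatch")
  spec <- event_spec_from_tensor(out)
  expect_equal(spec$kind, "ordinal")
  expect_equal(spec$n_events, 48)
  expect_equal(unname(spec$pathology["tau3"]), "tau")
})
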