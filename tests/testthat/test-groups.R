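# Early-window derivation, five-group construction, comparison schemes.

test_that("early window ends before the first other-class event", {
  spec <- event_spec(c("a1", "a2", "t1"), c("amyloid", "amyloid", "tau"),
                    levels = list(c(2, 5), 1, 1))
  # toy ordering A, A, T, A -> window [1, 2]
  model <- sustain_model(spec, c(1L, 3L, 4L, 2L))
  w <- early_stage_window(model, 1)
  expect_equal(w$window, c(1L, 2L))
  expect_equal(w$leading_class, "amyloid")
  expect_equal(w$first_other_pos, 3L)
  # auto-derived leading class follows the first event
  model2 <- sustain_model(spec, c(4L, 1L, 3L, 2L))
  w2 <- early_stage_window(model2, 1)
  expect_equal(w2$leading_class, "tau")
  expect_equal(w2$window, c(1L, 1L))
  # a subtype regarded as amyloid-leading whose first event is tau has an
  # empty early window
  expect_equal(early_stage_window(model2, 1, "amyloid")$window, c(1L, 0L))
  # single-class spec: full range with a warning
  spec1 <- event_spec(c("a1", "a2"), "amyloid", levels = list(1, 1))
  model3 <- sustain_model(spec1, c(1L, 2L))
  expect_warning(w3 <- early_stage_window(model3, 1), "full stage range")
  expect_equal(w3$window, c(1L, 2L))
})

test_that("default amyloid-first ordering yields a stage 1-9 early window", {
  cfg <- small_config(seed = 121)
  model <- sustain_model(cfg$spec, cfg$sequences, cfg$subtype_fractions)
  w1 <- early_stage_window(model, 1)
  expect_equal(w1$leading_class, "amyloid")
  expect_equal(w1$window, c(1L, 9L))
  w2 <- early_stage_window(model, 2)
  expect_equal(w2$leading_class, "tau")
  expect_equal(w2$window, c(1L, 3L))
  # by construction no other-class event inside either window
  for (w in list(w1, w2)) {
    seqn <- model$sequences[[w$subtype]]
    cls <- cfg$spec$events$pathology[seqn]
    if (w$window[2] >= 1)
      expect_true(all(cls[seq_len(w$window[2])] == w$leading_class))
  }
})

make_placements <- function(stage, subtype) {
  structure(data.frame(subject_id = as.character(seq_along(stage)),
                       map_subtype = ifelse(stage == 0, NA, subtype),
                       subtype_label = ifelse(stage == 0, "none",
                                              paste0("S", subtype)),
                       map_stage = stage, stage_zero = stage == 0,
                       entropy = 0),
            class = c("sustain_placement", "data.frame"))
}

default_windows <- function() {
  list(list(subtype = 1, leading_class = "amyloid", window = c(1L, 9L),
            first_other_pos = 10L),
       list(subtype = 2, leading_class = "tau", window = c(1L, 3L),
            first_other_pos = 4L))
}

test_that("group labels partition subjects per the five-group rules", {
  pl <- make_placements(stage = c(0, 3, 3, 12, 2, 5, 0),
                        subtype = c(1, 1, 1, 1, 2, 2, 2))
  apoe <- c(0, 1, 0, 0, 2, 0, 1)
  g <- define_groups(pl, default_windows(), apoe)
  expect_equal(as.character(g),
               c("stage_zero", "earlyA_e4pos", "earlyA_e4neg", "other",
                 "earlyT_e4pos", "other", "stage_zero"))
  expect_equal(length(g), nrow(pl))
  expect_equal(sum(table(g)), nrow(pl))
  # missing APOE goes to other, with a log message
  expect_message(g2 <- define_groups(pl, default_windows(),
                                     c(NA, apoe[-1])), "missing APOE")
  expect_equal(as.character(g2)[1], "stage_zero")
  expect_message(g3 <- define_groups(make_placements(2, 1),
                                     default_windows(), NA), "missing")
  expect_equal(as.character(g3), "other")
})

test_that("group regressions recover known shifts and null effects", {
  set.seed(131)
  n_per <- 50
  lev <- c("stage_zero", "earlyA_e4neg", "earlyA_e4pos", "earlyT_e4neg",
           "earlyT_e4pos")
  groups <- factor(rep(lev, each = n_per), levels = c(lev, "other"))
  cov <- data.frame(sex = rbinom(length(groups), 1, 0.5),
                    education = rnorm(length(groups), 16, 2))
  # outcome with a +1 shift in earlyA_e4pos only, sd 0.1
  y <- 0.2 * cov$sex + rnorm(length(groups), 0, 0.1) +
    (groups == "earlyA_e4pos") * 1
  res <- group_regression(y, groups, cov, "all_vs_stage_zero")
  row <- res[res$contrast == "earlyA_e4pos vs stage_zero", ]
  expect_lt(abs(row$estimate - 1), 2 * row$se)
  expect_lt(row$p, 1e-6)
  # outcome identical across groups: all |t| small
  y0 <- 0.2 * cov$sex + rnorm(length(groups), 0, 0.1)
  res0 <- group_regression(y0, groups, cov, "all_vs_stage_zero")
  expect_true(all(abs(res0$t) < 3.5))
  # within-scheme contrast uses the e4- reference
  res2 <- group_regression(y, groups, cov, "within_earlyA")
  expect_equal(res2$contrast, "earlyA_e4pos vs earlyA_e4neg")
  expect_lt(abs(res2$estimate - 1), 2 * res2$se)
  expect_error(group_regression(y[groups != "earlyT_e4pos"],
                                droplevels(groups[groups != "earlyT_e4pos"]),
                                cov[groups != "earlyT_e4pos", ],
                                "all_vs_stage_zero"), "empty")
})

test_that("proportion test matches the closed-form Pearson statistic", {
  # identical proportions across strata: statistic exactly 0
  g <- factor(rep(c("stage_zero", "earlyA_e4neg", "earlyT_e4neg",
                    "stage_zero", "earlyA_e4pos", "earlyT_e4pos"),
                  each = 10),
              levels = c("stage_zero", "earlyA_e4neg", "earlyA_e4pos",
                         "earlyT_e4neg", "earlyT_e4pos", "other"))
  apoe <- rep(c(0, 0, 0, 1, 1, 1), each = 10)
  pt <- proportion_test(g, apoe)
  expect_equal(pt$statistic, 0)
  expect_equal(pt$dof, 2)
  # hand-computed Pearson chi-squared on the 3x2 table
  g2 <- factor(c(rep("stage_zero", 40), rep("earlyA_e4neg", 10),
                 rep("earlyA_e4pos", 30), rep("earlyT_e4neg", 30),
                 rep("earlyT_e4pos", 10)),
               levels = levels(g))
  apoe2 <- c(rep(0, 20), rep(1, 20), rep(0, 10), rep(1, 30), rep(0, 30),
             rep(1, 10))
  tab <- pt2 <- proportion_test(g2, apoe2)
  O <- pt2$table
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(pt2$statistic, sum((O - E)^2 / E))
  # transposition invariance of the statistic
  ct <- suppressWarnings(chisq.test(t(O), correct = FALSE))
  expect_equal(pt2$statistic, unname(ct$statistic))
  expect_error(proportion_test(g2[1:40], apoe2[1:40]), "zero margin")
})

test_that("configured APOE association is detectable with high power", {
  reject <- 0
  for (i in 1:20) {
    cfg <- synth_config(n_subjects = 600, seed = 140 + i)
    gen <- generate_cross_sectional(cfg)
    tr <- gen$truth$subjects
    model <- sustain_model(cfg$spec, cfg$sequences, cfg$subtype_fractions)
    windows <- lapply(1:2, function(c) early_stage_window(model, c))
    pl <- make_placements(tr$stage, tr$subtype)
    g <- define_groups(pl, windows, ifelse(tr$apoe_pos, 1, 0))
    pt <- proportion_test(g, ifelse(tr$apoe_pos, 1, 0))
    if (pt$p < 0.05) reject <- reject + 1
  }
  expect_gte(reject / 20, 0.8)
})

test_that("logistic group tests estimate odds ratios correctly", {
  set.seed(151)
  n_per <- 200
  lev <- c("earlyA_e4neg", "earlyA_e4pos")
  groups <- factor(rep(lev, each = n_per),
                   levels = c("stage_zero", lev, "earlyT_e4neg",
                              "earlyT_e4pos", "other"))
  cov <- data.frame(age = rnorm(2 * n_per, 75, 7),
                    education = rnorm(2 * n_per, 16, 2))
  # true OR 3 between groups
  p <- plogis(qlogis(0.35) + log(3) * (groups == "earlyA_e4pos"))
  y <- rbinom(2 * n_per, 1, p)
  res <- logistic_group_test(y, groups, cov, "within_earlyA")
  expect_lt(abs(res$estimate - log(3)), 2 * res$se)
  # null outcome: OR near 1
  y0 <- rbinom(2 * n_per, 1, 0.4)
  res0 <- logistic_group_test(y0, groups, cov, "within_earlyA")
  expect_lt(abs(res0$estimate), 3 * res0$se)
  # reversing the factor's reference inverts the odds ratio
  groups_rev <- factor(as.character(groups),
                       levels = c("stage_zero", "earlyA_e4pos",
                                  "earlyA_e4neg", "earlyT_e4neg",
                                  "earlyT_e4pos", "other"))
  fit1 <- glm(y ~ I(groups == "earlyA_e4pos"), family = binomial())
  fit2 <- glm(y ~ I(groups == "earlyA_e4neg"), family = binomial())
  expect_equal(exp(coef(fit1)[2]), 1 / exp(coef(fit2)[2]),
               ignore_attr = TRUE)
  # perfect separation is reported as an error
  ysep <- as.integer(groups == "earlyA_e4pos")
  suppressWarnings(
    expect_error(logistic_group_test(ysep, groups, cov, "within_earlyA"),
                 "separation"))
})
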