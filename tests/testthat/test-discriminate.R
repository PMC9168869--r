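test_that("window enumeration covers all 30 within-phase ranges", {
  w <- enumerate_windows()
  expect_equal(nrow(w), 30L)
  expect_true("0%-100% night" %in% w$label)
  expect_true(all(w$start_bin <= w$end_bin))
  # no range crosses the day/night boundary
  expect_true(all((w$lo < 0.5) == (w$hi <= 0.5)))
  # deterministic (phase, start, end) order
  expect_identical(w$label, w$label[order(match(w$phase, c("day", "night")),
                                          w$start_bin, w$end_bin)])
  expect_equal(ncol(utils::combn(w$window_id, 2)), 435L)
})

test_that("DeLong AUC equals the pair-counting oracle and matches pROC", {
  skip_if_not_installed("pROC")
  expect_equal(auc_delong(1:8, c(F, F, F, F, T, T, T, T))[["auc"]], 1)
  set.seed(8)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    v <- round(rnorm(n), 1)  # ties likely
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(l) || all(l)) next
    a <- auc_delong(v, l)
    expect_equal(a[["auc"]], auc_pairs(v, l))
    pr <- pROC::roc(response = l, predictor = v, quiet = TRUE, direction = "<")
    ci <- suppressWarnings(pROC::ci.auc(pr, method = "delong"))
    expect_equal(a[["auc"]], as.numeric(pROC::auc(pr)))
    if (all(is.finite(ci))) {  # pROC yields NA CIs on degenerate splits
      expect_equal(a[["ci_low"]], max(0, ci[1]), tolerance = 1e-8)
      expect_equal(a[["ci_high"]], min(1, ci[3]), tolerance = 1e-8)
    }
  }
  # label-independent values give AUC near 1/2
  set.seed(9)
  a <- auc_delong(rnorm(2000), rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(a[["auc"]] - 0.5), 0.05)
  expect_error(auc_delong(1:5, rep(TRUE, 5)), "non-empty")
})

test_that("label flips map auc to 1 - auc and smd to -smd", {
  set.seed(10)
  v <- rnorm(30); l <- rep(c(TRUE, FALSE), 15)
  expect_equal(auc_delong(v, l)[["auc"]], 1 - auc_delong(v, !l)[["auc"]])
  expect_equal(compare_groups(v, l)$smd, -compare_groups(v, !l)$smd)
})

test_that("Mann-Whitney p equals exhaustive permutation enumeration on small samples", {
  set.seed(11)
  for (i in 1:10) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- round(rnorm(n1), 3); y <- round(rnorm(n2, 0.5), 3)
    cg <- compare_groups(c(x, y), c(rep(TRUE, n1), rep(FALSE, n2)))
    expect_equal(cg$p_mwu, mwu_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("SMD has the case-minus-comparison sign convention and consistent scale", {
  x <- c(5, 6, 7, 8); y <- c(1, 2, 3, 4)
  cg <- compare_groups(c(x, y), c(rep(TRUE, 4), rep(FALSE, 4)))
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  expect_equal(cg$smd, (mean(x) - mean(y)) / sp)
  expect_true(cg$smd_ci[1] < cg$smd & cg$smd < cg$smd_ci[2])
  # identical samples: smd undefined (zero pooled SD) is an error
  expect_error(compare_groups(rep(1, 8), rep(c(TRUE, FALSE), 4)), "pooled")
  # two shifted normals at large n recover d = 1
  set.seed(12)
  v <- c(rnorm(10000, 1), rnorm(10000, 0))
  cg <- compare_groups(v, rep(c(TRUE, FALSE), each = 10000))
  expect_lt(abs(cg$smd - 1), 0.05)
})

test_that("correlations match direct formula evaluation on toy pairs", {
  x <- c(1, 2, 3, 5, 8, 13)
  y <- c(2.2, 1.8, 3.5, 4.9, 9.1, 12.5)
  ct <- correlate(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r[ct$method == "pearson"], r_hand)
  expect_equal(ct$r[ct$method == "spearman"], cor(rank(x), rank(y)))
  # y = x: both 1; monotone nonlinear: spearman 1, pearson < 1
  ct2 <- correlate(x, exp(x))
  expect_equal(ct2$r[ct2$method == "spearman"], 1)
  expect_lt(ct2$r[ct2$method == "pearson"], 1)
  ct3 <- correlate(x, x)
  expect_equal(ct3$r, c(1, 1))
})

test_that("Benjamini-Hochberg follows the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  # order invariance and the step-up lower bound
  set.seed(13)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  # adjusted values never fall below the raw p and are monotone in raw-p order
  adj <- adjust_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj <= 1))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("confounder screen flags planted associations and skips constants", {
  set.seed(14)
  age <- runif(60, 20, 70)
  v <- age + rnorm(60, 0, 5)
  f <- confounder_screen(v, age = age, gender = rep(c(0, 1), 30),
                         medication = rep(0, 60))
  expect_true(all(f$flagged[f$covariate == "age"]))
  expect_true(is.finite(f$p[f$covariate == "gender"]))
  expect_match(f$note[f$covariate == "medication"], "skipped")
  # independent covariates on pure noise: no systematic flags expected
  v0 <- rnorm(60)
  f0 <- confounder_screen(v0, age = age, gender = rep(c(0, 1), 30),
                          medication = rep(c(0, 1), each = 30))
  expect_true(is.finite(f0$p[f0$covariate == "medication"]))
})

test_that("descriptive cohort tests reproduce printed 2x2 and 2x4 chi-square p-values", {
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:79),
    group = rep(c("control", "patient"), c(24, 55)),
    gender = c(rep("m", 11), rep("w", 13), rep("m", 20), rep("w", 35)),
    # one patient has no recorded ethnicity (printed percentages are out of 54)
    ethnicity = c(rep("Asian", 3), rep("Caucasian", 18), rep("Hispanic", 1),
                  rep("Middle-Eastern", 2), rep("Caucasian", 51),
                  rep("Middle-Eastern", 3), NA),
    age = c(rnorm(24, 33.5, 10.6), rnorm(55, 36.8, 9.5))
  )
  d <- suppressWarnings(describe_cohort(subjects, "group",
                                        c("gender", "ethnicity", "age")))
  expect_lt(abs(d$p[d$variable == "gender"] - 0.588), 0.001)
  expect_lt(abs(d$p[d$variable == "ethnicity"] - 0.019), 0.001)
  # identical compositions give p = 1
  same <- tibble::tibble(subject_id = as.character(1:40),
                         group = rep(c("a", "b"), each = 20),
                         sex = rep(rep(c("m", "w"), each = 10), 2))
  expect_equal(describe_cohort(same, "group", "sex")$p, 1)
})

test_that("identical groups give flat searches with deterministic tie-break order", {
  # two copies of the same trend set: every AUC is exactly 1/2
  set.seed(15)
  p <- runif(300)
  tr <- fit_trend(p, 100 + 10 * sin(2 * pi * p))
  trends <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:8), metric = "sdnn_pct",
    n_points = 300, trend = replicate(8, tr, simplify = FALSE)
  )
  grouping <- tibble::tibble(subject_id = trends$subject_id,
                             class = rep(c(TRUE, FALSE), 4))
  res <- search_single(trends, grouping, metrics = "sdnn_pct")
  expect_true(all(res$auc == 0.5))
  w <- enumerate_windows()
  expect_identical(res$selector, w$label)  # pure tie-break order
  resd <- search_delta(trends, grouping, metrics = "sdnn_pct")
  expect_true(all(resd$auc == 0.5))
  expect_equal(nrow(resd), 435L)
})

test_that("clinical groupings resolve with the configured thresholds", {
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:12),
    group = rep(c("control", "case"), each = 6),
    edss = c(rep(NA, 6), 1, 2.5, 3, 3.5, 4, 6),
    armss = c(rep(NA, 6), 2, 4, 4.01, 5, 6, 7),
    compass31 = c(rep(5, 6), 10, 16.9, 17, 20, 30, 40),
    fsmc_total = c(rep(NA, 6), 40, 64, 65, 70, 80, 90),
    inflammatory_activity = c(rep(NA, 6), rep(c(TRUE, FALSE), 3)),
    progressive = c(rep(NA, 6), rep(c(FALSE, TRUE), 3)),
    medication = FALSE
  )
  expect_equal(sum(resolve_grouping(subjects, "edss")$class), 4)    # >= 3
  expect_equal(sum(resolve_grouping(subjects, "armss")$class), 4)   # > 4 (strict)
  expect_equal(sum(resolve_grouping(subjects, "fsmc")$class), 4)    # >= 65
  g <- resolve_grouping(subjects, "compass31")                      # vs controls
  expect_equal(nrow(g), 6 + 4)
  gw <- resolve_grouping(subjects, "compass31_within")
  expect_equal(nrow(gw), 6)
  expect_error(resolve_grouping(subjects, "nope"), "unknown")
})
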