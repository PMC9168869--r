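test_that("AR(1) streams reproduce their closed-form SDNN and RMSSD", {
  # white noise: RMSSD = sigma * sqrt(2)
  st <- generate_ibi_series(flat_truth(sigma = 20, rho = 0), days = 1, seed = 101)
  x <- st$ibi$ibi_ms
  expect_gt(length(x), 50000)
  expect_lt(abs(sd(x) - 20) / 20, 0.02)
  rmssd <- sqrt(mean(diff(x)^2))
  expect_lt(abs(rmssd / sd(x) - sqrt(2)) / sqrt(2), 0.02)
  # rho = 0.5: RMSSD = sigma * sqrt(2 * (1 - rho)) = sigma
  st2 <- generate_ibi_series(flat_truth(sigma = 30, rho = 0.5), days = 1, seed = 102)
  x2 <- st2$ibi$ibi_ms
  expect_lt(abs(sd(x2) - 30) / 30, 0.02)
  expect_lt(abs(sqrt(mean(diff(x2)^2)) - 30) / 30, 0.02)
})

test_that("artifact-free runs record no artifacts and seeds are reproducible", {
  a <- generate_ibi_series(flat_truth(artifact_rate = 0), days = 1, seed = 7)
  expect_equal(nrow(a$artifacts), 0L)
  b <- generate_ibi_series(flat_truth(artifact_rate = 0), days = 1, seed = 7)
  expect_identical(a$ibi, b$ibi)
  expect_identical(a$activity, b$activity)
  c2 <- generate_ibi_series(flat_truth(artifact_rate = 5), days = 1, seed = 8)
  expect_gt(nrow(c2$artifacts), 0L)
})

test_that("invalid subject profiles are rejected", {
  expect_error(subject_truth(sigma_profile = function(p) rep(-1, length(p))),
               "positive")
  expect_error(subject_truth(mean_ibi_profile = function(p) rep(2000, length(p))),
               "300")
  expect_error(subject_truth(rho_profile = function(p) rep(1.2, length(p))),
               "inside")
  expect_error(subject_truth(sigma_profile = function(p) rep(NaN, length(p))),
               "finite")
})

test_that("sleep/wake and activity structure matches the simulated schedule", {
  st <- generate_ibi_series(flat_truth(jitter = 10), days = 3, seed = 5)
  expect_equal(nrow(st$labels), 4L)  # 3 days + terminal wake onset
  validate_sleep_labels(st$labels)
  # activity is higher during wake than sleep
  l <- st$labels
  wake_mask <- rep(FALSE, nrow(st$activity))
  for (d in 1:3) {
    wake_mask <- wake_mask |
      (st$activity$time_s >= l$wake_onset_s[d] & st$activity$time_s < l$sleep_onset_s[d])
  }
  expect_gt(mean(st$activity$magnitude[wake_mask]),
            3 * mean(st$activity$magnitude[!wake_mask]))
})

test_that("cohort generation is deterministic and carries all grouping fields", {
  cfg <- cohort_config(n_per_group = 5, days = 2, seed = 31)
  a <- generate_cohort(cfg, resolution = "segment")
  b <- generate_cohort(cfg, resolution = "segment")
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$segments, b$segments)
  need <- c("group", "age", "sex", "edss", "armss", "compass31", "fsmc_total",
            "inflammatory_activity", "progressive", "medication")
  expect_true(all(need %in% names(a$subjects)))
  expect_equal(nrow(a$subjects), 10L)
})

test_that("effect windows off the ten-bin grid are rejected", {
  expect_error(
    cohort_config(group_effects = list(list(window = "35%-80% night",
                                            metric = "sdnn_pct", smd = 1))),
    "grid")
  expect_error(
    cohort_config(group_effects = list(list(window = "40%-80% night",
                                            metric = "rmssd_pct", smd = 1))),
    "target")
})

test_that("injected effects shift the targeted trend window median as calibrated", {
  # single moderate-n check; the multi-seed calibration envelope is exercised
  # by the recovery study in the acceptance suite
  cfg <- cohort_config(
    n_per_group = 30, days = 7, seed = 99,
    group_effects = list(list(window = "40%-80% night", metric = "sdnn_pct", smd = 1.2))
  )
  coh <- generate_cohort(cfg, resolution = "segment")
  expect_equal(coh$truth$effects$smd_target, 1.2)
  expect_gt(coh$truth$effects$delta, 0)
  pts <- cohort_points(coh)
  trends <- fit_cohort_trends(pts, metrics = "sdnn_pct")
  wv <- window_values(trends)
  sel <- wv$label == "40%-80% night"
  grouping <- resolve_grouping(coh$subjects, "case")
  cls <- grouping$class[match(wv$subject_id[sel], grouping$subject_id)]
  cg <- compare_groups(wv$value[sel], cls)
  expect_lt(abs(cg$smd - 1.2), 0.6)  # single-seed sampling envelope
})

test_that("with no injected effects the groups are exchangeable under permutation", {
  cfg <- cohort_config(n_per_group = 8, days = 3, seed = 17)
  coh <- generate_cohort(cfg, resolution = "segment")
  pts <- cohort_points(coh)
  trends <- fit_cohort_trends(pts, metrics = "sdnn_pct")
  grouping <- resolve_grouping(coh$subjects, "case")
  res <- search_single(trends, grouping, metrics = "sdnn_pct")
  obs <- abs(res$auc[1] - 0.5)
  # selection-aware permutation null of the best |AUC - 0.5|
  wv <- window_values(trends)
  mat <- matrix(wv$value, nrow = 16, byrow = TRUE)
  cls <- grouping$class[match(unique(wv$subject_id), grouping$subject_id)]
  set.seed(1)
  null_best <- replicate(200, {
    perm <- sample(cls)
    max(apply(mat, 2, function(v) abs(auc_pairs(v, perm) - 0.5)))
  })
  expect_lte(obs, quantile(null_best, 0.95) + 1e-12)
})

test_that("the synthetic normative table is positive, complete and smooth in hour", {
  nt <- generate_normative_table(seed = 4)
  expect_true(all(nt$reference > 0))
  expect_equal(sort(unique(nt$hour)), 0:23)
  expect_setequal(unique(nt$sex), c("m", "w"))
  # every age 18-80 resolvable
  expect_true(all(vapply(18:80, function(a) {
    any(nt$age_min <= a & a < nt$age_max)
  }, logical(1))))
  # smoothness: successive-hour steps are small relative to the diurnal range
  one <- nt[nt$metric == "sdnn" & nt$sex == "m" & nt$age_min == 18, ]
  one <- one[order(one$hour), ]
  expect_lt(max(abs(diff(one$reference))), diff(range(one$reference)) / 3)
  # round-trip through CSV is lossless
  f <- tempfile(fileext = ".csv")
  data.table::fwrite(nt, f)
  back <- read_normative_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(nt), tolerance = 1e-12)
})
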