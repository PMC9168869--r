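test_that("artifact criterion matches its brute-force evaluation", {
  # constant series: zero deviation, no flags
  det <- detect_artifacts(make_ibi(rep(800, 100)))
  expect_true(all(det$flag == "clean"))
  # one gross outlier is exactly the flagged beat
  x <- rep(800, 99); x[50] <- 300
  det <- detect_artifacts(make_ibi(x))
  expect_identical(which(det$flag == "artifact"), 50L)
  expect_identical(det$flag == "artifact", brute_artifacts(x))
  # alternating 790/810: bounded by the neighborhood quartile deviation + floor
  alt <- rep(c(790, 810), 60)
  det <- detect_artifacts(make_ibi(alt))
  expect_true(all(det$flag == "clean"))
  expect_false(any(brute_artifacts(alt)))
  # random AR-ish series: full agreement with the literal criterion
  set.seed(42)
  z <- 800 + cumsum(rnorm(300, 0, 8)) * 0.3 + rnorm(300, 0, 25)
  z[c(40, 140, 240)] <- c(300, 1600, 420)
  det <- detect_artifacts(make_ibi(z))
  expect_identical(det$flag == "artifact", brute_artifacts(z))
})

test_that("short series warn and stay unflagged", {
  expect_warning(det <- detect_artifacts(make_ibi(rep(800, 10))), "shorter")
  expect_true(all(det$flag == "clean"))
})

test_that("interpolation fills gaps conserving elapsed time", {
  # clean input passes through unchanged
  s <- make_ibi(rep(800, 20))
  expect_identical(correct_artifacts(s), s)
  # one 300 ms artifact spanning a 1900 ms timestamp gap -> two interpolated
  # beats summing to 1900 ms (oracle: count minimizing the time mismatch)
  ibi <- c(rep(800, 10), 300, rep(800, 10))
  t <- cumsum(ibi) / 1000
  t[11:21] <- t[11:21] + 1.6  # device gap: artifact spans 1900 ms
  s <- tibble::tibble(subject_id = "S01", time_s = t, ibi_ms = ibi,
                      flag = c(rep("clean", 10), "artifact", rep("clean", 10)))
  out <- correct_artifacts(s)
  repl <- out[out$flag == "interpolated", ]
  gap <- 1900
  counts <- 1:6
  mism <- abs(gap - vapply(counts, function(m) sum(800 + (800 - 800) * seq_len(m) / (m + 1)),
                           numeric(1)))
  expect_equal(nrow(repl), counts[which.min(mism)])  # = 2
  expect_equal(sum(repl$ibi_ms), 1900)
  expect_equal(max(out$time_s), max(s$time_s))
  # a run of three artifacts becomes one interpolated gap
  ibi3 <- c(rep(800, 5), 400, 350, 420, rep(800, 5))
  s3 <- make_ibi(ibi3, flag = c(rep("clean", 5), rep("artifact", 3), rep("clean", 5)))
  out3 <- correct_artifacts(s3)
  expect_true(all(out3$flag %in% c("clean", "interpolated")))
  expect_equal(sum(out3$ibi_ms), sum(ibi3))
  expect_equal(max(out3$time_s), max(s3$time_s))
})

test_that("boundary artifact runs are dropped, not interpolated", {
  s <- make_ibi(rep(800, 10), flag = c("artifact", "artifact", rep("clean", 8)))
  out <- correct_artifacts(s)
  expect_equal(nrow(out), 8L)
  expect_true(all(out$flag == "clean"))
})

test_that("flag partition holds through detection and correction", {
  st <- generate_ibi_series(flat_truth(sigma = 18, mean_ibi = 850,
                                       artifact_rate = 15), days = 1, seed = 13)
  det <- detect_artifacts(st$ibi)
  expect_true(all(det$flag %in% c("clean", "artifact")))
  out <- correct_artifacts(det)
  expect_true(all(out$flag %in% c("clean", "interpolated")))
  expect_false(any(out$flag == "artifact"))
  # elapsed time conserved overall
  expect_lt(abs(max(out$time_s) - max(det$time_s)), 1)
})

test_that("segmentation yields floor(span / 300) windows and per-segment stats", {
  # 20 min of 1000 ms beats -> 4 segments
  s <- make_ibi(rep(1000, 1200))
  segs <- segment_ibi(s)
  expect_equal(nrow(segs), 4L)
  expect_true(all(segs$n_beats == 300))
  # 14 min -> 2 segments, remainder dropped
  expect_equal(nrow(segment_ibi(make_ibi(rep(1000, 840)))), 2L)
  # interpolated run bookkeeping
  fl <- rep("clean", 1200); fl[500:504] <- "interpolated"
  segs <- segment_ibi(make_ibi(rep(1000, 1200), flag = fl))
  expect_equal(segs$max_interpolated_run[2], 5L)
  expect_equal(segs$n_interpolated[2], 5L)
})

test_that("validity rules fire in order with the 'more than four in a row' boundary", {
  base <- tibble::tibble(
    subject_id = "S01", segment_id = 0:3, start_s = (0:3) * 300,
    midpoint_s = (0:3) * 300 + 150, n_beats = c(300L, 300L, 300L, 50L),
    n_interpolated = c(0L, 8L, 4L, 0L),
    max_interpolated_run = c(0L, 5L, 4L, 0L),
    mean_activity = c(1, 1, 1, 1), valid = TRUE, exclusion_reason = "none"
  )
  out <- filter_segments(base, activity_threshold = 10)
  expect_equal(out$exclusion_reason, c("none", "interpolation_run", "none", "too_few_beats"))
  expect_equal(out$valid, c(TRUE, FALSE, TRUE, FALSE))
  # activity rule, and precedence of the interpolation rule over it
  base$mean_activity <- c(1, 50, 50, 1)
  out <- filter_segments(base, activity_threshold = 10)
  expect_equal(out$exclusion_reason, c("none", "interpolation_run", "activity", "too_few_beats"))
  # idempotence
  expect_identical(filter_segments(out, activity_threshold = 10), out)
})

test_that("planted artifacts are recovered with high sensitivity and low false flags", {
  # low-variability night-like recording: floor-dominated detection regime
  st <- generate_ibi_series(flat_truth(sigma = 18, rho = 0.5, mean_ibi = 850,
                                       artifact_rate = 20, jitter = 5),
                            days = 1, seed = 11)
  det <- detect_artifacts(st$ibi)
  flagged <- which(det$flag == "artifact")
  truth <- st$artifacts$index
  expect_gt(length(truth), 300)
  expect_gte(mean(truth %in% flagged), 0.95)
  clean <- setdiff(seq_len(nrow(det)), truth)
  expect_lte(mean(clean %in% flagged), 0.01)
})
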