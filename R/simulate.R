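#' Ground-truth description of one simulated subject
#'
#' The simulated IBI process is, within each 5-minute block, a stationary
#' Gaussian AR(1) with mean `mean_ibi_profile(p)`, marginal SD
#' `sigma_profile(p)` and lag-1 autocorrelation `rho_profile(p)`, where `p`
#' is the block's position on the standardized day (0 = wake onset, 0.5 =
#' sleep onset). AR(1) gives closed-form oracles for every downstream
#' metric: SDNN = sigma, RMSSD = sigma * sqrt(2 * (1 - rho)),
#' SD1 = sigma * sqrt(1 - rho), SD2 = sigma * sqrt(1 + rho).
#'
#' The default profiles emulate a healthy circadian pattern: slower heart
#' rate and higher variability during sleep, with moderate short-range
#' autocorrelation.
#'
#' @param subject_id identifier
#' @param sigma_profile function position -> target IBI SD, ms (> 0)
#' @param rho_profile function position -> lag-1 autocorrelation in (-1, 1)
#' @param mean_ibi_profile function position -> mean IBI, ms (300-1500)
#' @param wake_duration,sleep_duration nominal phase durations, hours
#'   (must sum to ~24)
#' @param schedule_jitter_sd day-to-day onset jitter SD, minutes
#' @param artifact_rate expected detector-relevant artifacts per hour
#' @param activity_burst_rate movement bursts per waking hour
#' @return a `subject_truth` list, validated
#' @export
subject_truth <- function(subject_id = "S01",
                          sigma_profile = function(p) 40 + 15 * cos(2 * pi * (p - 0.70)),
                          rho_profile = function(p) 0.45 + 0.20 * cos(2 * pi * (p - 0.75)),
                          mean_ibi_profile = function(p) 900 + 120 * cos(2 * pi * (p - 0.75)),
                          wake_duration = 16, sleep_duration = 8,
                          schedule_jitter_sd = 20, artifact_rate = 3,
                          activity_burst_rate = 1.5) {
  truth <- structure(
    list(subject_id = subject_id, sigma_profile = sigma_profile,
         rho_profile = rho_profile, mean_ibi_profile = mean_ibi_profile,
         wake_duration = wake_duration, sleep_duration = sleep_duration,
         schedule_jitter_sd = schedule_jitter_sd, artifact_rate = artifact_rate,
         activity_burst_rate = activity_burst_rate),
    class = "subject_truth"
  )
  validate_subject_truth(truth)
  truth
}

validate_subject_truth <- function(truth) {
  p <- seq(0, 0.9995, length.out = 400)
  s <- truth$sigma_profile(p)
  r <- truth$rho_profile(p)
  m <- truth$mean_ibi_profile(p)
  stop_if_not(all(is.finite(s)) && all(is.finite(r)) && all(is.finite(m)),
              "profiles must be finite everywhere on [0, 1)")
  stop_if_not(all(s > 0), "sigma_profile must be positive everywhere")
  stop_if_not(all(abs(r) < 1), "rho_profile must lie strictly inside (-1, 1)")
  stop_if_not(all(m >= 300 & m <= 1500), "mean IBI must lie in [300, 1500] ms")
  stop_if_not(abs(truth$wake_duration + truth$sleep_duration - 24) < 0.5,
              "wake + sleep duration must be ~24 h")
  invisible(truth)
}

# Wake/sleep schedule over `days` cycles. Time 0 is the first wake onset
# (clock 07:00 by convention); later onsets carry Gaussian day-to-day jitter.
# Returns days + 1 rows; the last row only supplies the final wake onset.
build_schedule <- function(truth, days) {
  jit <- function(n) rnorm(n, 0, truth$schedule_jitter_sd * 60)
  wake <- (0:days) * 86400 + c(0, jit(days))
  sleep <- wake + truth$wake_duration * 3600 + jit(days + 1)
  sleep[days + 1] <- NA
  tibble::tibble(subject_id = truth$subject_id, day_index = 1:(days + 1),
                 wake_onset_s = wake, sleep_onset_s = sleep)
}

# Standardized position of absolute times given one subject's schedule.
schedule_position <- function(t, sched) {
  pos <- rep(NA_real_, length(t))
  n <- nrow(sched)
  for (d in seq_len(n - 1)) {
    w0 <- sched$wake_onset_s[d]; s0 <- sched$sleep_onset_s[d]
    w1 <- sched$wake_onset_s[d + 1]
    iw <- t >= w0 & t < s0
    is <- t >= s0 & t < w1
    pos[iw] <- 0.5 * (t[iw] - w0) / (s0 - w0)
    pos[is] <- 0.5 + 0.5 * (t[is] - s0) / (w1 - s0)
  }
  pos
}

#' Simulate one subject's wearable streams
#'
#' Generates the beat-level IBI stream (block-wise AR(1), see
#' [subject_truth()]), a 1 Hz movement-magnitude stream (near-zero during
#' sleep, baseline plus Poisson bursts during wake) and the matching
#' sleep/wake labels. Artifact events are inserted as a Poisson process at
#' `artifact_rate` per hour, each either a beat split (one IBI replaced by
#' two complementary short IBIs) or a beat merge (two IBIs fused into one
#' long IBI) — the two failure modes of wearable beat detection. Affected
#' stream rows are recorded in the returned ground truth; elapsed time is
#' conserved by both edit types.
#'
#' @param truth a [subject_truth()]
#' @param days number of recorded 24-h cycles (>= 1)
#' @param seed random seed
#' @return list with `ibi`, `activity`, `labels` tibbles and `artifacts`
#'   (ground truth: affected row `index`, `time_s`, `type`)
#' @export
generate_ibi_series <- function(truth, days, seed = NULL) {
  validate_subject_truth(truth)
  stop_if_not(days >= 1, "days must be >= 1")
  with_seed(seed, {
    sched <- build_schedule(truth, days)
    t_end <- sched$wake_onset_s[days + 1]
    block_starts <- seq(0, t_end - 300, by = 300)
    pos <- schedule_position(block_starts + 150, sched)
    pos[is.na(pos)] <- 0.999  # blocks straddling jittered boundaries
    mu <- truth$mean_ibi_profile(pos)
    sg <- truth$sigma_profile(pos)
    rh <- truth$rho_profile(pos)
    nb <- pmax(2L, as.integer(round(300000 / mu)))
    total <- sum(nb)
    # unit-variance AR(1) innovation chain, block-wise rho, continuous across blocks
    z <- numeric(total)
    eps <- rnorm(total)
    idx0 <- cumsum(nb) - nb
    zprev <- rnorm(1)
    for (b in seq_along(nb)) {
      zz <- stats::filter(eps[(idx0[b] + 1):(idx0[b] + nb[b])] * sqrt(1 - rh[b]^2),
                          rh[b], method = "recursive", init = zprev)
      z[(idx0[b] + 1):(idx0[b] + nb[b])] <- zz
      zprev <- zz[nb[b]]
    }
    ibi <- rep(mu, nb) + rep(sg, nb) * z
    ibi <- pmax(ibi, 250)  # physiological floor
    # --- artifacts ---------------------------------------------------------
    n_art <- rpois(1, truth$artifact_rate * t_end / 3600)
    art <- sort(sample(3:(total - 3), min(n_art, max(0, total %/% 10)), replace = FALSE))
    if (length(art) > 1) art <- art[c(TRUE, diff(art) > 2)]  # no adjacent edits
    type <- sample(c("split", "merge"), length(art), replace = TRUE)
    n_rep <- rep(1L, total)
    n_rep[art[type == "split"]] <- 2L
    n_rep[art[type == "merge"] + 1L] <- 0L
    src <- rep(seq_len(total), n_rep)
    out <- ibi[src]
    first_pos <- cumsum(n_rep) - n_rep + 1L
    truth_flag <- logical(length(out))
    for (k in seq_along(art)) {
      i <- art[k]
      if (type[k] == "split") {
        u <- runif(1, 0.4, 0.6)
        out[first_pos[i]] <- u * ibi[i]
        out[first_pos[i] + 1L] <- (1 - u) * ibi[i]
        truth_flag[first_pos[i] + 0:1] <- TRUE
      } else {
        out[first_pos[i]] <- ibi[i] + ibi[i + 1L]
        truth_flag[first_pos[i]] <- TRUE
      }
    }
    time_s <- cumsum(out) / 1000
    ibi_tbl <- tibble::tibble(subject_id = truth$subject_id, time_s = time_s,
                              ibi_ms = out, flag = "clean")
    art_idx <- which(truth_flag)
    artifacts <- tibble::tibble(index = art_idx, time_s = time_s[art_idx],
                                type = rep(type, ifelse(type == "split", 2L, 1L)))
    # --- activity (1 Hz) ---------------------------------------------------
    at <- seq(0, floor(t_end) - 1)
    apos <- schedule_position(at, sched)
    asleep <- !is.na(apos) & apos >= 0.5
    mag <- abs(rnorm(length(at), 2, 1))
    mag[asleep] <- abs(rnorm(sum(asleep), 0.3, 0.2))
    for (d in seq_len(days)) {
      w0 <- sched$wake_onset_s[d]; s0 <- sched$sleep_onset_s[d]
      nburst <- rpois(1, truth$activity_burst_rate * (s0 - w0) / 3600)
      if (nburst > 0) {
        bs <- runif(nburst, w0, s0)
        bd <- runif(nburst, 300, 1200)
        bh <- runif(nburst, 20, 60)
        for (j in seq_len(nburst)) {
          hitrows <- at >= bs[j] & at < bs[j] + bd[j]
          mag[hitrows] <- mag[hitrows] + bh[j]
        }
      }
    }
    list(
      ibi = ibi_tbl,
      activity = tibble::tibble(subject_id = truth$subject_id, time_s = at,
                                magnitude = mag),
      labels = sched,
      artifacts = artifacts
    )
  })
}

#' Cohort simulation settings
#'
#' @param n_per_group subjects per group (>= 2)
#' @param group_effects list of effects injected into the case group, each
#'   `list(window = "40%-80% night", metric = "sdnn_pct", smd = 1.2)`;
#'   windows must align to the ten-bin grid
#' @param days recording days per subject (default 14, the nominal two-week
#'   protocol; 1-31)
#' @param seed cohort seed
#' @param between_subject_cv coefficient of variation of the subject-level
#'   HRV scale (default 0.15) — the between-subject spread that effect sizes
#'   are calibrated against
#' @param demographics per-group age mean/SD and female proportion
#' @param normative normative table used for effect calibration (and,
#'   downstream, normalization); default [generate_normative_table()]
#' @param truth template [subject_truth()] supplying the base profiles
#' @return a validated `cohort_config` list
#' @export
cohort_config <- function(n_per_group = 30L, group_effects = list(), days = 14L,
                          seed = 1L, between_subject_cv = 0.15,
                          demographics = list(
                            control = list(age_mean = 33.5, age_sd = 10.6, prop_female = 0.542),
                            case = list(age_mean = 36.8, age_sd = 9.5, prop_female = 0.636)
                          ),
                          normative = NULL, truth = subject_truth()) {
  stop_if_not(n_per_group >= 2, "n_per_group must be >= 2")
  stop_if_not(days >= 1 && days <= 31, "days must lie in 1..31")
  for (ef in group_effects) {
    parse_window(ef$window)  # errors if off the ten-bin grid
    stop_if_not(ef$metric %in% c("sdnn_pct", "sd1_pct", "sd2_pct"),
                "effects target sdnn_pct, sd1_pct or sd2_pct")
  }
  structure(
    list(n_per_group = as.integer(n_per_group), group_effects = group_effects,
         days = as.integer(days), seed = as.integer(seed),
         between_subject_cv = between_subject_cv, demographics = demographics,
         normative = normative %||% generate_normative_table(seed = 1L),
         truth = truth),
    class = "cohort_config"
  )
}

# Hour of day corresponding to a standardized position under the nominal
# schedule (wake onset 07:00, 16 h wake / 8 h sleep).
nominal_hour <- function(p, wake_duration = 16) {
  sleep_duration <- 24 - wake_duration
  ifelse(p < 0.5,
         (7 + p / 0.5 * wake_duration) %% 24,
         (7 + wake_duration + (p - 0.5) / 0.5 * sleep_duration) %% 24)
}

# Noise-free metric profile (in normative %) under an effect multiplier
# delta inside the window, as seen through the degree-10 trend fit.
effect_trend_median <- function(cfg, ef, delta) {
  w <- parse_window(ef$window)
  # sampling-density-matched grid: wake segments are twice as dense in time
  p <- c(seq(0.5 / 600, 0.5 - 0.5 / 600, length.out = 600),
         seq(0.5 + 0.5 / 300, 1 - 0.5 / 300, length.out = 300))
  tr <- cfg$truth
  prof <- switch(ef$metric,
    sdnn_pct = tr$sigma_profile(p),
    sd1_pct = tr$sigma_profile(p) * sqrt(1 - tr$rho_profile(p)),
    sd2_pct = tr$sigma_profile(p) * sqrt(1 + tr$rho_profile(p))
  )
  base_metric <- sub("_pct$", "", ef$metric)
  nt <- cfg$normative[cfg$normative$metric == base_metric, ]
  ref_by_hour <- tapply(nt$reference, nt$hour, mean)
  ref <- as.numeric(ref_by_hour[as.character(floor(nominal_hour(p, tr$wake_duration)))])
  f <- 100 * prof / ref * (1 + delta * (p >= w$lo & p < w$hi))
  fit <- fit_trend(p, f, metric = ef$metric)
  g <- trend_grid(fit)
  median(g$value[g$position >= w$lo & g$position < w$hi])
}

# Solve the within-window multiplier delta so the population SMD of the
# trend window median equals the requested value (delta method: the
# between-subject SD is cv times the group mean of the median, and the case
# group's SD inflates with the multiplier).
calibrate_effect <- function(cfg, ef) {
  cv <- cfg$between_subject_cv
  k0 <- effect_trend_median(cfg, ef, 0)
  smd_at <- function(delta) {
    kd <- effect_trend_median(cfg, ef, delta)
    (kd - k0) / (cv * sqrt((k0^2 + kd^2) / 2)) - ef$smd
  }
  stats::uniroot(smd_at, interval = c(-0.9, 5), tol = 1e-4)$root
}

# Effect multipliers applied to a case subject's sigma/rho profiles.
apply_effects <- function(truth, effects) {
  if (!length(effects)) return(truth)
  base_sigma <- truth$sigma_profile
  base_rho <- truth$rho_profile
  sig_mult <- function(p) {
    m <- rep(1, length(p))
    for (ef in effects) {
      if (ef$metric %in% c("sdnn_pct", "sd2_pct")) {
        w <- parse_window(ef$window)
        m <- m * ifelse(p >= w$lo & p < w$hi, 1 + ef$delta, 1)
      }
    }
    m
  }
  rho_new <- function(p) {
    r <- base_rho(p)
    for (ef in effects) {
      if (ef$metric == "sd1_pct") {
        w <- parse_window(ef$window)
        inw <- p >= w$lo & p < w$hi
        r[inw] <- pmax(-0.99, 1 - (1 + ef$delta)^2 * (1 - r[inw]))
      }
    }
    r
  }
  truth$sigma_profile <- function(p) base_sigma(p) * sig_mult(p)
  truth$rho_profile <- rho_new
  truth
}

scaled_truth <- function(truth, subject_id, scale) {
  base <- truth$sigma_profile
  truth$subject_id <- subject_id
  truth$sigma_profile <- function(p) scale * base(p)
  truth
}

#' Simulate a two-group wearable cohort
#'
#' Generates `n_per_group` control and case subjects with known circadian
#' ground truth. Between-subject heterogeneity is a subject-level HRV scale
#' multiplier (truncated normal, CV `between_subject_cv`). Each requested
#' group effect shifts the case group's sigma profile (for `sdnn_pct` /
#' `sd2_pct` targets) or rho profile (for `sd1_pct`) inside its window by a
#' multiplier calibrated so the population standardized mean difference of
#' the trend window median equals the requested value (see the effect ledger
#' in the returned `truth`).
#'
#' `resolution = "segment"` (default) draws each 5-minute segment's metric
#' estimates directly from their AR(1) sampling distributions — the fast
#' path for cohort-scale recovery and power studies. `resolution = "beat"`
#' generates full IBI/activity/sleep streams per subject
#' ([generate_ibi_series()]) for end-to-end pipeline runs; use small cohorts
#' there.
#'
#' @param config a [cohort_config()]
#' @param resolution `"segment"` or `"beat"`
#' @return list: `segments` (segment resolution only; includes `position`,
#'   `day_index`, `clock_hour` and raw metric columns), `streams` (beat
#'   resolution only; one [generate_ibi_series()] bundle per subject),
#'   `subjects` (metadata table), `labels` (pooled sleep/wake labels),
#'   `truth` (effect ledger, per-subject scales, calibrated deltas)
#' @export
generate_cohort <- function(config, resolution = c("segment", "beat")) {
  stop_if_not(inherits(config, "cohort_config"), "config must be a cohort_config")
  resolution <- match.arg(resolution)
  effects <- config$group_effects
  for (i in seq_along(effects)) {
    effects[[i]]$delta <- calibrate_effect(config, effects[[i]])
  }
  with_seed(config$seed, {
    n <- config$n_per_group
    ids <- sprintf("S%03d", seq_len(2 * n))
    group <- rep(c("control", "case"), each = n)
    demo <- config$demographics
    age <- pmin(79, pmax(18, round(c(
      rnorm(n, demo$control$age_mean, demo$control$age_sd),
      rnorm(n, demo$case$age_mean, demo$case$age_sd)
    ))))
    sex <- ifelse(runif(2 * n) < rep(c(demo$control$prop_female,
                                       demo$case$prop_female), each = n), "w", "m")
    scale <- pmax(0.4, rnorm(2 * n, 1, config$between_subject_cv))
    is_case <- group == "case"
    subjects <- tibble::tibble(
      subject_id = ids, group = group, age = age, sex = sex,
      start_clock_s = 7 * 3600,
      edss = ifelse(is_case, pmin(7, pmax(0, round(rnorm(2 * n, 2.2, 1.4) * 2) / 2)), NA),
      inflammatory_activity = ifelse(is_case, runif(2 * n) < 0.309, NA),
      progressive = ifelse(is_case, runif(2 * n) < 0.255, NA),
      compass31 = pmax(0, ifelse(is_case, rnorm(2 * n, 16.9, 8.6), rnorm(2 * n, 8, 4))),
      fsmc_total = ifelse(is_case, pmin(100, pmax(20, rnorm(2 * n, 53, 21.8))), NA),
      medication = ifelse(is_case, runif(2 * n) < 0.364, FALSE)
    )
    subjects$armss <- ifelse(is_case, pmin(10, pmax(0, subjects$edss * 1.2 + rnorm(2 * n, 0.8, 1))), NA)
    subject_seeds <- sample.int(2^31 - 1, 2 * n)
    truths <- lapply(seq_len(2 * n), function(j) {
      tr <- scaled_truth(config$truth, ids[j], scale[j])
      if (is_case[j]) tr <- apply_effects(tr, effects) else tr
    })
    ledger <- if (length(effects)) {
      do.call(rbind, lapply(effects, function(ef) tibble::tibble(
        window = ef$window, metric = ef$metric, smd_target = ef$smd,
        delta = ef$delta,
        mechanism = if (ef$metric == "sd1_pct") "rho" else "sigma"
      )))
    } else {
      tibble::tibble(window = character(0), metric = character(0),
                     smd_target = numeric(0), delta = numeric(0),
                     mechanism = character(0))
    }
    truth_out <- list(effects = ledger,
                      subjects = tibble::tibble(subject_id = ids, group = group,
                                                scale = scale))
    if (resolution == "beat") {
      streams <- lapply(seq_len(2 * n), function(j) {
        generate_ibi_series(truths[[j]], config$days, seed = subject_seeds[j])
      })
      names(streams) <- ids
      labels <- do.call(rbind, lapply(streams, `[[`, "labels"))
      return(list(segments = NULL, streams = streams, subjects = subjects,
                  labels = labels, truth = truth_out, config = config))
    }
    seg_list <- vector("list", 2 * n)
    lab_list <- vector("list", 2 * n)
    for (j in seq_len(2 * n)) {
      seg_list[[j]] <- with_seed(subject_seeds[j],
                                 simulate_segments(truths[[j]], config$days))
      lab_list[[j]] <- attr(seg_list[[j]], "labels")
      attr(seg_list[[j]], "labels") <- NULL
    }
    list(segments = do.call(rbind, seg_list), streams = NULL,
         subjects = subjects, labels = do.call(rbind, lab_list),
         truth = truth_out, config = config)
  })
}

# Segment-resolution simulation of one subject: per-block metric estimates
# drawn from their AR(1) sampling distributions (chi-square scale noise on
# SDNN and RMSSD), skipping beat-level synthesis.
simulate_segments <- function(truth, days) {
  sched <- build_schedule(truth, days)
  t_end <- sched$wake_onset_s[days + 1]
  start <- seq(0, t_end - 300, by = 300)
  mid <- start + 150
  pos <- schedule_position(mid, sched)
  keep <- !is.na(pos)
  start <- start[keep]; mid <- mid[keep]; pos <- pos[keep]
  day_index <- findInterval(mid, sched$wake_onset_s)
  sg <- truth$sigma_profile(pos)
  rh <- truth$rho_profile(pos)
  mu <- truth$mean_ibi_profile(pos)
  nb <- pmax(2L, as.integer(round(300000 / mu)))
  sdnn <- sg * sqrt(rchisq(length(pos), nb - 1) / (nb - 1))
  rmssd_true <- sg * sqrt(2 * (1 - rh))
  rmssd <- rmssd_true * sqrt(rchisq(length(pos), nb - 1) / (nb - 1))
  sd1 <- rmssd / sqrt(2)
  sd2 <- sqrt(pmax(0, 2 * sdnn^2 - rmssd^2 / 2))
  out <- tibble::tibble(
    subject_id = truth$subject_id, segment_id = seq_along(pos) - 1L,
    start_s = start, midpoint_s = mid, n_beats = nb,
    n_interpolated = 0L, max_interpolated_run = 0L, mean_activity = 0,
    valid = TRUE, exclusion_reason = "none",
    day_index = day_index, position = pos,
    phase = ifelse(pos < 0.5, "wake", "sleep"),
    sdnn = sdnn, rmssd = rmssd,
    pnn20 = 100 * 2 * pnorm(-20 / rmssd_true),
    pnn50 = 100 * 2 * pnorm(-50 / rmssd_true),
    sd1 = sd1, sd2 = sd2
  )
  attr(out, "labels") <- sched
  out
}

#' Generate a synthetic normative reference table
#'
#' A stand-in for external population normative HRV values: positive
#' reference values per metric, sex, age band and hour of day, smooth in
#' hour (a cosine diurnal shape peaking at night) and declining with age.
#' This synthetic table defines the interface only; it does not reconstruct
#' any published normative dataset.
#'
#' @param seed seed for the per-metric diurnal amplitude/phase draws
#' @param age_breaks age band edges (default 18, 30, 40, 50, 65, 81 —
#'   covering ages 18-80)
#' @param metrics metric names to tabulate
#' @return tibble: `sex`, `age_min`, `age_max`, `hour`, `metric`, `reference`
#' @export
generate_normative_table <- function(seed = 1L,
                                     age_breaks = c(18, 30, 40, 50, 65, 81),
                                     metrics = c("sdnn", "rmssd", "sd1", "sd2",
                                                 "lf", "hf", "pnn20", "pnn50")) {
  stop_if_not(length(age_breaks) >= 2 && all(diff(age_breaks) > 0),
              "age_breaks must be increasing")
  base <- c(sdnn = 50, rmssd = 42, sd1 = 30, sd2 = 62, lf = 1100, hf = 900,
            pnn20 = 30, pnn50 = 12)
  stop_if_not(all(metrics %in% names(base)), "unknown metric in normative request")
  with_seed(seed, {
    amp <- runif(length(metrics), 0.15, 0.30)
    peak <- runif(length(metrics), 2, 5)
    sexf <- runif(length(metrics), 0.90, 1.00)
    names(amp) <- names(peak) <- names(sexf) <- metrics
    rows <- list()
    for (m in metrics) {
      for (s in c("m", "w")) {
        for (b in seq_len(length(age_breaks) - 1)) {
          midage <- (age_breaks[b] + age_breaks[b + 1]) / 2
          agef <- max(0.3, 1 - 0.006 * (midage - 30))
          h <- 0:23
          ref <- base[[m]] * agef * (if (s == "w") sexf[[m]] else 1) *
            (1 + amp[[m]] * cos(2 * pi * (h - peak[[m]]) / 24))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sex = s, age_min = age_breaks[b], age_max = age_breaks[b + 1],
            hour = h, metric = m, reference = ref
          )
        }
      }
    }
    do.call(rbind, rows)
  })
}
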