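#' Time-domain HRV metrics of one segment
#'
#' SDNN is the sample standard deviation (n-1 denominator) of the IBIs,
#' RMSSD the root mean square of successive differences, and pNNx the
#' percentage of successive-difference magnitudes strictly greater than
#' x milliseconds.
#'
#' @param ibi_ms numeric vector of inter-beat intervals, ms (>= 2 beats)
#' @return named numeric vector: `sdnn`, `rmssd`, `pnn20`, `pnn50`
#' @export
#' @examples
#' hrv_time_domain(c(800, 850))  # rmssd 50, pnn20 100, pnn50 0
hrv_time_domain <- function(ibi_ms) {
  stop_if_not(length(ibi_ms) >= 2, "time-domain metrics need >= 2 beats")
  d <- abs(diff(ibi_ms))
  c(
    sdnn = sd(ibi_ms),
    rmssd = sqrt(mean(d^2)),
    pnn20 = 100 * mean(d > 20),
    pnn50 = 100 * mean(d > 50)
  )
}

#' Poincare-plot dispersions SD1 and SD2
#'
#' Computed from the standard estimator identities `sd1 = rmssd / sqrt(2)`
#' and `sd2 = sqrt(max(0, 2 * sdnn^2 - rmssd^2 / 2))`, which satisfy the
#' conservation law `sd1^2 + sd2^2 = 2 * sdnn^2` by construction.
#'
#' @param ibi_ms numeric vector of inter-beat intervals, ms (>= 3 beats)
#' @return named numeric vector: `sd1`, `sd2`
#' @export
hrv_poincare <- function(ibi_ms) {
  stop_if_not(length(ibi_ms) >= 3, "Poincare metrics need >= 3 beats")
  td <- hrv_time_domain(ibi_ms)
  c(
    sd1 = unname(td["rmssd"]) / sqrt(2),
    sd2 = sqrt(max(0, 2 * td["sdnn"]^2 - td["rmssd"]^2 / 2))
  )
}

# Welch power spectral density: Hann-windowed, demeaned, 50%-overlapping
# modified periodograms averaged; one-sided density in units^2/Hz.
welch_psd <- function(x, fs, nperseg, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nperseg - 1) / nperseg))
  u <- sum(w^2)
  nf <- nperseg %/% 2
  acc <- numeric(nf + 1)
  for (s in starts) {
    xs <- x[s:(s + nperseg - 1L)]
    xs <- (xs - mean(xs)) * w
    p <- abs(fft(xs))^2 / (fs * u)
    half <- p[1:(nf + 1)]
    half[2:(nf + if (nperseg %% 2 == 0) 0 else 1)] <-
      2 * half[2:(nf + if (nperseg %% 2 == 0) 0 else 1)]
    acc <- acc + half
  }
  list(freq = (0:nf) * fs / nperseg, psd = acc / length(starts))
}

#' Frequency-domain HRV metrics of one segment
#'
#' The IBI tachogram is resampled at `fs` Hz by cubic spline interpolation,
#' demeaned, and its Welch power spectral density (120-s Hann segments, 50%
#' overlap) integrated over the standard low-frequency (0.04-0.15 Hz) and
#' high-frequency (0.15-0.40 Hz) bands.
#'
#' @param time_s beat timestamps, seconds
#' @param ibi_ms inter-beat intervals, ms
#' @param bands list with numeric `lf` and `hf` band edges in Hz
#' @param fs resampling frequency, Hz
#' @param seg_s Welch segment length, seconds
#' @return named numeric vector: `lf`, `hf` (ms^2)
#' @export
hrv_frequency_domain <- function(time_s, ibi_ms,
                                 bands = list(lf = c(0.04, 0.15), hf = c(0.15, 0.40)),
                                 fs = 4, seg_s = 120) {
  stop_if_not(length(ibi_ms) >= 2 && diff(range(time_s)) >= 120,
              "frequency-domain metrics need >= 2 min of beats")
  grid <- seq(min(time_s), max(time_s), by = 1 / fs)
  x <- spline(time_s, ibi_ms, xout = grid)$y
  x <- x - mean(x)
  if (sd(x) == 0) return(c(lf = 0, hf = 0))
  ps <- welch_psd(x, fs, nperseg = round(fs * seg_s))
  df <- ps$freq[2] - ps$freq[1]
  band_power <- function(b) sum(ps$psd[ps$freq > b[1] & ps$freq <= b[2]]) * df
  c(lf = band_power(bands$lf), hf = band_power(bands$hf))
}

#' Per-segment HRV metrics for a whole recording
#'
#' Computes the time-domain and Poincare metrics (and optionally the
#' frequency-domain metrics) on every segment's beats and appends them as
#' columns to the segment table. Segments with fewer than 3 beats get `NA`
#' metrics.
#'
#' @param ibi corrected IBI series
#' @param segments segment table ([segment_ibi()] / [filter_segments()])
#' @param frequency also compute `lf`/`hf` (slower); default `FALSE` —
#'   downstream trend analysis operates on SDNN/SD1/SD2
#' @param duration_s segment length used when segmenting, seconds
#' @return segment table with columns `sdnn`, `rmssd`, `pnn20`, `pnn50`,
#'   `sd1`, `sd2` (and `lf`, `hf` if requested)
#' @export
segment_metrics <- function(ibi, segments, frequency = FALSE, duration_s = 300) {
  bt <- data.table::as.data.table(validate_ibi_series(ibi))
  bt[, t0 := time_s[1] - ibi_ms[1] / 1000, by = subject_id]
  bt[, segment_id := ceiling((time_s - t0) / duration_s) - 1]
  stats <- bt[, {
    if (.N >= 3) {
      d <- abs(diff(ibi_ms))
      sdnn <- sd(ibi_ms)
      rmssd <- sqrt(mean(d^2))
      .(sdnn = sdnn, rmssd = rmssd,
        pnn20 = 100 * mean(d > 20), pnn50 = 100 * mean(d > 50),
        sd1 = rmssd / sqrt(2), sd2 = sqrt(max(0, 2 * sdnn^2 - rmssd^2 / 2)))
    } else {
      .(sdnn = NA_real_, rmssd = NA_real_, pnn20 = NA_real_, pnn50 = NA_real_,
        sd1 = NA_real_, sd2 = NA_real_)
    }
  }, by = .(subject_id, segment_id)]
  out <- merge(data.table::as.data.table(segments), stats,
               by = c("subject_id", "segment_id"), all.x = TRUE, sort = FALSE)
  if (frequency) {
    out[, `:=`(lf = NA_real_, hf = NA_real_)]
    for (i in seq_len(nrow(out))) {
      b <- bt[subject_id == out$subject_id[i] & segment_id == out$segment_id[i]]
      if (nrow(b) >= 2 && diff(range(b$time_s)) >= 120) {
        fd <- hrv_frequency_domain(b$time_s, b$ibi_ms)
        out$lf[i] <- fd["lf"]; out$hf[i] <- fd["hf"]
      }
    }
  }
  data.table::setorder(out, subject_id, segment_id)
  tibble::as_tibble(out)
}

#' Convert segment metrics to normative percentage scores
#'
#' Each metric is divided by the reference value of the matching
#' (sex, age band, clock hour) cell of the normative table and multiplied by
#' 100. The clock hour is the hour of the segment midpoint in local time;
#' `start_clock_s` (seconds past midnight at recording time 0, a
#' `subjects`-table column) anchors the recording to the clock. Segments
#' whose (sex, age, hour) cell cannot be resolved are dropped with a message.
#'
#' @param metrics segment table with metric columns ([segment_metrics()])
#' @param subjects subject metadata table with `subject_id`, `age`, `sex`
#'   and optionally `start_clock_s`
#' @param normative normative table: `sex`, `age_min`, `age_max`, `hour`,
#'   `metric`, `reference` (see [generate_normative_table()])
#' @param metrics_to_normalize metric columns to convert (default the table's
#'   metrics intersected with the segment columns)
#' @return segment table with `<metric>_pct` columns and a `clock_hour` column
#' @export
normalize_segments <- function(metrics, subjects, normative,
                               metrics_to_normalize = NULL) {
  stop_if_not(all(c("subject_id", "age", "sex") %in% names(subjects)),
              "subjects table needs subject_id, age, sex")
  segs <- metrics
  sub <- subjects[match(segs$subject_id, subjects$subject_id), ]
  stop_if_not(!anyNA(sub$subject_id), "segment subjects missing from metadata")
  start_clock <- if ("start_clock_s" %in% names(subjects)) sub$start_clock_s else 0
  segs$clock_hour <- floor(((segs$midpoint_s + start_clock) %% 86400) / 3600)
  mets <- metrics_to_normalize %||%
    intersect(unique(normative$metric), names(segs))
  keep <- rep(TRUE, nrow(segs))
  for (m in mets) {
    nt <- normative[normative$metric == m, ]
    bands <- unique(nt[, c("age_min", "age_max")])
    bands <- bands[order(bands$age_min), ]
    bidx <- findInterval(sub$age, bands$age_min)
    in_band <- bidx >= 1 & sub$age < bands$age_max[pmax(bidx, 1)]
    bidx[!in_band] <- NA_integer_
    nt_band <- match(nt$age_min, bands$age_min)
    ref <- nt$reference[match(
      paste(sub$sex, segs$clock_hour, bidx),
      paste(nt$sex, nt$hour, nt_band)
    )]
    segs[[paste0(m, "_pct")]] <- 100 * segs[[m]] / ref
    keep <- keep & !is.na(ref)
  }
  if (any(!keep)) {
    message(sprintf("normalize_segments: dropped %d segment(s) with unresolvable normative cells",
                    sum(!keep)))
    segs <- segs[keep, ]
  }
  segs
}

#' Pooled cross-domain correlations of normalized metrics
#'
#' Pearson correlations (with Fisher-z 95% CIs) between SD1% and HF% and
#' between SD2% and LF%, pooled over all segments — a consistency check that
#' the nonlinear-domain percentages track their frequency-domain analogues.
#'
#' @param segments normalized segment table with `sd1_pct`, `hf_pct`,
#'   `sd2_pct`, `lf_pct`
#' @return tibble with one row per metric pair: `pair`, `n`, `r`, `ci_low`,
#'   `ci_high`
#' @export
crossdomain_correlation <- function(segments) {
  one <- function(a, b, nm) {
    ok <- complete.cases(segments[[a]], segments[[b]])
    x <- segments[[a]][ok]; y <- segments[[b]][ok]
    stop_if_not(length(x) >= 3, "need >= 3 paired values")
    stop_if_not(sd(x) > 0 && sd(y) > 0, "degenerate variance in correlation input")
    r <- cor(x, y)
    ci <- fisher_ci(r, length(x))
    tibble::tibble(pair = nm, n = length(x), r = r,
                   ci_low = ci[1], ci_high = ci[2])
  }
  rbind(one("sd1_pct", "hf_pct", "sd1_pct~hf_pct"),
        one("sd2_pct", "lf_pct", "sd2_pct~lf_pct"))
}

# Fisher-z 95% confidence interval for a correlation coefficient.
fisher_ci <- function(r, n, level = 0.95) {
  if (n <= 3 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}
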