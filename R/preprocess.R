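#' Flag beat artifacts with a robust local criterion
#'
#' Implements a quartile-deviation variant of the classic robust beat-artifact
#' check: beat *i* is flagged as an artifact when its deviation from the local
#' median exceeds `max(coef * QD, floor_ms)`, where the median and quartile
#' deviation QD = (Q3 - Q1) / 2 are computed over the `window_beats`-wide
#' neighborhood of *i* with beat *i* itself excluded (windows are shifted
#' inward at the series ends). The absolute floor prevents over-flagging in
#' very low-variability stretches.
#'
#' @param ibi IBI series (see [validate_ibi_series()]); processed per subject
#' @param window_beats odd neighborhood width in beats (default 41)
#' @param coef multiplier on the quartile deviation (default 3.32, a robust
#'   analogue of a ~2.2 SD cutoff for Gaussian data)
#' @param floor_ms absolute minimum deviation, ms (default 50)
#' @return the series with `flag` set to `"artifact"` on flagged beats
#' @export
detect_artifacts <- function(ibi, window_beats = 41L, coef = 3.32, floor_ms = 50) {
  ibi <- validate_ibi_series(ibi)
  stop_if_not(window_beats %% 2 == 1 && window_beats >= 5,
              "window_beats must be odd and >= 5")
  out <- ibi
  for (id in unique(ibi$subject_id)) {
    sel <- which(ibi$subject_id == id)
    x <- ibi$ibi_ms[sel]
    if (length(x) < window_beats) {
      warning(sprintf("subject '%s': series shorter than window_beats; no flags set", id))
      next
    }
    mq <- .rollingMedQd(x, as.integer(window_beats))
    thr <- pmax(coef * mq[, "qd"], floor_ms)
    hit <- abs(x - mq[, "med"]) > thr
    out$flag[sel][hit] <- "artifact"
  }
  out
}

# Linearly interpolated replacement IBIs for one gap: m values on the line
# between the flanking clean IBIs, rescaled so they sum to the elapsed gap.
interp_gap <- function(left_ibi, right_ibi, gap_ms) {
  m <- max(1L, round(gap_ms / ((left_ibi + right_ibi) / 2)))
  v <- left_ibi + (right_ibi - left_ibi) * seq_len(m) / (m + 1)
  v * gap_ms / sum(v)
}

#' Remove flagged artifacts and fill gaps by linear interpolation
#'
#' Each maximal run of artifact-flagged beats is removed and replaced by
#' linearly interpolated IBIs between the flanking clean beats. The gap is
#' measured from the flanking timestamps (so device-side timestamp jumps are
#' honored); the replacement count is chosen so the replacements' summed
#' duration matches the elapsed gap to within half the local mean IBI, and
#' the values are then rescaled to conserve elapsed time exactly.
#' Replacements are flagged `"interpolated"` and given cumulative timestamps
#' inside the gap; clean beats keep their original timestamps. Runs touching
#' a series boundary are dropped rather than interpolated.
#'
#' @param ibi IBI series with artifact flags assigned ([detect_artifacts()])
#' @return corrected series; no `"artifact"` flags remain
#' @export
correct_artifacts <- function(ibi) {
  ibi <- validate_ibi_series(ibi)
  pieces <- lapply(unique(ibi$subject_id), function(id) {
    s <- ibi[ibi$subject_id == id, ]
    if (!any(s$flag == "artifact")) return(s)
    r <- rle(s$flag == "artifact")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    new_ibi <- list(); new_flag <- list(); new_time <- list()
    for (k in seq_along(r$lengths)) {
      idx <- starts[k]:ends[k]
      if (!r$values[k]) {
        new_ibi[[k]] <- s$ibi_ms[idx]
        new_flag[[k]] <- s$flag[idx]
        new_time[[k]] <- s$time_s[idx]
      } else if (starts[k] == 1L || ends[k] == nrow(s)) {
        # boundary run: dropped, not interpolated
        new_ibi[[k]] <- numeric(0)
        new_flag[[k]] <- character(0)
        new_time[[k]] <- numeric(0)
      } else {
        t_left <- s$time_s[starts[k] - 1L]
        gap <- (s$time_s[ends[k]] - t_left) * 1000
        repl <- interp_gap(s$ibi_ms[starts[k] - 1L], s$ibi_ms[ends[k] + 1L], gap)
        new_ibi[[k]] <- repl
        new_flag[[k]] <- rep("interpolated", length(repl))
        new_time[[k]] <- t_left + cumsum(repl) / 1000
      }
    }
    tibble::tibble(
      subject_id = id,
      time_s = unlist(new_time),
      ibi_ms = unlist(new_ibi),
      flag = unlist(new_flag)
    )
  })
  do.call(rbind, pieces)
}

#' Divide a recording into non-overlapping 5-minute segments
#'
#' Contiguous 300-second windows anchored at the first beat of each subject's
#' recording; the trailing partial window is discarded. Each segment records
#' its interpolation load (`n_interpolated`, `max_interpolated_run`) and mean
#' movement magnitude over its span.
#'
#' @param ibi corrected IBI series ([correct_artifacts()])
#' @param activity optional activity series; `mean_activity` is `NA` without it
#' @param duration_s segment length, seconds (default 300)
#' @return tibble with one row per segment: `subject_id`, `segment_id`,
#'   `start_s`, `midpoint_s`, `n_beats`, `n_interpolated`,
#'   `max_interpolated_run`, `mean_activity`, `valid`, `exclusion_reason`
#' @export
segment_ibi <- function(ibi, activity = NULL, duration_s = 300) {
  ibi <- validate_ibi_series(ibi)
  stop_if_not(nrow(ibi) > 0, "empty IBI series")
  if (!is.null(activity)) activity <- validate_activity_series(activity)
  bt <- data.table::as.data.table(ibi)
  # recording start = start of the first beat's interval; a beat belongs to
  # the segment containing its interval end
  bt[, t0 := time_s[1] - ibi_ms[1] / 1000, by = subject_id]
  bt[, seg := ceiling((time_s - t0) / duration_s) - 1]
  bt[, span := floor((max(time_s) - t0) / duration_s), by = subject_id]
  bt <- bt[seg >= 0 & seg < span]  # drop trailing partial window
  if (nrow(bt) == 0) {
    return(tibble::tibble(
      subject_id = character(0), segment_id = integer(0), start_s = numeric(0),
      midpoint_s = numeric(0), n_beats = integer(0), n_interpolated = integer(0),
      max_interpolated_run = integer(0), mean_activity = numeric(0),
      valid = logical(0), exclusion_reason = character(0)
    ))
  }
  max_run <- function(f) {
    r <- rle(f == "interpolated")
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }
  segs <- bt[, .(
    start_s = t0[1] + seg[1] * duration_s,
    n_beats = .N,
    n_interpolated = sum(flag == "interpolated"),
    max_interpolated_run = max_run(flag)
  ), by = .(subject_id, seg)]
  data.table::setnames(segs, "seg", "segment_id")
  segs[, midpoint_s := start_s + duration_s / 2]
  segs[, mean_activity := NA_real_]
  if (!is.null(activity)) {
    at <- data.table::as.data.table(activity)
    for (id in unique(segs$subject_id)) {
      a <- at[subject_id == id]
      rows <- which(segs$subject_id == id)
      if (nrow(a) == 0) next
      idx <- findInterval(a$time_s, c(segs$start_s[rows], Inf))
      ok <- idx >= 1 & idx <= length(rows) &
        a$time_s < segs$start_s[rows][pmin(idx, length(rows))] + duration_s
      mm <- tapply(a$magnitude[ok], idx[ok], mean)
      segs$mean_activity[rows[as.integer(names(mm))]] <- as.numeric(mm)
    }
  }
  segs[, `:=`(valid = TRUE, exclusion_reason = "none")]
  data.table::setorder(segs, subject_id, segment_id)
  tibble::as_tibble(segs[, .(subject_id, segment_id, start_s, midpoint_s, n_beats,
                             n_interpolated, max_interpolated_run, mean_activity,
                             valid, exclusion_reason)])
}

#' Apply segment validity rules
#'
#' A segment is invalidated by the first matching rule, in order: more than
#' four interpolated beats in a row (`interpolation_run`), mean activity above
#' the threshold (`activity`), or fewer than `min_beats` beats
#' (`too_few_beats`). The default activity threshold is the subject-specific
#' 90th percentile of mean segment activity (restricted to wake-time segments
#' when `labels` are supplied); pass a named numeric vector or a scalar to
#' override it absolutely.
#'
#' @param segments segment table from [segment_ibi()]
#' @param activity_threshold `NULL` (subject-specific 90th percentile), a
#'   scalar, or a named vector by subject
#' @param min_beats minimum beat count for a usable 5-minute segment
#' @param labels optional sleep/wake labels used to restrict the threshold
#'   quantile to wake-time segments
#' @param max_interp_run longest tolerated interpolated run (default 4; runs
#'   strictly longer are discarded)
#' @return segment table with `valid` and `exclusion_reason` set; idempotent
#' @export
filter_segments <- function(segments, activity_threshold = NULL, min_beats = 100L,
                            labels = NULL, max_interp_run = 4L) {
  segs <- segments
  segs$valid <- TRUE
  segs$exclusion_reason <- "none"
  ids <- unique(segs$subject_id)
  thr <- rep(Inf, nrow(segs))
  if (is.null(activity_threshold)) {
    for (id in ids) {
      rows <- which(segs$subject_id == id)
      base <- rows
      if (!is.null(labels)) {
        l <- labels[labels$subject_id == id & !is.na(labels$sleep_onset_s), ]
        if (nrow(l)) {
          in_wake <- vapply(segs$midpoint_s[rows], function(t) {
            any(t >= l$wake_onset_s & t < l$sleep_onset_s)
          }, logical(1))
          if (any(in_wake)) base <- rows[in_wake]
        }
      }
      act <- segs$mean_activity[base]
      if (all(is.na(act))) next
      thr[rows] <- quantile(act, 0.9, na.rm = TRUE, names = FALSE)
    }
  } else if (length(activity_threshold) == 1L && is.null(names(activity_threshold))) {
    thr[] <- activity_threshold
  } else {
    for (id in ids) {
      stop_if_not(id %in% names(activity_threshold),
                  sprintf("no activity threshold for subject '%s'", id))
      thr[segs$subject_id == id] <- activity_threshold[[id]]
    }
  }
  act <- ifelse(is.na(segs$mean_activity), -Inf, segs$mean_activity)
  # first matching rule wins: interpolation_run, then activity, then too_few_beats
  reason <- rep("none", nrow(segs))
  reason[segs$n_beats < min_beats] <- "too_few_beats"
  reason[act > thr] <- "activity"
  reason[segs$max_interpolated_run > max_interp_run] <- "interpolation_run"
  segs$exclusion_reason <- reason
  segs$valid <- reason == "none"
  segs
}
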