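#' Validate an IBI series table
#'
#' An IBI series is a tibble with columns `subject_id`, `time_s` (timestamp of
#' each beat, seconds since recording start), `ibi_ms` (inter-beat interval in
#' milliseconds) and optionally `flag` (one of `"clean"`, `"artifact"`,
#' `"interpolated"`). Timestamps must be strictly increasing within a subject
#' and all intervals positive.
#'
#' @param ibi data frame to validate
#' @return the input, invisibly, with a `flag` column added (all `"clean"`)
#'   if missing
#' @export
validate_ibi_series <- function(ibi) {
  stop_if_not(all(c("subject_id", "time_s", "ibi_ms") %in% names(ibi)),
              "IBI series needs columns subject_id, time_s, ibi_ms")
  stop_if_not(all(is.finite(ibi$time_s)) && all(is.finite(ibi$ibi_ms)),
              "IBI series contains non-finite values")
  stop_if_not(all(ibi$ibi_ms > 0), "all IBIs must be positive")
  for (id in unique(ibi$subject_id)) {
    ts <- ibi$time_s[ibi$subject_id == id]
    bad <- which(diff(ts) <= 0)
    if (length(bad)) {
      stop(sprintf("timestamps not strictly increasing for subject '%s' (row %d)",
                   id, bad[1] + 1L), call. = FALSE)
    }
  }
  if (!"flag" %in% names(ibi)) {
    ibi$flag <- "clean"
  } else {
    stop_if_not(all(ibi$flag %in% c("clean", "artifact", "interpolated")),
                "flag must be one of clean/artifact/interpolated")
  }
  invisible(tibble::as_tibble(ibi))
}

#' Validate an activity series table
#'
#' Movement-magnitude samples (nominally 1 Hz) with columns `subject_id`,
#' `time_s`, `magnitude` (device units, non-negative); timestamps
#' non-decreasing per subject.
#'
#' @param activity data frame to validate
#' @return the input, invisibly
#' @export
validate_activity_series <- function(activity) {
  stop_if_not(all(c("subject_id", "time_s", "magnitude") %in% names(activity)),
              "activity series needs columns subject_id, time_s, magnitude")
  stop_if_not(all(activity$magnitude >= 0), "activity magnitude must be >= 0")
  for (id in unique(activity$subject_id)) {
    ts <- activity$time_s[activity$subject_id == id]
    bad <- which(diff(ts) < 0)
    if (length(bad)) {
      stop(sprintf("activity timestamps decreasing for subject '%s' (row %d)",
                   id, bad[1] + 1L), call. = FALSE)
    }
  }
  invisible(tibble::as_tibble(activity))
}

#' Validate sleep/wake labels
#'
#' One row per recorded day with columns `subject_id`, `day_index`,
#' `wake_onset_s`, `sleep_onset_s`. The sleep interval of day *d* runs from
#' `sleep_onset_s[d]` to `wake_onset_s[d + 1]`; a trailing row whose
#' `sleep_onset_s` is `NA` may supply the final wake onset. Within a subject
#' the sequence wake < sleep < next wake must hold.
#'
#' @param labels data frame to validate
#' @return the input, invisibly
#' @export
validate_sleep_labels <- function(labels) {
  need <- c("subject_id", "day_index", "wake_onset_s", "sleep_onset_s")
  stop_if_not(all(need %in% names(labels)),
              "labels need columns subject_id, day_index, wake_onset_s, sleep_onset_s")
  for (id in unique(labels$subject_id)) {
    l <- labels[labels$subject_id == id, ]
    l <- l[order(l$day_index), ]
    seq_ts <- as.vector(rbind(l$wake_onset_s, l$sleep_onset_s))
    seq_ts <- seq_ts[!is.na(seq_ts)]
    stop_if_not(all(diff(seq_ts) > 0),
                sprintf("wake/sleep onsets not strictly ordered for subject '%s'", id))
  }
  invisible(tibble::as_tibble(labels))
}
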