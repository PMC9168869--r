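#' Read wearable input tables from CSV
#'
#' Schema-checked readers for the pipeline's plain-text interchange formats.
#' Malformed rows (non-monotone timestamps, negative values, unknown subject
#' references) are rejected with the offending row identified.
#'
#' Schemas: IBI `subject_id,time_s,ibi_ms[,flag]`; activity
#' `subject_id,time_s,magnitude`; labels
#' `subject_id,day_index,wake_onset_s,sleep_onset_s`; subjects
#' `subject_id,group,age,sex,...`; normative
#' `sex,age_min,age_max,hour,metric,reference`.
#'
#' @param path CSV file path
#' @return validated tibble
#' @name read_streams_csv
NULL

#' @rdname read_streams_csv
#' @export
read_ibi_csv <- function(path) {
  validate_ibi_series(tibble::as_tibble(data.table::fread(path,
                                                          colClasses = list(character = "subject_id"))))
}

#' @rdname read_streams_csv
#' @export
read_activity_csv <- function(path) {
  validate_activity_series(tibble::as_tibble(data.table::fread(path,
                                                               colClasses = list(character = "subject_id"))))
}

#' @rdname read_streams_csv
#' @export
read_labels_csv <- function(path) {
  validate_sleep_labels(tibble::as_tibble(data.table::fread(path,
                                                            colClasses = list(character = "subject_id"))))
}

#' @rdname read_streams_csv
#' @export
read_subjects_csv <- function(path) {
  x <- tibble::as_tibble(data.table::fread(path,
                                           colClasses = list(character = "subject_id")))
  stop_if_not(all(c("subject_id", "age", "sex") %in% names(x)),
              "subjects CSV needs at least subject_id, age, sex")
  stop_if_not(!any(duplicated(x$subject_id)), "duplicate subject_id in metadata")
  x
}

#' @rdname read_streams_csv
#' @export
read_normative_csv <- function(path) {
  x <- tibble::as_tibble(data.table::fread(path))
  need <- c("sex", "age_min", "age_max", "hour", "metric", "reference")
  stop_if_not(all(need %in% names(x)), "normative CSV schema mismatch")
  stop_if_not(all(x$reference > 0), "normative references must be positive")
  x
}

#' Read and cross-validate a full stream bundle
#'
#' @param paths named list with elements `ibi`, `activity`, `labels`,
#'   `subjects`, `normative` (file paths); `activity` may be `NULL`
#' @return named list of validated tibbles
#' @export
read_streams <- function(paths) {
  out <- list(
    ibi = read_ibi_csv(paths$ibi),
    activity = if (!is.null(paths$activity)) read_activity_csv(paths$activity),
    labels = read_labels_csv(paths$labels),
    subjects = read_subjects_csv(paths$subjects),
    normative = read_normative_csv(paths$normative)
  )
  unknown <- setdiff(unique(out$ibi$subject_id), out$subjects$subject_id)
  stop_if_not(length(unknown) == 0,
              sprintf("IBI rows reference subjects absent from metadata: %s",
                      paste(unknown, collapse = ", ")))
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. `inputs` is either a named
#' list of file paths (as for [read_streams()]) or a named list of in-memory
#' tables with the same elements.
#'
#' @param inputs input bundle (paths or tables)
#' @param window_beats,artifact_coef,artifact_floor_ms artifact detector
#'   settings ([detect_artifacts()])
#' @param activity_threshold,min_beats segment validity settings
#'   ([filter_segments()])
#' @param degree,margin_fraction trend settings ([fit_trend()])
#' @param metrics normalized metrics carried through trend and search
#' @param groupings grouping names or custom lists ([resolve_grouping()])
#' @param out_dir optional directory for result CSV/TSV exports
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(inputs, window_beats = 41L, artifact_coef = 3.32,
                            artifact_floor_ms = 50, activity_threshold = NULL,
                            min_beats = 100L, degree = 10L, margin_fraction = 0.15,
                            metrics = c("sdnn_pct", "sd1_pct", "sd2_pct"),
                            groupings = "case", out_dir = NULL) {
  structure(
    list(inputs = inputs, window_beats = window_beats,
         artifact_coef = artifact_coef, artifact_floor_ms = artifact_floor_ms,
         activity_threshold = activity_threshold, min_beats = min_beats,
         degree = degree, margin_fraction = margin_fraction, metrics = metrics,
         groupings = groupings, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in order: artifact detection, artifact
#' correction, 5-minute segmentation, validity filtering, HRV metrics,
#' normative percentage scoring, wake-anchored time standardization,
#' per-subject trend fitting, and the single-window and delta discrimination
#' searches for each configured grouping. Deterministic given its inputs.
#'
#' @param config a [pipeline_config()]
#' @return list: `segments` (with validity and metrics), `points`
#'   (standardized, normalized), `trends`, `results` (per grouping: `single`
#'   and `delta` ranked reports), `manifest` (per-stage record accounting:
#'   segments in = valid + excluded by reason)
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  inp <- config$inputs
  if (is.character(inp$ibi)) inp <- read_streams(inp)
  ibi <- validate_ibi_series(inp$ibi)
  flagged <- detect_artifacts(ibi, config$window_beats, config$artifact_coef,
                              config$artifact_floor_ms)
  corrected <- correct_artifacts(flagged)
  segs <- segment_ibi(corrected, inp$activity)
  segs <- filter_segments(segs, config$activity_threshold, config$min_beats,
                          labels = inp$labels)
  mets <- segment_metrics(corrected, segs)
  valid <- mets[mets$valid, ]
  norm <- normalize_segments(valid, inp$subjects, inp$normative)
  points <- standardize_time(norm, inp$labels)
  # subjects without enough usable segments are excluded with a message
  counts <- table(points$subject_id)
  usable <- names(counts)[counts >= config$degree + 2]
  dropped_subjects <- setdiff(unique(ibi$subject_id), usable)
  if (length(dropped_subjects)) {
    message(sprintf("run_pipeline: excluded %d subject(s) with too few valid segments: %s",
                    length(dropped_subjects), paste(dropped_subjects, collapse = ", ")))
  }
  points <- points[points$subject_id %in% usable, ]
  trends <- fit_cohort_trends(points, config$metrics, config$degree,
                              config$margin_fraction)
  results <- list()
  for (g in config$groupings) {
    gname <- if (is.character(g)) g else (g$name %||% "custom")
    grouping <- resolve_grouping(inp$subjects[inp$subjects$subject_id %in% usable, ], g)
    results[[gname]] <- list(
      single = search_single(trends, grouping, config$metrics),
      delta = search_delta(trends, grouping, config$metrics)
    )
  }
  excl <- table(factor(segs$exclusion_reason,
                       levels = c("none", "interpolation_run", "activity", "too_few_beats")))
  manifest <- list(
    n_subjects_in = length(unique(ibi$subject_id)),
    n_subjects_analyzed = length(usable),
    n_beats_in = nrow(ibi),
    n_beats_flagged = sum(flagged$flag == "artifact"),
    n_beats_after_correction = nrow(corrected),
    segments_in = nrow(segs),
    segments_valid = as.integer(excl[["none"]]),
    segments_excluded = as.list(excl[-1]),
    points_standardized = nrow(points)
  )
  out <- list(segments = mets, points = points, trends = trends,
              results = results, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(mets, file.path(config$out_dir, "segments.csv"))
    data.table::fwrite(points, file.path(config$out_dir, "points.csv"))
    for (gname in names(results)) {
      data.table::fwrite(results[[gname]]$single,
                         file.path(config$out_dir, sprintf("search_single_%s.tsv", gname)),
                         sep = "\t")
      data.table::fwrite(results[[gname]]$delta,
                         file.path(config$out_dir, sprintf("search_delta_%s.tsv", gname)),
                         sep = "\t")
    }
  }
  out
}
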