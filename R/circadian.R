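#' Map segments onto the wake-anchored standardized day
#'
#' Each segment midpoint is located in its labeled wake or sleep interval and
#' mapped to a position in `[0, 1)`: the wake phase occupies `[0, 0.5)`
#' (0 = wake onset) and the sleep phase `[0.5, 1)` (0.5 = sleep onset), each
#' phase rescaled linearly to its half regardless of actual duration. The
#' sleep interval of day *d* ends at the wake onset of day *d + 1*; all days
#' are pooled (superimposed). Segments not covered by any labeled interval
#' are dropped with a message.
#'
#' @param segments segment table (typically valid segments with metric columns)
#' @param labels sleep/wake labels ([validate_sleep_labels()])
#' @return segment table with `position` (standardized day coordinate),
#'   `phase` (`"wake"`/`"sleep"`) and `day_index` columns
#' @export
standardize_time <- function(segments, labels) {
  labels <- validate_sleep_labels(labels)
  out <- segments
  n <- nrow(segments)
  position <- rep(NA_real_, n)
  phase <- rep(NA_character_, n)
  day_index <- rep(NA_integer_, n)
  for (id in unique(segments$subject_id)) {
    l <- labels[labels$subject_id == id, ]
    l <- l[order(l$day_index), ]
    rows <- which(segments$subject_id == id)
    if (nrow(l) == 0) next
    t <- segments$midpoint_s[rows]
    p <- rep(NA_real_, length(t)); ph <- rep(NA_character_, length(t))
    di <- rep(NA_integer_, length(t))
    for (d in seq_len(nrow(l))) {
      w0 <- l$wake_onset_s[d]; s0 <- l$sleep_onset_s[d]
      if (!is.na(s0)) {
        in_wake <- t >= w0 & t < s0
        p[in_wake] <- 0.5 * (t[in_wake] - w0) / (s0 - w0)
        ph[in_wake] <- "wake"
        di[in_wake] <- l$day_index[d]
        if (d < nrow(l)) {
          w1 <- l$wake_onset_s[d + 1]
          in_sleep <- t >= s0 & t < w1
          p[in_sleep] <- 0.5 + 0.5 * (t[in_sleep] - s0) / (w1 - s0)
          ph[in_sleep] <- "sleep"
          di[in_sleep] <- l$day_index[d]
        }
      }
    }
    position[rows] <- p; phase[rows] <- ph; day_index[rows] <- di
  }
  out$position <- position
  out$phase <- phase
  out$day_index <- day_index
  dropped <- is.na(out$position)
  if (any(dropped)) {
    message(sprintf("standardize_time: dropped %d segment(s) outside labeled intervals",
                    sum(dropped)))
  }
  out[!dropped, ]
}

#' Fit the superimposed circadian trend of one metric
#'
#' Ordinary least-squares polynomial regression of metric values on the
#' standardized day position. Because the standardized day is periodic,
#' points within `margin_fraction` of each boundary are first replicated
#' across it (end-of-sleep points copied before 0, start-of-wake points
#' copied after 1) so the fit is not distorted at the edges; the trend is
#' then only ever evaluated on `[0, 1)`. The polynomial is fitted in an
#' orthogonalized basis (a raw degree-10 monomial basis on `[0, 1]` is badly
#' conditioned); the result is basis-independent.
#'
#' If there are too few points the degree is reduced to `n - 2` with a
#' message; fewer than 4 points is an error.
#'
#' @param position standardized day positions in `[0, 1)`
#' @param value metric values (typically normative percentages)
#' @param metric metric name carried in the result
#' @param degree polynomial degree (default 10)
#' @param margin_fraction width of the replicated margins (default 0.15)
#' @return a `circadian_trend` object: coefficients, basis, the ten window
#'   medians ([window_medians()]) and per-bin point counts
#' @export
fit_trend <- function(position, value, metric = "metric", degree = 10L,
                      margin_fraction = 0.15) {
  ok <- is.finite(position) & is.finite(value)
  position <- position[ok]; value <- value[ok]
  n <- length(position)
  stop_if_not(n >= 4, "fit_trend needs at least 4 points")
  stop_if_not(all(position >= 0 & position < 1), "positions must lie in [0, 1)")
  if (n <= degree + 1) {
    degree <- n - 2L
    message(sprintf("fit_trend: degree reduced to %d for %d points", degree, n))
  }
  hi <- position >= 1 - margin_fraction
  lo <- position < margin_fraction
  x <- c(position, position[hi] - 1, position[lo] + 1)
  y <- c(value, value[hi], value[lo])
  # orthogonal polynomial basis on the extended domain
  pb <- poly(x, degree = degree)
  fit <- lm.fit(cbind(1, unclass(pb)), y)
  trend <- structure(
    list(
      metric = metric,
      degree = degree,
      coefficients = unname(fit$coefficients),
      basis = attr(pb, "coefs"),
      margin_fraction = margin_fraction,
      n_points = n
    ),
    class = "circadian_trend"
  )
  trend$window_medians <- window_medians(trend)
  trend$n_per_bin <- tabulate(pmin(floor(position * 10) + 1L, 10L), nbins = 10L)
  names(trend$n_per_bin) <- bin_labels()
  trend
}

#' Evaluate a fitted circadian trend
#'
#' @param object a `circadian_trend` from [fit_trend()]
#' @param position positions in `[0, 1)` at which to evaluate
#' @param ... unused
#' @return numeric vector of trend values
#' @export
predict.circadian_trend <- function(object, position, ...) {
  pb <- poly(position, degree = object$degree, coefs = object$basis)
  drop(cbind(1, unclass(pb)) %*% object$coefficients)
}

#' @export
print.circadian_trend <- function(x, ...) {
  cat(sprintf("<circadian_trend> metric=%s degree=%d n=%d\n",
              x$metric, x$degree, x$n_points))
  print(round(x$window_medians, 3))
  invisible(x)
}

#' Ten circadian window medians of a fitted trend
#'
#' Each value is the median of the fitted trend evaluated on a `grid_n`-point
#' uniform grid within its 0.1-wide bin of the standardized day (five wake
#' bins, then five sleep bins). Medians are taken over the fitted curve, not
#' over raw points.
#'
#' @param trend a `circadian_trend`
#' @param grid_n grid points per bin (default 1000)
#' @return named numeric vector of length 10 (see [bin_labels()])
#' @export
window_medians <- function(trend, grid_n = 1000L) {
  g <- trend_grid(trend, grid_n)
  med <- vapply(split(g$value, g$bin), median, numeric(1))
  setNames(as.numeric(med[as.character(0:9)]), bin_labels())
}

# Dense within-bin midpoint grid evaluation of a trend: grid_n points per
# bin, symmetric about the bin midpoint so the median of a linear trend over
# a bin equals its midpoint value exactly.
trend_grid <- function(trend, grid_n = 1000L) {
  offs <- (seq_len(grid_n) - 0.5) / grid_n / 10
  pos <- rep(0:9 / 10, each = grid_n) + offs
  list(position = pos, bin = rep(0:9, each = grid_n),
       value = predict(trend, pos))
}

#' Fit circadian trends for every subject and metric
#'
#' @param points standardized segment table ([standardize_time()]) carrying
#'   the metric columns
#' @param metrics metric column names to fit (default the normalized
#'   SDNN/SD1/SD2 percentages)
#' @param degree,margin_fraction passed to [fit_trend()]
#' @return tibble with columns `subject_id`, `metric`, `n_points` and a
#'   `trend` list-column of `circadian_trend` objects
#' @export
fit_cohort_trends <- function(points,
                              metrics = c("sdnn_pct", "sd1_pct", "sd2_pct"),
                              degree = 10L, margin_fraction = 0.15) {
  stop_if_not(all(metrics %in% names(points)),
              "metric columns missing from points table")
  ids <- unique(points$subject_id)
  rows <- vector("list", length(ids) * length(metrics))
  k <- 0L
  for (id in ids) {
    p <- points[points$subject_id == id, ]
    for (m in metrics) {
      k <- k + 1L
      tr <- fit_trend(p$position, p[[m]], metric = m, degree = degree,
                      margin_fraction = margin_fraction)
      rows[[k]] <- tibble::tibble(subject_id = id, metric = m,
                                  n_points = tr$n_points, trend = list(tr))
    }
  }
  do.call(rbind, rows)
}

#' Trend stability across subsets of recorded days
#'
#' For each requested subset size *k*, the trend is refitted on every
#' combination of *k* recorded days (all combinations when there are at most
#' `max_combinations`, otherwise a seeded random sample of that many) and the
#' resulting ten-window-median vector is correlated (Pearson) with the vector
#' from the full data. High correlations at small *k* indicate that shorter
#' recordings already capture the circadian trend.
#'
#' @param points standardized segment table of one subject, with `day_index`
#' @param metric metric column to analyze
#' @param subset_sizes day-subset sizes to evaluate (sizes exceeding the
#'   number of recorded days are skipped)
#' @param max_combinations cap on combinations per subset size (default 5000)
#' @param seed seed for combination sampling
#' @param degree,margin_fraction passed to [fit_trend()]
#' @return tibble: `metric`, `k`, `combo`, `r`
#' @export
stability_analysis <- function(points, metric = "sdnn_pct",
                               subset_sizes = NULL, max_combinations = 5000L,
                               seed = NULL, degree = 10L, margin_fraction = 0.15) {
  stop_if_not(length(unique(points$subject_id)) == 1,
              "stability_analysis expects a single subject")
  days <- sort(unique(points$day_index))
  stop_if_not(length(days) >= 2, "stability_analysis needs >= 2 recorded days")
  subset_sizes <- subset_sizes %||% seq_along(days)
  full <- fit_trend(points$position, points[[metric]], metric = metric,
                    degree = degree, margin_fraction = margin_fraction)$window_medians
  res <- list()
  with_seed(seed, {
    for (k in subset_sizes) {
      if (k > length(days)) next
      n_comb <- choose(length(days), k)
      combos <- if (n_comb <= max_combinations) {
        combn(days, k, simplify = FALSE)
      } else {
        lapply(seq_len(max_combinations), function(i) sort(sample(days, k)))
      }
      r <- vapply(combos, function(dd) {
        p <- points[points$day_index %in% dd, ]
        med <- fit_trend(p$position, p[[metric]], metric = metric,
                         degree = degree,
                         margin_fraction = margin_fraction)$window_medians
        if (sd(med) == 0 || sd(full) == 0) NA_real_ else cor(med, full)
      }, numeric(1))
      res[[length(res) + 1L]] <-
        tibble::tibble(metric = metric, k = k, combo = seq_along(r), r = r)
    }
  })
  do.call(rbind, res)
}
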