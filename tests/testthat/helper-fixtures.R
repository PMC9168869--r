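# Shared fixtures: small, code-built, deterministic.

# Flat-profile subject truth: stationary AR(1) everywhere, closed-form oracles.
flat_truth <- function(sigma = 30, rho = 0.5, mean_ibi = 800, artifact_rate = 0,
                       jitter = 0, id = "S01") {
  subject_truth(
    subject_id = id,
    sigma_profile = function(p) rep(sigma, length(p)),
    rho_profile = function(p) rep(rho, length(p)),
    mean_ibi_profile = function(p) rep(mean_ibi, length(p)),
    artifact_rate = artifact_rate, schedule_jitter_sd = jitter
  )
}

# Consistent IBI series (timestamps = cumsum of IBIs) from a vector of IBIs.
make_ibi <- function(ibi_ms, id = "S01", flag = NULL) {
  tibble::tibble(
    subject_id = id,
    time_s = cumsum(ibi_ms) / 1000,
    ibi_ms = ibi_ms,
    flag = flag %||% rep("clean", length(ibi_ms))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force artifact criterion: literal evaluation at every index.
brute_artifacts <- function(x, window_beats = 41, coef = 3.32, floor_ms = 50) {
  n <- length(x)
  half <- window_beats %/% 2
  flagged <- logical(n)
  for (i in seq_len(n)) {
    lo <- min(max(1, i - half), n - window_beats + 1)
    nb <- x[setdiff(lo:(lo + window_beats - 1), i)]
    qd <- (quantile(nb, 0.75, names = FALSE) - quantile(nb, 0.25, names = FALSE)) / 2
    flagged[i] <- abs(x[i] - median(nb)) > max(coef * qd, floor_ms)
  }
  flagged
}

# Exhaustive two-sided Mann-Whitney p-value by rank-assignment enumeration.
mwu_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  mu <- n1 * length(y) / 2
  all_u <- combn(length(pooled), n1, u_stat)
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-12)
}

# Pair-counting AUC oracle.
auc_pairs <- function(values, labels) {
  x <- values[labels]; y <- values[!labels]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Standardized normalized points for one simulated segment-resolution cohort.
cohort_points <- function(coh) {
  norm <- suppressMessages(normalize_segments(coh$segments, coh$subjects,
                                              coh$config$normative))
  suppressMessages(standardize_time(norm, coh$labels))
}
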