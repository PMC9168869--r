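#' Enumerate all contiguous circadian windows
#'
#' All contiguous within-phase ranges over the five 20% bins of each phase:
#' 15 per phase, 30 in total, in deterministic (phase, start, end) order.
#' Windows never span the day/night boundary.
#'
#' @return tibble: `window_id`, `phase`, `start_bin`, `end_bin`, `label`,
#'   `lo`, `hi` (covered position range on the standardized day)
#' @export
#' @examples
#' nrow(enumerate_windows())  # 30
enumerate_windows <- function() {
  rows <- list()
  for (phase in c("day", "night")) {
    off <- if (phase == "day") 0 else 0.5
    for (s in 0:4) for (e in s:4) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        phase = phase, start_bin = s, end_bin = e,
        label = window_label(phase, s, e),
        lo = off + s / 10, hi = off + (e + 1) / 10
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(tibble::tibble(window_id = seq_len(nrow(out))), out)
  tibble::as_tibble(out)
}

#' AUC with DeLong confidence interval
#'
#' Mann-Whitney AUC of `values` for discriminating `labels` (ties counted
#' one-half), oriented toward the positive class (`TRUE` labels). The
#' variance is DeLong's structural-components estimator and the 95% CI a
#' normal approximation clipped to `[0, 1]`.
#'
#' @param values numeric predictor, one per subject
#' @param labels logical (or coercible) class labels; `TRUE` = positive class
#' @param level confidence level (default 0.95)
#' @return named numeric vector: `auc`, `ci_low`, `ci_high`, `se`
#' @export
auc_delong <- function(values, labels, level = 0.95) {
  labels <- as.logical(labels)
  ok <- is.finite(values) & !is.na(labels)
  x <- values[ok & labels]   # cases
  y <- values[ok & !labels]  # comparisons
  m <- length(x); n <- length(y)
  stop_if_not(m >= 1 && n >= 1, "both classes must be non-empty")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)  # structural components of the cases
  v01 <- colMeans(psi)  # ... of the comparisons
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  q <- qnorm(1 - (1 - level) / 2)
  c(auc = auc,
    ci_low = max(0, auc - q * se),
    ci_high = min(1, auc + q * se),
    se = se)
}

#' Mann-Whitney test and standardized mean difference for two groups
#'
#' Two-sided Mann-Whitney-U p-value (exact when both groups have at most 8
#' untied observations, otherwise normal approximation with continuity and
#' tie correction) and the standardized mean difference
#' `(mean_case - mean_comparison) / pooled SD` (n-1 pooling) with its
#' asymptotic-variance 95% CI.
#'
#' @param values numeric vector
#' @param labels logical class labels; `TRUE` = case
#' @return list: `p_mwu`, `smd`, `smd_ci` (length-2), `n_case`, `n_comparison`
#' @export
compare_groups <- function(values, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(values) & !is.na(labels)
  x <- values[ok & labels]; y <- values[ok & !labels]
  n1 <- length(x); n2 <- length(y)
  stop_if_not(n1 >= 2 && n2 >= 2, "need >= 2 observations per group")
  exact <- n1 <= 8 && n2 <= 8 && !any(duplicated(c(x, y)))
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  stop_if_not(sp > 0, "zero pooled SD: SMD undefined")
  d <- (mean(x) - mean(y)) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  list(p_mwu = p, smd = d, smd_ci = c(d - 1.96 * se, d + 1.96 * se),
       n_case = n1, n_comparison = n2)
}

#' Pearson and Spearman correlations with Fisher-z confidence intervals
#'
#' Binary covariates coded 0/1 are accepted (the Pearson coefficient is then
#' the point-biserial correlation).
#'
#' @param x,y numeric vectors (>= 4 complete pairs)
#' @return tibble with one row per method: `method`, `n`, `r`, `ci_low`,
#'   `ci_high`, `p`
#' @export
correlate <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  stop_if_not(length(x) >= 4, "correlate needs >= 4 complete pairs")
  stop_if_not(sd(x) > 0 && sd(y) > 0, "degenerate variance in correlate input")
  out <- lapply(c("pearson", "spearman"), function(m) {
    ct <- suppressWarnings(cor.test(x, y, method = m))
    r <- unname(ct$estimate)
    ci <- fisher_ci(r, length(x))
    tibble::tibble(method = m, n = length(x), r = r,
                   ci_low = ci[1], ci_high = ci[2], p = ct$p.value)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjustment of one comparison family
#'
#' Step-up false-discovery-rate adjustment; the family is whatever set of
#' p-values is passed in (by convention, all comparisons emitted by one
#' search report).
#'
#' @param p raw p-values in `[0, 1]`
#' @return adjusted p-values, same order as the input
#' @export
adjust_bh <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-subject circadian window medians
#'
#' Evaluates each subject's fitted trend on a shared dense grid and takes
#' the median over every window's covered bins — the per-subject values the
#' discrimination searches operate on.
#'
#' @param trends cohort trend table ([fit_cohort_trends()])
#' @param windows window set (default [enumerate_windows()])
#' @param grid_n grid points per bin
#' @return tibble: `subject_id`, `metric`, `window_id`, `label`, `value`
#' @export
window_values <- function(trends, windows = enumerate_windows(), grid_n = 1000L) {
  rows <- vector("list", nrow(trends))
  for (i in seq_len(nrow(trends))) {
    g <- trend_grid(trends$trend[[i]], grid_n)
    vals <- vapply(seq_len(nrow(windows)), function(w) {
      b0 <- windows$start_bin[w] + if (windows$phase[w] == "night") 5L else 0L
      b1 <- windows$end_bin[w] + if (windows$phase[w] == "night") 5L else 0L
      median(g$value[g$bin >= b0 & g$bin <= b1])
    }, numeric(1))
    rows[[i]] <- data.frame(
      subject_id = trends$subject_id[i], metric = trends$metric[i],
      window_id = windows$window_id, label = windows$label, value = vals
    )
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# Shared statistics for one candidate selector: AUC battery + MWU + SMD.
# Degenerate selectors (zero pooled SD, e.g. identical window medians in a
# delta pair) get NA effect statistics rather than aborting the search.
selector_stats <- function(values, labels) {
  a <- auc_delong(values, labels)
  cg <- tryCatch(compare_groups(values, labels), error = function(e) NULL)
  data.frame(
    auc = a[["auc"]], auc_ci_low = a[["ci_low"]], auc_ci_high = a[["ci_high"]],
    p_mwu = if (is.null(cg)) NA_real_ else cg$p_mwu,
    smd = if (is.null(cg)) NA_real_ else cg$smd,
    smd_ci_low = if (is.null(cg)) NA_real_ else cg$smd_ci[1],
    smd_ci_high = if (is.null(cg)) NA_real_ else cg$smd_ci[2],
    n_case = sum(as.logical(labels), na.rm = TRUE),
    n_comparison = sum(!as.logical(labels), na.rm = TRUE)
  )
}

rank_report <- function(report, metrics) {
  report$p_adjusted <- adjust_bh(report$p_mwu)
  o <- order(-abs(report$auc - 0.5), match(report$metric, metrics),
             report$phase_key, report$start_key, report$end_key)
  report <- report[o, ]
  report$rank <- seq_len(nrow(report))
  report$phase_key <- report$start_key <- report$end_key <- NULL
  tibble::as_tibble(report)
}

#' Ordered single-window discrimination search
#'
#' For every contiguous circadian window and metric, each subject's value is
#' the median of their fitted trend over the window; candidates are ranked by
#' `|AUC - 0.5|` (descending; ties broken by metric, phase, start, end order)
#' with the full statistical battery attached and Benjamini-Hochberg
#' adjustment over the whole report.
#'
#' @param trends cohort trend table ([fit_cohort_trends()])
#' @param grouping tibble with `subject_id` and logical `class`
#'   (`TRUE` = positive class); subjects absent from it are excluded
#' @param metrics metrics to search (default SDNN/SD1/SD2 percentages)
#' @param windows window set (default [enumerate_windows()])
#' @return ranked tibble of comparison results, one row per (window, metric)
#' @export
search_single <- function(trends, grouping,
                          metrics = c("sdnn_pct", "sd1_pct", "sd2_pct"),
                          windows = enumerate_windows()) {
  trends <- trends[trends$metric %in% metrics &
                     trends$subject_id %in% grouping$subject_id, ]
  wv <- window_values(trends, windows)
  labs <- grouping$class[match(wv$subject_id, grouping$subject_id)]
  rows <- list()
  for (m in metrics) {
    for (w in seq_len(nrow(windows))) {
      sel <- wv$metric == m & wv$window_id == windows$window_id[w]
      st <- selector_stats(wv$value[sel], labs[sel])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(selector = windows$label[w], metric = m,
                   phase_key = match(windows$phase[w], c("day", "night")),
                   start_key = windows$start_bin[w],
                   end_key = windows$end_bin[w]),
        st
      )
    }
  }
  rank_report(do.call(rbind, rows), metrics)
}

#' Adaptive two-window (delta) discrimination search
#'
#' For every unordered pair of distinct windows (435 pairs) and metric, each
#' subject's value is the difference of their trend medians in the two
#' windows (first minus second in enumeration order), ranked as in
#' [search_single()].
#'
#' @inheritParams search_single
#' @return ranked tibble of comparison results, one row per (pair, metric)
#' @export
search_delta <- function(trends, grouping,
                         metrics = c("sdnn_pct", "sd1_pct", "sd2_pct"),
                         windows = enumerate_windows()) {
  trends <- trends[trends$metric %in% metrics &
                     trends$subject_id %in% grouping$subject_id, ]
  wv <- window_values(trends, windows)
  labs_by_subject <- grouping$class
  names(labs_by_subject) <- grouping$subject_id
  pairs <- combn(windows$window_id, 2)
  rows <- list()
  for (m in metrics) {
    wvm <- wv[wv$metric == m, ]
    # subjects x windows matrix of medians
    mat <- matrix(wvm$value,
                  nrow = length(unique(wvm$subject_id)),
                  ncol = nrow(windows), byrow = TRUE,
                  dimnames = list(unique(wvm$subject_id), windows$label))
    labs <- as.logical(labs_by_subject[rownames(mat)])
    for (k in seq_len(ncol(pairs))) {
      a <- match(pairs[1, k], windows$window_id)
      b <- match(pairs[2, k], windows$window_id)
      delta <- mat[, a] - mat[, b]
      st <- selector_stats(delta, labs)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(
          selector = paste(windows$label[a], "and", windows$label[b]),
          metric = m,
          phase_key = a, start_key = b, end_key = 0L
        ),
        st
      )
    }
  }
  rank_report(do.call(rbind, rows), metrics)
}

#' Screen a selector for confounding by age, gender and medication
#'
#' Age is tested by Pearson/Spearman correlation against the subject values;
#' gender and concomitant medication (0/1) by [compare_groups()]. Findings
#' are flagged at `alpha`; constant covariates are skipped with a note.
#'
#' @param values per-subject selector values
#' @param age numeric ages
#' @param gender 0/1 (or logical) gender coding
#' @param medication 0/1 (or logical) concomitant-medication flag
#' @param alpha significance level for flagging (default 0.05)
#' @return tibble: `covariate`, `test`, `estimate`, `p`, `flagged`, `note`
#' @export
confounder_screen <- function(values, age = NULL, gender = NULL,
                              medication = NULL, alpha = 0.05) {
  rows <- list()
  if (!is.null(age)) {
    ct <- correlate(values, age)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      covariate = "age", test = paste0("correlation_", ct$method),
      estimate = ct$r, p = ct$p, flagged = ct$p < alpha, note = ""
    )
  }
  binary <- list(gender = gender, medication = medication)
  for (nm in names(binary)) {
    b <- binary[[nm]]
    if (is.null(b)) next
    b <- as.logical(b)
    if (length(unique(b[!is.na(b)])) < 2 || min(table(b)) < 2) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        covariate = nm, test = "mwu_smd", estimate = NA_real_, p = NA_real_,
        flagged = FALSE, note = "skipped: covariate constant or group too small"
      )
      next
    }
    cg <- compare_groups(values, b)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      covariate = nm, test = "mwu_smd", estimate = cg$smd, p = cg$p_mwu,
      flagged = cg$p_mwu < alpha, note = ""
    )
  }
  do.call(rbind, rows)
}

#' Descriptive group comparison of a cohort metadata table
#'
#' Categorical variables are compared by chi-square (Yates continuity
#' correction for 2x2 tables, uncorrected Pearson otherwise; zero-margin
#' rows/columns dropped), continuous variables by Mann-Whitney-U. Emits
#' counts or mean (SD) per group alongside the p-value.
#'
#' @param subjects metadata table
#' @param group name of the grouping column
#' @param variables columns to test (default all except the group column)
#' @return tibble: `variable`, `type`, `summary_a`, `summary_b`, `p`
#' @export
describe_cohort <- function(subjects, group, variables = NULL) {
  stop_if_not(group %in% names(subjects), "grouping column not found")
  g <- factor(subjects[[group]])
  stop_if_not(nlevels(g) == 2, "describe_cohort expects exactly two groups")
  variables <- variables %||% setdiff(names(subjects), c(group, "subject_id"))
  rows <- list()
  fmt_ms <- function(v) sprintf("%.1f (%.1f)", mean(v, na.rm = TRUE), sd(v, na.rm = TRUE))
  for (v in variables) {
    x <- subjects[[v]]
    if (is.numeric(x)) {
      ok <- !is.na(x)
      p <- if (sum(ok & g == levels(g)[1]) >= 2 && sum(ok & g == levels(g)[2]) >= 2) {
        suppressWarnings(wilcox.test(x[ok] ~ droplevels(g[ok]))$p.value)
      } else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, type = "continuous",
        summary_a = fmt_ms(x[g == levels(g)[1]]),
        summary_b = fmt_ms(x[g == levels(g)[2]]), p = p
      )
    } else {
      tab <- table(x, g)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      p <- if (nrow(tab) >= 2 && ncol(tab) >= 2) {
        suppressWarnings(
          chisq.test(tab, correct = nrow(tab) == 2 && ncol(tab) == 2)$p.value
        )
      } else NA_real_
      count_str <- function(col) paste(sprintf("%s:%d", rownames(tab), tab[, col]),
                                       collapse = " ")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, type = "categorical",
        summary_a = if (ncol(tab) >= 1) count_str(1) else "",
        summary_b = if (ncol(tab) >= 2) count_str(2) else "", p = p
      )
    }
  }
  do.call(rbind, rows)
}

#' Resolve a clinical grouping to class labels
#'
#' Built-in groupings mirror the standard clinical thresholds: `"case"`
#' (case vs control group column), `"inflammation"` (inflammatory activity
#' within cases), `"progression"`, `"edss"` (EDSS >= 3), `"armss"`
#' (ARMSS > 4), `"compass31"` (COMPASS-31 >= 17 vs controls),
#' `"compass31_within"` (within cases), `"fsmc"` (FSMC total >= 65 within
#' cases). Custom groupings can be given as
#' `list(field =, op =, threshold =, population =)`.
#'
#' @param subjects metadata table
#' @param grouping name of a built-in grouping or a custom list
#' @return tibble with `subject_id` and logical `class` restricted to the
#'   comparison population; both classes are guaranteed non-empty
#' @export
resolve_grouping <- function(subjects, grouping = "case") {
  builtin <- list(
    case = list(field = "group", op = "eq", threshold = "case", population = "all"),
    inflammation = list(field = "inflammatory_activity", op = "eq", threshold = TRUE,
                        population = "case"),
    progression = list(field = "progressive", op = "eq", threshold = TRUE,
                       population = "case"),
    edss = list(field = "edss", op = "ge", threshold = 3, population = "case"),
    armss = list(field = "armss", op = "gt", threshold = 4, population = "case"),
    compass31 = list(field = "compass31", op = "ge", threshold = 17,
                     population = "case_vs_control"),
    compass31_within = list(field = "compass31", op = "ge", threshold = 17,
                            population = "case"),
    fsmc = list(field = "fsmc_total", op = "ge", threshold = 65, population = "case")
  )
  spec <- if (is.character(grouping)) {
    stop_if_not(grouping %in% names(builtin),
                sprintf("unknown grouping '%s'", grouping))
    builtin[[grouping]]
  } else grouping
  stop_if_not(spec$field %in% names(subjects),
              sprintf("grouping field '%s' missing from metadata", spec$field))
  x <- subjects[[spec$field]]
  pos <- switch(spec$op,
    eq = x == spec$threshold,
    ge = x >= spec$threshold,
    gt = x > spec$threshold,
    le = x <= spec$threshold,
    lt = x < spec$threshold,
    stop("unknown grouping operator")
  )
  keep <- switch(spec$population %||% "all",
    all = rep(TRUE, nrow(subjects)),
    case = subjects$group == "case",
    case_vs_control = (subjects$group == "case" & pos) | subjects$group == "control",
    stop("unknown comparison population")
  )
  keep <- keep & !is.na(pos)
  out <- tibble::tibble(subject_id = subjects$subject_id[keep],
                        class = as.logical(pos[keep]))
  stop_if_not(any(out$class) && any(!out$class),
              "grouping yields an empty class")
  out
}
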