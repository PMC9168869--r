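#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All exported stochastic entry points
# funnel their seeds through here so that global RNG state is never clobbered.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Ten-bin labels of the standardized day
#'
#' The standardized day is split into ten windows of width 0.1: five during
#' the wake phase (positions 0-0.5) and five during sleep (0.5-1).
#'
#' @return character vector of length 10, e.g. `"0%-20% day"`, `"80%-100% night"`.
#' @export
#' @examples
#' bin_labels()
bin_labels <- function() {
  c(
    sprintf("%d%%-%d%% day", seq(0, 80, 20), seq(20, 100, 20)),
    sprintf("%d%%-%d%% night", seq(0, 80, 20), seq(20, 100, 20))
  )
}

# Parse a window label like "40%-80% night" into phase, within-phase bins
# (0-4), and the covered [lo, hi) position range on the standardized day.
parse_window <- function(label) {
  m <- regmatches(label, regexec("^([0-9]+)%-([0-9]+)% (day|night)$", label))[[1]]
  stop_if_not(length(m) == 4, sprintf("unparseable window label: '%s'", label))
  from <- as.integer(m[2]); to <- as.integer(m[3]); phase <- m[4]
  stop_if_not(from %% 20 == 0 && to %% 20 == 0 && from < to && to <= 100,
              sprintf("window '%s' is not aligned to the ten-bin grid", label))
  start_bin <- from %/% 20
  end_bin <- to %/% 20 - 1L
  offset <- if (phase == "day") 0 else 0.5
  list(
    phase = phase, start_bin = start_bin, end_bin = end_bin,
    lo = offset + from / 200, hi = offset + to / 200,
    label = label
  )
}

window_label <- function(phase, start_bin, end_bin) {
  sprintf("%d%%-%d%% %s", start_bin * 20L, (end_bin + 1L) * 20L, phase)
}
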