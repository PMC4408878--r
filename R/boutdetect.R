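#' Parameters of the trailing-mean bout rule
#'
#' A bout is three or more consecutive pyloric cycles each at least 40% above
#' the background frequency, where background is the trailing mean of the
#' previous ten cycles. These defaults implement that rule; all three knobs
#' are exposed.
#'
#' @param lookback cycles in the trailing background mean (default 10).
#' @param lookahead consecutive qualifying cycles required (default 3).
#' @param rel_increase required relative increase over background
#'   (default 0.40).
#' @param strict logical; `FALSE` (default) reads the rule as "at least a 40%
#'   increase" (`>=`), `TRUE` as a strict `>`.
#' @return an object of class `pyloric_boutparams`.
#' @export
bout_params <- function(lookback = 10L, lookahead = 3L, rel_increase = 0.40,
                        strict = FALSE) {
  structure(list(lookback = check_count(lookback, "lookback", 1L),
                 lookahead = check_count(lookahead, "lookahead", 1L),
                 rel_increase = check_number(rel_increase, "rel_increase",
                                             lower = .Machine$double.eps),
                 strict = isTRUE(strict)),
            class = "pyloric_boutparams")
}

#' Detect frequency bouts in an ordered per-cycle frequency series
#'
#' For each cycle index `i` past the lookback window, the background `b` is
#' the mean frequency of the previous `lookback` cycles (the candidate cycle
#' itself excluded). The rule fires at `i` if the next `lookahead` cycles
#' (`i`, ..., `i + lookahead - 1`) are all at least `(1 + rel_increase) * b`.
#' Runs of consecutive firing indices are merged into a single bout event; a
#' new event requires at least one non-firing index between firings.
#'
#' Indices are 1-based, following R convention. The unmerged firing count is
#' returned in the `n_unmerged` attribute.
#'
#' @param frequencies ordered per-cycle frequencies, Hz.
#' @param times optional per-cycle times (PD burst starts, s) used to stamp
#'   `detect_time`.
#' @param params a [bout_params()] object.
#' @return a `pyloric_bouts_detected` data.frame: `detect_index`,
#'   `detect_time` (NA without `times`), `extent_first`, `extent_last`.
#'   Fewer cycles than `lookback + lookahead` give an empty result with a
#'   message.
#' @examples
#' f <- c(rep(1, 20), rep(1.5, 5), rep(1, 10))
#' detect_bouts(f)  # one bout, detect_index 21
#' @export
detect_bouts <- function(frequencies, times = NULL, params = bout_params()) {
  stopifnot(inherits(params, "pyloric_boutparams"))
  f <- as.numeric(frequencies)
  n <- length(f)
  lb <- params$lookback; la <- params$lookahead
  empty <- data.frame(detect_index = integer(0), detect_time = numeric(0),
                      extent_first = integer(0), extent_last = integer(0))
  if (!is.null(times) && length(times) != n)
    stop("`times` must match `frequencies` in length")
  if (n < lb + la) {
    message(sprintf("only %d cycles; need at least %d for bout detection", n, lb + la))
    return(structure(empty, class = c("pyloric_bouts_detected", "data.frame"),
                     n_unmerged = 0L))
  }
  cs <- c(0, cumsum(f))
  idx <- (lb + 1L):(n - la + 1L)                    # candidate detection indices
  bg <- (cs[idx] - cs[idx - lb]) / lb               # mean of previous lb cycles
  runmin <- f[idx]
  if (la > 1L) for (k in 1L:(la - 1L)) runmin <- pmin(runmin, f[idx + k])
  thr <- (1 + params$rel_increase) * bg
  fires <- if (params$strict) runmin > thr else runmin >= thr
  if (!any(fires))
    return(structure(empty, class = c("pyloric_bouts_detected", "data.frame"),
                     n_unmerged = 0L))
  fi <- idx[fires]
  run_start <- c(TRUE, diff(fi) > 1L)
  grp <- cumsum(run_start)
  first <- tapply(fi, grp, min)
  last <- tapply(fi, grp, max)
  out <- data.frame(detect_index = as.integer(first),
                    detect_time = if (is.null(times)) NA_real_ else times[first],
                    extent_first = as.integer(first),
                    extent_last = as.integer(last + la - 1L))
  rownames(out) <- NULL
  structure(out, class = c("pyloric_bouts_detected", "data.frame"),
            n_unmerged = length(fi))
}

#' Count detected bouts per 24 h day of recording
#'
#' Events are binned by 24 h windows from recording start (day 1 covers the
#' first 24 h).
#'
#' @param events a `pyloric_bouts_detected` data.frame with `detect_time`
#'   stamped.
#' @param timeline a [preparation_timeline()] giving `recording_start` and
#'   `recording_end`.
#' @return an integer vector of per-day counts, length
#'   `ceiling(duration / 24 h)`.
#' @export
count_bouts_per_day <- function(events, timeline) {
  stopifnot(inherits(timeline, "pyloric_timeline"))
  dur <- timeline$recording_end - timeline$recording_start
  n_days <- max(1L, ceiling(dur / 86400))
  if (nrow(events) == 0L) return(integer(n_days))
  if (anyNA(events$detect_time)) stop("events lack detect_time stamps")
  t <- events$detect_time - timeline$recording_start
  if (any(t < 0 | t > dur)) stop("bout event outside the recorded span")
  day <- pmin(floor(t / 86400) + 1L, n_days)
  tabulate(day, nbins = n_days)
}

#' Time from decentralization to the first detected bout
#'
#' @param events a `pyloric_bouts_detected` data.frame with `detect_time`.
#' @param timeline a [preparation_timeline()] with a decentralization time.
#' @return seconds from decentralization to the first bout detected after it,
#'   or `NA` if none.
#' @export
time_to_first_bout <- function(events, timeline) {
  stopifnot(inherits(timeline, "pyloric_timeline"))
  if (is.na(timeline$decentralization_time))
    stop("timeline has no decentralization time")
  t <- events$detect_time[!is.na(events$detect_time) &
                            events$detect_time > timeline$decentralization_time]
  if (!length(t)) return(NA_real_)
  min(t) - timeline$decentralization_time
}
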