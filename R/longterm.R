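#' Preparation timeline: condition and event metadata
#'
#' @param prep_id identifier.
#' @param condition `"intact"` or `"decentralized"`.
#' @param recording_start,recording_end recording span, seconds.
#' @param decentralization_time seconds, or `NA` for intact preparations.
#' @param saline_exchange_times numeric vector of exchange times, seconds.
#' @return an object of class `pyloric_timeline`.
#' @export
preparation_timeline <- function(prep_id, condition = c("decentralized", "intact"),
                                 recording_start = 0, recording_end,
                                 decentralization_time = NA_real_,
                                 saline_exchange_times = numeric(0)) {
  condition <- match.arg(condition)
  check_number(recording_start, "recording_start")
  check_number(recording_end, "recording_end", lower = recording_start)
  ev <- c(decentralization_time, saline_exchange_times)
  ev <- ev[!is.na(ev)]
  if (any(ev < recording_start | ev > recording_end))
    stop("event times must lie within the recording span")
  if (condition == "decentralized" && is.na(decentralization_time))
    stop("decentralized preparations need a decentralization_time")
  structure(list(prep_id = prep_id, condition = condition,
                 recording_start = recording_start, recording_end = recording_end,
                 decentralization_time = as.numeric(decentralization_time),
                 saline_exchange_times = as.numeric(saline_exchange_times)),
            class = "pyloric_timeline")
}

# reference time from which day bins are counted: decentralization for
# decentralized preparations, matched post-baseline time (start + 1 h) for
# intact ones
day_origin <- function(timeline) {
  if (!is.na(timeline$decentralization_time)) timeline$decentralization_time
  else timeline$recording_start + 3600
}

valid_cycles <- function(cycles) cycles[cycles$valid, , drop = FALSE]

#' Bin per-cycle frequencies into fixed-width time bins
#'
#' Cycles are assigned to bins by PD burst start; the per-bin statistic of
#' frequency (median by default, matching 6 min = 0.1 h binned long-term
#' frequency plots) is computed over valid cycles. Empty bins are `NA`, not
#' zero.
#'
#' @param cycles a `pyloric_cycles` data.frame.
#' @param bin_width bin width in hours (default 0.1 h = 6 min).
#' @param statistic `"median"` or `"mean"`.
#' @param origin time origin of the first bin, seconds (default 0).
#' @param span optional total span in seconds to fix the number of bins.
#' @return a `pyloric_binned` data.frame: `bin_start_h`, `bin_mid_h`,
#'   `value`, `n`.
#' @export
bin_series <- function(cycles, bin_width = 0.1,
                       statistic = c("median", "mean"), origin = 0,
                       span = NULL) {
  statistic <- match.arg(statistic)
  check_number(bin_width, "bin_width", lower = .Machine$double.eps)
  cy <- valid_cycles(cycles)
  w <- hours_to_s(bin_width)
  last <- if (!is.null(span)) span else if (nrow(cy)) max(cy$pd_start) - origin + 1e-9 else w
  n_bins <- max(1L, ceiling(last / w))
  bin <- floor((cy$pd_start - origin) / w) + 1L
  keep <- bin >= 1L & bin <= n_bins
  stat_fun <- if (statistic == "median") stats::median else mean
  value <- rep(NA_real_, n_bins)
  counts <- tabulate(bin[keep], nbins = n_bins)
  if (any(keep)) {
    agg <- tapply(cy$frequency[keep], bin[keep], stat_fun)
    value[as.integer(names(agg))] <- as.numeric(agg)
  }
  out <- data.frame(bin_start_h = (seq_len(n_bins) - 1L) * bin_width,
                    bin_mid_h = (seq_len(n_bins) - 0.5) * bin_width,
                    value = value, n = counts)
  structure(out, class = c("pyloric_binned", "data.frame"),
            statistic = statistic, bin_width = bin_width)
}

#' Box-plot statistics with the 1.5 IQR whisker rule
#'
#' Median and first/third quartiles (linear-interpolation, type-7 quantiles);
#' whiskers extend to the most extreme datum within 1.5 times the
#' interquartile range from the nearest quartile; every point beyond the
#' whiskers is listed as an outlier.
#'
#' @param values numeric vector (NAs dropped).
#' @return a list of class `pyloric_boxstats`: `n`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
box_stats <- function(values) {
  x <- values[is.finite(values)]
  if (!length(x)) stop("no finite values")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  structure(list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(x[inside]), whisker_high = max(x[inside]),
                 outliers = sort(x[!inside])),
            class = "pyloric_boxstats")
}

#' @export
print.pyloric_boxstats <- function(x, ...) {
  cat(sprintf("box stats (n=%d): median %.4g [Q1 %.4g, Q3 %.4g], whiskers [%.4g, %.4g], %d outlier(s)\n",
              x$n, x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}

#' Per-hour box statistics across preparations
#'
#' @param data data.frame with columns `hour` (integer hour index) and
#'   `value` (per-preparation hourly mean, Hz).
#' @return data.frame with one row per hour: `hour`, `n`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `n_outliers`; the full outlier
#'   lists are in the `outliers` attribute.
#' @export
hourly_boxstats <- function(data) {
  stopifnot(all(c("hour", "value") %in% names(data)))
  hours <- sort(unique(data$hour))
  stats_list <- lapply(hours, function(h) box_stats(data$value[data$hour == h]))
  out <- data.frame(hour = hours,
                    n = vapply(stats_list, `[[`, 0L, "n"),
                    median = vapply(stats_list, `[[`, 0, "median"),
                    q1 = vapply(stats_list, `[[`, 0, "q1"),
                    q3 = vapply(stats_list, `[[`, 0, "q3"),
                    whisker_low = vapply(stats_list, `[[`, 0, "whisker_low"),
                    whisker_high = vapply(stats_list, `[[`, 0, "whisker_high"),
                    n_outliers = vapply(stats_list, function(s) length(s$outliers), 0L))
  attr(out, "outliers") <- lapply(stats_list, `[[`, "outliers")
  out
}

#' Daily means of frequency and phases
#'
#' Days are 24 h bins counted from decentralization (decentralized
#' preparations) or from the matched post-baseline reference time (intact:
#' recording start + 1 h). Means are over valid cycles; LP phases exclude
#' LP-silent cycles. Days with zero valid cycles are flagged for exclusion
#' from repeated-measures analyses.
#'
#' @param cycles a `pyloric_cycles` data.frame.
#' @param timeline a [preparation_timeline()].
#' @param n_days number of days to summarize (default: all complete or
#'   partial days in the recording).
#' @return data.frame: `day`, `n_cycles`, `frequency`, `pd_off_phase`,
#'   `lp_on_phase`, `lp_off_phase`, `complete` (any valid cycles that day).
#' @export
daily_mean <- function(cycles, timeline, n_days = NULL) {
  stopifnot(inherits(timeline, "pyloric_timeline"))
  origin <- day_origin(timeline)
  cy <- valid_cycles(cycles)
  cy <- cy[cy$pd_start >= origin, , drop = FALSE]
  if (is.null(n_days))
    n_days <- max(1L, ceiling((timeline$recording_end - origin) / 86400))
  day <- floor((cy$pd_start - origin) / 86400) + 1L
  keep <- day >= 1L & day <= n_days
  cy <- cy[keep, , drop = FALSE]; day <- day[keep]
  mean_by_day <- function(v, d) {
    ok <- is.finite(v)
    out <- rep(NA_real_, n_days)
    if (any(ok)) {
      agg <- tapply(v[ok], d[ok], mean)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
    out
  }
  lp_ok <- !cy$lp_silent
  out <- data.frame(day = seq_len(n_days),
                    n_cycles = tabulate(day, nbins = n_days),
                    frequency = mean_by_day(cy$frequency, day),
                    pd_off_phase = mean_by_day(cy$pd_off_phase, day),
                    lp_on_phase = mean_by_day(cy$lp_on_phase[lp_ok], day[lp_ok]),
                    lp_off_phase = mean_by_day(cy$lp_off_phase[lp_ok], day[lp_ok]))
  out$complete <- out$n_cycles > 0L
  out
}

#' Mean frequency in a short window around a time point
#'
#' Used e.g. for the "30 min post-decentralization" snapshot: the mean
#' frequency of valid cycles whose PD start lies in
#' `[t0 - halfwidth, t0 + halfwidth]`. The default half-width of 5 min makes
#' a 10 min snapshot window.
#'
#' @param cycles a `pyloric_cycles` data.frame.
#' @param t0 window centre, seconds.
#' @param halfwidth window half-width, seconds (default 300).
#' @return mean frequency in Hz, or `NA` (with a message) if the window holds
#'   no valid cycles.
#' @export
snapshot_mean <- function(cycles, t0, halfwidth = 300) {
  check_number(t0, "t0"); check_number(halfwidth, "halfwidth", lower = 0)
  cy <- valid_cycles(cycles)
  sel <- cy$pd_start >= t0 - halfwidth & cy$pd_start <= t0 + halfwidth
  if (!any(sel)) {
    message(sprintf("no valid cycles in [%g, %g] s", t0 - halfwidth, t0 + halfwidth))
    return(NA_real_)
  }
  mean(cy$frequency[sel])
}

#' Fastest post-decentralization stretch of fixed length
#'
#' Slides a window of `window` hours in steps of `step` hours over
#' `[decentralization, decentralization + horizon]` and returns the window
#' maximizing mean frequency over valid cycles; ties are broken by earliest
#' start. Windows with less than `min_occupancy` of their 0.1 h sub-bins
#' populated are ineligible, so sparse or silent stretches cannot win.
#'
#' @param cycles a `pyloric_cycles` data.frame.
#' @param timeline a [preparation_timeline()] with a decentralization time.
#' @param window window length, hours (default 5).
#' @param horizon search horizon after decentralization, hours (default 120).
#' @param step slide step, hours (default 0.1).
#' @param min_occupancy minimum fraction of populated 0.1 h sub-bins.
#' @return a list of class `pyloric_window`: `start` (s), `start_h_post`
#'   (hours after decentralization), `mean_freq`, `phases` (named means),
#'   `cv` (cycle-to-cycle CV inside the window), `n_cycles`, `occupancy`;
#'   or `NULL` if no window is eligible.
#' @export
fastest_window <- function(cycles, timeline, window = 5, horizon = 120,
                           step = 0.1, min_occupancy = 0.5) {
  stopifnot(inherits(timeline, "pyloric_timeline"))
  if (is.na(timeline$decentralization_time))
    stop("fastest_window needs a decentralized preparation")
  dec <- timeline$decentralization_time
  w <- hours_to_s(window)
  avail <- timeline$recording_end - dec
  if (avail < w) stop("need at least `window` hours of post-decentralization data")
  last_start <- dec + min(hours_to_s(horizon), avail) - w
  starts <- seq(dec, last_start, by = hours_to_s(step))
  cy <- valid_cycles(cycles)
  cy <- cy[cy$pd_start >= dec, , drop = FALSE]
  sub <- hours_to_s(0.1)
  n_sub <- round(w / sub)
  best <- NULL
  for (s in starts) {
    sel <- cy$pd_start >= s & cy$pd_start < s + w
    if (!any(sel)) next
    f <- cy$frequency[sel]
    occ <- length(unique(floor((cy$pd_start[sel] - s) / sub))) / n_sub
    if (occ < min_occupancy) next
    m <- mean(f)
    if (is.null(best) || m > best$mean_freq) {
      lp_ok <- sel & !cy$lp_silent
      best <- list(start = s, start_h_post = s_to_hours(s - dec), mean_freq = m,
                   phases = c(pd_off_phase = mean(cy$pd_off_phase[sel]),
                              lp_on_phase = mean(cy$lp_on_phase[lp_ok]),
                              lp_off_phase = mean(cy$lp_off_phase[lp_ok])),
                   cv = stats::sd(f) / m, n_cycles = sum(sel), occupancy = occ)
    }
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "pyloric_window")
}

#' @export
print.pyloric_window <- function(x, ...) {
  cat(sprintf("fastest window: %.1f h post-decentralization, mean %.3f Hz (n=%d cycles, CV %.3f)\n",
              x$start_h_post, x$mean_freq, x$n_cycles, x$cv))
  invisible(x)
}

#' Within-preparation cycle-to-cycle variability for one day
#'
#' Coefficient of variation (SD/mean) of per-cycle frequency within a 24 h
#' day bin (days counted as in [daily_mean()]).
#'
#' @param cycles a `pyloric_cycles` data.frame.
#' @param day 1-based day index.
#' @param timeline a [preparation_timeline()].
#' @return dimensionless CV, or `NA` with fewer than 2 valid cycles.
#' @export
within_prep_cv <- function(cycles, day, timeline) {
  stopifnot(inherits(timeline, "pyloric_timeline"))
  day <- check_count(day, "day", lower = 1L)
  origin <- day_origin(timeline)
  cy <- valid_cycles(cycles)
  sel <- cy$pd_start >= origin + (day - 1) * 86400 &
    cy$pd_start < origin + day * 86400
  f <- cy$frequency[sel]
  if (length(f) < 2L) return(NA_real_)
  stats::sd(f) / mean(f)
}

#' Across-preparation variability of daily means
#'
#' Coefficient of variation (SD/mean) across preparations of a per-day
#' summary value.
#'
#' @param values per-preparation values for one day (e.g. daily mean
#'   frequencies), NAs dropped.
#' @return dimensionless CV.
#' @export
across_prep_cv <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / mean(x)
}

#' Detect silent stretches from PD burst times
#'
#' The record is tiled into consecutive windows of `window` seconds; a window
#' is silent if it contains fewer than `min_bursts` PD bursts. Maximal runs
#' of silent windows are merged into intervals.
#'
#' @param burst_starts PD burst start times, seconds (cycle PD starts work
#'   equally).
#' @param span `c(start, end)` of the record, seconds.
#' @param window tile width, seconds (default 60).
#' @param min_bursts bursts required for a window to count as active
#'   (default 3).
#' @return data.frame of silent intervals: `start`, `end` (seconds); zero
#'   rows when none.
#' @export
detect_silence <- function(burst_starts, span, window = 60, min_bursts = 3L) {
  stopifnot(length(span) == 2L, span[2] > span[1])
  check_number(window, "window", lower = .Machine$double.eps)
  min_bursts <- check_count(min_bursts, "min_bursts", lower = 1L)
  n_win <- ceiling((span[2] - span[1]) / window)
  t <- burst_starts[burst_starts >= span[1] & burst_starts < span[2]]
  counts <- tabulate(floor((t - span[1]) / window) + 1L, nbins = n_win)
  silent <- counts < min_bursts
  if (!any(silent)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(silent)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values
  data.frame(start = span[1] + (starts_i[keep] - 1L) * window,
             end = pmin(span[1] + ends_i[keep] * window, span[2]))
}

#' Pre/post contrast of mean frequency around saline exchanges
#'
#' For each exchange at time `t`, computes the mean frequency of valid cycles
#' in the hour before (`[t - window, t)`) and the hour after (`(t, t + window]`).
#' Exchanges closer than `2 * window` apart use truncated, non-overlapping
#' windows (half the gap on each side), with a message.
#'
#' @param cycles a `pyloric_cycles` data.frame.
#' @param timeline a [preparation_timeline()] with `saline_exchange_times`.
#' @param window full window length on each side, seconds (default 3600).
#' @return a list: `per_exchange` (data.frame `time`, `pre`, `post`, `n_pre`,
#'   `n_post`), `pre_mean`, `post_mean` (per-preparation averages over
#'   exchanges).
#' @export
saline_effect <- function(cycles, timeline, window = 3600) {
  stopifnot(inherits(timeline, "pyloric_timeline"))
  ex <- sort(timeline$saline_exchange_times)
  if (!length(ex)) stop("timeline has no saline exchanges")
  cy <- valid_cycles(cycles)
  rows <- lapply(seq_along(ex), function(i) {
    t <- ex[i]
    w_pre <- window; w_post <- window
    if (i > 1L && t - ex[i - 1L] < 2 * window) {
      w_pre <- (t - ex[i - 1L]) / 2
      message(sprintf("exchanges at %g and %g s are < %g s apart; pre window truncated to %g s",
                      ex[i - 1L], t, 2 * window, w_pre))
    }
    if (i < length(ex) && ex[i + 1L] - t < 2 * window) {
      w_post <- (ex[i + 1L] - t) / 2
      message(sprintf("exchanges at %g and %g s are < %g s apart; post window truncated to %g s",
                      t, ex[i + 1L], 2 * window, w_post))
    }
    pre_sel <- cy$pd_start >= t - w_pre & cy$pd_start < t
    post_sel <- cy$pd_start > t & cy$pd_start <= t + w_post
    data.frame(time = t,
               pre = if (any(pre_sel)) mean(cy$frequency[pre_sel]) else NA_real_,
               post = if (any(post_sel)) mean(cy$frequency[post_sel]) else NA_real_,
               n_pre = sum(pre_sel), n_post = sum(post_sel))
  })
  per <- do.call(rbind, rows)
  list(per_exchange = per,
       pre_mean = mean(per$pre, na.rm = TRUE),
       post_mean = mean(per$post, na.rm = TRUE))
}
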