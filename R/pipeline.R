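#' Simulate one preparation end to end
#'
#' Convenience wrapper: builds the ground-truth cycle series, renders PD/LP
#' spike trains, and assembles the matching timeline.
#'
#' @param params a [prep_params()] object.
#' @param duration recording duration, seconds.
#' @param rng_seed integer seed.
#' @param spikes_per_burst spikes per rendered burst.
#' @return list with `truth` (`pyloric_truth`), `spikes` (`pyloric_spikes`),
#'   `timeline` (`pyloric_timeline`).
#' @export
simulate_preparation <- function(params, duration, rng_seed = NULL,
                                 spikes_per_burst = 5L) {
  truth <- generate_cycle_series(params, duration, rng_seed)
  spikes <- render_spike_times(truth, spikes_per_burst)
  timeline <- preparation_timeline(
    prep_id = params$prep_id,
    condition = if (is.null(params$decentralization_time)) "intact" else "decentralized",
    recording_start = 0, recording_end = duration,
    decentralization_time = params$decentralization_time %||% NA_real_,
    saline_exchange_times = params$saline_exchange_times)
  list(truth = truth, spikes = spikes, timeline = timeline)
}

#' Analyze one preparation from spike times to summaries
#'
#' Runs the full quantification chain: interspike-interval burst segmentation
#' for PD and LP, the per-cycle period/frequency/phase table referenced to PD
#' burst onset, frequency-range validity filtering, trailing-mean bout
#' detection, 0.1 h binned medians, silence detection, and daily means.
#'
#' @param spikes a `pyloric_spikes` data.frame for one preparation.
#' @param timeline the matching [preparation_timeline()].
#' @param max_isi burst-segmentation ISI threshold, seconds.
#' @param min_spikes minimum spikes per burst.
#' @param min_freq,max_freq validity range for cycle frequencies, Hz.
#' @param bout a [bout_params()] object.
#' @param bin_width binning width, hours.
#' @return an object of class `pyloric_analysis`: `bursts`, `cycles`,
#'   `bouts`, `binned`, `silence`, `daily`, `timeline`, `summary` (list with
#'   per-preparation means and counts).
#' @export
analyze_preparation <- function(spikes, timeline, max_isi = 0.3,
                                min_spikes = 2L, min_freq = 0.02,
                                max_freq = 5, bout = bout_params(),
                                bin_width = 0.1) {
  stopifnot(inherits(timeline, "pyloric_timeline"))
  seg <- function(u) segment_bursts(spikes[spikes$unit == u, , drop = FALSE],
                                    max_isi = max_isi, min_spikes = min_spikes,
                                    unit = u, prep_id = timeline$prep_id)
  pd <- seg("PD"); lp <- seg("LP")
  cycles <- filter_cycles(build_cycles(pd, lp), min_freq = min_freq,
                          max_freq = max_freq)
  cv <- valid_cycles(cycles)
  bouts <- if (nrow(cv) >= bout$lookback + bout$lookahead)
    detect_bouts(cv$frequency, cv$pd_start, bout)
  else structure(data.frame(detect_index = integer(0), detect_time = numeric(0),
                            extent_first = integer(0), extent_last = integer(0)),
                 class = c("pyloric_bouts_detected", "data.frame"), n_unmerged = 0L)
  span <- c(timeline$recording_start, timeline$recording_end)
  silence <- detect_silence(pd$start, span)
  binned <- bin_series(cycles, bin_width = bin_width,
                       origin = timeline$recording_start,
                       span = diff(span))
  daily <- daily_mean(cycles, timeline)
  summary <- list(
    prep_id = timeline$prep_id,
    condition = timeline$condition,
    n_spikes = nrow(spikes), n_pd_bursts = nrow(pd), n_lp_bursts = nrow(lp),
    n_cycles = nrow(cycles), n_valid = nrow(cv),
    mean_freq = if (nrow(cv)) mean(cv$frequency) else NA_real_,
    mean_pd_off = if (nrow(cv)) mean(cv$pd_off_phase) else NA_real_,
    mean_lp_on = mean(cv$lp_on_phase[!cv$lp_silent]),
    mean_lp_off = mean(cv$lp_off_phase[!cv$lp_silent]),
    n_bouts = nrow(bouts), n_bouts_unmerged = attr(bouts, "n_unmerged"),
    silent_fraction = if (nrow(silence)) sum(silence$end - silence$start) / diff(span) else 0)
  structure(list(bursts = rbind(pd, lp), cycles = cycles, bouts = bouts,
                 binned = binned, silence = silence, daily = daily,
                 timeline = timeline, summary = summary),
            class = "pyloric_analysis")
}

#' @export
print.pyloric_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Pyloric analysis of %s (%s)\n", s$prep_id, s$condition))
  cat(sprintf("  %d spikes -> %d PD / %d LP bursts -> %d cycles (%d valid)\n",
              s$n_spikes, s$n_pd_bursts, s$n_lp_bursts, s$n_cycles, s$n_valid))
  cat(sprintf("  mean frequency %.3f Hz; phases PD off %.3f, LP on %.3f, LP off %.3f\n",
              s$mean_freq, s$mean_pd_off, s$mean_lp_on, s$mean_lp_off))
  cat(sprintf("  %d bout(s) (%d unmerged firings); %.1f%% of record silent\n",
              s$n_bouts, s$n_bouts_unmerged, 100 * s$silent_fraction))
  invisible(x)
}

#' @export
summary.pyloric_analysis <- function(object, ...) {
  print(object)
  cat("\nDaily means:\n")
  print(object$daily, row.names = FALSE, digits = 4)
  invisible(object$summary)
}

#' Plot binned frequency against time for an analyzed preparation
#'
#' Binned median frequency versus time in hours, with decentralization and
#' saline-exchange times marked and detected bouts indicated by arrows.
#'
#' @param x a `pyloric_analysis` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pyloric_analysis <- function(x, ...) {
  b <- x$binned
  graphics::plot(b$bin_mid_h, b$value, type = "l", xlab = "time (h)",
                 ylab = "cycle frequency (Hz)",
                 main = sprintf("%s (%s)", x$summary$prep_id,
                                x$summary$condition), ...)
  tl <- x$timeline
  if (!is.na(tl$decentralization_time))
    graphics::abline(v = s_to_hours(tl$decentralization_time), col = "red",
                     lty = 2)
  if (length(tl$saline_exchange_times))
    graphics::abline(v = s_to_hours(tl$saline_exchange_times), col = "blue",
                     lty = 3)
  if (nrow(x$bouts))
    graphics::points(s_to_hours(x$bouts$detect_time),
                     rep(max(b$value, na.rm = TRUE), nrow(x$bouts)),
                     pch = 25, bg = "darkorange")
  invisible(x)
}
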