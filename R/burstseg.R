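#' Detect spikes in a sampled trace by thresholded peak picking
#'
#' A spike is each local maximum of the rectified trace exceeding the
#' threshold; candidate maxima are accepted in order of decreasing amplitude,
#' and any candidate within the refractory window of an accepted detection is
#' suppressed (so noise-induced shoulders on a spike's flanks never displace
#' its true peak). The returned time is the time of the peak sample.
#'
#' @param trace a `pyloric_trace` object (see [render_trace()]) or a numeric
#'   vector with attribute-free samples plus `sampling_rate`.
#' @param threshold detection threshold on the rectified trace (> 0). A
#'   threshold below 3 x the estimated noise SD (robust MAD estimate) gives a
#'   warning.
#' @param refractory suppression window in seconds (>= one sample; the
#'   default 3 ms also suppresses the template undershoot of synthetic
#'   traces).
#' @param sampling_rate required when `trace` is a bare numeric vector.
#' @return data.frame with columns `time` (s) and `amplitude` (rectified peak
#'   height), ordered by time.
#' @export
detect_spikes <- function(trace, threshold, refractory = 0.003,
                          sampling_rate = NULL) {
  if (inherits(trace, "pyloric_trace")) {
    vals <- trace$values; fs <- trace$sampling_rate
  } else {
    vals <- as.numeric(trace)
    fs <- sampling_rate %||% stop("`sampling_rate` required for a bare numeric trace")
  }
  check_number(threshold, "threshold", lower = .Machine$double.eps)
  if (refractory < 1 / fs) stop("`refractory` must be at least one sample")
  r <- abs(vals)
  noise_sd <- stats::median(r) / 0.6745
  if (threshold < 3 * noise_sd)
    warning(sprintf("threshold %.3g is below 3x estimated noise SD (%.3g)",
                    threshold, 3 * noise_sd))
  n <- length(r)
  if (n < 3L) return(data.frame(time = numeric(0), amplitude = numeric(0)))
  cand <- which(r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n] &
                  r[2:(n - 1)] >= threshold) + 1L
  # non-maximum suppression: strongest candidates win; ties resolved by
  # earlier time (stable order of the sort)
  refr_samp <- refractory * fs
  ord <- cand[order(-r[cand], cand)]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= refr_samp))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  data.frame(time = (accepted - 1L) / fs, amplitude = r[accepted])
}

#' Assign detected spikes to units by amplitude windows
#'
#' Each spike is labeled by the (disjoint) amplitude window containing its
#' peak amplitude; spikes falling in no window are discarded and counted in
#' the `discarded` attribute.
#'
#' @param spikes data.frame with `time` and `amplitude` (from
#'   [detect_spikes()]).
#' @param amplitude_windows named list of `c(low, high)` per unit, e.g.
#'   `list(PD = c(0.2, 0.7), LP = c(0.8, 1.3))`. Windows must not overlap.
#' @param prep_id preparation identifier attached to the output.
#' @return a `pyloric_spikes` data.frame (`prep_id`, `unit`, `time`) ordered
#'   by unit then time, with attribute `discarded` (count of unassigned
#'   spikes).
#' @export
assign_units <- function(spikes, amplitude_windows, prep_id = "prep001") {
  stopifnot(is.list(amplitude_windows), length(amplitude_windows) >= 1L,
            !is.null(names(amplitude_windows)))
  w <- do.call(rbind, lapply(amplitude_windows, function(x) {
    stopifnot(length(x) == 2L, x[1] < x[2]); as.numeric(x)
  }))
  o <- order(w[, 1])
  if (any(w[o, 1][-1] < w[o, 2][-nrow(w)]))
    stop("amplitude windows overlap")
  unit <- rep(NA_character_, nrow(spikes))
  for (u in rownames(w))
    unit[spikes$amplitude >= w[u, 1] & spikes$amplitude <= w[u, 2]] <- u
  discarded <- sum(is.na(unit))
  out <- data.frame(prep_id = prep_id, unit = unit[!is.na(unit)],
                    time = spikes$time[!is.na(unit)])
  out <- out[order(out$unit, out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pyloric_spikes", "data.frame"), discarded = discarded)
}

#' Segment a spike train into bursts by an interspike-interval threshold
#'
#' Bursts are maximal runs of consecutive spikes in which every inter-spike
#' interval is at most `max_isi`; runs with fewer than `min_spikes` spikes are
#' dropped. Burst start/end are the first/last spike of the run.
#'
#' @param times strictly increasing spike times in seconds, or a
#'   `pyloric_spikes` data.frame holding a single unit.
#' @param max_isi maximum within-burst inter-spike interval, seconds (> 0).
#'   The default 0.3 s suits pyloric-range rhythms (0.1-2.5 Hz with several
#'   spikes per burst); see [adaptive_max_isi()] for a period-scaled choice.
#' @param min_spikes minimum spikes per burst (>= 2; a one-spike burst has
#'   zero duration and breaks phase definitions).
#' @param unit,prep_id labels attached to the output when `times` is numeric.
#' @return a `pyloric_bursts` data.frame: `prep_id`, `unit`, `start`, `end`,
#'   `n_spikes`, ordered and non-overlapping.
#' @examples
#' segment_bursts(c(0, 0.05, 0.10, 1.0, 1.05, 1.10), max_isi = 0.5)
#' @export
segment_bursts <- function(times, max_isi = 0.3, min_spikes = 2L,
                           unit = "PD", prep_id = "prep001") {
  if (is.data.frame(times)) {
    stopifnot(length(unique(times$unit)) <= 1L)
    if (nrow(times)) { unit <- times$unit[1]; prep_id <- times$prep_id[1] }
    times <- times$time
  }
  check_number(max_isi, "max_isi", lower = .Machine$double.eps)
  min_spikes <- check_count(min_spikes, "min_spikes", lower = 2L)
  empty <- data.frame(prep_id = character(0), unit = character(0),
                      start = numeric(0), end = numeric(0), n_spikes = integer(0))
  if (length(times) == 0L)
    return(structure(empty, class = c("pyloric_bursts", "data.frame")))
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  brk <- which(diff(times) > max_isi)
  starts_i <- c(1L, brk + 1L)
  ends_i <- c(brk, length(times))
  n_sp <- ends_i - starts_i + 1L
  keep <- n_sp >= min_spikes
  out <- data.frame(prep_id = rep(prep_id, sum(keep)),
                    unit = rep(unit, sum(keep)),
                    start = times[starts_i[keep]], end = times[ends_i[keep]],
                    n_spikes = n_sp[keep])
  rownames(out) <- NULL
  structure(out, class = c("pyloric_bursts", "data.frame"))
}

#' Period-scaled interspike-interval threshold
#'
#' Returns 0.25 x the median of the supplied cycle periods when at least
#' `min_cycles` periods are available, else the fixed fallback. Useful when a
#' provisional cycle estimate exists and the rhythm is far from the default
#' pyloric range.
#'
#' @param periods numeric vector of cycle periods, seconds.
#' @param fallback fixed threshold used with insufficient data, seconds.
#' @param min_cycles minimum number of periods to trust the median.
#' @return a single `max_isi` value in seconds.
#' @export
adaptive_max_isi <- function(periods, fallback = 0.3, min_cycles = 10L) {
  periods <- periods[is.finite(periods) & periods > 0]
  if (length(periods) >= min_cycles) 0.25 * stats::median(periods) else fallback
}
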