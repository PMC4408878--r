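#' Population-level configuration for synthetic pyloric preparations
#'
#' Holds the across-preparation frequency distributions used to sample
#' per-preparation parameters. Defaults follow the population statistics
#' reported for *Cancer borealis*: intact pyloric cycle frequency
#' 1.2 +/- 0.29 Hz (mean +/- SD across preparations) falling to
#' 0.52 +/- 0.30 Hz after decentralization.
#'
#' @param n_preparations number of preparations to sample (>= 1).
#' @param condition `"decentralized"` (1 h of baseline, then a step to the
#'   decentralized frequency distribution) or `"intact"` (baseline throughout).
#' @param intact_freq_mean,intact_freq_sd mean and across-preparation SD of
#'   baseline cycle frequency, Hz.
#' @param decentralized_freq_mean,decentralized_freq_sd mean and SD of the
#'   post-decentralization frequency, Hz.
#' @param decentralization_time time of decentralization in seconds from
#'   recording start (default 3600 s: one hour of baseline data).
#' @param seed integer seed used by [sample_population()].
#' @return an object of class `pyloric_popconfig`.
#' @seealso [sample_population()], [prep_params()]
#' @export
population_config <- function(n_preparations,
                              condition = c("decentralized", "intact"),
                              intact_freq_mean = 1.2,
                              intact_freq_sd = 0.29,
                              decentralized_freq_mean = 0.52,
                              decentralized_freq_sd = 0.30,
                              decentralization_time = 3600,
                              seed = 1L) {
  condition <- match.arg(condition)
  check_count(n_preparations, "n_preparations", lower = 1L)
  check_number(intact_freq_mean, "intact_freq_mean", lower = .Machine$double.eps)
  check_number(decentralized_freq_mean, "decentralized_freq_mean", lower = .Machine$double.eps)
  check_number(intact_freq_sd, "intact_freq_sd", lower = 0)
  check_number(decentralized_freq_sd, "decentralized_freq_sd", lower = 0)
  check_number(decentralization_time, "decentralization_time", lower = 0)
  structure(list(
    n_preparations = as.integer(n_preparations),
    condition = condition,
    intact_freq_mean = intact_freq_mean,
    intact_freq_sd = intact_freq_sd,
    decentralized_freq_mean = decentralized_freq_mean,
    decentralized_freq_sd = decentralized_freq_sd,
    decentralization_time = decentralization_time,
    seed = as.integer(seed)
  ), class = "pyloric_popconfig")
}

# truncated-normal sampler: rejection below `lower` (0.05 Hz by default --
# active preparations never show sustained frequencies at or below this)
rtruncnorm_low <- function(n, mean, sd, lower = 0.05) {
  if (sd == 0) {
    if (mean <= lower) stop("degenerate truncated normal: mean at or below truncation point")
    return(rep(mean, n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Sample per-preparation parameters from a population configuration
#'
#' Baseline (and, for decentralized preparations, post-decentralization)
#' frequencies are drawn from truncated normal distributions with the
#' configured mean/SD, redrawing below 0.05 Hz. Deterministic for a fixed
#' seed.
#'
#' @param config a [population_config()] object.
#' @param rng_seed integer seed; defaults to `config$seed`.
#' @param ... further arguments passed to [prep_params()] for every
#'   preparation (e.g. `cycle_jitter_cv`, `phase_targets`).
#' @return a list of `pyloric_prep_params` objects, one per preparation.
#' @export
sample_population <- function(config, rng_seed = config$seed, ...) {
  if (!inherits(config, "pyloric_popconfig"))
    stop("`config` must be created by population_config()")
  with_seed(rng_seed, {
    n <- config$n_preparations
    base <- rtruncnorm_low(n, config$intact_freq_mean, config$intact_freq_sd)
    if (config$condition == "decentralized") {
      post <- rtruncnorm_low(n, config$decentralized_freq_mean, config$decentralized_freq_sd)
      dect <- config$decentralization_time
    } else {
      post <- rep(NA_real_, n)
      dect <- NA_real_
    }
    lapply(seq_len(n), function(i) {
      prep_params(prep_id = sprintf("prep%03d", i),
                  baseline_freq = base[i],
                  decentralization_time = if (is.na(dect)) NULL else dect,
                  post_dec_freq = if (is.na(post[i])) NULL else post[i],
                  ...)
    })
  })
}

#' Per-preparation generative parameters
#'
#' Describes one synthetic preparation: its baseline cycle frequency, the
#' optional decentralization step, slow Ornstein-Uhlenbeck frequency drift,
#' short-term multiplicative cycle jitter, burst phases, scheduled frequency
#' bouts, silence episodes, and saline-exchange transients.
#'
#' Phases are onset-referenced fractions of the period: `pd_off` is the PD
#' burst duty cycle, `lp_on`/`lp_off` the LP burst onset/offset phases, with
#' `0 < pd_off < lp_on < lp_off < 1`. With `duration_mode = "fixed"` the
#' corresponding events are instead placed at fixed latencies in seconds
#' (`fixed_durations`), so that phase grows in proportion to frequency.
#'
#' @param prep_id identifier string.
#' @param baseline_freq baseline cycle frequency, Hz (> 0.05).
#' @param decentralization_time seconds from recording start, or `NULL` for an
#'   intact preparation.
#' @param post_dec_freq target frequency after decentralization, Hz; required
#'   when `decentralization_time` is given.
#' @param drift_rate mean-reversion rate of the OU drift, 1/s.
#' @param drift_sd stationary SD of the OU drift, Hz.
#' @param cycle_jitter_cv coefficient of variation of i.i.d. multiplicative
#'   per-cycle period jitter (dimensionless).
#' @param phase_targets named numeric `c(pd_off=, lp_on=, lp_off=)` in (0,1).
#' @param duration_mode `"phase"` (burst events at fixed phases) or `"fixed"`
#'   (burst events at fixed latencies in seconds).
#' @param fixed_durations named numeric `c(pd_off=, lp_on=, lp_off=)`,
#'   latencies from PD burst start in seconds; used when
#'   `duration_mode = "fixed"`.
#' @param bout_schedule `NULL` or a data.frame with columns `start_cycle`
#'   (1-based cycle index), `n_cycles` (>= 3) and `factor` (>= 1.4): frequency
#'   is multiplied by `factor` over the scheduled cycles.
#' @param silence_episodes `NULL` or a data.frame with columns `start` and
#'   `duration` (seconds): no cycles are emitted inside these intervals.
#' @param saline_exchange_times numeric vector of exchange times, seconds.
#' @param saline_boost named numeric `c(factor=, decay=)`: at each exchange the
#'   frequency is boosted to `factor` times its regime baseline, decaying
#'   exponentially with time constant `decay` seconds (default 2 h).
#' @return an object of class `pyloric_prep_params`.
#' @export
prep_params <- function(prep_id = "prep001",
                        baseline_freq = 1.2,
                        decentralization_time = NULL,
                        post_dec_freq = NULL,
                        drift_rate = 1 / 300,
                        drift_sd = 0.05,
                        cycle_jitter_cv = 0.03,
                        phase_targets = c(pd_off = 0.30, lp_on = 0.45, lp_off = 0.75),
                        duration_mode = c("phase", "fixed"),
                        fixed_durations = NULL,
                        bout_schedule = NULL,
                        silence_episodes = NULL,
                        saline_exchange_times = numeric(0),
                        saline_boost = c(factor = 1.5, decay = 7200)) {
  duration_mode <- match.arg(duration_mode)
  check_number(baseline_freq, "baseline_freq", lower = 0.05)
  if (!is.null(decentralization_time)) {
    check_number(decentralization_time, "decentralization_time", lower = 0)
    if (is.null(post_dec_freq))
      stop("`post_dec_freq` is required when `decentralization_time` is set")
    check_number(post_dec_freq, "post_dec_freq", lower = 0.05)
  }
  check_number(drift_rate, "drift_rate", lower = 0)
  check_number(drift_sd, "drift_sd", lower = 0)
  check_number(cycle_jitter_cv, "cycle_jitter_cv", lower = 0, upper = 0.5)
  pt <- phase_targets[c("pd_off", "lp_on", "lp_off")]
  if (anyNA(pt) || !(0 < pt[1] && pt[1] < pt[2] && pt[2] < pt[3] && pt[3] < 1))
    stop("phase_targets must satisfy 0 < pd_off < lp_on < lp_off < 1")
  if (duration_mode == "fixed") {
    fd <- fixed_durations[c("pd_off", "lp_on", "lp_off")]
    if (anyNA(fd) || !(0 < fd[1] && fd[1] < fd[2] && fd[2] < fd[3]))
      stop("fixed_durations must satisfy 0 < pd_off < lp_on < lp_off (seconds)")
  } else fd <- NULL
  if (!is.null(bout_schedule)) {
    bout_schedule <- as.data.frame(bout_schedule)
    stopifnot(all(c("start_cycle", "n_cycles", "factor") %in% names(bout_schedule)))
    if (any(bout_schedule$n_cycles < 3))
      stop("injected bouts must span at least 3 cycles")
    if (any(bout_schedule$factor < 1.4))
      stop("injected bout amplitude factors must be >= 1.4")
    if (any(bout_schedule$start_cycle < 1))
      stop("bout start_cycle indices are 1-based and must be >= 1")
  }
  if (!is.null(silence_episodes)) {
    silence_episodes <- as.data.frame(silence_episodes)
    stopifnot(all(c("start", "duration") %in% names(silence_episodes)),
              all(silence_episodes$duration > 0))
    silence_episodes <- silence_episodes[order(silence_episodes$start), , drop = FALSE]
  }
  sb <- saline_boost[c("factor", "decay")]
  if (length(saline_exchange_times) && (anyNA(sb) || sb[1] <= 1 || sb[2] <= 0))
    stop("saline_boost must have factor > 1 and decay > 0")
  structure(list(
    prep_id = prep_id, baseline_freq = baseline_freq,
    decentralization_time = decentralization_time, post_dec_freq = post_dec_freq,
    drift_rate = drift_rate, drift_sd = drift_sd,
    cycle_jitter_cv = cycle_jitter_cv,
    phase_targets = pt, duration_mode = duration_mode, fixed_durations = fd,
    bout_schedule = bout_schedule, silence_episodes = silence_episodes,
    saline_exchange_times = as.numeric(saline_exchange_times),
    saline_boost = sb
  ), class = "pyloric_prep_params")
}

#' Generate a ground-truth cycle series for one preparation
#'
#' Produces the full per-cycle ground truth: PD burst start/end, LP burst
#' start/end, period and the instantaneous target frequency. The
#' instantaneous target is the regime baseline (pre- or post-decentralization)
#' plus OU drift plus any decaying saline boost, truncated below at 0.05 Hz,
#' and multiplied by the bout amplitude over scheduled bout cycles. Each
#' realized period is `1/target * (1 + jitter)` with i.i.d. Gaussian jitter of
#' mean 0 and CV `cycle_jitter_cv`. No cycles are emitted inside silence
#' episodes.
#'
#' The OU drift is discretized on a fixed clock at the nominal baseline
#' period, giving a stationary AR(1) sequence per cycle.
#'
#' @param params a [prep_params()] object.
#' @param duration recording duration, seconds.
#' @param rng_seed integer seed (or `NULL` to use the current RNG stream).
#' @return an object of class `pyloric_truth`: a list with elements `cycles`
#'   (data.frame: `index`, `pd_start`, `pd_end`, `lp_start`, `lp_end`,
#'   `period`, `freq_target`), `bout_cycles` (indices of scheduled bout
#'   cycles actually emitted), `silence` (episodes), `params`, `duration`.
#' @export
generate_cycle_series <- function(params, duration, rng_seed = NULL) {
  if (!inherits(params, "pyloric_prep_params"))
    stop("`params` must be created by prep_params()")
  check_number(duration, "duration", lower = .Machine$double.eps)
  with_seed(rng_seed, generate_cycle_series_impl(params, duration))
}

generate_cycle_series_impl <- function(params, duration) {
  p <- params
  fmax <- max(p$baseline_freq, p$post_dec_freq %||% 0) + 4 * p$drift_sd
  if (!is.null(p$bout_schedule) && nrow(p$bout_schedule)) fmax <- fmax * max(p$bout_schedule$factor)
  if (length(p$saline_exchange_times)) fmax <- fmax * p$saline_boost[["factor"]]
  nmax <- ceiling(duration * fmax * 1.3) + 64L

  # precomputed randomness: AR(1) OU drift on the nominal baseline clock, and
  # multiplicative jitter (clamped so periods stay positive)
  if (p$drift_sd > 0) {
    dt0 <- 1 / p$baseline_freq
    phi <- exp(-p$drift_rate * dt0)
    innov <- stats::rnorm(nmax, 0, p$drift_sd * sqrt(1 - phi^2))
    innov[1L] <- stats::rnorm(1, 0, p$drift_sd)
    drift <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  } else drift <- numeric(nmax)
  jit <- if (p$cycle_jitter_cv > 0)
    pmax(stats::rnorm(nmax, 0, p$cycle_jitter_cv), -0.8) else numeric(nmax)

  mult <- rep(1, nmax)
  if (!is.null(p$bout_schedule) && nrow(p$bout_schedule)) {
    for (r in seq_len(nrow(p$bout_schedule))) {
      i0 <- p$bout_schedule$start_cycle[r]
      idx <- i0:(i0 + p$bout_schedule$n_cycles[r] - 1L)
      idx <- idx[idx <= nmax]
      mult[idx] <- p$bout_schedule$factor[r]
    }
  }

  sil <- p$silence_episodes
  n_sil <- if (is.null(sil)) 0L else nrow(sil)
  exch <- p$saline_exchange_times
  has_dec <- !is.null(p$decentralization_time)
  bfac <- if (length(exch)) p$saline_boost[["factor"]] - 1 else 0
  bdec <- if (length(exch)) p$saline_boost[["decay"]] else 1

  pd_start <- numeric(nmax); period <- numeric(nmax); ftarg <- numeric(nmax)
  t <- 0; k <- 0L
  while (t < duration && k < nmax) {
    if (n_sil) {
      for (s in seq_len(n_sil)) {
        s0 <- sil$start[s]; s1 <- s0 + sil$duration[s]
        if (t >= s0 && t < s1) {
          if (mult[k + 1L] != 1)
            stop(sprintf("bout scheduled at cycle %d overlaps silence episode [%g, %g] s",
                         k + 1L, s0, s1))
          t <- s1
        }
      }
      if (t >= duration) break
    }
    k <- k + 1L
    base <- if (has_dec && t >= p$decentralization_time) p$post_dec_freq else p$baseline_freq
    f <- base + drift[k]
    if (bfac > 0) {
      past <- exch[exch <= t]
      if (length(past)) f <- f + base * bfac * sum(exp(-(t - past) / bdec))
    }
    f <- max(f, 0.05) * mult[k]
    per <- (1 / f) * (1 + jit[k])
    pd_start[k] <- t; period[k] <- per; ftarg[k] <- f
    t <- t + per
  }
  n <- k
  pd_start <- pd_start[seq_len(n)]; period <- period[seq_len(n)]; ftarg <- ftarg[seq_len(n)]

  if (p$duration_mode == "phase") {
    pd_end <- pd_start + p$phase_targets[["pd_off"]] * period
    lp_start <- pd_start + p$phase_targets[["lp_on"]] * period
    lp_end <- pd_start + p$phase_targets[["lp_off"]] * period
  } else {
    fd <- p$fixed_durations
    pd_end <- pd_start + pmin(fd[["pd_off"]], 0.90 * period)
    lp_start <- pd_start + pmin(fd[["lp_on"]], 0.93 * period)
    lp_end <- pd_start + pmin(fd[["lp_off"]], 0.96 * period)
  }

  cycles <- data.frame(index = seq_len(n), pd_start = pd_start, pd_end = pd_end,
                       lp_start = lp_start, lp_end = lp_end,
                       period = period, freq_target = ftarg)
  bout_cycles <- which(mult[seq_len(n)] != 1)
  structure(list(cycles = cycles, bout_cycles = bout_cycles,
                 silence = sil, params = p, duration = duration),
            class = "pyloric_truth")
}

#' @export
print.pyloric_truth <- function(x, ...) {
  cat(sprintf("Synthetic pyloric ground truth: %d cycles over %.1f h (prep %s)\n",
              nrow(x$cycles), s_to_hours(x$duration), x$params$prep_id))
  cat(sprintf("  mean target frequency %.3f Hz; %d scheduled bout cycles; %d silence episodes\n",
              mean(x$cycles$freq_target), length(x$bout_cycles),
              if (is.null(x$silence)) 0L else nrow(x$silence)))
  invisible(x)
}

#' Render PD and LP spike trains from a ground-truth cycle series
#'
#' Spikes are evenly spaced within each burst interval with both endpoints
#' included, so the first/last spike of every burst reproduce the burst
#' start/end exactly and burst segmentation round-trips to machine precision.
#'
#' @param truth a `pyloric_truth` object from [generate_cycle_series()].
#' @param spikes_per_burst number of spikes per burst (>= 2).
#' @param absolute_refractory minimum admissible inter-spike interval,
#'   seconds; bursts too short to hold the requested spikes raise an error.
#' @return a `pyloric_spikes` data.frame with columns `prep_id`, `unit`
#'   (`"PD"`/`"LP"`), `time` (seconds), ordered by unit then time.
#' @export
render_spike_times <- function(truth, spikes_per_burst = 5L,
                               absolute_refractory = 0.001) {
  if (!inherits(truth, "pyloric_truth")) stop("`truth` must be a pyloric_truth object")
  m <- check_count(spikes_per_burst, "spikes_per_burst", lower = 2L)
  cy <- truth$cycles
  if (nrow(cy) == 0L) {
    out <- data.frame(prep_id = character(0), unit = character(0), time = numeric(0))
    return(structure(out, class = c("pyloric_spikes", "data.frame")))
  }
  spread <- function(start, end) {
    dur <- end - start
    if (any(dur < (m - 1) * absolute_refractory))
      stop(sprintf("burst shorter than (spikes_per_burst-1) x refractory = %g s",
                   (m - 1) * absolute_refractory))
    rep(start, each = m) + rep(seq(0, 1, length.out = m), times = length(start)) *
      rep(dur, each = m)
  }
  pd <- spread(cy$pd_start, cy$pd_end)
  lp <- spread(cy$lp_start, cy$lp_end)
  out <- data.frame(
    prep_id = truth$params$prep_id,
    unit = rep(c("PD", "LP"), times = c(length(pd), length(lp))),
    time = c(pd, lp))
  out <- out[order(out$unit, out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pyloric_spikes", "data.frame"))
}

# fixed biphasic extracellular spike template: positive peak of exactly +1
# at lag 0 followed by a shallower negative undershoot (peak-first, so
# left-to-right peak picking lands on the spike time); support
# [-2 sigma, +4 sigma]
spike_template <- function(sampling_rate, sigma = 0.001) {
  lag <- seq(-2 * sigma, 4 * sigma, by = 1 / sampling_rate)
  x <- 1 - lag / sigma
  v <- x * exp((1 - x^2) / 2)
  v[v < 0] <- 0.4 * v[v < 0]
  list(lag = lag, values = v)
}

#' Render a voltage-like extracellular trace from spike trains
#'
#' Emulates an extracellular nerve recording carrying both units: each spike
#' adds a fixed biphasic template (positive peak followed by a shallower
#' undershoot) scaled by the unit's amplitude, plus white Gaussian noise.
#' Overlapping spikes sum. The template peak (amplitude exactly the unit
#' amplitude) falls on the spike time, so peak detection recovers spike
#' times to sample resolution; a detection refractory of at least 2 ms
#' suppresses the undershoot.
#'
#' @param spikes a `pyloric_spikes` data.frame.
#' @param sampling_rate samples per second (>= 1000).
#' @param unit_amplitudes named numeric amplitude per unit, e.g.
#'   `c(PD = 0.4, LP = 1)`. For reliable amplitude sorting the amplitudes
#'   should differ by at least 4 x `noise_sd`.
#' @param noise_sd white-noise SD in amplitude units.
#' @param duration trace duration in seconds; defaults to last spike + 50 ms.
#' @param rng_seed integer seed for the noise (or `NULL`).
#' @return a `pyloric_trace` list: `values`, `sampling_rate`, `times`
#'   implied as `(seq_along(values) - 1) / sampling_rate`.
#' @export
render_trace <- function(spikes, sampling_rate = 10000,
                         unit_amplitudes = c(PD = 0.4, LP = 1),
                         noise_sd = 0.05, duration = NULL, rng_seed = NULL) {
  check_number(sampling_rate, "sampling_rate", lower = 1000)
  check_number(noise_sd, "noise_sd", lower = 0)
  tmax <- duration %||% (if (nrow(spikes)) max(spikes$time) + 0.05 else 1)
  nsamp <- ceiling(tmax * sampling_rate) + 1L
  tpl <- spike_template(sampling_rate)
  halfneg <- sum(tpl$lag < 0)  # samples before the peak
  vals <- numeric(nsamp + length(tpl$values))  # padded; trimmed below
  if (nrow(spikes)) {
    amp <- unit_amplitudes[spikes$unit]
    if (anyNA(amp)) stop("unit_amplitudes must name every unit present")
    centre <- round(spikes$time * sampling_rate) + 1L
    for (i in seq_len(nrow(spikes))) {
      idx <- centre[i] - halfneg + seq_along(tpl$values) - 1L
      keep <- idx >= 1L
      vals[idx[keep]] <- vals[idx[keep]] + amp[i] * tpl$values[keep]
    }
  }
  vals <- vals[seq_len(nsamp)]
  if (noise_sd > 0)
    vals <- vals + with_seed(rng_seed, stats::rnorm(nsamp, 0, noise_sd))
  structure(list(values = vals, sampling_rate = sampling_rate),
            class = "pyloric_trace")
}

#' @export
print.pyloric_trace <- function(x, ...) {
  cat(sprintf("Extracellular-style trace: %.1f s at %g Hz (%d samples)\n",
              length(x$values) / x$sampling_rate, x$sampling_rate, length(x$values)))
  invisible(x)
}
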