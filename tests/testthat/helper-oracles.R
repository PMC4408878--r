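# Independent brute-force oracles. These deliberately re-evaluate every
# definition from scratch (no cumulative sums, no vectorized shortcuts) so
# they stay independent of the implementation paths they check.

# bout rule: re-evaluate the trailing mean and the lookahead run at every
# index; merge consecutive firing indices into events
oracle_bouts <- function(f, lookback = 10L, lookahead = 3L,
                         rel_increase = 0.40, strict = FALSE) {
  n <- length(f)
  fires <- integer(0)
  if (n >= lookback + lookahead) {
    for (i in (lookback + 1L):(n - lookahead + 1L)) {
      bg <- mean(f[(i - lookback):(i - 1L)])
      ahead <- f[i:(i + lookahead - 1L)]
      hit <- if (strict) all(ahead > (1 + rel_increase) * bg)
      else all(ahead >= (1 + rel_increase) * bg)
      if (hit) fires <- c(fires, i)
    }
  }
  if (!length(fires))
    return(data.frame(detect_index = integer(0), extent_first = integer(0),
                      extent_last = integer(0)))
  events <- list()
  start <- fires[1L]; prev <- fires[1L]
  for (i in fires[-1L]) {
    if (i != prev + 1L) {
      events[[length(events) + 1L]] <- c(start, prev)
      start <- i
    }
    prev <- i
  }
  events[[length(events) + 1L]] <- c(start, prev)
  do.call(rbind, lapply(events, function(e)
    data.frame(detect_index = e[1], extent_first = e[1],
               extent_last = e[2] + lookahead - 1L)))
}

# burst rule: walk the train spike by spike, enumerating maximal runs
oracle_bursts <- function(times, max_isi, min_spikes = 2L) {
  runs <- list()
  cur <- c()
  for (t in times) {
    if (!length(cur) || t - cur[length(cur)] <= max_isi) cur <- c(cur, t)
    else { runs[[length(runs) + 1L]] <- cur; cur <- t }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  runs <- Filter(function(r) length(r) >= min_spikes, runs)
  if (!length(runs))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0)))
  do.call(rbind, lapply(runs, function(r)
    data.frame(start = r[1], end = r[length(r)], n_spikes = length(r))))
}

# exhaustive fastest-window search: every candidate start evaluated afresh
oracle_fastest_window <- function(times, freqs, dec, window_s, horizon_s,
                                  step_s, data_end, min_occupancy = 0.5) {
  last_start <- dec + min(horizon_s, data_end - dec) - window_s
  if (last_start < dec) return(NULL)
  best_start <- NA_real_; best_mean <- -Inf
  for (s in seq(dec, last_start, by = step_s)) {
    inw <- which(times >= s & times < s + window_s)
    if (!length(inw)) next
    sub_bins <- floor((times[inw] - s) / 360)
    occ <- length(unique(sub_bins)) / round(window_s / 360)
    if (occ < min_occupancy) next
    m <- sum(freqs[inw]) / length(inw)
    if (m > best_mean) { best_mean <- m; best_start <- s }
  }
  if (!is.finite(best_mean)) NULL else list(start = best_start, mean_freq = best_mean)
}

# split-plot sums of squares from cell and marginal means by explicit loops
oracle_split_plot_ss <- function(values, groups) {
  groups <- as.factor(groups)
  G <- nlevels(groups); Tn <- ncol(values); N <- nrow(values)
  grand <- mean(values)
  ss_group <- 0; ss_subj <- 0; ss_time <- 0; ss_inter <- 0; ss_resid <- 0
  time_mean <- numeric(Tn)
  for (t in 1:Tn) time_mean[t] <- mean(values[, t])
  for (g in levels(groups)) {
    rows <- which(groups == g)
    gmean <- mean(values[rows, , drop = FALSE])
    ss_group <- ss_group + length(rows) * Tn * (gmean - grand)^2
    for (i in rows) {
      smean <- mean(values[i, ])
      ss_subj <- ss_subj + Tn * (smean - gmean)^2
    }
    for (t in 1:Tn) {
      cmean <- mean(values[rows, t])
      ss_inter <- ss_inter + length(rows) * (cmean - gmean - time_mean[t] + grand)^2
      for (i in rows) {
        smean <- mean(values[i, ])
        ss_resid <- ss_resid +
          (values[i, t] - cmean - smean + gmean)^2
      }
    }
  }
  for (t in 1:Tn) ss_time <- ss_time + N * (time_mean[t] - grand)^2
  list(group = ss_group, subj_within = ss_subj, time = ss_time,
       interaction = ss_inter, resid = ss_resid)
}

# random frequency series with occasional elevated stretches, for bout tests
random_freq_series <- function(n, base = 1) {
  f <- base * exp(stats::rnorm(n, 0, 0.15))
  if (n >= 20 && stats::runif(1) < 0.6) {
    k <- sample(3:6, 1L)
    i0 <- sample(seq_len(n - k + 1L), 1L)
    f[i0:(i0 + k - 1L)] <- f[i0:(i0 + k - 1L)] * stats::runif(1, 1.2, 1.9)
  }
  f
}
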