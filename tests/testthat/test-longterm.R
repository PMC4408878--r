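const_cycles <- function(freq, duration, t0 = 0) {
  # noiseless cycle table at a constant frequency
  starts <- seq(t0, t0 + duration - 1 / freq, by = 1 / freq)
  n <- length(starts)
  structure(data.frame(index = seq_len(n), pd_start = starts,
                       pd_end = starts + 0.3 / freq,
                       lp_start = starts + 0.45 / freq,
                       lp_end = starts + 0.75 / freq,
                       period = 1 / freq, frequency = freq,
                       pd_off_phase = 0.3, lp_on_phase = 0.45,
                       lp_off_phase = 0.75, lp_silent = FALSE,
                       lp_extra = 0L, valid = TRUE,
                       invalid_reason = NA_character_),
            class = c("pyloric_cycles", "data.frame"))
}

test_that("bin_series produces per-bin statistics with NA for empty bins", {
  cy <- const_cycles(1, 3600)
  b <- bin_series(cy, bin_width = 0.1)
  expect_equal(nrow(b), 10L)
  expect_equal(b$value, rep(1, 10))
  expect_equal(sum(b$n), 3600L)

  # median robustness inside a bin
  cy2 <- const_cycles(1, 360)
  cy2$frequency <- rep(c(0.4, 0.6, 5.0), length.out = nrow(cy2))
  expect_equal(bin_series(cy2, bin_width = 0.1)$value, 0.6)

  # empty bins are NA, not zero
  cy3 <- rbind(const_cycles(1, 300), const_cycles(1, 300, t0 = 900))
  b3 <- bin_series(cy3, bin_width = 0.1, span = 1200)
  expect_equal(is.na(b3$value), c(FALSE, TRUE, FALSE, FALSE))

  # independent group-by recomputation on a random fixture
  set.seed(5)
  cy4 <- const_cycles(1, 1800)
  cy4$frequency <- stats::runif(nrow(cy4), 0.3, 2)
  b4 <- bin_series(cy4, bin_width = 0.1, statistic = "mean")
  want <- as.numeric(tapply(cy4$frequency,
                            floor(cy4$pd_start / 360), mean))
  expect_equal(b4$value, want)
})

test_that("box statistics follow the 1.5 IQR whisker rule", {
  b <- box_stats(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3); expect_equal(b$q1, 2); expect_equal(b$q3, 4)
  expect_equal(b$whisker_low, 1); expect_equal(b$whisker_high, 5)
  expect_length(b$outliers, 0L)

  be <- box_stats(rep(2.5, 8))
  expect_equal(be$q1, be$q3)
  expect_length(be$outliers, 0L)

  bo <- box_stats(c(1, 1, 1, 1, 10))
  expect_equal(bo$outliers, 10)
  expect_equal(bo$whisker_high, 1)

  hb <- hourly_boxstats(data.frame(hour = rep(1:2, each = 5),
                                   value = c(1:5, c(1, 1, 1, 1, 10))))
  expect_equal(hb$median, c(3, 1))
  expect_equal(hb$n_outliers, c(0L, 1L))
})

test_that("daily means are referenced to decentralization and flag empty days", {
  tl <- preparation_timeline("p", "decentralized", 0, 3600 + 2 * 86400,
                             decentralization_time = 3600)
  cy <- const_cycles(0.5, 3600 + 2 * 86400)
  d <- daily_mean(cy, tl)
  expect_equal(d$frequency, c(0.5, 0.5))
  expect_equal(d$pd_off_phase, c(0.3, 0.3))
  expect_true(all(d$complete))

  # a silent day yields no row data and is flagged
  cy2 <- cy[cy$pd_start < 3600 + 86400, ]
  d2 <- daily_mean(cy2, tl)
  expect_true(is.na(d2$frequency[2]))
  expect_false(d2$complete[2])

  # intact preparations use the matched post-baseline origin (start + 1 h)
  tli <- preparation_timeline("p", "intact", 0, 3600 + 86400)
  di <- daily_mean(const_cycles(1.2, 3600 + 86400), tli)
  expect_equal(nrow(di), 1L)
  expect_equal(di$frequency, 1.2)
})

test_that("snapshot_mean averages a window and handles empty windows", {
  cy <- const_cycles(0.8, 7200)
  expect_equal(snapshot_mean(cy, 5400, 300), 0.8)

  # noiseless step: snapshot after the step sees exactly the new value
  step <- rbind(const_cycles(1.2, 3600), const_cycles(0.5, 3600, t0 = 3600))
  expect_equal(snapshot_mean(step, 3600 + 1800, 300), 0.5)
  expect_equal(snapshot_mean(step, 1800, 300), 1.2)

  expect_message(out <- snapshot_mean(cy[0, ], 100, 50), "no valid cycles")
  expect_true(is.na(out))
})

test_that("fastest_window finds elevated plateaus and breaks ties early", {
  tl <- preparation_timeline("p", "decentralized", 0, 20 * 3600,
                             decentralization_time = 3600)
  # constant series: tie-break picks the window starting at decentralization
  cy <- const_cycles(0.5, 20 * 3600)
  w <- fastest_window(cy, tl, window = 2, horizon = 12)
  expect_equal(w$start, 3600)
  expect_equal(w$mean_freq, 0.5)

  # a 3 h elevated plateau: the chosen window lies inside it
  cy2 <- cy
  up <- cy2$pd_start >= 8 * 3600 & cy2$pd_start < 11 * 3600
  cy2$frequency[up] <- 0.9
  w2 <- fastest_window(cy2, tl, window = 2, horizon = 12)
  expect_gte(w2$start, 8 * 3600)
  expect_lte(w2$start + 2 * 3600, 11 * 3600 + 1)
  expect_equal(w2$mean_freq, 0.9)
  expect_equal(w2$cv, 0)
})

test_that("fastest_window matches the exhaustive oracle on random fixtures", {
  set.seed(55)
  for (i in 1:40) {
    dur <- 12 * 3600
    n <- 600
    times <- sort(stats::runif(n, 0, dur))
    times <- times[c(TRUE, diff(times) > 1e-3)]
    freqs <- stats::runif(length(times), 0.2, 1.5)
    cy <- const_cycles(1, 10)[rep(1, length(times)), ]
    cy$pd_start <- times; cy$frequency <- freqs
    tl <- preparation_timeline("p", "decentralized", 0, dur,
                               decentralization_time = 1800)
    got <- fastest_window(cy, tl, window = 2, horizon = 10)
    want <- oracle_fastest_window(times, freqs, 1800, 2 * 3600, 10 * 3600,
                                  360, dur)
    if (is.null(want)) expect_null(got)
    else {
      expect_equal(got$start, want$start)
      expect_equal(got$mean_freq, want$mean_freq)
    }
  }
})

test_that("variability measures match hand computation", {
  tl <- preparation_timeline("p", "decentralized", 0, 86400 + 3600,
                             decentralization_time = 3600)
  cy <- const_cycles(1, 86400 + 3600)
  expect_equal(within_prep_cv(cy, 1, tl), 0)

  cy$frequency <- rep(c(0.9, 1.1), length.out = nrow(cy))
  got <- within_prep_cv(cy, 1, tl)
  f <- cy$frequency[cy$pd_start >= 3600]
  expect_equal(got, stats::sd(f) / mean(f))

  expect_equal(across_prep_cv(c(0.5, 0.5, 0.5)), 0)
  expect_equal(across_prep_cv(c(0.4, 0.6)), stats::sd(c(0.4, 0.6)) / 0.5)
})

test_that("decentralized populations are relatively more variable than intact", {
  # frequency distributions 0.52 +/- 0.30 Hz vs 1.2 +/- 0.29 Hz imply a
  # higher across-preparation CV after decentralization
  cfg_d <- population_config(40, "decentralized", seed = 8L)
  cfg_i <- population_config(40, "intact", seed = 8L)
  post <- vapply(sample_population(cfg_d), `[[`, 0, "post_dec_freq")
  base <- vapply(sample_population(cfg_i), `[[`, 0, "baseline_freq")
  expect_gt(across_prep_cv(post), across_prep_cv(base))
})

test_that("silence detection recovers quiet stretches", {
  span <- c(0, 7200)
  expect_equal(detect_silence(numeric(0), span),
               data.frame(start = 0, end = 7200))
  # continuous 1 Hz rhythm: no silent windows
  expect_equal(nrow(detect_silence(seq(0, 7199), span)), 0L)

  # a generated 30 min silence episode is recovered within one window
  p <- prep_params(baseline_freq = 1, cycle_jitter_cv = 0.03,
                   silence_episodes = data.frame(start = 3000, duration = 1800))
  tr <- generate_cycle_series(p, 7200, rng_seed = 6)
  sil <- detect_silence(tr$cycles$pd_start, span)
  expect_equal(nrow(sil), 1L)
  expect_lt(abs(sil$start - 3000), 60 + 1e-9)
  expect_lt(abs(sil$end - 4800), 60 + 1e-9)
  # agreement: no cycles inside the reported silent interval
  expect_false(any(tr$cycles$pd_start >= sil$start &
                     tr$cycles$pd_start < sil$end))
})

test_that("saline exchanges raise the following hour's frequency", {
  # no change: pre equals post
  tl0 <- preparation_timeline("p", "decentralized", 0, 14400,
                              decentralization_time = 600,
                              saline_exchange_times = 7200)
  cy0 <- const_cycles(0.5, 14400)
  s0 <- saline_effect(cy0, tl0)
  expect_equal(s0$pre_mean, s0$post_mean)

  # boosted exchanges: post > pre in every seeded run, and the paired t
  # across preparations rejects
  seeds_hit <- vapply(1:8, function(s) {
    pre_post <- vapply(1:6, function(j) {
      p <- prep_params(baseline_freq = 0.5, decentralization_time = 600,
                       post_dec_freq = 0.5, cycle_jitter_cv = 0.03,
                       saline_exchange_times = 7200,
                       saline_boost = c(factor = 1.5, decay = 7200))
      tr <- generate_cycle_series(p, 12600, rng_seed = 1000 * s + j)
      cy <- tr$cycles
      cyc <- const_cycles(1, 10)[rep(1, nrow(cy)), ]
      cyc$pd_start <- cy$pd_start; cyc$frequency <- 1 / cy$period
      tl <- preparation_timeline("p", "decentralized", 0, 12600,
                                 decentralization_time = 600,
                                 saline_exchange_times = 7200)
      eff <- saline_effect(cyc, tl)
      c(eff$pre_mean, eff$post_mean)
    }, numeric(2))
    all(pre_post[2, ] > pre_post[1, ]) &&
      paired_t(pre_post[2, ], pre_post[1, ])$p < 0.05
  }, TRUE)
  expect_true(all(seeds_hit))

  # close exchanges get truncated windows, with a message
  tl2 <- preparation_timeline("p", "decentralized", 0, 14400,
                              decentralization_time = 600,
                              saline_exchange_times = c(7200, 9000))
  expect_message(saline_effect(cy0, tl2), "truncated")
})
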