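test_that("population sampling matches the configured distribution", {
  cfg <- population_config(30, "intact", seed = 11L)
  pars <- sample_population(cfg)
  base <- vapply(pars, `[[`, 0, "baseline_freq")
  se <- 0.29 / sqrt(30)
  expect_lt(abs(mean(base) - 1.2), 3 * se)
  expect_true(all(base > 0.05))

  # degenerate SD: every preparation at exactly the mean
  cfg0 <- population_config(5, "intact", intact_freq_sd = 0, seed = 1L)
  expect_equal(vapply(sample_population(cfg0), `[[`, 0, "baseline_freq"),
               rep(1.2, 5))

  # determinism: identical seed, identical parameter lists
  expect_identical(sample_population(cfg), sample_population(cfg))

  # truncation: heavy low tail still never produces <= 0.05 Hz
  cfgt <- population_config(200, "decentralized", decentralized_freq_mean = 0.1,
                            decentralized_freq_sd = 0.3, seed = 3L)
  post <- vapply(sample_population(cfgt), `[[`, 0, "post_dec_freq")
  expect_true(all(post > 0.05))
})

test_that("population config rejects invalid parameters", {
  expect_error(population_config(0, "intact"), "n_preparations")
  expect_error(population_config(3, "intact", intact_freq_mean = 0), "intact_freq_mean")
  expect_error(population_config(3, "intact", intact_freq_sd = -1), "intact_freq_sd")
})

test_that("noiseless generation is exact and deterministic", {
  p <- prep_params(baseline_freq = 1, cycle_jitter_cv = 0, drift_sd = 0)
  tr <- generate_cycle_series(p, 100, rng_seed = 1)
  expect_equal(nrow(tr$cycles), 100L)
  expect_equal(tr$cycles$period, rep(1, 100))
  expect_equal(tr$cycles$pd_start, 0:99)
  expect_equal(tr$cycles$pd_end - tr$cycles$pd_start, rep(0.30, 100))

  p2 <- prep_params(baseline_freq = 0.9)
  a <- generate_cycle_series(p2, 3600, rng_seed = 7)
  b <- generate_cycle_series(p2, 3600, rng_seed = 7)
  expect_identical(a, b)
})

test_that("decentralization step lowers frequency in every seeded run", {
  for (seed in 1:5) {
    p <- prep_params(baseline_freq = 1.2, decentralization_time = 3600,
                     post_dec_freq = 0.6)
    tr <- generate_cycle_series(p, 7200, rng_seed = seed)
    cy <- tr$cycles
    pre <- mean(1 / cy$period[cy$pd_start < 3600])
    post <- mean(1 / cy$period[cy$pd_start >= 3600])
    expect_lt(post, pre)
  }
})

test_that("emitted cycles conserve active duration", {
  p <- prep_params(baseline_freq = 1.1, cycle_jitter_cv = 0.05)
  tr <- generate_cycle_series(p, 5000, rng_seed = 5)
  cy <- tr$cycles
  active <- max(cy$pd_start + cy$period) - min(cy$pd_start)
  expect_lt(abs(nrow(cy) * mean(cy$period) - active) / active, 1e-9)
  # and the whole record is tiled: last cycle ends at/after the duration
  expect_gte(max(cy$pd_start + cy$period), 5000 * 0.999)
})

test_that("silence episodes suppress cycles and conflict with scheduled bouts", {
  sil <- data.frame(start = 100, duration = 50)
  p <- prep_params(baseline_freq = 1, cycle_jitter_cv = 0, drift_sd = 0,
                   silence_episodes = sil)
  tr <- generate_cycle_series(p, 300, rng_seed = 1)
  expect_false(any(tr$cycles$pd_start >= 100 & tr$cycles$pd_start < 150))
  # cycles resume right at the episode end
  expect_true(any(abs(tr$cycles$pd_start - 150) < 1e-9))

  pb <- prep_params(baseline_freq = 1, cycle_jitter_cv = 0, drift_sd = 0,
                    silence_episodes = sil,
                    bout_schedule = data.frame(start_cycle = 99, n_cycles = 5,
                                               factor = 1.5))
  expect_error(generate_cycle_series(pb, 300, rng_seed = 1), "silence")
})

test_that("bout schedule validation enforces the detectability floor", {
  expect_error(prep_params(bout_schedule = data.frame(start_cycle = 10,
                                                      n_cycles = 2, factor = 1.5)),
               "at least 3")
  expect_error(prep_params(bout_schedule = data.frame(start_cycle = 10,
                                                      n_cycles = 3, factor = 1.2)),
               ">= 1.4")
})

test_that("rendered spikes are evenly spaced and round-trip through segmentation", {
  p <- prep_params(baseline_freq = 1, cycle_jitter_cv = 0, drift_sd = 0)
  tr <- generate_cycle_series(p, 10, rng_seed = 1)
  sp <- render_spike_times(tr, 4)
  pd1 <- sp$time[sp$unit == "PD"][1:4]
  expect_equal(pd1, c(0, 0.1, 0.2, 0.3))

  # round-trip: burst boundaries recovered to machine precision
  tr2 <- generate_cycle_series(prep_params(baseline_freq = 1.3,
                                           cycle_jitter_cv = 0.05), 600,
                               rng_seed = 2)
  sp2 <- render_spike_times(tr2, 5)
  for (u in c("PD", "LP")) {
    b <- segment_bursts(sp2[sp2$unit == u, ], max_isi = 0.2)
    tru_start <- if (u == "PD") tr2$cycles$pd_start else tr2$cycles$lp_start
    tru_end <- if (u == "PD") tr2$cycles$pd_end else tr2$cycles$lp_end
    expect_equal(nrow(b), nrow(tr2$cycles))
    expect_equal(b$start, tru_start, tolerance = 1e-12)
    expect_equal(b$end, tru_end, tolerance = 1e-12)
  }

  # degenerate cases
  p0 <- prep_params(baseline_freq = 1, cycle_jitter_cv = 0, drift_sd = 0)
  t0 <- generate_cycle_series(p0, 0.5, rng_seed = 1)  # one cycle
  expect_error(render_spike_times(t0, 400), "refractory")
  empty <- t0; empty$cycles <- t0$cycles[0, ]
  expect_equal(nrow(render_spike_times(empty, 4)), 0L)
})

test_that("rendered traces have the declared peak and noise statistics", {
  sp <- structure(data.frame(prep_id = "p", unit = "PD", time = 0.05),
                  class = c("pyloric_spikes", "data.frame"))
  tr <- render_trace(sp, sampling_rate = 10000, unit_amplitudes = c(PD = 1),
                     noise_sd = 0, duration = 0.1)
  expect_equal(max(tr$values), 1, tolerance = 1e-6)
  expect_equal((which.max(tr$values) - 1) / 10000, 0.05, tolerance = 1e-4)

  none <- structure(data.frame(prep_id = character(0), unit = character(0),
                               time = numeric(0)),
                    class = c("pyloric_spikes", "data.frame"))
  tn <- render_trace(none, sampling_rate = 10000, noise_sd = 0.2,
                     duration = 10, rng_seed = 4)
  expect_lt(abs(stats::sd(tn$values) - 0.2) / 0.2, 0.05)

  t1 <- render_trace(sp, noise_sd = 0.05, duration = 0.1, rng_seed = 9)
  t2 <- render_trace(sp, noise_sd = 0.05, duration = 0.1, rng_seed = 9)
  expect_identical(t1$values, t2$values)
})
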