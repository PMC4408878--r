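# Config-driven entry points tying the stages together. A single YAML (or
# plain list) config with per-stage sections drives simulate -> analyze ->
# stats; every run echoes the effective configuration next to its outputs.

default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "pyloric_out",
    simulate = list(
      n_preparations = 5L,
      condition = "decentralized",
      duration_h = 4,
      intact_freq_mean = 1.2, intact_freq_sd = 0.29,
      decentralized_freq_mean = 0.52, decentralized_freq_sd = 0.30,
      decentralization_time = 3600,
      cycle_jitter_cv = 0.03,
      spikes_per_burst = 5L),
    analyze = list(
      max_isi = 0.3, min_spikes = 2L,
      min_freq = 0.02, max_freq = 5,
      bout_lookback = 10L, bout_lookahead = 3L, bout_rel_increase = 0.40,
      bin_width = 0.1),
    stats = list(
      snapshot_after_s = 1800, snapshot_halfwidth_s = 300,
      n_days = 6L,
      fastest_window_h = 5, fastest_horizon_h = 120))
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills unset keys from the defaults,
#' and rejects unknown keys.
#'
#' @param config path to a YAML file, a list, or `NULL` for pure defaults.
#' @return the merged configuration list.
#' @export
load_run_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else if (is.list(config)) config
  else stop("`config` must be a path, a list, or NULL")
  def <- default_run_config()
  merge_section <- function(d, u, path) {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop(sprintf("unknown config key(s): %s",
                   paste0(path, unknown, collapse = ", ")))
    for (k in names(u)) {
      d[[k]] <- if (is.list(d[[k]])) merge_section(d[[k]], u[[k]],
                                                   paste0(path, k, "."))
      else u[[k]]
    }
    d
  }
  merge_section(def, user, "")
}

echo_config <- function(cfg, outdir) {
  yaml::write_yaml(cfg, file.path(outdir, "config_used.yaml"))
}

#' Simulate a synthetic population and write its files
#'
#' Samples a population with [sample_population()], generates ground truth
#' and spike trains per preparation, and writes `spikes.tsv`,
#' `truth_cycles.tsv`, and `timelines.json` (plus a `config_used.yaml` echo)
#' into the output directory.
#'
#' @param config path to a YAML config, a list, or `NULL` for defaults; see
#'   [load_run_config()].
#' @param seed optional override of the config seed.
#' @param outdir optional override of the config output directory.
#' @return invisibly, a list with the written paths and the per-preparation
#'   simulations.
#' @export
run_simulate <- function(config = NULL, seed = NULL, outdir = NULL) {
  cfg <- load_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- cfg$simulate
  pop <- population_config(
    n_preparations = sc$n_preparations, condition = sc$condition,
    intact_freq_mean = sc$intact_freq_mean, intact_freq_sd = sc$intact_freq_sd,
    decentralized_freq_mean = sc$decentralized_freq_mean,
    decentralized_freq_sd = sc$decentralized_freq_sd,
    decentralization_time = sc$decentralization_time,
    seed = cfg$seed)
  params <- sample_population(pop, cycle_jitter_cv = sc$cycle_jitter_cv)
  duration <- hours_to_s(sc$duration_h)
  sims <- lapply(seq_along(params), function(i)
    simulate_preparation(params[[i]], duration, rng_seed = cfg$seed + i,
                         spikes_per_burst = sc$spikes_per_burst))
  spikes <- do.call(rbind, lapply(sims, `[[`, "spikes"))
  truth <- do.call(rbind, lapply(sims, function(s)
    cbind(prep_id = s$truth$params$prep_id, s$truth$cycles)))
  paths <- list(spikes = file.path(cfg$outdir, "spikes.tsv"),
                truth = file.path(cfg$outdir, "truth_cycles.tsv"),
                timelines = file.path(cfg$outdir, "timelines.json"))
  write_spike_tsv(spikes, paths$spikes)
  write_tsv(truth, paths$truth)
  write_timeline_json(lapply(sims, `[[`, "timeline"), paths$timelines)
  echo_config(cfg, cfg$outdir)
  invisible(list(paths = paths, sims = sims, config = cfg))
}

#' Analyze a simulated or recorded population from its files
#'
#' Reads `spikes.tsv` and `timelines.json` from the output directory (as
#' written by [run_simulate()] or by hand), runs [analyze_preparation()] per
#' preparation, and writes `bursts.tsv`, `cycles.tsv`, `bouts.tsv`, and
#' `summary.json`.
#'
#' @inheritParams run_simulate
#' @return invisibly, a list of `pyloric_analysis` objects plus the paths.
#' @export
run_analyze <- function(config = NULL, seed = NULL, outdir = NULL) {
  cfg <- load_run_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  ac <- cfg$analyze
  spikes <- read_spike_tsv(file.path(cfg$outdir, "spikes.tsv"))
  timelines <- read_timeline_json(file.path(cfg$outdir, "timelines.json"))
  if (inherits(timelines, "pyloric_timeline")) timelines <- list(timelines)
  bp <- bout_params(ac$bout_lookback, ac$bout_lookahead, ac$bout_rel_increase)
  analyses <- lapply(timelines, function(tl) {
    sp <- spikes[spikes$prep_id == tl$prep_id, , drop = FALSE]
    if (nrow(sp) == 0L)
      warning(sprintf("no spikes for preparation %s", tl$prep_id))
    analyze_preparation(sp, tl, max_isi = ac$max_isi,
                        min_spikes = ac$min_spikes, min_freq = ac$min_freq,
                        max_freq = ac$max_freq, bout = bp,
                        bin_width = ac$bin_width)
  })
  names(analyses) <- vapply(timelines, `[[`, "", "prep_id")
  paths <- list(bursts = file.path(cfg$outdir, "bursts.tsv"),
                cycles = file.path(cfg$outdir, "cycles.tsv"),
                bouts = file.path(cfg$outdir, "bouts.tsv"),
                summary = file.path(cfg$outdir, "summary.json"))
  write_burst_tsv(do.call(rbind, lapply(analyses, `[[`, "bursts")), paths$bursts)
  write_tsv(do.call(rbind, lapply(names(analyses), function(p)
    cbind(prep_id = p, analyses[[p]]$cycles))), paths$cycles)
  bouts_all <- do.call(rbind, lapply(names(analyses), function(p) {
    b <- analyses[[p]]$bouts
    data.frame(prep_id = rep(p, nrow(b)), detect_index = b$detect_index,
               detect_time_s = b$detect_time, extent_first = b$extent_first,
               extent_last = b$extent_last)
  }))
  write_tsv(bouts_all, paths$bouts)
  jsonlite::write_json(lapply(analyses, `[[`, "summary"), paths$summary,
                       auto_unbox = TRUE, digits = NA, null = "null")
  echo_config(cfg, cfg$outdir)
  invisible(list(analyses = analyses, paths = paths, config = cfg))
}

#' Run the comparison-statistics battery over an analyzed population
#'
#' From the per-preparation cycle tables and timelines, computes baseline
#' (pre-decentralization) means, the 30 min post-decentralization snapshot,
#' first-days daily means, and fastest-window summaries, then applies the
#' battery: paired t (baseline vs snapshot), Pearson correlation (baseline vs
#' snapshot), Mood's median test (fastest-window vs snapshot frequencies),
#' and, when both conditions are present with at least two preparations each,
#' the split-plot mixed ANOVA on daily mean frequency. Writes `stats.csv`
#' and `stats.json`.
#'
#' @inheritParams run_simulate
#' @param analyses optional result of [run_analyze()]; read from disk
#'   otherwise.
#' @return invisibly, the results data.frame (`test`, `n`, `statistic`,
#'   `df`, `p`).
#' @export
run_stats <- function(config = NULL, seed = NULL, outdir = NULL,
                      analyses = NULL) {
  cfg <- load_run_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  st <- cfg$stats
  if (is.null(analyses)) analyses <- run_analyze(cfg)$analyses
  tls <- lapply(analyses, `[[`, "timeline")
  dec <- vapply(tls, function(tl) !is.na(tl$decentralization_time), TRUE)

  baseline <- vapply(analyses, function(a) {
    tl <- a$timeline
    end <- if (is.na(tl$decentralization_time)) day_origin(tl)
    else tl$decentralization_time
    cy <- valid_cycles(a$cycles)
    mean(cy$frequency[cy$pd_start < end])
  }, 0)
  snap <- vapply(analyses, function(a) {
    tl <- a$timeline
    t0 <- (if (is.na(tl$decentralization_time)) day_origin(tl)
           else tl$decentralization_time) + st$snapshot_after_s
    suppressMessages(snapshot_mean(a$cycles, t0, st$snapshot_halfwidth_s))
  }, 0)

  rows <- list()
  add <- function(rows, s) c(rows, list(
    data.frame(test = s$test, n = paste(s$n, collapse = "/"),
               statistic = s$statistic, df = paste(signif(s$df, 6), collapse = "/"),
               p = s$p)))
  ok <- dec & is.finite(baseline) & is.finite(snap)
  if (sum(ok) >= 3L) {
    rows <- add(rows, paired_t(baseline[ok], snap[ok]))
    if (stats::var(baseline[ok]) > 0 && stats::var(snap[ok]) > 0)
      rows <- add(rows, pearson_corr(baseline[ok], snap[ok]))
  }
  fw <- lapply(analyses[dec], function(a) {
    tl <- a$timeline
    if (tl$recording_end - tl$decentralization_time <
        hours_to_s(st$fastest_window_h)) return(NULL)
    fastest_window(a$cycles, tl, window = st$fastest_window_h,
                   horizon = st$fastest_horizon_h)
  })
  fw_freq <- vapply(fw, function(w) if (is.null(w)) NA_real_ else w$mean_freq, 0)
  if (sum(is.finite(fw_freq)) >= 2L && sum(is.finite(snap[dec])) >= 2L)
    rows <- tryCatch(add(rows, moods_median(fw_freq[is.finite(fw_freq)],
                                            snap[dec][is.finite(snap[dec])])),
                     error = function(e) rows)
  if (length(unique(dec)) == 2L && min(table(dec)) >= 2L) {
    dm <- t(vapply(analyses, function(a)
      daily_mean(a$cycles, a$timeline, n_days = st$n_days)$frequency,
      numeric(st$n_days)))
    keep <- stats::complete.cases(dm)
    if (min(table(dec[keep])) >= 2L) {
      an <- mixed_anova(dm[keep, , drop = FALSE],
                        ifelse(dec[keep], "decentralized", "intact"))
      rows <- c(rows, list(data.frame(
        test = c("mixed ANOVA: condition", "mixed ANOVA: day",
                 "mixed ANOVA: condition x day"),
        n = paste(an$n_per_group, collapse = "/"),
        statistic = c(an$F_between, an$F_within, an$F_interaction),
        df = c(paste(an$table$df[1], an$table$df[2], sep = "/"),
               paste(an$table$df[3], an$table$df[5], sep = "/"),
               paste(an$table$df[4], an$table$df[5], sep = "/")),
        p = c(an$p_between, an$p_within, an$p_interaction))))
    }
  }
  res <- if (length(rows)) do.call(rbind, rows)
  else data.frame(test = character(0), n = character(0),
                  statistic = numeric(0), df = character(0), p = numeric(0))
  utils::write.csv(res, file.path(cfg$outdir, "stats.csv"), row.names = FALSE)
  jsonlite::write_json(res, file.path(cfg$outdir, "stats.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  echo_config(cfg, cfg$outdir)
  invisible(res)
}
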