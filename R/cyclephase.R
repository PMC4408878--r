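#' Build the per-cycle table of period, frequency and phases
#'
#' Cycle `i` spans from the start of PD burst `i` to the start of PD burst
#' `i+1` (onset-referenced period); frequency is its reciprocal. Phases are
#' latencies from PD burst start divided by the period: `pd_off_phase` is the
#' PD duty cycle, `lp_on_phase`/`lp_off_phase` the LP burst onset/offset
#' phases. The LP burst assigned to a cycle is the first LP burst starting in
#' `[pd_start, next_pd_start)`; cycles with none are flagged `lp_silent`, and
#' a second LP burst within one cycle is counted in `lp_extra` (the first is
#' used).
#'
#' Gaps: a putative period exceeding `gap_factor` times the trailing median
#' of up to the previous 10 accepted periods breaks the cycle chain -- the
#' row is retained but marked invalid with reason `"gap"`, so no cycle spans
#' a silence. The chain restarts after a break: the trailing median is
#' rebuilt from the cycles that follow, so a rhythm resuming at a much
#' slower pace (e.g. after decentralization or a pause) is picked up again
#' rather than rejected against the old tempo.
#'
#' @param pd_bursts,lp_bursts `pyloric_bursts` data.frames (ordered,
#'   non-overlapping per unit). Fewer than 2 PD bursts yield an empty table.
#' @param gap_factor chain-break multiple of the trailing median period.
#' @return a `pyloric_cycles` data.frame: `index`, `pd_start`, `pd_end`,
#'   `lp_start`, `lp_end`, `period`, `frequency`, `pd_off_phase`,
#'   `lp_on_phase`, `lp_off_phase`, `lp_silent`, `lp_extra`, `valid`,
#'   `invalid_reason`.
#' @examples
#' pd <- data.frame(prep_id = "p", unit = "PD",
#'                  start = c(0, 1), end = c(0.3, 1.3), n_spikes = 5L)
#' lp <- data.frame(prep_id = "p", unit = "LP",
#'                  start = 0.4, end = 0.7, n_spikes = 5L)
#' build_cycles(pd, lp)
#' @export
build_cycles <- function(pd_bursts, lp_bursts = NULL, gap_factor = 5) {
  check_number(gap_factor, "gap_factor", lower = 1)
  empty <- cycles_skeleton(0L)
  if (is.null(pd_bursts) || nrow(pd_bursts) < 2L)
    return(structure(empty, class = c("pyloric_cycles", "data.frame")))
  ps <- pd_bursts$start
  pe <- pd_bursts$end
  if (is.unsorted(ps, strictly = TRUE)) stop("PD bursts must be ordered by start")
  if (any(pe[-length(pe)] > ps[-1])) stop("PD bursts overlap")
  n <- length(ps) - 1L
  period <- diff(ps)
  out <- cycles_skeleton(n)
  out$pd_start <- ps[seq_len(n)]
  out$pd_end <- pe[seq_len(n)]
  out$period <- period
  out$frequency <- 1 / period

  # chain breaks: trailing median over up to the 10 previously accepted
  # periods. Fast path: a period can only break the chain if it exceeds
  # gap_factor x the rolling MIN of the previous 10 raw periods (the accepted
  # median can never fall below that min); when nothing passes that screen no
  # period is dropped, the accepted set equals the raw set, and the
  # sequential walk is skipped.
  if (any(period > gap_factor * roll_min_prev(period, 10L) &
            seq_len(n) > 3L)) {
    accepted <- rep(NA_real_, n)
    n_acc <- 0L
    for (i in seq_len(n)) {
      if (n_acc >= 3L &&
          period[i] > gap_factor *
            stats::median(accepted[max(1L, n_acc - 9L):n_acc])) {
        out$valid[i] <- FALSE
        out$invalid_reason[i] <- "gap"
        n_acc <- 0L  # the chain restarts after a break
      } else {
        n_acc <- n_acc + 1L
        accepted[n_acc] <- period[i]
      }
    }
  }

  if (!is.null(lp_bursts) && nrow(lp_bursts)) {
    ls <- lp_bursts$start
    if (is.unsorted(ls, strictly = TRUE)) stop("LP bursts must be ordered by start")
    cyc <- findInterval(ls, ps)           # half-open [pd_start, next_pd_start)
    inside <- cyc >= 1L & cyc <= n & ls >= ps[1]
    cyc <- cyc[inside]
    first <- !duplicated(cyc)
    out$lp_start[cyc[first]] <- ls[inside][first]
    out$lp_end[cyc[first]] <- lp_bursts$end[inside][first]
    extras <- table(cyc[!first])
    if (length(extras))
      out$lp_extra[as.integer(names(extras))] <- as.integer(extras)
  }
  out$lp_silent <- is.na(out$lp_start)
  out$pd_off_phase <- (out$pd_end - out$pd_start) / out$period
  out$lp_on_phase <- (out$lp_start - out$pd_start) / out$period
  out$lp_off_phase <- (out$lp_end - out$pd_start) / out$period
  structure(out, class = c("pyloric_cycles", "data.frame"))
}

cycles_skeleton <- function(n) {
  data.frame(index = seq_len(n),
             pd_start = numeric(n), pd_end = numeric(n),
             lp_start = rep(NA_real_, n), lp_end = rep(NA_real_, n),
             period = numeric(n), frequency = numeric(n),
             pd_off_phase = numeric(n),
             lp_on_phase = rep(NA_real_, n), lp_off_phase = rep(NA_real_, n),
             lp_silent = logical(n), lp_extra = integer(n),
             valid = rep(TRUE, n), invalid_reason = rep(NA_character_, n))
}

#' Flag cycles outside a plausible frequency range as invalid
#'
#' Cycles with frequency outside `[min_freq, max_freq]`, or whose LP burst
#' ends at or after the next PD start (`lp_off_phase >= 1`), are marked
#' invalid with a recorded reason. Nothing is deleted; downstream aggregate
#' statistics use `valid` cycles only.
#'
#' @param cycles a `pyloric_cycles` data.frame.
#' @param min_freq,max_freq admissible frequency range, Hz
#'   (`0 < min_freq < max_freq`).
#' @return the same table with `valid`/`invalid_reason` updated.
#' @export
filter_cycles <- function(cycles, min_freq = 0.02, max_freq = 5) {
  check_number(min_freq, "min_freq", lower = .Machine$double.eps)
  check_number(max_freq, "max_freq", lower = min_freq + .Machine$double.eps)
  bad_f <- cycles$frequency < min_freq | cycles$frequency > max_freq
  bad_lp <- !is.na(cycles$lp_off_phase) & cycles$lp_off_phase >= 1
  cycles$invalid_reason[bad_lp & cycles$valid] <- "lp_overrun"
  cycles$invalid_reason[bad_f & cycles$valid] <- "freq_range"
  cycles$valid <- cycles$valid & !bad_f & !bad_lp
  cycles
}

#' Linear regression of a phase on cycle frequency
#'
#' Ordinary least squares of phase on frequency, with Pearson R and its
#' two-sided p value (see [pearson_corr()]). Used per preparation or on
#' per-preparation mean points, as in phase-constancy analyses.
#'
#' @param data a `pyloric_cycles` table (valid, LP-active rows are used for
#'   LP phases) or any data.frame with a `frequency` column and the phase
#'   column.
#' @param phase one of `"pd_off_phase"`, `"lp_on_phase"`, `"lp_off_phase"`,
#'   or any column name present in `data`.
#' @return a list of class `pyloric_phasefit`: `slope`, `intercept`, `r`,
#'   `p`, `n`, `phase`.
#' @export
phase_frequency_regression <- function(data,
                                       phase = c("pd_off_phase", "lp_on_phase",
                                                 "lp_off_phase")) {
  phase <- if (is.character(phase) && length(phase) == 1L && phase %in% names(data))
    phase else match.arg(phase)
  x <- data$frequency
  y <- data[[phase]]
  if ("valid" %in% names(data)) { keep <- data$valid; x <- x[keep]; y <- y[keep] }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 finite points for a regression")
  if (stats::var(x) == 0) stop("zero variance in frequency: slope undefined")
  if (stats::var(y) == 0) {
    # constant phase: flat line, no association
    slope <- 0; r <- 0; p <- 1
  } else {
    corr <- pearson_corr(x, y)
    r <- corr$statistic; p <- corr$p
    slope <- r * stats::sd(y) / stats::sd(x)
  }
  structure(list(slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 r = r, p = p, n = length(x), phase = phase),
            class = "pyloric_phasefit")
}

#' @export
print.pyloric_phasefit <- function(x, ...) {
  cat(sprintf("%s ~ frequency: slope %.4f, intercept %.4f (R = %.3f, p = %.3g, n = %d)\n",
              x$phase, x$slope, x$intercept, x$r, x$p, x$n))
  invisible(x)
}
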