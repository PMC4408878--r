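# Readers and writers for the on-disk exchange formats: tab-separated tables
# with a header line, UTF-8, '.' decimal; JSON for event metadata.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, col_classes) {
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = col_classes,
                    fileEncoding = "UTF-8")
}

#' Write / read spike-time tables
#'
#' Columns: `prep_id`, `unit` (PD or LP), `time_s`.
#'
#' @param spikes a `pyloric_spikes` data.frame (`prep_id`, `unit`, `time`).
#' @param path file path.
#' @return `write_spike_tsv` returns the path invisibly; `read_spike_tsv`
#'   returns a `pyloric_spikes` data.frame.
#' @export
write_spike_tsv <- function(spikes, path) {
  write_tsv(data.frame(prep_id = spikes$prep_id, unit = spikes$unit,
                       time_s = spikes$time), path)
}

#' @rdname write_spike_tsv
#' @export
read_spike_tsv <- function(path) {
  df <- read_tsv(path, c(prep_id = "character", unit = "character",
                         time_s = "numeric"))
  out <- data.frame(prep_id = df$prep_id, unit = df$unit, time = df$time_s)
  out <- out[order(out$prep_id, out$unit, out$time), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pyloric_spikes", "data.frame"))
}

#' Write / read burst tables
#'
#' Columns: `prep_id`, `unit`, `start_s`, `end_s`, `n_spikes`.
#'
#' @param bursts a `pyloric_bursts` data.frame.
#' @param path file path.
#' @export
write_burst_tsv <- function(bursts, path) {
  write_tsv(data.frame(prep_id = bursts$prep_id, unit = bursts$unit,
                       start_s = bursts$start, end_s = bursts$end,
                       n_spikes = bursts$n_spikes), path)
}

#' @rdname write_burst_tsv
#' @export
read_burst_tsv <- function(path) {
  df <- read_tsv(path, c(prep_id = "character", unit = "character",
                         start_s = "numeric", end_s = "numeric",
                         n_spikes = "integer"))
  out <- data.frame(prep_id = df$prep_id, unit = df$unit, start = df$start_s,
                    end = df$end_s, n_spikes = df$n_spikes)
  structure(out, class = c("pyloric_bursts", "data.frame"))
}

#' Write / read per-cycle tables
#'
#' One row per cycle with the full `pyloric_cycles` column set.
#'
#' @param cycles a `pyloric_cycles` data.frame.
#' @param path file path.
#' @export
write_cycle_tsv <- function(cycles, path) write_tsv(cycles, path)

#' @rdname write_cycle_tsv
#' @export
read_cycle_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          fileEncoding = "UTF-8")
  df$invalid_reason <- as.character(df$invalid_reason)
  structure(df, class = c("pyloric_cycles", "data.frame"))
}

#' Write bout-event tables
#'
#' Columns: `prep_id`, `detect_index`, `detect_time_s`, `extent_first`,
#' `extent_last`.
#'
#' @param bouts a `pyloric_bouts_detected` data.frame.
#' @param prep_id preparation id column value.
#' @param path file path.
#' @export
write_bout_tsv <- function(bouts, prep_id, path) {
  write_tsv(data.frame(prep_id = if (nrow(bouts)) prep_id else character(0),
                       detect_index = bouts$detect_index,
                       detect_time_s = bouts$detect_time,
                       extent_first = bouts$extent_first,
                       extent_last = bouts$extent_last), path)
}

#' Write / read preparation timelines as JSON
#'
#' @param timeline a [preparation_timeline()] object (or a list of them).
#' @param path file path.
#' @export
write_timeline_json <- function(timeline, path) {
  tl <- if (inherits(timeline, "pyloric_timeline")) list(timeline) else timeline
  payload <- lapply(tl, function(x) {
    list(prep_id = x$prep_id, condition = x$condition,
         recording_start = x$recording_start, recording_end = x$recording_end,
         decentralization_time = if (is.na(x$decentralization_time)) NULL
           else x$decentralization_time,
         saline_exchange_times = I(x$saline_exchange_times))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_timeline_json
#' @export
read_timeline_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(payload, function(x) {
    preparation_timeline(
      prep_id = x$prep_id, condition = x$condition,
      recording_start = x$recording_start, recording_end = x$recording_end,
      decentralization_time = x$decentralization_time %||% NA_real_,
      saline_exchange_times = unlist(x$saline_exchange_times) %||% numeric(0))
  })
  if (length(out) == 1L) out[[1L]] else out
}
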