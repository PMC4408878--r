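# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar checks -------------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (allow_na && (is.null(x) || length(x) == 0L || all(is.na(x)))) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < lower)
    stop(sprintf("`%s` must be an integer >= %s", name, lower), call. = FALSE)
  invisible(as.integer(x))
}

# hours <-> seconds; all public time arguments state their unit explicitly
hours_to_s <- function(h) h * 3600
s_to_hours <- function(s) s / 3600

`%||%` <- function(a, b) if (is.null(a)) b else a

# rolling minimum over the up-to-w elements strictly before each position
# (Inf where none exist); vectorized as pmin over lagged copies
roll_min_prev <- function(x, w) {
  n <- length(x)
  out <- rep(Inf, n)
  for (k in seq_len(min(w, n - 1L)))
    out <- pmin(out, c(rep(Inf, k), x[seq_len(n - k)]))
  out
}
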