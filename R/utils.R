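# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "reverb_invalid_config")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed for a named stage from a master seed, so that every
# stochastic stage of a pipeline consumes an independent, reproducible stream.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 99991L)) %% 2147483197L
}

# Largest-remainder apportionment of `n` into counts proportional to `p`.
# Guarantees sum(out) == n and |out/n - p| minimal, so configured category
# fractions are honoured exactly.
round_largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0))
  if (sum(p) == 0) return(rep(0L, length(p)))
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Validate a spikes tibble (columns unit_id, time) and return it normalised:
# unit_id as character, times sorted within unit.
check_spikes <- function(spikes, arg = "spikes") {
  if (!is.data.frame(spikes) || !all(c("unit_id", "time") %in% names(spikes))) {
    abort(sprintf("`%s` must be a data frame with columns `unit_id` and `time`.", arg),
          class = "reverb_bad_input")
  }
  out <- as_tibble(spikes)
  out$unit_id <- as.character(out$unit_id)
  if (any(!is.finite(out$time)) || any(out$time < 0)) {
    abort(sprintf("`%s` contains negative or non-finite spike times.", arg),
          class = "reverb_bad_input")
  }
  dplyr::arrange(out, .data$unit_id, .data$time)
}

check_schedule <- function(events, arg = "events") {
  if (!is.data.frame(events) || !all(c("event", "onset") %in% names(events))) {
    abort(sprintf("`%s` must be a data frame with at least columns `event` and `onset`.", arg),
          class = "reverb_bad_input")
  }
  out <- as_tibble(events)
  if (!"level" %in% names(out)) out$level <- 1L
  if (!"session" %in% names(out)) out$session <- 1L
  out
}

# Half-open interval membership [start, end)
in_window <- function(x, start, end) x >= start & x < end

# Count spikes of one sorted vector in many half-open windows.
count_in_windows <- function(times, start, end) {
  findInterval(end, times, left.open = TRUE) - findInterval(start, times, left.open = TRUE)
}

recording_span <- function(spikes, events = NULL) {
  hi <- max(spikes$time, if (!is.null(events)) max(events$onset) + 3 else 0, 0)
  sp <- attr(spikes, "span")
  if (!is.null(sp)) hi <- max(hi, sp[2])
  if (!is.null(events) && !is.null(attr(events, "span"))) hi <- max(hi, attr(events, "span")[2])
  c(0, hi)
}
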