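#' Build a randomized event schedule
#'
#' Lays out one session per (event type, intensity level), each containing
#' `n_repetitions` events separated by uniformly randomized inter-trial
#' intervals. Sessions are concatenated on a single timeline with a quiet
#' baseline span before the first event and a quiet tail after the last one.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A tibble of class `"event_schedule"` with columns `event`, `level`,
#'   `intensity` (physical label where defined), `onset` (s), `session`, and a
#'   `"span"` attribute giving the recording interval.
#' @export
#' @examples
#' sched <- build_schedule(simulation_config(), seed = 1)
#' dplyr::count(sched, event, level)
build_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  with_seed(seed, {
    sessions <- purrr::imap(config$event_types, function(levels, type) {
      purrr::map(levels, function(lv) list(event = type, level = as.integer(lv)))
    })
    sessions <- purrr::flatten(sessions)
    t0 <- config$baseline_s
    rows <- vector("list", length(sessions))
    for (k in seq_along(sessions)) {
      s <- sessions[[k]]
      gaps <- runif(config$n_repetitions, config$iti_s[1], config$iti_s[2])
      onsets <- t0 + cumsum(gaps) - gaps[1]
      meta <- config$level_meta[[s$event]]
      rows[[k]] <- tibble(
        event = s$event, level = s$level,
        intensity = if (!is.null(meta)) meta[s$level] else NA_character_,
        onset = onsets, session = k
      )
      # next session starts after a full inter-session pause
      t0 <- max(onsets) + runif(1, config$iti_s[1], config$iti_s[2])
    }
    out <- bind_rows(rows)
    attr(out, "span") <- c(0, max(out$onset) + config$event_window_s + config$tail_s)
    attr(out, "event_window_s") <- config$event_window_s
    class(out) <- c("event_schedule", class(out))
    out
  })
}

#' @export
print.event_schedule <- function(x, ...) {
  sp <- attr(x, "span")
  cat(sprintf("<event_schedule> %d events, %d sessions, span %.0f-%.0f s\n",
              nrow(x), dplyr::n_distinct(x$session), sp[1], sp[2]))
  NextMethod()
}

# Half-open event windows [onset, onset + width) as a tibble.
event_windows <- function(events, width = NULL, offset = 0) {
  width <- width %||% attr(events, "event_window_s") %||% 1
  tibble(start = events$onset + offset, end = events$onset + offset + width)
}

# Times eligible as baseline: the recording span minus [onset, onset+exclude_s)
# around every event. Returns a tibble of free intervals.
baseline_intervals <- function(events, span = NULL, exclude_before = 1, exclude_after = 3) {
  span <- span %||% attr(events, "span")
  if (is.null(span)) span <- c(0, max(events$onset) + exclude_after)
  excl <- tibble(start = pmax(events$onset - exclude_before, span[1]),
                 end = pmin(events$onset + exclude_after, span[2]))
  excl <- dplyr::arrange(excl, .data$start)
  free <- list()
  cur <- span[1]
  for (i in seq_len(nrow(excl))) {
    if (excl$start[i] > cur) free[[length(free) + 1]] <- c(cur, excl$start[i])
    cur <- max(cur, excl$end[i])
  }
  if (cur < span[2]) free[[length(free) + 1]] <- c(cur, span[2])
  if (!length(free)) return(tibble(start = numeric(), end = numeric()))
  tibble(start = vapply(free, `[`, 0, 1), end = vapply(free, `[`, 0, 2))
}

# Draw n window start times of length `width` uniformly from free intervals.
sample_baseline_windows <- function(free, n, width) {
  free <- dplyr::filter(free, .data$end - .data$start >= width)
  if (!nrow(free)) abort("No eligible baseline time available.", class = "reverb_no_baseline")
  len <- free$end - free$start - width
  w <- len + 1e-9
  idx <- sample.int(nrow(free), n, replace = TRUE, prob = w)
  start <- free$start[idx] + runif(n) * len[idx]
  tibble(start = start, end = start + width)
}
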