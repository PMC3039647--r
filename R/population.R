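#' Generate a synthetic spike-train population with ground truth
#'
#' Simulates a piecewise-constant inhomogeneous-Poisson population around an
#' event schedule. Each unit has a constant baseline rate (uniform within its
#' putative pyramidal or interneuron range). Responsive units elevate (or, for
#' sensitive-down units, suppress) their rate in the 1-s window after events of
#' the types they are selective for: intensity-sensitive units with a gain
#' strictly monotone in intensity level, intensity-invariant units with the
#' same gain at every level. A shared per-trial log-normal gain jitter within
#' each selectivity group induces the within-group event-period correlations
#' the correlation analyses probe.
#'
#' @param config A [simulation_config()].
#' @param schedule An event schedule from [build_schedule()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list of class `"spike_population"` with elements `spikes`
#'   (tibble `unit_id`, `time`), `truth` (per-unit ground-truth tibble),
#'   `schedule`, and `config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_units = 30)
#' pop <- generate_population(cfg, build_schedule(cfg, seed = 1), seed = 2)
#' dplyr::count(pop$truth, intensity_class)
generate_population <- function(config, schedule, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  schedule <- check_schedule(schedule)
  if (config$n_units == 0) abort("`n_units` must be positive.", class = "reverb_invalid_config")

  with_seed(seed, {
    truth <- assign_ground_truth(config)
    span <- attr(schedule, "span") %||% c(0, max(schedule$onset) + 3)
    groups <- c("general", "subgeneral", "specific")
    types <- unique(schedule$event)

    # shared per-(event instance, selectivity group) gain multiplier
    jit <- matrix(nrow = nrow(schedule), ncol = length(groups),
                  dimnames = list(NULL, groups))
    for (g in groups) {
      s <- config$trial_coupling[[g]]
      jit[, g] <- rlnorm(nrow(schedule), meanlog = -s^2 / 2, sdlog = s)
    }

    spikes <- vector("list", config$n_units)
    for (u in seq_len(config$n_units)) {
      tu <- truth[u, ]
      segs <- unit_rate_segments(tu, schedule, config, jit, span)
      spikes[[u]] <- tibble(unit_id = tu$unit_id,
                            time = sample_poisson_segments(segs))
    }
    out <- list(spikes = dplyr::arrange(bind_rows(spikes), .data$unit_id, .data$time),
                truth = truth, schedule = schedule, config = config)
    attr(out$spikes, "span") <- span
    class(out) <- "spike_population"
    out
  })
}

# Category assignment with largest-remainder rounding so configured fractions
# are matched exactly.
assign_ground_truth <- function(config) {
  n <- config$n_units
  ids <- sprintf("u%03d", seq_len(n))
  n_resp <- round_largest_remainder(n, c(config$p_responsive, 1 - config$p_responsive))[1]
  n_ic <- round_largest_remainder(n_resp, c(config$p_invariant, 1 - config$p_invariant))
  n_inv <- n_ic[1]; n_sen <- n_ic[2]
  inv_counts <- round_largest_remainder(n_inv, config$invariant_split)
  sen_counts <- round_largest_remainder(n_sen, config$sensitive_split)
  n_down <- round_largest_remainder(n_sen, c(config$p_sensitive_down, 1 - config$p_sensitive_down))[1]

  groups <- c("general", "subgeneral", "specific")
  sel <- c(rep(groups, inv_counts), rep(groups, sen_counts))
  icl <- c(rep("invariant", n_inv), rep("sensitive", n_sen))
  dir <- rep("up", n_resp)
  if (n_down > 0) dir[n_inv + seq_len(n_down)] <- "down"

  types <- names(config$event_types)
  pick <- function(n) types[sample.int(length(types), n)]
  resp_types <- purrr::map(seq_len(n_resp), function(i) {
    switch(sel[i],
           general = types,
           subgeneral = sort(pick(min(sample(2:3, 1), length(types)))),
           specific = pick(1))
  })

  n_pyr <- round_largest_remainder(n, c(config$p_pyramidal, 1 - config$p_pyramidal))[1]
  unit_class <- sample(c(rep("pyramidal", n_pyr), rep("interneuron", n - n_pyr)))
  baseline <- ifelse(unit_class == "pyramidal",
                     runif(n, config$baseline_pyramidal[1], config$baseline_pyramidal[2]),
                     runif(n, config$baseline_interneuron[1], config$baseline_interneuron[2]))

  responsive <- c(rep(TRUE, n_resp), rep(FALSE, n - n_resp))
  # shuffle unit order so categories are not blocked by id
  ord <- sample.int(n)
  tibble(
    unit_id = ids,
    responsive = responsive[ord],
    selectivity_group = c(sel, rep("none", n - n_resp))[ord],
    resp_types = c(resp_types, rep(list(character()), n - n_resp))[ord],
    intensity_class = c(ifelse(icl == "invariant", "invariant",
                               paste0("sensitive-", dir)),
                        rep("none", n - n_resp))[ord],
    unit_class = unit_class,
    baseline_hz = baseline
  ) |>
    mutate(selectivity = selectivity_label(.data$selectivity_group, .data$resp_types))
}

selectivity_label <- function(group, resp_types) {
  purrr::map2_chr(group, resp_types, function(g, tt) {
    switch(g,
           none = "none",
           general = "general",
           subgeneral = paste0("subgeneral:", paste(sort(tt), collapse = "+")),
           specific = paste0("specific:", tt))
  })
}

# Event-window gain (Hz above baseline; may be negative for down units) for
# one unit at one event instance.
unit_event_gain <- function(tu, event, level, config) {
  if (!tu$responsive || !(event %in% tu$resp_types[[1]])) return(0)
  lv <- if (length(config$event_types[[event]]) > 1) level else 2L
  switch(tu$intensity_class,
         invariant = config$gain_invariant_hz,
         `sensitive-up` = config$gain_sensitive_hz[lv],
         `sensitive-down` = -(1 - config$down_multiplier[lv]) * tu$baseline_hz,
         0)
}

# Piecewise-constant rate profile of one unit: baseline plus event windows.
unit_rate_segments <- function(tu, schedule, config, jit, span) {
  b <- tu$baseline_hz
  segs <- tibble(start = span[1], end = span[2], rate = b)
  if (!tu$responsive) return(segs)
  w <- config$event_window_s
  idx <- which(schedule$event %in% tu$resp_types[[1]])
  if (!length(idx)) return(segs)
  gains <- vapply(idx, function(i) {
    unit_event_gain(tu, schedule$event[i], schedule$level[i], config) *
      jit[i, tu$selectivity_group]
  }, numeric(1))
  ev <- tibble(start = schedule$onset[idx], end = schedule$onset[idx] + w,
               rate = pmax(b + gains, 0))
  # carve event windows out of the baseline segment
  pieces <- list()
  cur <- span[1]
  ord <- order(ev$start)
  for (k in ord) {
    if (ev$start[k] > cur) pieces[[length(pieces) + 1]] <- c(cur, ev$start[k], b)
    pieces[[length(pieces) + 1]] <- c(ev$start[k], ev$end[k], ev$rate[k])
    cur <- ev$end[k]
  }
  if (cur < span[2]) pieces[[length(pieces) + 1]] <- c(cur, span[2], b)
  m <- do.call(rbind, pieces)
  tibble(start = m[, 1], end = m[, 2], rate = m[, 3])
}

# Homogeneous Poisson sampling per constant-rate segment.
sample_poisson_segments <- function(segs) {
  len <- segs$end - segs$start
  keep <- len > 0 & segs$rate > 0
  if (!any(keep)) return(numeric())
  n <- rpois(sum(keep), segs$rate[keep] * len[keep])
  t <- rep(segs$start[keep], n) + runif(sum(n)) * rep(len[keep], n)
  sort(t)
}

#' @export
print.spike_population <- function(x, ...) {
  cat(sprintf("<spike_population> %d units, %d spikes, %d events\n",
              nrow(x$truth), nrow(x$spikes), nrow(x$schedule)))
  invisible(x)
}

#' Inject reduced-amplitude pattern reactivations into a population
#'
#' Adds spontaneous post-event re-expressions of the event response pattern:
#' for each scheduled event, 1--3 reactivation times are drawn uniformly
#' within a window after the event, and during each 1-s reactivation the
#' responsive units re-express their event gain scaled by
#' `config$react_amplitude`. Participation follows the ground-truth structure
#' the analyses test for: intensity-invariant units participate with a shared
#' Bernoulli gate per (injection, selectivity group) whose probability and
#' amplitude weight are ordered general > subgeneral > specific;
#' intensity-sensitive units participate only with a small per-unit
#' probability.
#'
#' @param population A `"spike_population"` from [generate_population()].
#' @param seed Integer seed.
#' @param times Optional explicit injection times (s). Each is matched with a
#'   preceding event of the schedule (the nearest earlier event). Times outside
#'   the recording span are an error.
#' @return The population with extra spikes merged in and an `injections`
#'   element: a tibble with `time`, `event`, `level`, `source_event` plus the
#'   per-group gate draws.
#' @export
inject_reactivations <- function(population, seed = NULL, times = NULL) {
  stopifnot(inherits(population, "spike_population"))
  config <- population$config
  schedule <- population$schedule
  truth <- population$truth
  span <- attr(population$spikes, "span") %||% recording_span(population$spikes, schedule)
  if (config$react_amplitude < 0 || config$react_amplitude > 1) {
    abort("Reactivation amplitude must lie in [0, 1].", class = "reverb_invalid_config")
  }

  with_seed(seed, {
    dur <- config$react_duration_s
    if (is.null(times)) {
      inj <- purrr::map(seq_len(nrow(schedule)), function(i) {
        k <- sample(seq(config$react_per_event[1], config$react_per_event[2]), 1)
        t <- draw_injection_times(k, schedule$onset[i], schedule, config, span)
        if (!length(t)) return(NULL)
        tibble(time = t, event = schedule$event[i], level = schedule$level[i],
               source_event = i)
      })
      inj <- bind_rows(inj)
    } else {
      if (any(times < span[1] | times + dur > span[2])) {
        abort("Injection time outside the recording span.", class = "reverb_range_error")
      }
      src <- vapply(times, function(t) {
        prior <- which(schedule$onset < t)
        if (!length(prior)) abort("Injection time precedes all events.",
                                  class = "reverb_range_error")
        prior[which.max(schedule$onset[prior])]
      }, integer(1))
      inj <- tibble(time = times, event = schedule$event[src],
                    level = schedule$level[src], source_event = src)
    }
    if (!nrow(inj)) {
      population$injections <- inj
      return(population)
    }
    inj <- dplyr::arrange(inj, .data$time)

    groups <- c("general", "subgeneral", "specific")
    gates <- matrix(rbinom(nrow(inj) * 3, 1, rep(config$react_gate_prob[groups],
                                                 each = nrow(inj))),
                    ncol = 3, dimnames = list(NULL, groups))

    resp <- dplyr::filter(truth, .data$responsive)
    extra <- vector("list", nrow(inj))
    for (j in seq_len(nrow(inj))) {
      ev <- inj$event[j]; lv <- inj$level[j]
      sel <- vapply(resp$resp_types, function(tt) ev %in% tt, logical(1))
      cand <- resp[sel, ]
      if (!nrow(cand)) next
      part_rate <- vapply(seq_len(nrow(cand)), function(r) {
        tu <- cand[r, ]
        g <- tu$selectivity_group
        if (tu$intensity_class == "invariant") {
          if (gates[j, g] == 0) return(0)
          config$react_amplitude * config$react_weight[[g]] * config$gain_invariant_hz
        } else if (tu$intensity_class == "sensitive-up") {
          if (runif(1) > config$react_sensitive_prob) return(0)
          config$react_amplitude * config$gain_sensitive_hz[
            if (length(config$event_types[[ev]]) > 1) lv else 2L]
        } else 0
      }, numeric(1))
      on <- part_rate > 0
      if (!any(on)) next
      n_sp <- rpois(sum(on), part_rate[on] * dur)
      extra[[j]] <- tibble(
        unit_id = rep(cand$unit_id[on], n_sp),
        time = inj$time[j] + runif(sum(n_sp)) * dur
      )
    }
    new_spikes <- bind_rows(population$spikes, bind_rows(extra))
    new_spikes <- dplyr::arrange(new_spikes, .data$unit_id, .data$time)
    attr(new_spikes, "span") <- span
    population$spikes <- new_spikes
    population$injections <- dplyr::bind_cols(inj, as_tibble(gates))
    population
  })
}

# Uniform draws in (lo, hi) s after `onset`, rejecting times whose window
# would overlap an event's stimulation vicinity or run off the recording.
draw_injection_times <- function(k, onset, schedule, config, span) {
  lo <- config$react_window_s[1]; hi <- config$react_window_s[2]
  dur <- config$react_duration_s
  ok <- numeric()
  for (attempt in seq_len(50 * k)) {
    if (length(ok) >= k) break
    t <- onset + runif(1, lo, hi)
    if (t + dur > span[2]) next
    near <- any(t + dur > schedule$onset - 1 & t < schedule$onset + 3)
    if (near) next
    ok <- c(ok, t)
  }
  ok
}
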