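#' Bin peri-event firing rates
#'
#' Counts spikes of every unit in `n_bins` consecutive half-open bins of
#' `bin_width` seconds after each event onset and converts counts to rates
#' (Hz). Overlapping event windows trigger a warning; the later event wins for
#' exclusive statistics downstream.
#'
#' @param spikes Tibble with columns `unit_id`, `time` (s).
#' @param events Event schedule (columns `event`, `level`, `onset`, ...).
#' @param bin_width Bin width in seconds (default 0.5).
#' @param n_bins Number of post-onset bins (default 2).
#' @return Tibble with one row per (unit, event instance, bin): `unit_id`,
#'   `event_index`, `event`, `level`, `onset`, `bin`, `rate`.
#' @export
#' @examples
#' spk <- tibble::tibble(unit_id = "u1", time = c(0.1, 0.2, 0.3, 0.8))
#' ev <- tibble::tibble(event = "drop", level = 1, onset = 0)
#' bin_event_responses(spk, ev)
bin_event_responses <- function(spikes, events, bin_width = 0.5, n_bins = 2) {
  spikes <- check_spikes(spikes)
  events <- check_schedule(events)
  stopifnot(bin_width > 0, n_bins >= 1)
  win <- bin_width * n_bins
  if (nrow(events) > 1) {
    on <- sort(events$onset)
    if (any(diff(on) < win)) {
      warn("Event windows overlap; later events take precedence in exclusive statistics.")
    }
  }
  units <- unique(spikes$unit_id)
  times_by_unit <- split(spikes$time, spikes$unit_id)
  edges0 <- rep(events$onset, each = n_bins) + bin_width * (seq_len(n_bins) - 1)
  counts <- purrr::map(units, function(u) {
    count_in_windows(times_by_unit[[u]], edges0, edges0 + bin_width)
  })
  tibble(
    unit_id = rep(units, each = nrow(events) * n_bins),
    event_index = rep(rep(seq_len(nrow(events)), each = n_bins), times = length(units)),
    event = rep(rep(events$event, each = n_bins), times = length(units)),
    level = rep(rep(events$level, each = n_bins), times = length(units)),
    onset = rep(rep(events$onset, each = n_bins), times = length(units)),
    bin = rep(rep(seq_len(n_bins), times = nrow(events)), times = length(units)),
    rate = unlist(counts) / bin_width
  )
}

#' Baseline firing rates
#'
#' Per-unit mean firing rate over all recording time excluding the
#' `[onset, onset + exclude_after)` window around every event (default 3 s),
#' plus the population baseline `g0` (mean of the per-unit baselines).
#'
#' @inheritParams bin_event_responses
#' @param exclude_after Seconds after each event onset excluded from baseline.
#' @param span Optional recording span `c(start, end)`; defaults to the
#'   schedule's span attribute or the data range.
#' @return List with `f0` (tibble `unit_id`, `f0`) and `g0` (scalar Hz).
#' @export
compute_baseline <- function(spikes, events, exclude_after = 3, span = NULL) {
  spikes <- check_spikes(spikes)
  events <- check_schedule(events)
  span <- span %||% recording_span(spikes, events)
  free <- baseline_intervals(events, span = span, exclude_before = 0,
                             exclude_after = exclude_after)
  total <- sum(free$end - free$start)
  if (total <= 0) abort("No eligible baseline time.", class = "reverb_no_baseline")
  times_by_unit <- split(spikes$time, spikes$unit_id)
  f0 <- vapply(times_by_unit, function(tt) {
    sum(count_in_windows(tt, free$start, free$end)) / total
  }, numeric(1))
  list(f0 = tibble(unit_id = names(f0), f0 = unname(f0)), g0 = mean(f0))
}

#' Normalized response score
#'
#' `R = (f_startle - f0) / (g0 + f0)` and `T = log(1 + R)` (natural log).
#' The denominator makes low-baseline units score proportionally to their
#' absolute rate change (`f0 << g0`) and high-baseline units to their relative
#' change (`f0 >> g0`).
#'
#' @param f_startle Mean event-window rate(s), Hz.
#' @param f0 Unit baseline rate(s), Hz.
#' @param g0 Population baseline rate, Hz (scalar, > 0 together with `f0`).
#' @return Tibble with columns `r_normalized` and `t_score` (`NA` where
#'   `R <= -1`).
#' @export
#' @examples
#' normalize_response(5, 1, 2.7)  # R = 4/3.7, T = log(1 + R)
normalize_response <- function(f_startle, f0, g0) {
  if (any(g0 + f0 <= 0)) {
    abort("`g0 + f0` must be positive for normalization.", class = "reverb_bad_input")
  }
  r <- (f_startle - f0) / (g0 + f0)
  tibble(r_normalized = r,
         t_score = ifelse(r > -1, log(1 + r), NA_real_))
}

#' Per-unit, per-event-type response table
#'
#' Aggregates binned peri-event rates into the quantities the taxonomy is
#' built from: per (unit, event type) the mean event-window rate over trials
#' (`f_startle`), the per-trial rates, the unit baseline `f0`, population
#' baseline `g0`, and the normalized scores `R` and `T`. Per-trial matched
#' pre-event baseline rates (window `[onset - 1.5, onset - 0.5)`) are kept for
#' the responsiveness test.
#'
#' @inheritParams bin_event_responses
#' @inheritParams compute_baseline
#' @return A list of class `"response_table"`: `by_type` (unit x event-type
#'   summary), `trials` (per-trial event and matched-baseline rates),
#'   `baseline` (`f0` per unit), `g0`, and the `events` used.
#' @export
response_table <- function(spikes, events, bin_width = 0.5, n_bins = 2,
                           exclude_after = 3, span = NULL) {
  spikes <- check_spikes(spikes)
  events <- check_schedule(events)
  binned <- bin_event_responses(spikes, events, bin_width, n_bins)
  base <- compute_baseline(spikes, events, exclude_after = exclude_after, span = span)
  win <- bin_width * n_bins

  trial <- binned |>
    group_by(.data$unit_id, .data$event_index, .data$event, .data$level, .data$onset) |>
    summarise(rate = mean(.data$rate), .groups = "drop")

  # matched pre-event baseline window of the same width, ending 0.5 s before onset
  units <- unique(spikes$unit_id)
  times_by_unit <- split(spikes$time, spikes$unit_id)
  pre_start <- events$onset - win - 0.5
  pre <- purrr::map(units, function(u) {
    count_in_windows(times_by_unit[[u]], pre_start, pre_start + win) / win
  })
  trial <- trial |>
    dplyr::arrange(.data$unit_id, .data$event_index) |>
    mutate(pre_rate = unlist(pre))

  by_type <- trial |>
    group_by(.data$unit_id, .data$event) |>
    summarise(f_startle = mean(.data$rate), n_trials = dplyr::n(), .groups = "drop") |>
    left_join(base$f0, by = "unit_id")
  sc <- normalize_response(by_type$f_startle, by_type$f0, base$g0)
  by_type <- dplyr::bind_cols(by_type, sc)

  structure(list(by_type = by_type, trials = trial, baseline = base$f0,
                 g0 = base$g0, events = events),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("<response_table> %d units x %d event types, g0 = %.2f Hz\n",
              dplyr::n_distinct(x$by_type$unit_id),
              dplyr::n_distinct(x$by_type$event), x$g0))
  invisible(x)
}

#' T-score matrix (units x event types)
#'
#' @param rt A [response_table()].
#' @param positive_only Keep only units whose maximum T is positive (the
#'   display convention for response heatmaps).
#' @return Numeric matrix, rownames unit ids, colnames event types.
#' @export
t_score_matrix <- function(rt, positive_only = FALSE) {
  wide <- rt$by_type |>
    select("unit_id", "event", "t_score") |>
    tidyr::pivot_wider(names_from = "event", values_from = "t_score")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$unit_id
  m[is.na(m)] <- 0
  if (positive_only) m <- m[apply(m, 1, max) > 0, , drop = FALSE]
  m
}

#' Responsiveness calls
#'
#' A unit is responsive to an event type when its absolute T-score reaches
#' `threshold_t` *and* its per-trial event-window rates differ significantly
#' from matched pre-event baseline rates (two-sample Wilcoxon rank test at
#' `alpha`). A unit is responsive overall when any type qualifies.
#'
#' @param rt A [response_table()].
#' @param threshold_t Minimum `|T|` (default 0.2). `Inf` selects nothing.
#' @param alpha Significance level of the rank test (default 0.05). `NULL`
#'   disables the test (threshold only).
#' @return List with `by_type` (tibble `unit_id`, `event`, `t_score`,
#'   `p_value`, `responsive`) and `units` (tibble `unit_id`, `responsive`).
#' @export
select_responsive <- function(rt, threshold_t = 0.2, alpha = 0.05) {
  stopifnot(inherits(rt, "response_table"))
  tests <- rt$trials |>
    group_by(.data$unit_id, .data$event) |>
    summarise(p_value = rank_test_p(.data$rate, .data$pre_rate), .groups = "drop")
  by_type <- rt$by_type |>
    select("unit_id", "event", "t_score") |>
    left_join(tests, by = c("unit_id", "event")) |>
    mutate(responsive = !is.na(.data$t_score) &
             abs(.data$t_score) >= threshold_t &
             (if (is.null(alpha)) TRUE else .data$p_value < alpha))
  units <- by_type |>
    group_by(.data$unit_id) |>
    summarise(responsive = any(.data$responsive), .groups = "drop")
  list(by_type = by_type, units = units)
}

rank_test_p <- function(x, y) {
  if (all(x == y)) return(1)
  suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
}

#' Selectivity labels
#'
#' Given per-type responsiveness calls, labels each responsive unit
#' `general` (all available types), `subgeneral:<types>` (2 to all-but-one),
#' or `specific:<type>` (exactly one). Units with no qualifying type are
#' `none`. With fewer than 4 event types present, labels are relative to the
#' available types and a warning is raised.
#'
#' @param responsive The result of [select_responsive()].
#' @return Tibble `unit_id`, `selectivity`, `selectivity_group`, `n_types`,
#'   `resp_types` (list-column).
#' @export
classify_selectivity <- function(responsive) {
  by_type <- responsive$by_type
  n_avail <- dplyr::n_distinct(by_type$event)
  if (n_avail < 4) {
    warn(sprintf("Only %d event types available; selectivity labels are relative to them.",
                 n_avail))
  }
  by_type |>
    group_by(.data$unit_id) |>
    summarise(resp_types = list(sort(.data$event[.data$responsive])), .groups = "drop") |>
    mutate(n_types = lengths(.data$resp_types),
           selectivity_group = dplyr::case_when(
             n_types == 0 ~ "none",
             n_types == n_avail ~ "general",
             n_types == 1 ~ "specific",
             TRUE ~ "subgeneral"
           ),
           selectivity = purrr::map2_chr(.data$selectivity_group, .data$resp_types,
                                         function(g, tt) {
                                           switch(g,
                                                  none = "none",
                                                  general = "general",
                                                  specific = paste0("specific:", tt[1]),
                                                  paste0("subgeneral:",
                                                         paste(tt, collapse = "+")))
                                         }))
}

#' Intensity-dependence classification
#'
#' For each responsive unit tested across several intensity levels of a
#' parametric event type, regresses the per-trial event-window rate on the
#' intensity rank and assesses the slope with a permutation test
#' (`n_perm` label permutations). A significant positive slope gives
#' `sensitive-up`, a significant negative slope `sensitive-down`; a
#' responsive unit without a significant slope is `invariant`. Units without
#' a responsive parametric type (or a single tested level) are `n/a`. When a
#' unit is responsive to both parametric types, the type with the larger
#' `|T|` is used.
#'
#' @param rt A [response_table()].
#' @param responsive Result of [select_responsive()].
#' @param alpha Significance level (default 0.05).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed for the permutation draws.
#' @return Tibble `unit_id`, `intensity_class`, `slope`, `p_value`,
#'   `tested_event`.
#' @export
classify_intensity_dependence <- function(rt, responsive, alpha = 0.05,
                                          n_perm = 1000, seed = NULL) {
  stopifnot(inherits(rt, "response_table"))
  param_types <- rt$events |>
    group_by(.data$event) |>
    summarise(n_levels = dplyr::n_distinct(.data$level), .groups = "drop") |>
    filter(.data$n_levels >= 2) |>
    pull(.data$event)

  resp_units <- responsive$units$unit_id[responsive$units$responsive]
  with_seed(seed, {
    res <- purrr::map(resp_units, function(u) {
      cand <- responsive$by_type |>
        filter(.data$unit_id == u, .data$responsive, .data$event %in% param_types)
      if (!nrow(cand)) {
        return(tibble(unit_id = u, intensity_class = "n/a", slope = NA_real_,
                      p_value = NA_real_, tested_event = NA_character_))
      }
      ev <- cand$event[which.max(abs(cand$t_score))]
      tr <- filter(rt$trials, .data$unit_id == u, .data$event == ev)
      if (dplyr::n_distinct(tr$level) < 2) {
        return(tibble(unit_id = u, intensity_class = "n/a", slope = NA_real_,
                      p_value = NA_real_, tested_event = ev))
      }
      ans <- permutation_slope(tr$rate, tr$level, n_perm)
      cls <- if (ans$p < alpha) {
        if (ans$slope > 0) "sensitive-up" else "sensitive-down"
      } else "invariant"
      tibble(unit_id = u, intensity_class = cls, slope = ans$slope,
             p_value = ans$p, tested_event = ev)
    })
    bind_rows(res)
  })
}

# Least-squares slope of y on x with a permutation p-value for |slope|.
permutation_slope <- function(y, x, n_perm) {
  x <- as.numeric(x)
  xc <- x - mean(x); yc <- y - mean(y)
  vx <- sum(xc^2)
  if (vx == 0 || all(yc == 0)) return(list(slope = 0, p = 1))
  slope <- sum(xc * yc) / vx
  perm <- replicate(n_perm, abs(sum(xc * sample(yc))) / vx)
  p <- (1 + sum(perm >= abs(slope))) / (n_perm + 1)
  list(slope = slope, p = p)
}

#' Putative pyramidal/interneuron classification and complex spike index
#'
#' Class is assigned by mean firing rate (`< 5` Hz pyramidal, `> 8` Hz
#' interneuron, otherwise `unknown`); units with fewer than 100 spikes are
#' `unknown`. The complex spike index (CSI) is the percentage of spikes whose
#' first-lag inter-spike interval falls in 2--15 ms and whose second spike has
#' a smaller amplitude than the first; it requires an `amplitude` column and
#' is `NA` otherwise.
#'
#' @param spikes Tibble `unit_id`, `time`, optionally `amplitude`.
#' @param span Optional recording span for the rate denominator.
#' @param pyramidal_max,interneuron_min Rate thresholds (Hz).
#' @return Tibble `unit_id`, `n_spikes`, `mean_rate`, `unit_class`, `csi`.
#' @export
classify_unit_type <- function(spikes, span = NULL, pyramidal_max = 5,
                               interneuron_min = 8) {
  spikes <- check_spikes(spikes)
  span <- span %||% recording_span(spikes)
  dur <- diff(span)
  has_amp <- "amplitude" %in% names(spikes)
  spikes |>
    group_by(.data$unit_id) |>
    summarise(
      n_spikes = dplyr::n(),
      mean_rate = dplyr::n() / dur,
      csi = if (has_amp) complex_spike_index(.data$time, .data$amplitude) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(unit_class = dplyr::case_when(
      n_spikes < 100 ~ "unknown",
      mean_rate < pyramidal_max ~ "pyramidal",
      mean_rate > interneuron_min ~ "interneuron",
      TRUE ~ "unknown"
    ))
}

complex_spike_index <- function(time, amplitude) {
  n <- length(time)
  if (n < 2) return(0)
  isi <- diff(time)
  hit <- isi >= 0.002 & isi <= 0.015 & diff(amplitude) < 0
  100 * sum(hit) / (n - 1)
}

#' Smoothed firing-rate estimate
#'
#' Causal rate estimate obtained by convolving the spike train with a
#' one-sided exponential kernel (`exp(-u / tau) / tau` for `u >= 0`), the
#' asymmetric kernel used for peri-event rate displays. The kernel integrates
#' to one, so the integral of the rate over a span covering the train equals
#' the spike count.
#'
#' @param times Spike times (s) of one unit.
#' @param t_start,t_end Evaluation span (s).
#' @param dt Grid step (s, default 0.001).
#' @param tau Kernel time constant (s, default 0.1).
#' @return Tibble `time`, `rate` (Hz).
#' @export
smooth_rate <- function(times, t_start, t_end, dt = 0.001, tau = 0.1) {
  stopifnot(t_end > t_start, dt > 0, tau > 0)
  grid <- seq(t_start, t_end, by = dt)
  times <- sort(times[times <= t_end])
  rate <- numeric(length(grid))
  decay <- exp(-dt / tau)
  # contribution of spikes before the grid start
  pre <- times[times <= grid[1]]
  acc <- sum(exp(-(grid[1] - pre) / tau)) / tau
  rate[1] <- acc
  idx <- findInterval(times, grid, left.open = TRUE)
  for (k in 2:length(grid)) {
    acc <- acc * decay
    new <- times[idx == (k - 1)]
    if (length(new)) acc <- acc + sum(exp(-(grid[k] - new) / tau)) / tau
    rate[k] <- acc
  }
  tibble(time = grid, rate = rate)
}

#' Full unit taxonomy
#'
#' Convenience wrapper chaining [response_table()], [select_responsive()],
#' [classify_selectivity()], [classify_intensity_dependence()] and
#' [classify_unit_type()] into the per-unit taxonomy tibble used by the
#' subpopulation analyses.
#'
#' @inheritParams response_table
#' @inheritParams select_responsive
#' @inheritParams classify_intensity_dependence
#' @return A list of class `"unit_taxonomy"`: `units` (per-unit tibble with
#'   `responsive`, `selectivity`, `selectivity_group`, `intensity_class`,
#'   `unit_class`), `by_type`, and the underlying `response_table`.
#' @export
characterize_units <- function(spikes, events, threshold_t = 0.2, alpha = 0.05,
                               n_perm = 1000, seed = NULL, span = NULL) {
  rt <- response_table(spikes, events, span = span)
  resp <- select_responsive(rt, threshold_t = threshold_t, alpha = alpha)
  sel <- classify_selectivity(resp)
  int <- classify_intensity_dependence(rt, resp, alpha = alpha,
                                       n_perm = n_perm, seed = seed)
  cls <- classify_unit_type(spikes, span = span)
  units <- resp$units |>
    left_join(select(sel, "unit_id", "selectivity", "selectivity_group",
                     "n_types", "resp_types"), by = "unit_id") |>
    left_join(select(int, "unit_id", "intensity_class", "slope", "p_value",
                     "tested_event"), by = "unit_id") |>
    left_join(select(cls, "unit_id", "mean_rate", "unit_class", "csi"),
              by = "unit_id") |>
    mutate(selectivity = ifelse(.data$responsive, .data$selectivity, "none"),
           selectivity_group = ifelse(.data$responsive, .data$selectivity_group, "none"),
           intensity_class = dplyr::coalesce(.data$intensity_class,
                                             ifelse(.data$responsive, "n/a", "none")))
  structure(list(units = units, by_type = resp$by_type, response_table = rt),
            class = "unit_taxonomy")
}

#' @export
print.unit_taxonomy <- function(x, ...) {
  n <- nrow(x$units)
  nr <- sum(x$units$responsive)
  cat(sprintf("<unit_taxonomy> %d units, %d responsive (%.1f%%)\n",
              n, nr, 100 * nr / n))
  invisible(x)
}

#' Taxonomy composition report
#'
#' Turns category counts into the percentages conventionally reported for
#' this taxonomy: the responsive fraction of all units (one decimal) and the
#' general/subgeneral/specific split within each intensity class (whole
#' percent). Counts can come from [characterize_units()] or be supplied
#' directly.
#'
#' @param x A `"unit_taxonomy"`, or a named list/tibble of counts with
#'   elements `n_total`, `n_responsive`, and per-class named vectors
#'   `invariant` and `sensitive` of general/subgeneral/specific counts.
#' @return Tibble `group`, `category`, `count`, `denominator`, `pct`
#'   (raw percentage) and `pct_printed` (rounded as reported).
#' @export
#' @examples
#' taxonomy_report(list(
#'   n_total = 1623, n_responsive = 583,
#'   invariant = c(general = 152, subgeneral = 75, specific = 57),
#'   sensitive = c(general = 134, subgeneral = 75, specific = 89)
#' ))
taxonomy_report <- function(x) {
  if (inherits(x, "unit_taxonomy")) {
    u <- x$units
    resp <- filter(u, .data$responsive)
    inv <- filter(resp, .data$intensity_class == "invariant")
    sen <- filter(resp, .data$intensity_class %in% c("sensitive-up", "sensitive-down"))
    cnt <- function(d, g) sum(d$selectivity_group == g)
    x <- list(
      n_total = nrow(u), n_responsive = nrow(resp),
      invariant = c(general = cnt(inv, "general"), subgeneral = cnt(inv, "subgeneral"),
                    specific = cnt(inv, "specific")),
      sensitive = c(general = cnt(sen, "general"), subgeneral = cnt(sen, "subgeneral"),
                    specific = cnt(sen, "specific"))
    )
  }
  rows <- list(tibble(group = "all", category = "responsive",
                      count = x$n_responsive, denominator = x$n_total,
                      digits = 1))
  for (g in c("invariant", "sensitive")) {
    v <- x[[g]]
    rows[[length(rows) + 1]] <- tibble(
      group = g, category = names(v), count = unname(v),
      denominator = sum(v), digits = 0
    )
  }
  bind_rows(rows) |>
    mutate(pct = 100 * .data$count / .data$denominator,
           pct_printed = round(.data$pct, .data$digits)) |>
    select(-"digits")
}

#' Taxonomy recovery accuracy against ground truth
#'
#' Compares an inferred taxonomy with the generator's ground truth. The
#' intensity class is compared only on units where both truth and inference
#' had a parametric type to test (`n/a`/`none` elsewhere is not an error).
#'
#' @param taxonomy A `"unit_taxonomy"`.
#' @param truth Ground-truth tibble from [generate_population()].
#' @return One-row tibble with `responsive_accuracy`, `selectivity_accuracy`,
#'   `intensity_accuracy` (invariant vs sensitive, on assessable units),
#'   `joint_accuracy`, and `recovered_responsive_fraction`.
#' @export
taxonomy_accuracy <- function(taxonomy, truth) {
  stopifnot(inherits(taxonomy, "unit_taxonomy"))
  m <- left_join(taxonomy$units, truth, by = "unit_id",
                 suffix = c("", ".true"))
  resp_ok <- m$responsive == m$responsive.true
  sel_ok <- m$selectivity == m$selectivity.true
  coarse <- function(z) ifelse(startsWith(z, "sensitive"), "sensitive", z)
  assessable <- m$responsive & m$responsive.true &
    !m$intensity_class %in% c("n/a", "none") &
    !m$intensity_class.true %in% c("n/a", "none")
  int_ok_all <- !assessable |
    coarse(m$intensity_class) == coarse(m$intensity_class.true)
  tibble(
    responsive_accuracy = mean(resp_ok),
    selectivity_accuracy = mean(sel_ok[m$responsive.true & m$responsive], na.rm = TRUE),
    intensity_accuracy = mean((coarse(m$intensity_class) ==
                                 coarse(m$intensity_class.true))[assessable]),
    joint_accuracy = mean(resp_ok & sel_ok & int_ok_all),
    recovered_responsive_fraction = mean(m$responsive)
  )
}
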