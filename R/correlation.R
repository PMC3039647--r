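#' Pairwise cross-correlations of binned unit activity
#'
#' For a set of equal-length repetition windows, each unit's activity is
#' binned at `bin` seconds inside every window and the per-repetition
#' frequency vectors are concatenated; `r` is the Pearson correlation of the
#' concatenated vectors for every unit pair. Pairs involving a zero-variance
#' vector are returned with `r = NA` and flagged. With
#' `per_repetition = TRUE` the correlation is instead computed per
#' repetition and averaged.
#'
#' @param spikes Tibble `unit_id`, `time`.
#' @param windows Tibble `start`, `end` (equal lengths; >= 2 windows).
#' @param bin Bin width (s, default 0.05).
#' @param units Optional unit subset.
#' @param per_repetition Average per-repetition correlations instead of
#'   correlating the concatenated vectors.
#' @return Tibble `unit_a`, `unit_b` (unordered, `unit_a < unit_b`), `r`,
#'   `n_bins`, `defined`.
#' @export
pair_correlations <- function(spikes, windows, bin = 0.05, units = NULL,
                              per_repetition = FALSE) {
  spikes <- check_spikes(spikes)
  if (nrow(windows) < 2) {
    abort("Need at least 2 repetition windows.", class = "reverb_bad_input")
  }
  len <- windows$end - windows$start
  if (any(abs(len - len[1]) > 1e-9)) {
    abort("Repetition windows must have equal lengths.", class = "reverb_bad_input")
  }
  units <- units %||% sort(unique(spikes$unit_id))
  nb <- as.integer(round(len[1] / bin))
  if (nb < 1) abort("Window shorter than one bin.", class = "reverb_bad_input")
  counts <- bin_counts_matrix(spikes, units, windows, bin, nb)  # (reps*nb) x units

  pair_index <- function() {
    idx <- which(upper.tri(diag(length(units))), arr.ind = TRUE)
    tibble(unit_a = units[idx[, 1]], unit_b = units[idx[, 2]],
           i = idx[, 1], j = idx[, 2])
  }
  pairs <- pair_index()
  if (per_repetition) {
    rep_id <- rep(seq_len(nrow(windows)), each = nb)
    cors <- purrr::map(seq_len(nrow(windows)), function(k) {
      m <- counts[rep_id == k, , drop = FALSE]
      suppressWarnings(cor(m))
    })
    # mean over repetitions where defined
    rmean <- apply(simplify2array(cors), c(1, 2), mean, na.rm = TRUE)
    r <- rmean[cbind(pairs$i, pairs$j)]
    r[!is.finite(r)] <- NA
  } else {
    sds <- apply(counts, 2, sd)
    suppressWarnings(cm <- cor(counts))
    r <- cm[cbind(pairs$i, pairs$j)]
    r[sds[pairs$i] == 0 | sds[pairs$j] == 0] <- NA
  }
  pairs |>
    select(-"i", -"j") |>
    mutate(r = r, n_bins = nrow(counts), defined = is.finite(r))
}

# counts matrix: rows = concatenated bins over windows, cols = units
bin_counts_matrix <- function(spikes, units, windows, bin, nb) {
  times_by_unit <- split(spikes$time, factor(spikes$unit_id, levels = units))
  edges <- unlist(purrr::map(seq_len(nrow(windows)), function(k) {
    windows$start[k] + bin * (seq_len(nb) - 1)
  }))
  m <- vapply(units, function(u) {
    count_in_windows(times_by_unit[[u]] %||% numeric(), edges, edges + bin) / bin
  }, numeric(length(edges)))
  matrix(m, ncol = length(units), dimnames = list(NULL, units))
}

#' Correlations of all unit pairs across analysis periods
#'
#' Convenience wrapper running [pair_correlations()] for each named period
#' window set and stacking the results.
#'
#' @param spikes Tibble `unit_id`, `time`.
#' @param periods Named list of window tibbles, e.g.
#'   `list(pre = ..., event = ..., reactivation = ...)`.
#' @inheritParams pair_correlations
#' @return Tibble `unit_a`, `unit_b`, `period`, `r`, `n_bins`, `defined`.
#' @export
period_pair_correlations <- function(spikes, periods, bin = 0.05, units = NULL) {
  purrr::imap(periods, function(w, nm) {
    mutate(pair_correlations(spikes, w, bin = bin, units = units), period = nm)
  }) |>
    bind_rows() |>
    select("unit_a", "unit_b", "period", "r", "n_bins", "defined")
}

#' Filter noisy correlation pairs
#'
#' Retains a pair when the maximum `|r|` over the non-basal periods (every
#' period except `basal_period`) reaches `threshold`. Undefined correlations
#' are ignored in the maximum; pairs undefined everywhere are dropped.
#'
#' @param correlations A [period_pair_correlations()] tibble.
#' @param threshold Minimum `|r|` (>= 0); 0.05 and 0.1 are typical.
#' @param basal_period Name of the basal period (default `"pre"`).
#' @return The retained subset (all periods of the retained pairs).
#' @export
filter_pairs <- function(correlations, threshold, basal_period = "pre") {
  stopifnot(threshold >= 0)
  keep <- correlations |>
    filter(.data$period != basal_period, .data$defined) |>
    group_by(.data$unit_a, .data$unit_b) |>
    summarise(max_r = max(abs(.data$r)), .groups = "drop") |>
    filter(.data$max_r >= threshold)
  dplyr::semi_join(correlations, keep, by = c("unit_a", "unit_b"))
}

#' Top correlated pairs per selectivity group
#'
#' Within each selectivity group (both units of a pair must share the group),
#' keeps the pairs with the largest event-period `|r|`; by default 10, 20 and
#' 30 pairs for the specific, subgeneral and general groups, reflecting their
#' population sizes. A warning is raised when a group holds fewer pairs than
#' requested.
#'
#' @param correlations A [period_pair_correlations()] tibble.
#' @param taxonomy Tibble `unit_id`, `selectivity_group`.
#' @param counts Named pair counts per group.
#' @param event_period Period used for ranking (default `"event"`).
#' @return The selected pairs (all periods), with a `selectivity_group`
#'   column.
#' @export
select_top_pairs <- function(correlations, taxonomy,
                             counts = c(specific = 10, subgeneral = 20, general = 30),
                             event_period = "event") {
  grp <- setNames(taxonomy$selectivity_group, taxonomy$unit_id)
  tagged <- correlations |>
    mutate(ga = unname(grp[.data$unit_a]), gb = unname(grp[.data$unit_b])) |>
    filter(!is.na(.data$ga), .data$ga == .data$gb, .data$ga %in% names(counts)) |>
    rename(selectivity_group = "ga") |>
    select(-"gb")
  ranked <- tagged |>
    filter(.data$period == event_period, .data$defined) |>
    group_by(.data$selectivity_group) |>
    arrange(dplyr::desc(abs(.data$r)), .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  chosen <- ranked |>
    filter(.data$rank <= counts[.data$selectivity_group]) |>
    select("unit_a", "unit_b", "selectivity_group")
  short <- ranked |>
    count(.data$selectivity_group) |>
    filter(.data$n < counts[.data$selectivity_group])
  if (nrow(short)) {
    warn(sprintf("Fewer pairs than requested for: %s.",
                 paste(short$selectivity_group, collapse = ", ")))
  }
  dplyr::inner_join(tagged, chosen, by = c("unit_a", "unit_b", "selectivity_group"))
}

#' Per-period correlation statistics
#'
#' Mean `|r|` per (selectivity group, period), with a paired one-sided
#' Wilcoxon signed-rank test of each period against the basal period across
#' pairs. Because the periods can contain very different numbers of 50-ms
#' bins, raw `|r|` values are not comparable across periods (the null width
#' scales as `1/sqrt(n_bins)`); the test therefore operates on Fisher-z
#' standardized magnitudes `|atanh(r)| * sqrt(n_bins - 3)`, which are
#' period-comparable under the null. Mean `|r|` is still reported
#' descriptively.
#'
#' @param correlations Tibble with `unit_a`, `unit_b`, `period`, `r`,
#'   `n_bins` and optionally `selectivity_group` (one group assumed
#'   otherwise).
#' @param basal_period Reference period (default `"pre"`).
#' @return Tibble `selectivity_group`, `period`, `n_pairs`, `mean_abs_r`,
#'   `mean_abs_z`, `p_vs_basal` (one-sided: period exceeds basal).
#' @export
period_correlation_stats <- function(correlations, basal_period = "pre") {
  if (!"selectivity_group" %in% names(correlations)) {
    correlations$selectivity_group <- "all"
  }
  zstd <- correlations |>
    mutate(z = abs(atanh(pmin(pmax(.data$r, -0.999), 0.999))) *
             sqrt(pmax(.data$n_bins - 3, 1)))
  wide_r <- zstd |>
    select("unit_a", "unit_b", "selectivity_group", "period", "r") |>
    tidyr::pivot_wider(names_from = "period", values_from = "r")
  wide_z <- zstd |>
    select("unit_a", "unit_b", "selectivity_group", "period", "z") |>
    tidyr::pivot_wider(names_from = "period", values_from = "z")
  periods <- unique(correlations$period)
  out <- purrr::map(periods, function(p) {
    g_r <- group_by(wide_r, .data$selectivity_group)
    stats_r <- summarise(g_r,
                         n_pairs = sum(is.finite(.data[[p]])),
                         mean_abs_r = mean(abs(.data[[p]]), na.rm = TRUE),
                         .groups = "drop")
    stats_z <- wide_z |>
      group_by(.data$selectivity_group) |>
      summarise(
        mean_abs_z = mean(.data[[p]], na.rm = TRUE),
        p_vs_basal = if (p == basal_period) NA_real_ else {
          a <- .data[[p]]; b <- .data[[basal_period]]
          ok <- is.finite(a) & is.finite(b)
          if (sum(ok) < 5 || all(a[ok] == b[ok])) NA_real_ else
            suppressWarnings(wilcox.test(a[ok], b[ok], paired = TRUE,
                                         alternative = "greater",
                                         exact = FALSE)$p.value)
        },
        .groups = "drop"
      )
    left_join(stats_r, stats_z, by = "selectivity_group") |>
      mutate(period = p, .after = "selectivity_group")
  })
  bind_rows(out)
}

#' Explained variance (EV)
#'
#' Squared partial correlation of the event-period and post-period pairwise
#' correlation vectors, controlling for the pre-period:
#' `EV = ((r_ep_post - r_ep_pre * r_pre_post) /
#'        sqrt((1 - r_ep_pre^2) (1 - r_pre_post^2)))^2`.
#' Bounded in \[0, 1\]; low values indicate no event-related reorganization
#' persists into the post period.
#'
#' @param r_ep_post Correlation (across pairs) of event-period and
#'   post-period pair correlations.
#' @param r_ep_pre,r_pre_post The remaining two correlations (strictly inside
#'   (-1, 1)).
#' @return EV scalar.
#' @export
#' @examples
#' explained_variance(0.5, 0, 0)    # reduces to r^2
#' explained_variance(0.12, 0.4, 0.3)
explained_variance <- function(r_ep_post, r_ep_pre, r_pre_post) {
  if (abs(r_ep_pre) >= 1 || abs(r_pre_post) >= 1) {
    abort("Conditioning correlations must lie strictly inside (-1, 1).",
          class = "reverb_bad_input")
  }
  num <- r_ep_post - r_ep_pre * r_pre_post
  den <- sqrt((1 - r_ep_pre^2) * (1 - r_pre_post^2))
  (num / den)^2
}

#' Explained-variance report from period correlations
#'
#' Computes the three across-pair correlations between the pre, event and
#' post (reactivation) period correlation vectors, the resulting EV, and the
#' reversed control `EV_reversed` (pre as the outcome, controlling for
#' post) whose comparison with EV distinguishes a genuine post-event effect
#' from pair-level similarity already present beforehand.
#'
#' @param correlations Tibble from [period_pair_correlations()] (optionally
#'   filtered); must contain the three periods.
#' @param pre,event,post Period names.
#' @return One-row tibble: `n_pairs`, `r_ep_post`, `r_ep_pre`, `r_pre_post`,
#'   `ev`, `ev_reversed`.
#' @export
explained_variance_report <- function(correlations, pre = "pre",
                                      event = "event", post = "reactivation") {
  wide <- correlations |>
    select("unit_a", "unit_b", "period", "r") |>
    tidyr::pivot_wider(names_from = "period", values_from = "r") |>
    filter(is.finite(.data[[pre]]), is.finite(.data[[event]]),
           is.finite(.data[[post]]))
  if (nrow(wide) < 5) abort("Too few pairs with all three periods defined.",
                            class = "reverb_bad_input")
  r_ep_post <- cor(wide[[event]], wide[[post]])
  r_ep_pre <- cor(wide[[event]], wide[[pre]])
  r_pre_post <- cor(wide[[pre]], wide[[post]])
  tibble(
    n_pairs = nrow(wide),
    r_ep_post = r_ep_post, r_ep_pre = r_ep_pre, r_pre_post = r_pre_post,
    ev = explained_variance(r_ep_post, r_ep_pre, r_pre_post),
    ev_reversed = explained_variance(r_ep_pre, r_ep_post, r_pre_post)
  )
}

#' Period windows for correlation analyses
#'
#' Builds the standard window sets: `pre` (baseline windows before the first
#' event), `event` (1 s after every onset), `reactivation` (+/- 2 s around
#' detected reactivation peaks) and `post_non_reactivation` (windows of the
#' same length drawn from post-event time away from any reactivation). All
#' windows within a set share one length so they can serve as repetitions.
#'
#' @param events Event schedule.
#' @param reactivations Optional [detect_reactivations()] tibble.
#' @param span Recording span.
#' @param event_window Event-period window length (s, default 1).
#' @param react_halfwidth Seconds before/after a reactivation peak (default 2).
#' @param n_pre Number of pre windows (default: number of events).
#' @param n_post_non Number of non-reactivation control windows (default:
#'   number of reactivations).
#' @param seed Seed for the random window draws.
#' @return Named list of window tibbles.
#' @export
make_period_windows <- function(events, reactivations = NULL, span = NULL,
                                event_window = 1, react_halfwidth = 2,
                                n_pre = NULL, n_post_non = NULL, seed = NULL) {
  events <- check_schedule(events)
  span <- span %||% attr(events, "span") %||% c(0, max(events$onset) + 3)
  first <- min(events$onset)
  n_pre <- n_pre %||% nrow(events)
  with_seed(seed, {
    out <- list()
    # pre: windows inside the initial baseline span
    pre_free <- tibble(start = span[1], end = max(first - 1, span[1] + event_window))
    out$pre <- sample_baseline_windows(pre_free, n_pre, event_window)
    out$event <- tibble(start = events$onset, end = events$onset + event_window)
    if (!is.null(reactivations) && nrow(reactivations)) {
      w <- 2 * react_halfwidth
      rt <- tibble(start = reactivations$time - react_halfwidth,
                   end = reactivations$time + react_halfwidth)
      rt <- filter(rt, .data$start >= span[1], .data$end <= span[2])
      out$reactivation <- rt
      n_post_non <- n_post_non %||% nrow(rt)
      post_free <- baseline_intervals(
        bind_rows(tibble(event = "x", onset = events$onset),
                  tibble(event = "r", onset = reactivations$time - react_halfwidth)),
        span = c(first, span[2]), exclude_before = 1,
        exclude_after = max(3, w + 1)
      )
      out$post_non_reactivation <-
        sample_baseline_windows(post_free, n_post_non, w)
    }
    out
  })
}
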