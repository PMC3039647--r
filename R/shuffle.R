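#' Unit-identity shuffle
#'
#' Randomly permutes which unit owns which spike train. By default the whole
#' trains are exchanged in one global permutation (per-train spike counts are
#' conserved as a multiset and the population rate function is exactly
#' preserved); a previously fitted model applied to such data projects event
#' patterns into regions unrelated to its clusters. With `windows` given, an
#' independent permutation is drawn inside each half-open window and spikes
#' outside all windows are untouched — this per-window form breaks the
#' unit-to-pattern correspondence sample by sample and collapses refitted
#' classification to chance.
#'
#' @param spikes Tibble `unit_id`, `time` (>= 2 units).
#' @param seed Seed.
#' @param windows Optional tibble `start`, `end` of analysis windows.
#' @return Shuffled spikes tibble (same span attribute).
#' @export
shuffle_unit_identity <- function(spikes, seed = NULL, windows = NULL) {
  spikes <- check_spikes(spikes)
  units <- sort(unique(spikes$unit_id))
  if (length(units) < 2) {
    abort("Unit-identity shuffle needs at least 2 units.", class = "reverb_bad_input")
  }
  span <- attr(spikes, "span")
  out <- with_seed(seed, {
    if (is.null(windows)) {
      perm <- setNames(sample(units), units)
      mutate(spikes, unit_id = unname(perm[.data$unit_id]))
    } else {
      s <- spikes
      for (i in seq_len(nrow(windows))) {
        perm <- setNames(sample(units), units)
        inside <- in_window(s$time, windows$start[i], windows$end[i])
        s$unit_id[inside] <- unname(perm[s$unit_id[inside]])
      }
      s
    }
  })
  out <- dplyr::arrange(out, .data$unit_id, .data$time)
  attr(out, "span") <- span
  out
}

#' Temporal shuffle of spikes around a time point
#'
#' Within `[center - window/2, center + window/2)`, each unit's spikes are
#' placed into bins of `bin` seconds and the bin sequence is randomly
#' permuted within that unit (spikes keep their offset inside the bin).
#' Spikes outside the window are untouched; per-unit spike counts in the
#' window are conserved exactly, as is each unit's window-average rate.
#'
#' @param spikes Tibble `unit_id`, `time`.
#' @param center Center of the shuffle window (s).
#' @param window Window length (s, default 4: 2 s before and after).
#' @param bin Bin width (s, default 0.01; 0.05 is the coarser alternative).
#' @param seed Seed.
#' @return Shuffled spikes tibble.
#' @export
shuffle_temporal <- function(spikes, center, window = 4, bin = 0.01, seed = NULL) {
  spikes <- check_spikes(spikes)
  if (window <= 0 || bin <= 0 || bin > window) {
    abort("Need `window` > 0, `bin` > 0 and `bin` <= `window`.",
          class = "reverb_bad_input")
  }
  span <- attr(spikes, "span") %||% recording_span(spikes)
  lo <- center - window / 2
  hi <- center + window / 2
  if (lo < span[1] || hi > span[2]) {
    abort("Shuffle window extends outside the recording.", class = "reverb_range_error")
  }
  n_bins <- as.integer(ceiling(window / bin - 1e-9))
  out <- with_seed(seed, {
    s <- spikes
    for (u in unique(s$unit_id)) {
      sel <- which(s$unit_id == u & in_window(s$time, lo, hi))
      if (!length(sel)) next
      rel <- s$time[sel] - lo
      b <- pmin(floor(rel / bin), n_bins - 1)
      off <- rel - b * bin
      perm <- sample.int(n_bins)        # new position of each original bin
      s$time[sel] <- lo + (perm[b + 1] - 1) * bin + pmin(off, bin - 1e-12)
    }
    s
  })
  out <- dplyr::arrange(out, .data$unit_id, .data$time)
  attr(out, "span") <- span
  out
}

#' Side-by-side original vs shuffled analysis report
#'
#' Summarizes how an analysis degrades under shuffling: classification
#' accuracy, reactivation counts, and whatever other scalar metrics both
#' analyses share. A collapse flag marks accuracy drops of at least
#' `margin`.
#'
#' @param original,shuffled Named lists (or one-row data frames) of scalar
#'   metrics, e.g. `list(accuracy = 0.98, n_reactivations = 41)`.
#' @param margin Accuracy drop (absolute) flagged as collapse (default 0.3).
#' @return Tibble `metric`, `original`, `shuffled`, `difference`, plus an
#'   attribute `collapsed` when an `accuracy` metric is present.
#' @export
shuffle_report <- function(original, shuffled, margin = 0.3) {
  o <- unlist(original)
  s <- unlist(shuffled)
  common <- intersect(names(o), names(s))
  if (!length(common)) abort("No shared metrics to compare.", class = "reverb_bad_input")
  out <- tibble(metric = common, original = unname(o[common]),
                shuffled = unname(s[common]),
                difference = unname(s[common] - o[common]))
  if ("accuracy" %in% common) {
    attr(out, "collapsed") <- (o["accuracy"] - s["accuracy"]) >= margin
  }
  out
}
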