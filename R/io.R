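#' Read spike trains from delimited text
#'
#' Expects a header with columns `unit_id` and `spike_time_s` (or `time`);
#' an optional `amplitude` column is carried along. Rows are sorted per unit;
#' duplicate timestamps within a unit are collapsed with a warning; negative
#' times or unknown columns are parse errors reporting the offending line.
#'
#' @param path File path (comma- or tab-separated).
#' @return Tibble `unit_id`, `time` (, `amplitude`).
#' @export
read_spikes <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  known <- c("unit_id", "spike_time_s", "time", "amplitude")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    abort(sprintf("Unknown column(s) in %s: %s.", path, paste(extra, collapse = ", ")),
          class = "reverb_parse_error")
  }
  if (!"unit_id" %in% names(df) || !any(c("spike_time_s", "time") %in% names(df))) {
    abort(sprintf("%s must have columns unit_id and spike_time_s.", path),
          class = "reverb_parse_error")
  }
  tcol <- if ("spike_time_s" %in% names(df)) "spike_time_s" else "time"
  bad <- which(!is.finite(df[[tcol]]) | df[[tcol]] < 0)
  if (length(bad)) {
    abort(sprintf("Negative or non-finite spike time at line %d of %s.",
                  bad[1] + 1L, path),
          class = "reverb_parse_error")
  }
  out <- tibble(unit_id = as.character(df$unit_id), time = df[[tcol]])
  if ("amplitude" %in% names(df)) out$amplitude <- df$amplitude
  out <- dplyr::arrange(out, .data$unit_id, .data$time)
  n0 <- nrow(out)
  out <- dplyr::distinct(out, .data$unit_id, .data$time, .keep_all = TRUE)
  if (nrow(out) < n0) {
    warn(sprintf("Collapsed %d duplicate (unit, time) rows.", n0 - nrow(out)))
  }
  out
}

#' Write spike trains to CSV
#'
#' @param spikes Tibble `unit_id`, `time` (, `amplitude`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  spikes <- check_spikes(spikes)
  df <- data.frame(unit_id = spikes$unit_id, spike_time_s = spikes$time)
  if ("amplitude" %in% names(spikes)) df$amplitude <- spikes$amplitude
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an event schedule as JSON
#'
#' The on-disk format is a JSON array of `{type, level, onset_s, session}`
#' objects with an optional top-level span.
#'
#' @param path File path.
#' @return An `"event_schedule"` tibble.
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- if (is.data.frame(obj)) obj else obj$events
  out <- tibble(event = ev$type, level = as.integer(ev$level),
                onset = ev$onset_s, session = as.integer(ev$session))
  if (!is.data.frame(obj) && !is.null(obj$span)) attr(out, "span") <- obj$span
  class(out) <- c("event_schedule", class(out))
  out
}

#' @rdname read_schedule
#' @param events An event schedule tibble.
#' @export
write_schedule <- function(events, path) {
  events <- check_schedule(events)
  payload <- list(
    events = data.frame(type = events$event, level = events$level,
                        onset_s = events$onset, session = events$session),
    span = attr(events, "span")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains the stages end to end: simulate -> characterize -> cluster ->
#' MDA fit/cross-validate -> sliding-window scan -> shuffle control ->
#' correlations -> explained variance. Stage toggles turn later stages off.
#' All randomness derives from the single `seed` through a documented
#' stream-splitting scheme, so two runs with the same seed give identical
#' summaries.
#'
#' @param config A [simulation_config()].
#' @param seed Master seed (mandatory).
#' @param stages Character vector of stages to run; later stages silently
#'   require earlier ones. Default: all.
#' @param lambda Shrinkage intensity for the MDA stages.
#' @param n_cv Cross-validation repetitions (default 200).
#' @param theta Reactivation detection threshold.
#' @param out Optional path for a JSON summary.
#' @return A list of class `"reverb_report"` with elements per stage and a
#'   `summary` tibble of scalar statistics.
#' @export
run_pipeline <- function(config = simulation_config(), seed,
                         stages = c("simulate", "characterize", "cluster",
                                    "mda", "scan", "shuffle", "correlate", "ev"),
                         lambda = 0.5, n_cv = 200, theta = 2, out = NULL) {
  if (missing(seed)) abort("`seed` is mandatory.", class = "reverb_invalid_config")
  stages <- match.arg(stages, several.ok = TRUE)
  res <- list(seed = seed, config = config)
  stat <- list()

  sched <- build_schedule(config, seed = child_seed(seed, "schedule"))
  pop <- generate_population(config, sched, seed = child_seed(seed, "population"))
  pop <- inject_reactivations(pop, seed = child_seed(seed, "react"))
  res$schedule <- sched
  res$truth <- pop$truth
  res$injections <- pop$injections
  stat$n_events <- nrow(sched)
  stat$n_injections <- nrow(pop$injections)

  if ("characterize" %in% stages) {
    tax <- characterize_units(pop$spikes, sched,
                              seed = child_seed(seed, "characterize"))
    res$taxonomy <- tax
    res$taxonomy_report <- taxonomy_report(tax)
    acc <- taxonomy_accuracy(tax, pop$truth)
    res$taxonomy_accuracy <- acc
    stat$responsive_fraction <- acc$recovered_responsive_fraction
    stat$taxonomy_joint_accuracy <- acc$joint_accuracy
  }
  if ("cluster" %in% stages && !is.null(res$taxonomy)) {
    m <- t_score_matrix(res$taxonomy$response_table)
    dend <- cluster_responses(m)
    res$dendrogram <- dend
    res$leaf_order <- order_leaves(dend, m)
  }
  if ("mda" %in% stages) {
    pats <- make_labelled_patterns(pop$spikes, sched,
                                   seed = child_seed(seed, "patterns"))
    model <- fit_mda(pats, lambda = lambda)
    cv <- cross_validate_mda(pats, lambda = lambda, n_rep = n_cv,
                             seed = child_seed(seed, "cv"))
    res$patterns <- pats
    res$model <- model
    res$cv <- cv
    res$cluster_distances <- cluster_rest_distances(model)
    stat$cv_accuracy <- mean(cv$accuracy)
  }
  if ("scan" %in% stages && !is.null(res$model)) {
    traj <- sliding_projection(pop$spikes, res$model)
    excl <- tibble(start = sched$onset - 1, end = sched$onset + 3)
    det <- detect_reactivations(traj, res$model, theta = theta, exclude = excl)
    res$trajectory_head <- head(traj, 1000)
    res$reactivations <- det
    stat$n_reactivations_detected <- nrow(det)
    if (nrow(det) >= 5) {
      ms <- reactivation_magnitude_stats(det, traj, exclude = excl,
                                         seed = child_seed(seed, "magstats"))
      res$magnitude_stats <- ms
      stat$reactivation_p <- ms$test$p_value
    }
    res$.traj <- traj
  }
  if ("shuffle" %in% stages && !is.null(res$patterns)) {
    shuf <- shuffle_pattern_units(res$patterns, seed = child_seed(seed, "shuffle"))
    cv_s <- cross_validate_mda(shuf, lambda = lambda, n_rep = max(50, n_cv %/% 4),
                               seed = child_seed(seed, "shufcv"))
    res$shuffle_cv <- cv_s
    res$shuffle_comparison <- shuffle_report(
      list(accuracy = mean(res$cv$accuracy)),
      list(accuracy = mean(cv_s$accuracy))
    )
    stat$shuffled_cv_accuracy <- mean(cv_s$accuracy)
  }
  if ("correlate" %in% stages && !is.null(res$reactivations) &&
      nrow(res$reactivations) >= 2) {
    periods <- make_period_windows(sched, res$reactivations,
                                   span = attr(pop$spikes, "span"),
                                   seed = child_seed(seed, "periods"))
    inv_units <- res$truth$unit_id[res$truth$responsive &
                                     res$truth$intensity_class == "invariant"]
    pc <- period_pair_correlations(pop$spikes, periods, units = inv_units)
    res$pair_correlations <- pc
    grp <- setNames(res$truth$selectivity_group, res$truth$unit_id)
    pc_grp <- pc |>
      mutate(ga = unname(grp[.data$unit_a]), gb = unname(grp[.data$unit_b])) |>
      filter(.data$ga == .data$gb) |>
      rename(selectivity_group = "ga") |>
      select(-"gb")
    res$period_stats <- period_correlation_stats(pc_grp)
    if ("ev" %in% stages) {
      res$ev <- explained_variance_report(filter_pairs(pc, 0.0))
      stat$ev <- res$ev$ev
      stat$ev_reversed <- res$ev$ev_reversed
    }
  }

  res$summary <- tibble(metric = names(stat), value = unlist(stat))
  res$.traj <- NULL
  class(res) <- "reverb_report"
  if (!is.null(out)) {
    jsonlite::write_json(list(version = 1L, seed = seed,
                              summary = as.data.frame(res$summary)),
                         out, auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.reverb_report <- function(x, ...) {
  cat("<reverb_report> seed =", x$seed, "\n")
  print(x$summary)
  invisible(x)
}
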