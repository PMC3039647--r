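#' Sliding-window subspace trajectory
#'
#' Projects population activity through a fitted MDA model with a sliding
#' window: at every step `t` (default 10 ms) the two 500-ms-bin rate vector
#' covering `[t, t + 0.5)` and `[t + 0.5, t + 1)` is projected with the
#' model's fixed coefficients. When the model has a rest class, each sample
#' also carries its Mahalanobis distance from the rest centroid
#' (`rest_distance`) and the coverage-calibrated score
#' `rest_score = (rest_distance - mu_rest) / sd_rest`, where `mu_rest` and
#' `sd_rest` are the mean and SD of the training rest samples' distances.
#' Under stationary baseline activity about 95% of samples score below 2.
#'
#' @param spikes Tibble `unit_id`, `time`. Must contain exactly the units the
#'   model was fitted on (same ordering is enforced internally).
#' @param model An `"mda_model"` from [fit_mda()].
#' @param t_start,t_end Scan span (s); the last window starts at
#'   `t_end - window`.
#' @param step Step size (s, default 0.01).
#' @return A tibble of class `"ensemble_trajectory"`: `time` (window start),
#'   `lda_1..lda_d`, `rest_distance`, `rest_score`; attributes `step`,
#'   `window`, `model_classes`.
#' @export
sliding_projection <- function(spikes, model, t_start = NULL, t_end = NULL,
                               step = 0.01) {
  stopifnot(inherits(model, "mda_model"))
  spikes <- check_spikes(spikes)
  if (is.null(model$units)) {
    abort("Model carries no unit set; fit it from labelled spike patterns.",
          class = "reverb_bad_input")
  }
  have <- unique(spikes$unit_id)
  if (!all(model$units %in% have)) {
    missing_units <- setdiff(model$units, have)
    # silent units are legal (zero spikes); only unknown extra units are not
    if (length(setdiff(have, model$units))) {
      abort("Spike data contain units the model was not fitted on.",
            class = "reverb_unit_mismatch")
    }
  } else if (length(setdiff(have, model$units))) {
    abort("Spike data contain units the model was not fitted on.",
          class = "reverb_unit_mismatch")
  }
  bw <- model$geom$bin_width
  nb <- model$geom$n_bins
  if (!is.finite(bw)) abort("Model was not fitted on binned spike patterns.",
                            class = "reverb_bad_input")
  win <- bw * nb
  span <- recording_span(spikes)
  t_start <- t_start %||% span[1]
  t_end <- t_end %||% span[2]
  if (t_end - win <= t_start) abort("Scan span shorter than the window.",
                                    class = "reverb_bad_input")
  # all bin edges live on the step grid when bw is a multiple of step
  ratio <- bw / step
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("`step` must divide the model's bin width.", class = "reverb_bad_input")
  }
  ratio <- as.integer(round(ratio))
  grid <- seq(t_start, t_end, by = step)
  n_starts <- length(grid) - nb * ratio
  if (n_starts < 1) abort("Scan span shorter than the window.", class = "reverb_bad_input")

  times_by_unit <- split(spikes$time, factor(spikes$unit_id, levels = model$units))
  cum <- purrr::map(times_by_unit, function(tt) {
    findInterval(grid, tt %||% numeric(), left.open = TRUE)
  })

  d <- model$d
  nu <- length(model$units)
  z <- matrix(0, n_starts, d)
  chunk <- max(1L, floor(8e6 / (nu * nb)))
  i0 <- 1L
  while (i0 <= n_starts) {
    i1 <- min(i0 + chunk - 1L, n_starts)
    rows <- i0:i1
    feat <- matrix(0, length(rows), nu * nb)
    for (u in seq_len(nu)) {
      cu <- cum[[u]]
      for (b in seq_len(nb)) {
        feat[, (u - 1) * nb + b] <-
          (cu[rows + b * ratio] - cu[rows + (b - 1) * ratio]) / bw
      }
    }
    colnames(feat) <- model$feature_names
    z[rows, ] <- project_patterns(model, feat)
    i0 <- i1 + 1L
  }

  out <- as_tibble(as.data.frame(z))
  names(out) <- paste0("lda_", seq_len(d))
  out <- dplyr::bind_cols(tibble(time = grid[seq_len(n_starts)]), out)
  if ("rest" %in% model$classes) {
    dr <- sqrt(mahalanobis(z, model$class_means["rest", ], model$class_cov[["rest"]]))
    out$rest_distance <- dr
    cal <- model$rest_cal
    out$rest_score <- (dr - cal$mean) / cal$sd
  }
  attr(out, "step") <- step
  attr(out, "window") <- win
  attr(out, "model_classes") <- model$classes
  class(out) <- c("ensemble_trajectory", class(out))
  out
}

#' Detect putative pattern reactivations in a trajectory
#'
#' Flags epochs where the rest-normalized trajectory score exceeds `theta`
#' for at least `min_duration` seconds outside the event-stimulation windows.
#' Runs separated by gaps shorter than `merge_gap` are merged. Each candidate
#' is assigned the nearest non-rest class (by Mahalanobis distance at the
#' peak) as its target and is kept only if the trajectory actually moved
#' toward that target (nearer at the peak than at the start of the run).
#'
#' @param trajectory An [sliding_projection()] result.
#' @param model The `"mda_model"` the trajectory was computed with.
#' @param theta Detection threshold in rest SDs (default 2).
#' @param min_duration Minimum epoch duration (s, default 0.05).
#' @param merge_gap Maximum gap merged into one epoch (s, default 0.1).
#' @param exclude Tibble `start`, `end` of time windows excluded from
#'   detection (typically `[onset - 1, onset + 3)` around each event).
#' @return Tibble: `start`, `end`, `duration`, `time` (peak), `peak_score`,
#'   `peak_distance`, `target`, `target_distance`.
#' @export
detect_reactivations <- function(trajectory, model, theta = 2,
                                 min_duration = 0.05, merge_gap = 0.1,
                                 exclude = NULL) {
  stopifnot(inherits(trajectory, "ensemble_trajectory"),
            "rest_score" %in% names(trajectory))
  step <- attr(trajectory, "step")
  ok <- trajectory$rest_score >= theta
  if (!is.null(exclude) && nrow(exclude)) {
    masked <- rep(FALSE, nrow(trajectory))
    for (i in seq_len(nrow(exclude))) {
      masked <- masked | (trajectory$time + attr(trajectory, "window") > exclude$start[i] &
                            trajectory$time < exclude$end[i])
    }
    ok[masked] <- FALSE
  }
  empty <- tibble(start = numeric(), end = numeric(), duration = numeric(),
                  time = numeric(), peak_score = numeric(),
                  peak_distance = numeric(), target = character(),
                  target_distance = numeric())
  if (!any(ok)) return(empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble(i0 = starts[r$values], i1 = ends[r$values])
  # merge runs separated by < merge_gap
  if (nrow(runs) > 1) {
    gap_steps <- (runs$i0[-1] - runs$i1[-nrow(runs)] - 1) * step
    grpid <- cumsum(c(1, gap_steps >= merge_gap))
    runs <- runs |>
      mutate(grp = grpid) |>
      group_by(.data$grp) |>
      summarise(i0 = min(.data$i0), i1 = max(.data$i1), .groups = "drop")
  }
  runs <- runs |>
    mutate(duration = (.data$i1 - .data$i0 + 1) * step) |>
    filter(.data$duration >= min_duration)
  if (!nrow(runs)) return(empty)

  zcols <- grep("^lda_", names(trajectory))
  zmat <- as.matrix(trajectory[, zcols])
  score <- trajectory$rest_score
  other <- setdiff(model$classes, "rest")
  res <- purrr::map(seq_len(nrow(runs)), function(k) {
    sl <- runs$i0[k]:runs$i1[k]
    pk <- sl[which.max(score[sl])]
    zpk <- zmat[pk, ]
    z0 <- zmat[runs$i0[k], ]
    dists <- vapply(other, function(cl) {
      sqrt(mahalanobis(matrix(zpk, 1), model$class_means[cl, ],
                       model$class_cov[[cl]]))
    }, numeric(1))
    d0 <- vapply(other, function(cl) {
      sqrt(mahalanobis(matrix(z0, 1), model$class_means[cl, ],
                       model$class_cov[[cl]]))
    }, numeric(1))
    approached <- dists < d0
    if (!any(approached)) return(NULL)   # excursion not directed at any cluster
    tgt <- other[approached][which.min(dists[approached])]
    tibble(start = trajectory$time[runs$i0[k]],
           end = trajectory$time[runs$i1[k]] + step,
           duration = runs$duration[k],
           time = trajectory$time[pk],
           peak_score = trajectory$rest_score[pk],
           peak_distance = trajectory$rest_distance[pk],
           target = tgt, target_distance = unname(dists[tgt]))
  })
  out <- bind_rows(res)
  if (!nrow(out)) empty else out
}

#' Subpopulation encoding subspace and trajectory
#'
#' Refits the MDA model using only the units of one taxonomic subpopulation
#' (all responsive, intensity-invariant, or intensity-sensitive units) and
#' computes the sliding-window trajectory in that subspace. Disjoint
#' subpopulations yield fully independent trajectories.
#'
#' @param spikes Tibble `unit_id`, `time`.
#' @param events Event schedule.
#' @param taxonomy Per-unit tibble with `unit_id`, `responsive`,
#'   `intensity_class` (e.g. `characterize_units()$units` or generator truth).
#' @param subpop `"all"`, `"invariant"` or `"sensitive"` (responsive units
#'   only in every case).
#' @param lambda Shrinkage intensity for the refit.
#' @param min_units Minimum subpopulation size (default 10).
#' @param seed Seed (rest-window placement).
#' @param t_start,t_end,step Passed to [sliding_projection()].
#' @return List of class `"subspace_projection"`: `model`, `trajectory`,
#'   `units`, `subpop`.
#' @export
subpopulation_projection <- function(spikes, events, taxonomy,
                                     subpop = c("all", "invariant", "sensitive"),
                                     lambda = 0.5, min_units = 10, seed = NULL,
                                     t_start = NULL, t_end = NULL, step = 0.01) {
  subpop <- match.arg(subpop)
  spikes <- check_spikes(spikes)
  resp <- dplyr::filter(taxonomy, .data$responsive)
  units <- switch(subpop,
                  all = resp$unit_id,
                  invariant = resp$unit_id[resp$intensity_class == "invariant"],
                  sensitive = resp$unit_id[startsWith(resp$intensity_class, "sensitive")])
  if (length(units) < min_units) {
    abort(sprintf("Subpopulation `%s` has only %d units (need >= %d).",
                  subpop, length(units), min_units),
          class = "reverb_bad_input")
  }
  sub <- dplyr::filter(spikes, .data$unit_id %in% units)
  attr(sub, "span") <- attr(spikes, "span")
  pats <- make_labelled_patterns(sub, events, units = sort(units), seed = seed)
  model <- fit_mda(pats, lambda = lambda)
  traj <- sliding_projection(sub, model, t_start = t_start, t_end = t_end,
                             step = step)
  structure(list(model = model, trajectory = traj, units = sort(units),
                 subpop = subpop),
            class = "subspace_projection")
}

#' @export
print.subspace_projection <- function(x, ...) {
  cat(sprintf("<subspace_projection> subpop = %s (%d units), %d trajectory samples\n",
              x$subpop, length(x$units), nrow(x$trajectory)))
  invisible(x)
}

#' Peak trajectory excursions inside given windows
#'
#' For each half-open time window, finds the trajectory sample with the
#' maximal rest-normalized score. Used to measure, in one subpopulation's
#' encoding subspace, the magnitude of reactivations detected in another
#' (e.g. the full-population) subspace.
#'
#' @param trajectory An [sliding_projection()] result.
#' @param windows Tibble `start`, `end`.
#' @return Tibble `start`, `end`, `time` (peak), `peak_distance`,
#'   `peak_score`; windows without trajectory samples are dropped.
#' @export
peak_in_windows <- function(trajectory, windows) {
  stopifnot(inherits(trajectory, "ensemble_trajectory"))
  tt <- trajectory$time
  lo <- findInterval(windows$start, tt, left.open = TRUE) + 1L
  hi <- findInterval(windows$end, tt, left.open = TRUE)
  res <- purrr::map(seq_len(nrow(windows)), function(i) {
    if (hi[i] < lo[i]) return(NULL)
    sl <- lo[i]:hi[i]
    pk <- sl[which.max(trajectory$rest_score[sl])]
    tibble(start = windows$start[i], end = windows$end[i],
           time = tt[pk],
           peak_distance = trajectory$rest_distance[pk],
           peak_score = trajectory$rest_score[pk])
  })
  bind_rows(res)
}

#' Reactivation magnitude statistics
#'
#' Compares the rest-normalized peak distances of reactivation windows
#' against the peak distances of matched baseline windows of the same
#' length, drawn at random non-reactivation times of the same scan
#' (excluding event windows), with a Mann-Whitney rank test. Matching the
#' window length matters: the maximum over a window is biased upward, so
#' single-sample baselines would overstate significance. When detected
#' events carry a `target` class, per-target magnitude means are reported as
#' well.
#'
#' @param reactivations A [detect_reactivations()] tibble, or any tibble with
#'   `start`, `end`, `peak_distance` (e.g. from [peak_in_windows()]).
#' @param trajectory The trajectory scanned.
#' @param exclude Event windows excluded when drawing baseline windows.
#' @param n_baseline Number of matched baseline windows (default
#'   `max(100, n events)`).
#' @param seed Seed for the baseline draw.
#' @return List of class `"reactivation_stats"`: `test` (one-row tibble with
#'   `n_events`, `mean_peak`, `mean_baseline`, `p_value`), `by_level`
#'   (per-target summary), `baseline_distances`.
#' @export
reactivation_magnitude_stats <- function(reactivations, trajectory,
                                         exclude = NULL, n_baseline = NULL,
                                         seed = NULL) {
  stopifnot(inherits(trajectory, "ensemble_trajectory"))
  n_ev <- nrow(reactivations)
  if (n_ev < 5) {
    warn("Fewer than 5 reactivation events; the magnitude test is underpowered.")
  }
  n_baseline <- n_baseline %||% max(100L, n_ev)
  mask <- rep(TRUE, nrow(trajectory))
  if (!is.null(exclude) && nrow(exclude)) {
    for (i in seq_len(nrow(exclude))) {
      mask <- mask & !(trajectory$time + attr(trajectory, "window") > exclude$start[i] &
                         trajectory$time < exclude$end[i])
    }
  }
  for (i in seq_len(n_ev)) {
    mask <- mask & !(trajectory$time >= reactivations$start[i] - 1 &
                       trajectory$time < reactivations$end[i] + 1)
  }
  wlen <- mean(reactivations$end - reactivations$start)
  step <- attr(trajectory, "step")
  k <- as.integer(ceiling(wlen / step))
  cm <- cumsum(mask)
  pool <- which(mask)
  pool <- pool[pool + k <= nrow(trajectory)]
  # keep only windows lying entirely in unmasked time
  pool <- pool[cm[pool + k] - cm[pool] == k]
  base <- with_seed(seed, {
    starts <- trajectory$time[sample(pool, min(n_baseline, length(pool)))]
    bw <- tibble(start = starts, end = starts + wlen)
    peak_in_windows(trajectory, bw)$peak_distance
  })
  p <- if (n_ev >= 1) {
    suppressWarnings(wilcox.test(reactivations$peak_distance, base,
                                 alternative = "greater", exact = FALSE)$p.value)
  } else NA_real_
  by_level <- if ("target" %in% names(reactivations)) {
    reactivations |>
      group_by(.data$target) |>
      summarise(n = dplyr::n(), mean_peak = mean(.data$peak_distance),
                sd_peak = sd(.data$peak_distance), .groups = "drop")
  } else {
    tibble(target = character(), n = integer(), mean_peak = numeric(),
           sd_peak = numeric())
  }
  structure(list(
    test = tibble(n_events = n_ev, mean_peak = mean(reactivations$peak_distance),
                  mean_baseline = mean(base), p_value = p),
    by_level = by_level,
    baseline_distances = base
  ), class = "reactivation_stats")
}

#' @export
print.reactivation_stats <- function(x, ...) {
  t <- x$test
  cat(sprintf("<reactivation_stats> %d events, peak %.2f vs baseline %.2f (p = %.3g)\n",
              t$n_events, t$mean_peak, t$mean_baseline, t$p_value))
  invisible(x)
}
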