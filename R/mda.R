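#' Build class-labelled population patterns from spikes
#'
#' Extracts one pattern vector per event instance: the concatenated firing
#' rates of every unit in the two 500-ms bins immediately after the event
#' onset (`2 * n_units` features). Rest patterns are drawn from randomly
#' positioned baseline windows of the same width, one per event instance by
#' default, and labelled `"rest"`. Parametric event types are labelled
#' `type_level` (e.g. `drop_3`) so each intensity level forms its own class.
#'
#' @param spikes Tibble `unit_id`, `time`.
#' @param events Event schedule.
#' @param bin_width,n_bins Pattern bin geometry (defaults 0.5 s x 2).
#' @param n_rest Number of rest patterns (default: one per event).
#' @param split_levels Label parametric types per level (default TRUE).
#' @param units Optional unit id vector fixing the feature order.
#' @param seed Seed for the rest-window placement.
#' @param span Optional recording span.
#' @return A list of class `"labelled_patterns"`: `x` (samples x features
#'   matrix), `labels` (factor, `"rest"` first), `units`, `meta` (per-sample
#'   tibble with window start), `bin_width`, `n_bins`.
#' @export
make_labelled_patterns <- function(spikes, events, bin_width = 0.5, n_bins = 2,
                                   n_rest = NULL, split_levels = TRUE,
                                   units = NULL, seed = NULL, span = NULL) {
  spikes <- check_spikes(spikes)
  events <- check_schedule(events)
  units <- units %||% sort(unique(spikes$unit_id))
  span <- span %||% recording_span(spikes, events)
  win <- bin_width * n_bins
  n_rest <- n_rest %||% nrow(events)

  with_seed(seed, {
    free <- baseline_intervals(events, span = span, exclude_before = win + 0.5,
                               exclude_after = 3)
    rest <- sample_baseline_windows(free, n_rest, win)
    starts <- c(events$onset, rest$start)
    lab <- c(if (split_levels) pattern_label(events$event, events$level, events) else events$event,
             rep("rest", n_rest))
    x <- pattern_matrix(spikes, units, starts, bin_width, n_bins)
    labels <- factor(lab, levels = c("rest", sort(setdiff(unique(lab), "rest"))))
    structure(list(x = x, labels = labels, units = units,
                   meta = tibble(start = starts, label = lab),
                   bin_width = bin_width, n_bins = n_bins),
              class = "labelled_patterns")
  })
}

pattern_label <- function(event, level, events) {
  multi <- events |>
    group_by(.data$event) |>
    summarise(multi = dplyr::n_distinct(.data$level) > 1, .groups = "drop")
  ml <- setNames(multi$multi, multi$event)
  ifelse(ml[event], paste0(event, "_", level), event)
}

# samples x (2 * n_units) rate matrix; feature order u1_b1, u1_b2, u2_b1, ...
pattern_matrix <- function(spikes, units, starts, bin_width, n_bins) {
  times_by_unit <- split(spikes$time, factor(spikes$unit_id, levels = units))
  edges <- rep(starts, each = n_bins) + bin_width * (seq_len(n_bins) - 1)
  cols <- purrr::map(units, function(u) {
    cnt <- count_in_windows(times_by_unit[[u]] %||% numeric(), edges, edges + bin_width)
    matrix(cnt / bin_width, ncol = n_bins, byrow = TRUE)
  })
  x <- do.call(cbind, cols)
  colnames(x) <- paste0(rep(units, each = n_bins), "_b", rep(seq_len(n_bins), length(units)))
  x
}

#' @export
print.labelled_patterns <- function(x, ...) {
  cat(sprintf("<labelled_patterns> %d samples x %d features, classes: %s\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s(%d)", levels(x$labels), table(x$labels)), collapse = " ")))
  invisible(x)
}

#' Simulate Gaussian class patterns with matched population rate
#'
#' Direct Gaussian pattern fixture for classifier studies: `n_classes` class
#' means are orthonormal zero-sum contrast vectors scaled so every pair of
#' means is `separation` noise standard deviations apart, plus unit-variance
#' Gaussian noise. Because the means are zero-sum and of equal norm, all
#' classes share the same population-summed rate and second moments, so any
#' unit-identity shuffle renders them indistinguishable to a linear readout.
#'
#' @param n_classes Number of classes.
#' @param n_per_class Samples per class.
#' @param n_features Feature dimension (must exceed `n_classes`).
#' @param separation Pairwise class-mean distance in noise SDs.
#' @param seed Seed.
#' @return A `"labelled_patterns"` object (classes `c1..cK`).
#' @export
simulate_labelled_patterns <- function(n_classes = 5, n_per_class = 8,
                                       n_features = 40, separation = 6,
                                       seed = NULL) {
  stopifnot(n_features > n_classes)
  with_seed(seed, {
    h <- stats::contr.helmert(n_classes + 1)   # (n_classes+1) x n_classes, zero-sum cols
    e <- apply(h, 2, function(v) v / sqrt(sum(v^2)))
    means <- matrix(0, n_classes, n_features)
    means[, seq_len(n_classes + 1)] <- t(e) * separation / sqrt(2)
    lab <- factor(rep(paste0("c", seq_len(n_classes)), each = n_per_class))
    x <- means[rep(seq_len(n_classes), each = n_per_class), ] +
      matrix(rnorm(n_classes * n_per_class * n_features), n_classes * n_per_class)
    colnames(x) <- paste0(sprintf("u%03d", seq_len(n_features)), "_b1")
    structure(list(x = x, labels = lab,
                   units = sprintf("u%03d", seq_len(n_features)),
                   meta = tibble(start = NA_real_, label = as.character(lab)),
                   bin_width = NA_real_, n_bins = 1L),
              class = "labelled_patterns")
  })
}

#' Shuffle unit identity within each pattern
#'
#' Applies an independent random permutation of the per-unit feature blocks
#' to every pattern vector, destroying the unit-to-activity correspondence
#' while preserving each sample's population rate. This is the pattern-level
#' unit-identity shuffle used to demonstrate classification collapse.
#'
#' @param patterns A `"labelled_patterns"` object.
#' @param seed Seed.
#' @return A shuffled `"labelled_patterns"` object.
#' @export
shuffle_pattern_units <- function(patterns, seed = NULL) {
  stopifnot(inherits(patterns, "labelled_patterns"))
  nb <- patterns$n_bins
  nu <- length(patterns$units)
  with_seed(seed, {
    x <- patterns$x
    for (i in seq_len(nrow(x))) {
      p <- sample.int(nu)
      cols <- as.vector(outer(seq_len(nb), (p - 1) * nb, `+`))
      x[i, ] <- x[i, cols]
    }
    patterns$x <- x
    patterns
  })
}

#' Between- and within-class scatter matrices
#'
#' `S_B = sum_i n_i (m_i - m)(m_i - m)^t` and
#' `S_W = sum_i sum_{x in D_i} (x - m_i)(x - m_i)^t`, with `m_i` the class
#' means and `m` the global mean. Their traces decompose the total scatter.
#'
#' @param x Samples x features matrix.
#' @param labels Factor of class labels (each class needs >= 2 samples).
#' @return List `s_b`, `s_w`, `class_means` (classes x features), `global_mean`,
#'   `n_i`, `omega` (list of per-class covariance matrices `S_W_i / n_i`).
#' @export
compute_scatter <- function(x, labels) {
  labels <- droplevels(as.factor(labels))
  n_i <- table(labels)
  if (any(n_i < 2)) {
    abort("Every class needs at least 2 samples.", class = "reverb_bad_input")
  }
  p <- ncol(x)
  m <- colMeans(x)
  cls <- levels(labels)
  class_means <- matrix(0, length(cls), p, dimnames = list(cls, colnames(x)))
  s_b <- matrix(0, p, p)
  s_w <- matrix(0, p, p)
  omega <- vector("list", length(cls))
  names(omega) <- cls
  for (k in seq_along(cls)) {
    xi <- x[labels == cls[k], , drop = FALSE]
    mi <- colMeans(xi)
    class_means[k, ] <- mi
    d <- mi - m
    s_b <- s_b + nrow(xi) * tcrossprod(d)
    ci <- sweep(xi, 2, mi)
    swi <- crossprod(ci)
    s_w <- s_w + swi
    omega[[k]] <- swi / nrow(xi)
  }
  list(s_b = s_b, s_w = s_w, class_means = class_means, global_mean = m,
       n_i = as.vector(n_i), omega = omega)
}

#' Shrinkage-regularized within-class scatter
#'
#' Shrinks every class covariance toward (a scaled) identity,
#' `Omega_i' = (1 - lambda) Omega_i + lambda * c_i * I`, and reassembles
#' `S_W' = sum_i n_i Omega_i'`. With `scale = "mean_diag"` (default) the
#' identity is scaled by the mean diagonal of `Omega_i`, so the shrinkage
#' target respects the units of the data; `scale = "identity"` uses the plain
#' identity. `lambda = 0` returns `S_W` unchanged; `lambda = 1` replaces every
#' class covariance by its (scaled) identity.
#'
#' @param omega List of per-class covariance matrices.
#' @param lambda Shrinkage intensity in \[0, 1\].
#' @param n_i Class sample sizes (weights).
#' @param scale `"mean_diag"` or `"identity"`.
#' @return List `s_w_reg` (regularized scatter), `omega_reg` (shrunk per-class
#'   covariances).
#' @export
regularize_within <- function(omega, lambda, n_i, scale = c("mean_diag", "identity")) {
  scale <- match.arg(scale)
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    abort("`lambda` must lie in [0, 1].", class = "reverb_bad_input")
  }
  p <- nrow(omega[[1]])
  global_scale <- mean(vapply(omega, function(o) mean(diag(o)), numeric(1)))
  omega_reg <- purrr::map(omega, function(o) {
    ci <- if (scale == "mean_diag") {
      s <- mean(diag(o))
      if (s <= 0) max(global_scale, 1e-8) else s
    } else 1
    (1 - lambda) * o + lambda * ci * diag(p)
  })
  s_w_reg <- Reduce(`+`, purrr::map2(omega_reg, n_i, `*`))
  list(s_w_reg = s_w_reg, omega_reg = omega_reg)
}

#' Fit a regularized multiple discriminant model
#'
#' Computes the discriminant basis as the leading eigenvectors of
#' `S_W'^{-1} S_B` (at most `N - 1` for `N` classes, limited by the rank of
#' `S_B`), solving the generalized problem in symmetrized form via the
#' Cholesky factor of `S_W'` for numerical stability. Class distributions in
#' the subspace are modelled as Gaussians (mean + covariance, the covariance
#' shrunk toward its mean-diagonal identity with the same `lambda`). If a
#' `"rest"` class is present, the model also stores the calibration of rest
#' Mahalanobis distances (mean and SD over training rest samples) used for
#' rest-normalized trajectory scores.
#'
#' @param patterns A `"labelled_patterns"` object, or a matrix (then `labels`
#'   must be given).
#' @param labels Class labels when `patterns` is a matrix.
#' @param lambda Shrinkage intensity in \[0, 1\].
#' @param shrink_scale Passed to [regularize_within()].
#' @return An object of class `"mda_model"`.
#' @export
fit_mda <- function(patterns, labels = NULL, lambda = 0.5,
                    shrink_scale = c("mean_diag", "identity")) {
  shrink_scale <- match.arg(shrink_scale)
  if (inherits(patterns, "labelled_patterns")) {
    x <- patterns$x
    labels <- patterns$labels
    units <- patterns$units
    geom <- list(bin_width = patterns$bin_width, n_bins = patterns$n_bins)
  } else {
    x <- as.matrix(patterns)
    if (is.null(labels)) abort("`labels` required when `patterns` is a matrix.",
                               class = "reverb_bad_input")
    units <- NULL
    geom <- list(bin_width = NA_real_, n_bins = 1L)
  }
  if (!all(is.finite(x))) abort("Patterns contain non-finite values.",
                                class = "reverb_bad_input")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- droplevels(as.factor(labels))
  keep <- which(apply(x, 2, function(col) any(col != 0)))
  if (!length(keep)) abort("All feature columns are zero.", class = "reverb_bad_input")
  xk <- x[, keep, drop = FALSE]

  sc <- compute_scatter(xk, labels)
  reg <- regularize_within(sc$omega, lambda, sc$n_i, scale = shrink_scale)
  sw <- reg$s_w_reg
  if (lambda == 0) {
    # may be singular; fall back to a tiny ridge so the contract at
    # lambda = 0 remains the naive S_W
    ridge <- 1e-8 * mean(diag(sw))
    sw <- sw + ridge * diag(ncol(sw))
  }
  ch <- tryCatch(chol(sw), error = function(e) {
    abort("Regularized within-class scatter is not positive definite; increase `lambda`.",
          class = "reverb_numeric_error")
  })
  # M = R^{-t} S_B R^{-1}, symmetric; generalized eigvecs W = R^{-1} U
  y <- backsolve(ch, sc$s_b, transpose = TRUE)
  m <- backsolve(ch, t(y), transpose = TRUE)
  m <- (m + t(m)) / 2
  es <- eigen(m, symmetric = TRUE)
  n_classes <- nlevels(labels)
  tol <- max(es$values) * 1e-10
  d <- min(n_classes - 1, sum(es$values > max(tol, 0)))
  d <- max(d, 1)
  w <- backsolve(ch, es$vectors[, seq_len(d), drop = FALSE])
  # deterministic orientation and unit norm
  w <- apply(w, 2, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  w <- matrix(w, ncol = d)
  rownames(w) <- colnames(xk)

  center <- sc$global_mean
  z <- sweep(xk, 2, center) %*% w
  colnames(z) <- paste0("lda_", seq_len(d))
  cls <- levels(labels)
  class_means <- matrix(0, length(cls), d, dimnames = list(cls, colnames(z)))
  class_cov <- vector("list", length(cls))
  names(class_cov) <- cls
  for (k in cls) {
    zi <- z[labels == k, , drop = FALSE]
    class_means[k, ] <- colMeans(zi)
    cv <- cov(zi)
    s <- mean(diag(cv))
    if (!is.finite(s) || s <= 0) s <- 1e-8
    class_cov[[k]] <- (1 - lambda) * cv + max(lambda, 0.05) * s * diag(d)
  }

  rest_cal <- NULL
  if ("rest" %in% cls) {
    zr <- z[labels == "rest", , drop = FALSE]
    # leave-one-out distances: the in-sample distribution underestimates the
    # out-of-sample null that sliding-window scores are compared against
    dr <- if (nrow(zr) >= 10) {
      vapply(seq_len(nrow(zr)), function(i) {
        zi <- zr[-i, , drop = FALSE]
        cv <- cov(zi)
        s <- mean(diag(cv)); if (!is.finite(s) || s <= 0) s <- 1e-8
        cv <- (1 - lambda) * cv + max(lambda, 0.05) * s * diag(d)
        sqrt(mahalanobis(zr[i, , drop = FALSE], colMeans(zi), cv))
      }, numeric(1))
    } else {
      sqrt(mahalanobis(zr, class_means["rest", ], class_cov[["rest"]]))
    }
    rest_cal <- list(mean = mean(dr), sd = max(sd(dr), 1e-8),
                     scalar_sd = sqrt(mean(diag(class_cov[["rest"]]))))
  }

  structure(list(
    basis = w, eigenvalues = es$values[seq_len(d)], center = center,
    keep = keep, feature_names = colnames(x), units = units,
    lambda = lambda, shrink_scale = shrink_scale,
    classes = cls, class_means = class_means, class_cov = class_cov,
    n_i = sc$n_i, rest_cal = rest_cal, d = d, geom = geom,
    scatter = list(s_b = sc$s_b, s_w = sc$s_w, s_w_reg = reg$s_w_reg)
  ), class = "mda_model")
}

#' @export
print.mda_model <- function(x, ...) {
  cat(sprintf("<mda_model> %d classes, %d discriminant dims, lambda = %.2f\n",
              length(x$classes), x$d, x$lambda))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Recalibrate the rest-distance null against fresh baseline windows
#'
#' The rest-distance calibration stored by [fit_mda()] is estimated from the
#' training rest samples, which the discriminant basis itself was fitted on;
#' for sliding-window scans the proper null is the distance distribution of
#' *fresh* baseline windows. This draws `n` new randomly placed baseline
#' windows (excluding event vicinities), projects them, and replaces the
#' model's rest-distance mean and SD, so that a rest-normalized score of 2
#' again corresponds to ~2 SDs above the typical out-of-sample baseline
#' distance.
#'
#' @param model An `"mda_model"` fitted with a rest class from spike patterns.
#' @param spikes The spike data the model will scan (same unit set).
#' @param events Event schedule whose windows are excluded.
#' @param n Number of calibration windows (default 500).
#' @param seed Seed.
#' @param span Optional recording span.
#' @return The model with an updated `rest_cal`.
#' @export
calibrate_rest <- function(model, spikes, events, n = 500, seed = NULL,
                           span = NULL) {
  stopifnot(inherits(model, "mda_model"), "rest" %in% model$classes)
  spikes <- check_spikes(spikes)
  events <- check_schedule(events)
  span <- span %||% recording_span(spikes, events)
  win <- model$geom$bin_width * model$geom$n_bins
  with_seed(seed, {
    free <- baseline_intervals(events, span = span, exclude_before = win + 0.5,
                               exclude_after = 3)
    w <- sample_baseline_windows(free, n, win)
    x <- pattern_matrix(spikes, model$units, w$start,
                        model$geom$bin_width, model$geom$n_bins)
    z <- project_patterns(model, x)
    dr <- sqrt(mahalanobis(z, model$class_means["rest", ],
                           model$class_cov[["rest"]]))
    model$rest_cal$mean <- mean(dr)
    model$rest_cal$sd <- max(sd(dr), 1e-8)
    model
  })
}

#' Project pattern vectors into the discriminant subspace
#'
#' @param model An `"mda_model"`.
#' @param x Matrix (or single vector) in the model's full feature space.
#' @return Matrix of subspace coordinates.
#' @export
project_patterns <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$feature_names)) {
    abort(sprintf("Expected %d features, got %d.",
                  length(model$feature_names), ncol(x)),
          class = "reverb_dim_error")
  }
  sweep(x[, model$keep, drop = FALSE], 2, model$center) %*% model$basis
}

#' Classify pattern vectors
#'
#' Assigns each pattern to the class with the smallest Mahalanobis distance
#' under its subspace Gaussian; equidistant ties go to the lowest class index
#' and are flagged. Distances from the rest centroid are reported in units of
#' the rest-cluster standard deviation when a rest class is present.
#'
#' @param model An `"mda_model"`.
#' @param x Matrix or vector of patterns (full feature space), or a
#'   `"labelled_patterns"` object.
#' @return Tibble with `class`, `tie`, `rest_distance` (Mahalanobis to the
#'   rest centroid, `NA` without a rest class) and one `dist_<class>` column
#'   per class.
#' @export
classify_patterns <- function(model, x) {
  if (inherits(x, "labelled_patterns")) x <- x$x
  z <- project_patterns(model, x)
  dmat <- vapply(model$classes, function(k) {
    sqrt(mahalanobis(z, model$class_means[k, ], model$class_cov[[k]]))
  }, numeric(nrow(z)))
  dmat <- matrix(dmat, nrow = nrow(z),
                 dimnames = list(NULL, paste0("dist_", model$classes)))
  idx <- apply(dmat, 1, which.min)
  mins <- dmat[cbind(seq_len(nrow(dmat)), idx)]
  tie <- apply(dmat, 1, function(r) sum(abs(r - min(r)) < 1e-12) > 1)
  rest <- if ("rest" %in% model$classes) {
    sqrt(mahalanobis(z, model$class_means["rest", ], model$class_cov[["rest"]]))
  } else rep(NA_real_, nrow(z))
  dplyr::bind_cols(
    tibble(class = model$classes[idx], tie = tie, min_distance = mins,
           rest_distance = rest),
    as_tibble(dmat)
  )
}

#' Rest-normalized distances of class centroids
#'
#' Mahalanobis distance of every non-rest class centroid from the rest
#' centroid under the rest-cluster covariance — the "distance from the rest
#' origin in rest SDs" summary used to compare cluster separations.
#'
#' @param model An `"mda_model"` fitted with a `"rest"` class.
#' @return Tibble `class`, `rest_distance`.
#' @export
cluster_rest_distances <- function(model) {
  stopifnot(inherits(model, "mda_model"), "rest" %in% model$classes)
  other <- setdiff(model$classes, "rest")
  d <- vapply(other, function(k) {
    sqrt(mahalanobis(matrix(model$class_means[k, ], 1),
                     model$class_means["rest", ], model$class_cov[["rest"]]))
  }, numeric(1))
  tibble(class = other, rest_distance = unname(d))
}

#' Cross-validate an MDA classifier
#'
#' Repeated random partitioning: in each repetition one sample per class is
#' held out, the model is refitted on the remainder, and the held-out samples
#' are classified. Reported accuracy is per repetition.
#'
#' @param patterns A `"labelled_patterns"` object.
#' @param lambda Shrinkage intensity.
#' @param n_rep Number of repetitions (default 1000).
#' @param holdout Held-out samples per class (default 1).
#' @param seed Seed.
#' @return An object of class `"mda_cv"`: tibble `rep`, `accuracy`, with
#'   attributes `n_classes`, `n_test`, `lambda`.
#' @export
cross_validate_mda <- function(patterns, lambda = 0.5, n_rep = 1000,
                               holdout = 1, seed = NULL) {
  stopifnot(inherits(patterns, "labelled_patterns"))
  labels <- droplevels(as.factor(patterns$labels))
  if (any(table(labels) < holdout + 2)) {
    abort("Every class needs at least `holdout` + 2 samples.", class = "reverb_bad_input")
  }
  idx_by_class <- split(seq_along(labels), labels)
  with_seed(seed, {
    acc <- vapply(seq_len(n_rep), function(r) {
      test <- unlist(purrr::map(idx_by_class, sample, size = holdout))
      fit <- fit_mda(patterns$x[-test, , drop = FALSE], labels[-test], lambda = lambda)
      pred <- classify_patterns(fit, patterns$x[test, , drop = FALSE])$class
      mean(pred == as.character(labels[test]))
    }, numeric(1))
    structure(tibble(rep = seq_len(n_rep), accuracy = acc),
              n_classes = nlevels(labels), n_test = nlevels(labels) * holdout,
              lambda = lambda, class = c("mda_cv", class(tibble())))
  })
}

#' Select the shrinkage intensity by cross-validation
#'
#' Grid search maximizing mean cross-validated accuracy; ties take the
#' smallest lambda.
#'
#' @param patterns A `"labelled_patterns"` object.
#' @param grid Candidate lambdas in \[0, 1\].
#' @param n_rep CV repetitions per candidate.
#' @param seed Seed (same partitions across candidates).
#' @return List `lambda` (the winner) and `path` (tibble `lambda`,
#'   `accuracy`).
#' @export
select_lambda <- function(patterns, grid = seq(0.1, 0.9, by = 0.2),
                          n_rep = 50, seed = NULL) {
  stopifnot(length(grid) >= 1, all(grid >= 0 & grid <= 1))
  grid <- sort(grid)
  acc <- vapply(grid, function(l) {
    mean(cross_validate_mda(patterns, lambda = l, n_rep = n_rep, seed = seed)$accuracy)
  }, numeric(1))
  best <- grid[which.max(acc)]   # which.max -> first (smallest) on ties
  list(lambda = best, path = tibble(lambda = grid, accuracy = acc))
}

#' @export
tidy.mda_model <- function(x, ...) {
  dplyr::bind_cols(tibble(class = x$classes, n = x$n_i),
                   as_tibble(x$class_means))
}

#' @export
glance.mda_model <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_dims = x$d, lambda = x$lambda,
         n_features = length(x$keep),
         eigenvalue_1 = x$eigenvalues[1])
}

#' @export
tidy.mda_cv <- function(x, ...) as_tibble(x)

#' @export
glance.mda_cv <- function(x, ...) {
  n <- nrow(x)
  m <- mean(x$accuracy)
  se <- sd(x$accuracy) / sqrt(n)
  tibble(mean_accuracy = m, se = se,
         ci_low = m - 1.96 * se, ci_high = m + 1.96 * se,
         chance = 1 / attr(x, "n_classes"),
         n_rep = n, lambda = attr(x, "lambda"))
}
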