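# Shared fixture builders. Everything is generated in code at test time.

# A small, fast configuration used across module tests.
tiny_config <- function(...) {
  simulation_config(
    n_units = 40,
    event_types = list(sound = 1L, drop = 1:3),
    baseline_s = 60, tail_s = 30,
    iti_s = c(20, 40),
    ...
  )
}

# One cached small population with injections (built lazily, reused within a file).
.fixture_env <- new.env(parent = emptyenv())
small_population <- function() {
  if (is.null(.fixture_env$pop)) {
    cfg <- tiny_config()
    sched <- build_schedule(cfg, seed = 101)
    pop <- generate_population(cfg, sched, seed = 102)
    .fixture_env$pop <- inject_reactivations(pop, seed = 103)
  }
  .fixture_env$pop
}

# Spike tibble from explicit times.
spikes_tbl <- function(...) {
  lst <- list(...)
  dplyr::bind_rows(purrr::imap(lst, function(tt, id) {
    tibble::tibble(unit_id = id, time = sort(tt))
  }))
}

# Homogeneous Poisson train on [0, t_end].
poisson_train <- function(rate, t_end, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, rate * t_end)
  sort(runif(n, 0, t_end))
}

# Adjusted Rand index (independent oracle for cluster agreement).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Brute-force centroid-linkage oracle: rescans every pairwise centroid
# distance at each step (O(N^3)), with the same lexicographic tie rule.
brute_force_centroid_merges <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), function(i) list(id = i, members = i))
  next_id <- n
  out <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        mi <- colMeans(x[clusters[[i]]$members, , drop = FALSE])
        mj <- colMeans(x[clusters[[j]]$members, , drop = FALSE])
        d <- sqrt(sum((mi - mj)^2))
        li <- min(clusters[[i]]$id, clusters[[j]]$id)
        ri <- max(clusters[[i]]$id, clusters[[j]]$id)
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (li < best$l || (li == best$l && ri < best$r)))) {
          best <- list(d = d, i = i, j = j, l = li, r = ri)
        }
      }
    }
    next_id <- next_id + 1
    out[[length(out) + 1]] <- c(left = best$l, right = best$r, dist = best$d)
    merged <- list(id = next_id,
                   members = c(clusters[[best$i]]$members,
                               clusters[[best$j]]$members))
    clusters <- clusters[-c(best$i, best$j)]
    clusters[[length(clusters) + 1]] <- merged
  }
  do.call(rbind, out)
}
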