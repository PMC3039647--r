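#' Agglomerative clustering of response vectors
#'
#' Centroid-linkage agglomeration of per-unit response vectors: start from one
#' cluster per vector, repeatedly merge the two clusters whose (re-computed)
#' mean vectors are closest in Euclidean distance, until one cluster remains.
#' Ties in the nearest-pair search are broken by the lexicographically
#' smallest (left id, right id) pair, making the merge sequence deterministic.
#' Note that centroid linkage can produce non-monotone merge distances; that
#' is expected.
#'
#' @param x Numeric matrix, one row per unit (e.g. [t_score_matrix()]),
#'   or a data frame of numeric columns with a `unit_id` column.
#' @return A list of class `"response_dendrogram"`: `merges` (tibble `step`,
#'   `left`, `right`, `distance`, `size`; leaves are ids `1..N`, merged
#'   clusters `N + step`), `labels` (row labels), `n`.
#' @export
#' @examples
#' m <- rbind(a = c(0, 0), b = c(0, 0.1), c = c(5, 5))
#' cluster_responses(m)$merges
cluster_responses <- function(x) {
  if (is.data.frame(x)) {
    ids <- if ("unit_id" %in% names(x)) x$unit_id else rownames(x)
    x <- as.matrix(dplyr::select(x, dplyr::where(is.numeric)))
    rownames(x) <- ids
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) abort("Response matrix contains missing values.", class = "reverb_bad_input")
  n <- nrow(x)
  labels <- rownames(x) %||% as.character(seq_len(n))
  if (n == 1) {
    return(structure(list(merges = tibble(step = integer(), left = integer(),
                                          right = integer(), distance = numeric(),
                                          size = integer()),
                          labels = labels, n = 1L),
                     class = "response_dendrogram"))
  }
  centers <- x
  sizes <- rep(1L, n)
  ids <- seq_len(n)          # current cluster id per active slot
  active <- rep(TRUE, n)
  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    dd <- d2
    dd[!active, ] <- Inf
    dd[, !active] <- Inf
    dd[lower.tri(dd, diag = TRUE)] <- Inf
    best <- min(dd)
    cand <- which(dd <= best + 1e-12, arr.ind = TRUE)
    # tie-break: smallest (left cluster id, right cluster id)
    key <- order(pmin(ids[cand[, 1]], ids[cand[, 2]]),
                 pmax(ids[cand[, 1]], ids[cand[, 2]]))[1]
    i <- cand[key, 1]; j <- cand[key, 2]
    li <- min(ids[i], ids[j]); ri <- max(ids[i], ids[j])
    new_size <- sizes[i] + sizes[j]
    new_center <- (sizes[i] * centers[i, ] + sizes[j] * centers[j, ]) / new_size
    merges[[step]] <- tibble(step = step, left = li, right = ri,
                             distance = sqrt(max(best, 0)), size = new_size)
    # slot i hosts the merged cluster; slot j retires
    centers[i, ] <- new_center
    sizes[i] <- new_size
    ids[i] <- n + step
    active[j] <- FALSE
    upd <- which(active & seq_len(n) != i)
    if (length(upd)) {
      di <- rowSums((centers[upd, , drop = FALSE] -
                       matrix(new_center, length(upd), ncol(centers), byrow = TRUE))^2)
      d2[i, upd] <- di
      d2[upd, i] <- di
    }
    d2[i, i] <- Inf
  }
  structure(list(merges = bind_rows(merges), labels = labels, n = n),
            class = "response_dendrogram")
}

#' @export
print.response_dendrogram <- function(x, ...) {
  cat(sprintf("<response_dendrogram> %d leaves, %d merges\n", x$n, nrow(x$merges)))
  invisible(x)
}

#' Leaf ordering for response heatmaps
#'
#' Orders the dendrogram leaves so that at every merge the two subtrees are
#' oriented to minimize the Euclidean distance between the adjacent boundary
#' leaves (the last leaf of the left block and the first leaf of the right
#' block). Ties prefer the unflipped orientation, so the order is
#' deterministic; for two leaves the lower id comes first.
#'
#' @param dendrogram A [cluster_responses()] result.
#' @param x The response matrix the dendrogram was built from.
#' @return Integer vector: permutation of `1..N` (row indices of `x`).
#' @export
order_leaves <- function(dendrogram, x) {
  stopifnot(inherits(dendrogram, "response_dendrogram"))
  if (is.data.frame(x)) x <- as.matrix(dplyr::select(x, dplyr::where(is.numeric)))
  n <- dendrogram$n
  if (n == 1) return(1L)
  seqs <- as.list(seq_len(n))          # leaf sequences per cluster id
  for (k in seq_len(nrow(dendrogram$merges))) {
    m <- dendrogram$merges[k, ]
    a <- seqs[[m$left]]; b <- seqs[[m$right]]
    d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
    cand <- list(c(tail(a, 1), head(b, 1)),       # a  b
                 c(tail(a, 1), tail(b, 1)),       # a  rev(b)
                 c(head(a, 1), head(b, 1)),       # rev(a) b
                 c(head(a, 1), tail(b, 1)))       # rev(a) rev(b)
    dd <- vapply(cand, function(p) d(p[1], p[2]), numeric(1))
    best <- which.min(dd)               # which.min takes the first on ties
    merged <- switch(best,
                     c(a, b),
                     c(a, rev(b)),
                     c(rev(a), b),
                     c(rev(a), rev(b)))
    seqs[[n + m$step]] <- merged
  }
  seqs[[n + nrow(dendrogram$merges)]]
}

#' Flat clusters from a dendrogram
#'
#' Cuts the merge sequence after `N - k` merges, yielding `k` clusters.
#'
#' @param dendrogram A [cluster_responses()] result.
#' @param k Number of clusters.
#' @return Integer vector of cluster memberships (1..k) per leaf.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "response_dendrogram"),
            k >= 1, k <= dendrogram$n)
  n <- dendrogram$n
  parent <- seq_len(n + n - 1)
  n_steps <- n - k
  if (n_steps > 0) {
    for (s in seq_len(n_steps)) {
      m <- dendrogram$merges[s, ]
      parent[m$left] <- n + m$step
      parent[m$right] <- n + m$step
    }
  }
  root_of <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  roots <- vapply(seq_len(n), root_of, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}
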