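# ggplot2 displays for the main result types.

#' Response heatmap ordered by the dendrogram
#'
#' Tile plot of the T-score matrix with units ordered general-to-specific by
#' [order_leaves()]. By convention only units with a positive maximal T are
#' displayed.
#'
#' @param rt A [response_table()].
#' @param dendrogram Optional [cluster_responses()] result (computed if
#'   missing).
#' @param positive_only Restrict the display to positively responding units.
#' @return A ggplot object.
#' @export
plot_response_heatmap <- function(rt, dendrogram = NULL, positive_only = TRUE) {
  m <- t_score_matrix(rt, positive_only = positive_only)
  if (is.null(dendrogram)) dendrogram <- cluster_responses(m)
  ord <- order_leaves(dendrogram, m)
  df <- as_tibble(m[ord, , drop = FALSE], rownames = "unit_id") |>
    mutate(unit_id = factor(.data$unit_id, levels = rev(rownames(m)[ord]))) |>
    tidyr::pivot_longer(-"unit_id", names_to = "event", values_to = "t_score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$event, y = .data$unit_id,
                                   fill = .data$t_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = "unit (general → specific)", fill = "T") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.mda_model <- function(object, dims = c(1, 2), sd_contour = 2, ...) {
  cm <- as_tibble(object$class_means, rownames = "class")
  dd <- paste0("lda_", dims)
  if (object$d < 2) {
    abort("Need at least 2 discriminant dimensions to plot.", class = "reverb_bad_input")
  }
  ell <- purrr::map(object$classes, function(k) {
    cv <- object$class_cov[[k]][dims, dims]
    mu <- object$class_means[k, dims]
    th <- seq(0, 2 * pi, length.out = 120)
    circ <- rbind(cos(th), sin(th)) * sd_contour
    ch <- chol(cv)
    pts <- t(t(ch) %*% circ + mu)
    tibble(class = k, x = pts[, 1], y = pts[, 2])
  }) |> bind_rows()
  ggplot2::ggplot() +
    ggplot2::geom_path(data = ell,
                       ggplot2::aes(x = .data$x, y = .data$y, colour = .data$class)) +
    ggplot2::geom_point(data = cm,
                        ggplot2::aes(x = .data[[dd[1]]], y = .data[[dd[2]]],
                                     colour = .data$class), size = 3) +
    ggplot2::labs(x = dd[1], y = dd[2],
                  title = sprintf("MDA subspace (%dσ contours)", sd_contour)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ensemble_trajectory <- function(object, theta = 2, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$rest_score)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = theta, linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "rest-normalized distance (SD)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mda_cv <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(binwidth = 1 / attr(object, "n_test"),
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = g$chance, linetype = "dashed") +
    ggplot2::labs(x = "held-out accuracy", y = "repetitions") +
    ggplot2::theme_minimal()
}
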