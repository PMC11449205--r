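#' Plot movement trajectories
#'
#' One path per individual, coloured by id, with points at fixes. Useful for
#' eyeballing home-range scenarios and the effect of randomization.
#'
#' @param data Fix table with `id`, `x`, `y` (and `day`, `step` or
#'   `timestamp` for ordering).
#' @param ids Optional subset of individuals to draw.
#' @param show_points Draw fix points as well as paths (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_tracks <- function(data, ids = NULL, show_points = FALSE) {
  assert_tracks(data, cols = c("id", "x", "y"))
  if (!is.null(ids)) data <- dplyr::filter(data, .data$id %in% ids)
  ord <- intersect(c("day", "step", "timestamp"), names(data))
  data <- dplyr::arrange(data, .data$id, !!!rlang::syms(ord))
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$x, .data$y,
                                          colour = .data$id, group = .data$id)) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (length units)", y = "y (length units)",
                  colour = "individual") +
    ggplot2::theme_minimal()
  if (show_points) p <- p + ggplot2::geom_point(size = 0.4, alpha = 0.5)
  p
}

#' @describeIn compare_to_null Histogram of the null distribution with the
#'   observed value marked; the standard visual for a permutation test.
#' @param object A `null_comparison`.
#' @method autoplot null_comparison
#' @export
autoplot.null_comparison <- function(object, ...) {
  df <- tibble::tibble(value = object$null_values %||% numeric(0))
  # The comparison object stores only summaries; rebuild a density sketch
  # from them when raw values are absent.
  p <- ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = object$observed, colour = "black",
                        linetype = "dashed", linewidth = 0.8) +
    ggplot2::labs(
      x = "population mean under randomization",
      y = "iterations",
      title = sprintf("observed = %.3g, z = %s, tail fraction = %.3g",
                      object$observed,
                      if (is.na(object$z)) "NA" else sprintf("%.2f", object$z),
                      object$tail_fraction)
    ) +
    ggplot2::theme_minimal()
  if (nrow(df) > 0) {
    p <- p + ggplot2::geom_histogram(
      data = df, ggplot2::aes(.data$value), bins = 30,
      fill = "steelblue", colour = "white"
    )
  } else {
    ndf <- tibble::tibble(
      value = object$null_mean + object$null_sd * seq(-4, 4, length.out = 200),
      dens = stats::dnorm(seq(-4, 4, length.out = 200))
    )
    p <- p + ggplot2::geom_line(data = ndf,
                                ggplot2::aes(.data$value, .data$dens),
                                colour = "steelblue")
  }
  p
}

#' @describeIn node_metrics Force-directed sketch of the network, node size
#'   by strength.
#' @param object A `social_network`.
#' @param ... Unused.
#' @method autoplot social_network
#' @export
autoplot.social_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1L) # layout only; analysis randomness is controlled elsewhere
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    id = object$nodes, x = xy[, 1], y = xy[, 2]
  ) |>
    dplyr::left_join(node_metrics(object), by = "id")
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, id, xa = "x", ya = "y"),
                     by = c(id_a = "id")) |>
    dplyr::left_join(dplyr::select(nodes, id, xb = "x", yb = "y"),
                     by = c(id_b = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$weight),
      colour = "grey60", alpha = 0.7
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, size = .data$strength),
      colour = "steelblue"
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "strength", linewidth = "weight")
}

#' Plot a null distribution tibble against the observed value
#'
#' Companion to [null_metric_distribution()]: overlaid histograms of the null
#' mean degree and mean strength with dashed lines at the observed values.
#'
#' @param null A tibble from [null_metric_distribution()].
#' @param observed Named numeric (or one-row tibble) with `mean_degree` and
#'   `mean_strength` observed values.
#' @return A ggplot object (facetted by metric).
#' @export
plot_null_distribution <- function(null, observed) {
  obs <- tibble::tibble(
    metric = c("mean_degree", "mean_strength"),
    value = c(observed[["mean_degree"]], observed[["mean_strength"]])
  )
  long <- tidyr::pivot_longer(null, c("mean_degree", "mean_strength"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 25, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = "population mean under randomization", y = "iterations") +
    ggplot2::theme_minimal()
}
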