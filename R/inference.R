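#' Compare an observed statistic to a randomization null distribution
#'
#' The permutation test at the heart of the method: the observed population
#' mean (degree or strength) is compared with the empirical distribution of
#' the same statistic over randomization iterations. The Z-score is
#' `(observed - mean(null)) / sd(null)`; the comparison is two-tailed, and the
#' observation is declared significant when it falls outside the central
#' `1 - alpha` fraction of the null (above the upper or below the lower
#' `alpha/2` empirical percentile), i.e. sociality — attraction or avoidance —
#' is detected. For a degenerate zero-variance null (possible at shift range
#' 0) the Z-score is undefined (`NA`) and significance falls back to a strict
#' comparison with the null's range.
#'
#' @param observed The observed population statistic (single number).
#' @param null Numeric vector of the statistic over randomization iterations.
#' @param alpha Two-tailed significance level (default 0.05).
#' @return An object of class `null_comparison`: a list with `observed`,
#'   `null_mean`, `null_sd`, `n_iterations`, `z`, `tail_fraction` (see
#'   [detection_likelihood()]), `significant`, `direction` (`"above"`,
#'   `"below"`, or `"none"`), and `alpha`.
#' @examples
#' compare_to_null(200, 1:100) # far above: significant
#' compare_to_null(50.5, 1:100) # dead centre: z = 0
#' @export
compare_to_null <- function(observed, null, alpha = 0.05) {
  if (!is.numeric(observed) || length(observed) != 1L || !is.finite(observed)) {
    abort("`observed` must be a single finite number.")
  }
  if (!is.numeric(null) || length(null) == 0L || !all(is.finite(null))) {
    abort("`null` must be a non-empty vector of finite values.")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).")
  }

  null_sd <- sd(null)
  degenerate <- length(null) < 2L || null_sd == 0
  z <- if (degenerate) NA_real_ else (observed - mean(null)) / null_sd

  if (degenerate) {
    significant <- observed > max(null) || observed < min(null)
  } else {
    significant <- observed > quantile(null, 1 - alpha / 2, names = FALSE) ||
      observed < quantile(null, alpha / 2, names = FALSE)
  }
  direction <- if (!significant) {
    "none"
  } else if (observed > mean(null)) "above" else "below"

  structure(
    list(
      observed = observed,
      null_mean = mean(null),
      null_sd = null_sd,
      n_iterations = length(null),
      z = z,
      tail_fraction = detection_likelihood(observed, null),
      significant = significant,
      direction = direction,
      alpha = alpha,
      null_values = null
    ),
    class = "null_comparison"
  )
}

#' Two-tailed empirical tail fraction of an observed value
#'
#' The proportion of null iterations at least as extreme as the observation:
#' `2 * min(frac(null >= observed), frac(null <= observed))`, clipped to
#' `[0, 1]` — an empirical two-tailed p-value. A social effect is considered
#' detected when the tail fraction is at most `alpha` (0.05 by convention).
#'
#' @inheritParams compare_to_null
#' @return A single proportion in `[0, 1]`.
#' @examples
#' detection_likelihood(101, 1:100) # 0: observed beyond every iteration
#' @export
detection_likelihood <- function(observed, null) {
  if (!is.numeric(null) || length(null) == 0L) {
    abort("`null` must be a non-empty numeric vector.")
  }
  min(1, 2 * min(mean(null >= observed), mean(null <= observed)))
}

#' @export
print.null_comparison <- function(x, ...) {
  cat("<null_comparison>\n")
  cat(sprintf("  observed %.4g vs null %.4g +/- %.4g (%d iterations)\n",
              x$observed, x$null_mean, x$null_sd, x$n_iterations))
  cat(sprintf("  z = %s, two-tailed tail fraction = %.3g\n",
              if (is.na(x$z)) "undefined" else sprintf("%.3f", x$z),
              x$tail_fraction))
  cat(sprintf("  %s at alpha = %g%s\n",
              if (x$significant) "SIGNIFICANT" else "not significant",
              x$alpha,
              if (x$direction == "none") "" else paste0(" (", x$direction, ")")))
  invisible(x)
}

#' @rdname compare_to_null
#' @param x A `null_comparison`.
#' @param ... Unused.
#' @method tidy null_comparison
#' @export
tidy.null_comparison <- function(x, ...) {
  tibble::tibble(
    observed = x$observed,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    n_iterations = x$n_iterations,
    z = x$z,
    tail_fraction = x$tail_fraction,
    significant = x$significant,
    direction = x$direction
  )
}

#' @rdname compare_to_null
#' @method glance null_comparison
#' @export
glance.null_comparison <- function(x, ...) tidy(x, ...)

#' Null distribution of network metrics under trajectory randomization
#'
#' Repeats a randomization (`wrap_around()` or `path_shuffle()`), rebuilds the
#' interaction network from each randomized dataset, and records the
#' population mean degree and strength per iteration — the null distributions
#' against which the observed network is tested.
#'
#' @param data Observed fix table.
#' @param method `"wrap"` or `"shuffle"`.
#' @param n_iterations Number of randomization iterations.
#' @param threshold Interaction distance threshold (see
#'   [interaction_threshold()]).
#' @param s Maximum absolute shift, required for `method = "wrap"`.
#' @param window Optional shuffle window (see [path_shuffle()]).
#' @param rule Interaction rule: `"colocation"` (default) or `"comovement"`.
#' @param weighting Edge weighting passed to [build_network()]; raw counts by
#'   default (simulated agents are observed every period, so counts and the
#'   simple ratio index are proportional).
#' @return A tibble: `iteration`, `mean_degree`, `mean_strength`.
#' @export
null_metric_distribution <- function(data, method = c("wrap", "shuffle"),
                                     n_iterations, threshold,
                                     s = NULL, window = NULL,
                                     rule = c("colocation", "comovement"),
                                     weighting = "count") {
  method <- match.arg(method)
  rule <- match.arg(rule)
  if (!is_count(n_iterations)) abort("`n_iterations` must be an integer >= 1.")
  if (method == "wrap" && is.null(s)) abort("`s` is required for the wrap method.")
  nodes <- sort(unique(data$id))
  detect <- if (rule == "colocation") detect_colocation else detect_comovement

  purrr::map_dfr(seq_len(n_iterations), function(it) {
    r <- if (method == "wrap") {
      wrap_around(data, s = s)
    } else {
      path_shuffle(data, window = window)
    }
    net <- build_network(detect(r, threshold), nodes = nodes,
                         tracking = if (weighting == "sri") r else NULL,
                         weighting = weighting)
    g <- glance(net)
    tibble::tibble(
      iteration = it,
      mean_degree = g$mean_degree,
      mean_strength = g$mean_strength
    )
  })
}
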