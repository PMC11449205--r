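#' Run one simulation-randomization-inference experiment
#'
#' The full validation pipeline for a single study condition: simulate an
#' "observed" population from `cfg`, optionally downsample it, build the
#' observed interaction network, generate the null distributions of population
#' mean degree and strength under one randomization method, and test the
#' observed means against them two-tailed.
#'
#' @param cfg A [sim_config()]; its `seed` (or `seed` below) makes the run
#'   reproducible.
#' @param method `"wrap"` or `"shuffle"`.
#' @param s Maximum absolute shift in days (wrap method).
#' @param window Optional shuffle window.
#' @param n_iterations Randomization iterations per null distribution
#'   (default 100).
#' @param points_per_day Optional downsampling of the observed data before
#'   analysis (see [downsample_tracks()]).
#' @param rule Interaction rule, `"colocation"` (default) or `"comovement"`.
#' @param alpha Two-tailed significance level.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A tibble with one row per metric (`mean_degree`, `mean_strength`):
#'   the scenario descriptors (`hr_scenario`, `social`, `social_weight`,
#'   `method`, `s`, `points_per_day`, `seed`) followed by the
#'   [tidy.null_comparison()] columns.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_agents = 8, n_days = 10, steps_per_day = 10, seed = 1)
#' run_experiment(cfg, method = "wrap", s = 2, n_iterations = 20)
#' }
#' @export
run_experiment <- function(cfg, method = c("wrap", "shuffle"), s = NULL,
                           window = NULL, n_iterations = 100,
                           points_per_day = NULL,
                           rule = c("colocation", "comovement"),
                           alpha = 0.05, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  method <- match.arg(method)
  rule <- match.arg(rule)
  seed <- seed %||% cfg$seed

  observed <- simulate_tracks(cfg, seed = seed)
  if (!is.null(points_per_day) && points_per_day < cfg$steps_per_day) {
    observed <- downsample_tracks(observed, points_per_day,
                                  steps_per_day = cfg$steps_per_day)
  }
  threshold <- interaction_threshold(cfg)
  detect <- if (rule == "colocation") detect_colocation else detect_comovement
  nodes <- sort(unique(observed$id))
  obs_net <- build_network(detect(observed, threshold), nodes = nodes)
  obs <- glance(obs_net)

  null <- null_metric_distribution(
    observed, method = method, n_iterations = n_iterations,
    threshold = threshold, s = s, window = window, rule = rule
  )

  purrr::map_dfr(c("mean_degree", "mean_strength"), function(metric) {
    cmp <- compare_to_null(obs[[metric]], null[[metric]], alpha = alpha)
    dplyr::bind_cols(
      tibble::tibble(
        hr_scenario = cfg$hr_scenario,
        social = cfg$social,
        social_weight = if (cfg$social) cfg$social_weight else 0,
        method = method,
        s = if (is.null(s)) NA_integer_ else as.integer(s),
        points_per_day = points_per_day %||% cfg$steps_per_day,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        metric = metric
      ),
      tidy(cmp)
    )
  })
}

#' Run a grid of replicate experiments
#'
#' Crosses randomization methods (and shift ranges), social weights, and
#' sampling frequencies over replicate simulations, and runs
#' [run_experiment()] for every cell. Within a replicate, every method/shift
#' cell reuses the same "observed" simulation (methods are compared on
#' identical data, as in a paired design); replicates use distinct seeds
#' derived reproducibly from `seed`.
#'
#' @param base A [sim_config()] giving the study conditions; `social` and
#'   `social_weight` are overridden by `social_weights`.
#' @param methods Character subset of `c("wrap", "shuffle")`.
#' @param s_values Integer vector of shift ranges for the wrap method
#'   (ignored for shuffle).
#' @param social_weights Numeric vector; 0 means non-sociable, positive
#'   values run sociable simulations at that weight.
#' @param points_per_day Vector of sampling frequencies (default: full
#'   resolution only).
#' @param n_iterations Randomization iterations per null distribution.
#' @param n_replicates Replicate observed simulations per condition
#'   (default 1; rates such as [false_positive_rate()] need several).
#' @param seed Integer seed for the whole grid.
#' @param rule Interaction rule.
#' @param alpha Two-tailed significance level.
#' @param verbose Print one progress line per cell to stderr.
#' @return A tibble of [run_experiment()] rows with `replicate` prepended.
#' @export
run_experiment_grid <- function(base, methods = c("wrap", "shuffle"),
                                s_values = integer(0), social_weights = 0,
                                points_per_day = NULL, n_iterations = 100,
                                n_replicates = 1, seed = 1,
                                rule = c("colocation", "comovement"),
                                alpha = 0.05, verbose = FALSE) {
  stopifnot(inherits(base, "sim_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  rule <- match.arg(rule)
  points_per_day <- points_per_day %||% base$steps_per_day
  if ("wrap" %in% methods && length(s_values) == 0L) {
    abort("`s_values` must be supplied when the wrap method is requested.")
  }

  method_cells <- dplyr::bind_rows(
    if ("wrap" %in% methods) {
      tibble::tibble(method = "wrap", s = as.integer(s_values))
    },
    if ("shuffle" %in% methods) {
      tibble::tibble(method = "shuffle", s = NA_integer_)
    }
  )
  obs_cells <- tidyr::expand_grid(
    social_weight = social_weights,
    points_per_day = points_per_day,
    replicate = seq_len(n_replicates)
  )
  set.seed(seed)
  obs_cells$obs_seed <- sample.int(.Machine$integer.max - 1L, nrow(obs_cells))

  grid <- tidyr::expand_grid(obs_cells, method_cells)
  results <- purrr::pmap_dfr(grid, function(social_weight, points_per_day,
                                            replicate, obs_seed, method, s) {
    cfg <- utils::modifyList(base, list(
      social = social_weight > 0,
      social_weight = if (social_weight > 0) social_weight else base$social_weight,
      seed = NULL
    ))
    class(cfg) <- "sim_config"
    if (verbose) {
      message(sprintf(
        "replicate %d | w = %g | %d pts/day | %s%s",
        replicate, social_weight, points_per_day, method,
        if (is.na(s)) "" else paste0(" (s = ", s, ")")
      ))
    }
    res <- run_experiment(
      cfg, method = method, s = if (is.na(s)) NULL else s,
      n_iterations = n_iterations,
      points_per_day = if (points_per_day < cfg$steps_per_day) points_per_day else NULL,
      rule = rule, alpha = alpha, seed = obs_seed
    )
    dplyr::bind_cols(tibble::tibble(replicate = replicate), res)
  })
  results
}

#' False-positive rate over non-sociable replicate experiments
#'
#' The fraction of experiments on populations simulated *without* social
#' attraction in which the two-tailed test nevertheless declared significance
#' (in either direction) — i.e. spurious detections of social attraction or
#' avoidance. Errors if any sociable run is present, since those cannot
#' produce false positives by definition.
#'
#' @param results A result tibble from [run_experiment()] /
#'   [run_experiment_grid()] (columns `social`, `metric`, `significant`).
#' @return A tibble with `metric`, `n_results`, `rate`.
#' @export
false_positive_rate <- function(results) {
  check_results(results)
  if (any(results$social)) {
    abort("`results` contains sociable runs; false positives are defined only for non-sociable simulations.")
  }
  summarise_rate(results, positive = TRUE)
}

#' False-negative rate over sociable replicate experiments
#'
#' The fraction of experiments on populations simulated *with* social
#' attraction in which the test failed to declare significance. Errors if any
#' non-sociable run is present.
#'
#' @inheritParams false_positive_rate
#' @return A tibble with `metric`, `n_results`, `rate`.
#' @export
false_negative_rate <- function(results) {
  check_results(results)
  if (any(!results$social)) {
    abort("`results` contains non-sociable runs; false negatives are defined only for sociable simulations.")
  }
  summarise_rate(results, positive = FALSE)
}

check_results <- function(results) {
  needed <- c("social", "metric", "significant")
  if (!is.data.frame(results) || !all(needed %in% names(results))) {
    abort("`results` must be an experiment result table with columns `social`, `metric`, `significant`.")
  }
  if (nrow(results) == 0L) abort("`results` is empty.")
  invisible(results)
}

summarise_rate <- function(results, positive) {
  results |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      n_results = dplyr::n(),
      rate = if (positive) mean(.data$significant) else mean(!.data$significant),
      .groups = "drop"
    )
}
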