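#' Co-location interaction distance threshold
#'
#' Two simulated agents interact at a time point when they are closer than
#' twice the mean agent step length; with the default step mean of 7 this is
#' 14 length units.
#'
#' @param cfg A [sim_config()].
#' @return `2 * cfg$step_mean`.
#' @export
interaction_threshold <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  2 * cfg$step_mean
}

# Wide position matrices (time grid x individuals) used by the detectors.
# Rows: observed (day, step) combinations in chronological order; columns:
# individuals in sorted id order; missing fixes are NA.
position_matrices <- function(data) {
  assert_tracks(data, cols = c("id", "day", "step", "x", "y"))
  ids <- sort(unique(data$id))
  grid <- data |>
    dplyr::distinct(.data$day, .data$step) |>
    dplyr::arrange(.data$day, .data$step)
  t_key <- paste(grid$day, grid$step)
  row_i <- match(paste(data$day, data$step), t_key)
  col_j <- match(data$id, ids)
  X <- matrix(NA_real_, nrow = nrow(grid), ncol = length(ids))
  Y <- X
  X[cbind(row_i, col_j)] <- data$x
  Y[cbind(row_i, col_j)] <- data$y
  list(x = X, y = Y, ids = ids, grid = grid)
}

# Shared pair scan: calls `emit(i, j, rows)` for every unordered pair with at
# least one hit, where `rows` indexes the time grid.
pair_scan <- function(m, hit_fun) {
  n <- length(m$ids)
  out <- vector("list", n * (n - 1) / 2)
  kk <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      d <- sqrt((m$x[, i] - m$x[, j])^2 + (m$y[, i] - m$y[, j])^2)
      rows <- hit_fun(d)
      kk <- kk + 1L
      if (length(rows) > 0) {
        out[[kk]] <- tibble::tibble(
          id_a = m$ids[i], id_b = m$ids[j],
          day = m$grid$day[rows], step = m$grid$step[rows]
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Detect co-location interactions
#'
#' Emits one interaction record per unordered pair per time point at which the
#' pair's Euclidean distance is strictly less than `threshold` ("closer than"
#' is read strictly; the boundary has measure zero). Time points where either
#' individual has no fix are skipped.
#'
#' @param data A fix table (`id`, `day`, `step`, `x`, `y`).
#' @param threshold Distance threshold in the data's length units (> 0).
#' @return A tibble of records: `id_a`, `id_b` (canonical sorted order),
#'   `day`, `step`, `rule`.
#' @seealso [interaction_threshold()], [detect_comovement()]
#' @export
detect_colocation <- function(data, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive distance.")
  }
  m <- position_matrices(data)
  rec <- pair_scan(m, function(d) which(!is.na(d) & d < threshold))
  empty_or(rec, rule = "colocation")
}

#' Detect co-movement interactions
#'
#' A stricter rule that excludes momentary path-crossings: a pair must be
#' within `threshold` at two consecutive within-day time points for a record
#' to be emitted (at the second point). Consecutive means adjacent entries of
#' the within-day observation grid, so the rule adapts to downsampled data;
#' chains never cross day boundaries, days being the randomization unit.
#'
#' @inheritParams detect_colocation
#' @return A tibble of records as in [detect_colocation()] with
#'   `rule = "comovement"`. Every co-movement record's time point is also a
#'   co-location time point for that pair.
#' @export
detect_comovement <- function(data, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive distance.")
  }
  m <- position_matrices(data)
  same_day <- c(FALSE, diff(m$grid$day) == 0)
  rec <- pair_scan(m, function(d) {
    close <- !is.na(d) & d < threshold
    which(close & dplyr::lag(close, default = FALSE) & same_day)
  })
  empty_or(rec, rule = "comovement")
}

empty_or <- function(rec, rule) {
  if (nrow(rec) == 0L) {
    rec <- tibble::tibble(
      id_a = character(0), id_b = character(0),
      day = integer(0), step = integer(0)
    )
  }
  dplyr::mutate(rec, rule = rule)
}

#' Detect in-flight interactions in timestamped GPS data
#'
#' Empirical interaction rule for soaring birds: two individuals interact when
#' both are flying (ground speed above `speed_min`) and within `dist_max` of
#' each other for `n_consecutive` successive observation intervals. Speeds are
#' computed per fix as the distance from the previous fix divided by the
#' elapsed time; distances are Euclidean for projected coordinates and
#' great-circle (haversine) for `coords = "lonlat"`. "Within" is inclusive
#' (`<= dist_max`). Records are emitted at the last interval of each
#' qualifying run; successive intervals must be exactly `interval` seconds
#' apart (use [regularize_timestamps()] first for jittery data).
#'
#' @param data A timestamped fix table: `id`, `timestamp` (POSIXct), `x`, `y`.
#' @param speed_min Minimum ground speed counted as flying, in length units
#'   per second (default 5, i.e. 5 m/s for metre coordinates).
#' @param dist_max Maximum pair distance, length units (default 1000).
#' @param n_consecutive Number of successive qualifying intervals required
#'   (default 2).
#' @param interval Observation interval in seconds (default 600 = 10 min).
#' @param coords `"projected"` (Euclidean, metres) or `"lonlat"` (`x` =
#'   longitude, `y` = latitude, degrees; haversine distances in metres).
#' @return A tibble of records: `id_a`, `id_b`, `timestamp`, `rule = "flight"`.
#' @export
detect_flight_interactions <- function(data, speed_min = 5, dist_max = 1000,
                                       n_consecutive = 2, interval = 600,
                                       coords = c("projected", "lonlat")) {
  assert_tracks(data, cols = c("id", "timestamp", "x", "y"))
  coords <- match.arg(coords)
  if (!is_count(n_consecutive)) abort("`n_consecutive` must be an integer >= 1.")
  if (anyDuplicated(data[c("id", "timestamp")])) {
    abort("Duplicate (id, timestamp) fixes; regularize or deduplicate first.")
  }

  data <- dplyr::arrange(tibble::as_tibble(data), .data$id, .data$timestamp)
  pair_dist <- function(x1, y1, x2, y2) {
    if (coords == "lonlat") {
      geosphere::distHaversine(cbind(x1, y1), cbind(x2, y2))
    } else {
      sqrt((x1 - x2)^2 + (y1 - y2)^2)
    }
  }

  data <- data |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(
      .dt = as.numeric(.data$timestamp) - dplyr::lag(as.numeric(.data$timestamp)),
      .dd = pair_dist(.data$x, .data$y, dplyr::lag(.data$x), dplyr::lag(.data$y)),
      speed = .data$.dd / .data$.dt
    ) |>
    dplyr::ungroup()

  ids <- sort(unique(data$id))
  times <- sort(unique(as.numeric(data$timestamp)))
  row_i <- match(as.numeric(data$timestamp), times)
  col_j <- match(data$id, ids)
  fill <- function(v) {
    m <- matrix(NA_real_, nrow = length(times), ncol = length(ids))
    m[cbind(row_i, col_j)] <- v
    m
  }
  X <- fill(data$x); Y <- fill(data$y); S <- fill(data$speed)
  contiguous <- c(FALSE, diff(times) == interval)

  out <- vector("list", 0L)
  for (i in seq_len(max(length(ids) - 1L, 0L))) {
    for (j in seq.int(i + 1L, length(ids))) {
      d <- pair_dist(X[, i], Y[, i], X[, j], Y[, j])
      cond <- !is.na(d) & d <= dist_max &
        !is.na(S[, i]) & S[, i] > speed_min &
        !is.na(S[, j]) & S[, j] > speed_min
      run <- integer(length(cond))
      r <- 0L
      for (t in seq_along(cond)) {
        r <- if (cond[t]) (if (t > 1L && contiguous[t]) r + 1L else 1L) else 0L
        run[t] <- r
      }
      hits <- which(run >= n_consecutive)
      if (length(hits) > 0) {
        out[[length(out) + 1L]] <- tibble::tibble(
          id_a = ids[i], id_b = ids[j],
          timestamp = as.POSIXct(times[hits], origin = "1970-01-01", tz = "UTC")
        )
      }
    }
  }
  rec <- dplyr::bind_rows(out)
  if (nrow(rec) == 0L) {
    rec <- tibble::tibble(
      id_a = character(0), id_b = character(0),
      timestamp = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")
    )
  }
  dplyr::mutate(rec, rule = "flight")
}

#' Build a weighted social network from interaction records
#'
#' Aggregates interaction records into an undirected weighted graph over
#' individuals. With `weighting = "count"` the edge weight is the number of
#' records for the pair. With `weighting = "sri"` it is the simple ratio
#' index: records for the pair divided by the number of observation periods
#' at which both individuals were tracked (computed from `tracking`, the fix
#' table the records came from), so weights lie in `[0, 1]`.
#'
#' @param records A record tibble from one of the `detect_*()` functions (or
#'   any tibble with `id_a`, `id_b`).
#' @param nodes Optional character vector of node ids; defaults to all ids in
#'   `tracking` if given, else all ids in `records`. Individuals with no
#'   interactions appear as isolated nodes.
#' @param tracking Fix table used to count jointly tracked periods (required
#'   for `"sri"`); periods are `(day, step)` combinations or timestamps,
#'   whichever the table carries.
#' @param weighting `"count"` or `"sri"`.
#' @return An object of class `social_network`: a list with `nodes`, `edges`
#'   (tibble `id_a`, `id_b`, `weight`), and `weighting`.
#' @examples
#' tracks <- simulate_tracks(sim_config(n_agents = 5, n_days = 4,
#'                                      steps_per_day = 10, seed = 3))
#' rec <- detect_colocation(tracks, threshold = 14)
#' net <- build_network(rec, tracking = tracks)
#' node_metrics(net)
#' @export
build_network <- function(records, nodes = NULL, tracking = NULL,
                          weighting = c("count", "sri")) {
  weighting <- match.arg(weighting)
  if (!all(c("id_a", "id_b") %in% names(records))) {
    abort("`records` must have columns `id_a` and `id_b`.")
  }
  if (any(records$id_a == records$id_b)) abort("Self-interactions are not allowed.")
  if (any(records$id_a > records$id_b)) {
    abort("`records` pairs must be in canonical sorted order (id_a < id_b).")
  }
  nodes <- nodes %||%
    (if (!is.null(tracking)) sort(unique(tracking$id)) else
      sort(unique(c(records$id_a, records$id_b))))

  edges <- records |>
    dplyr::count(.data$id_a, .data$id_b, name = "weight") |>
    dplyr::mutate(weight = as.numeric(.data$weight))

  if (weighting == "sri") {
    if (is.null(tracking)) {
      abort("`tracking` is required for simple-ratio-index weighting.")
    }
    joint <- joint_tracking_periods(tracking)
    edges <- edges |>
      dplyr::left_join(joint, by = c("id_a", "id_b")) |>
      dplyr::mutate(weight = ifelse(.data$n_joint > 0,
                                    .data$weight / .data$n_joint, 0)) |>
      dplyr::select("id_a", "id_b", "weight")
  }

  structure(
    list(nodes = nodes, edges = edges, weighting = weighting),
    class = "social_network"
  )
}

# Periods at which each pair was jointly tracked (for SRI denominators).
joint_tracking_periods <- function(tracking) {
  key <- if ("timestamp" %in% names(tracking)) {
    as.numeric(tracking$timestamp)
  } else {
    assert_tracks(tracking, cols = c("id", "day", "step"))
    paste(tracking$day, tracking$step)
  }
  ids <- sort(unique(tracking$id))
  periods <- unique(key)
  inc <- matrix(FALSE, nrow = length(periods), ncol = length(ids))
  inc[cbind(match(key, periods), match(tracking$id, ids))] <- TRUE
  joint <- crossprod(inc)
  idx <- which(upper.tri(joint), arr.ind = TRUE)
  tibble::tibble(
    id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
    n_joint = as.integer(joint[idx])
  )
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf(
    "<social_network> %d nodes, %d edges (%s weighting, total weight %g)\n",
    length(x$nodes), nrow(x$edges), x$weighting, sum(x$edges$weight)
  ))
  invisible(x)
}

#' Per-node degree and strength
#'
#' Degree is the number of unique interaction partners (incident edges with
#' positive weight); strength is the sum of incident edge weights. All nodes
#' are reported, including isolates, and the population means (which the
#' permutation tests compare) are attached by [glance.social_network()].
#'
#' @param net A [build_network()] result.
#' @return A tibble: `id`, `degree`, `strength`, one row per node.
#' @export
node_metrics <- function(net) {
  stopifnot(inherits(net, "social_network"))
  edges <- dplyr::filter(net$edges, .data$weight > 0)
  incident <- dplyr::bind_rows(
    dplyr::select(edges, id = "id_a", "weight"),
    dplyr::select(edges, id = "id_b", "weight")
  )
  tibble::tibble(id = net$nodes) |>
    dplyr::left_join(
      incident |>
        dplyr::group_by(.data$id) |>
        dplyr::summarise(degree = dplyr::n(), strength = sum(.data$weight)),
      by = "id"
    ) |>
    tidyr::replace_na(list(degree = 0L, strength = 0))
}

#' @rdname node_metrics
#' @param x A `social_network`.
#' @param ... Unused.
#' @method tidy social_network
#' @export
tidy.social_network <- function(x, ...) {
  x$edges
}

#' Network-level summary
#'
#' @param x A `social_network`.
#' @param ... Unused.
#' @return One-row tibble: node and edge counts, total edge weight, and the
#'   population mean degree and mean strength (isolates included).
#' @method glance social_network
#' @export
glance.social_network <- function(x, ...) {
  nm <- node_metrics(x)
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = sum(x$edges$weight > 0),
    total_weight = sum(x$edges$weight),
    mean_degree = mean(nm$degree),
    mean_strength = mean(nm$strength)
  )
}

#' Convert a social network to an igraph object
#'
#' @param net A `social_network`.
#' @return An undirected weighted [igraph::graph].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "social_network"))
  g <- igraph::graph_from_data_frame(
    dplyr::rename(net$edges, from = "id_a", to = "id_b"),
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
  g
}

#' Write a social network as GraphML
#'
#' @param net A `social_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
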