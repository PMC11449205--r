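#' Wrap-around (conveyor-belt) randomization of trajectories
#'
#' Shifts each individual's whole trajectory forwards or backwards by a random
#' whole number of days and re-attaches the overhanging days to the other end,
#' like a conveyor belt. Within-day movement and the day-to-day sequence are
#' preserved everywhere except at a single junction per individual, so the
#' randomized data contain at most one "teleportation" (an impossible
#' overnight jump) per individual — in contrast to day shuffling, which can
#' teleport every night. The shift `k` is drawn uniformly from the integers
#' `[-s, s]` independently for each individual; `k = 0` (the identity) is a
#' legal draw.
#'
#' By default each individual is wrapped around its own tracked days
#' (`period = "individual"`): its observed day labels, in order, form the
#' conveyor belt, and untracked days are skipped. With `period = "global"` the
#' belt is the full calendar span of the dataset (`min(day) .. max(day)`
#' across all individuals), so shifted data may land on days an individual was
#' not originally tracked.
#'
#' If `data` carries a `timestamp` column it is shifted by the whole-day
#' relabelling (`new_day - old_day` days), keeping times of day intact.
#'
#' @param data A fix table with columns `id` and `day` (any other columns are
#'   carried along unchanged).
#' @param s Maximum absolute shift in days (>= 0). Values up to half the
#'   number of tracked days are meaningful; larger values alias.
#' @param period `"individual"` (default) or `"global"`; see Details.
#' @return A tibble like `data` plus a provenance column `orig_day`, with
#'   attributes `"plan"` (a tibble: `id`, `k`, `n_days`) and `"method"`. The
#'   multiset of per-day movement sequences of every individual is unchanged —
#'   days are relabelled, never edited.
#' @examples
#' tracks <- simulate_tracks(sim_config(n_agents = 4, n_days = 6,
#'                                      steps_per_day = 3, seed = 7))
#' r <- wrap_around(tracks, s = 2)
#' randomization_plan(r)
#' count_teleportations(r)
#' @seealso [path_shuffle()], [count_teleportations()]
#' @export
wrap_around <- function(data, s, period = c("individual", "global")) {
  assert_tracks(data, cols = c("id", "day"))
  period <- match.arg(period)
  if (!is_count(s, min = 0L)) abort("`s` must be a single integer >= 0.")
  s <- as.integer(s)
  if (nrow(data) == 0L) {
    out <- dplyr::mutate(tibble::as_tibble(data), orig_day = integer(0))
    return(new_randomized(out, plan = tibble::tibble(
      id = character(0), k = integer(0), n_days = integer(0)
    ), method = "wrap", s = s))
  }

  ids <- sort(unique(data$id))
  shifts <- seq.int(-s, s)
  k <- shifts[sample.int(length(shifts), length(ids), replace = TRUE)]
  names(k) <- ids

  if (period == "global") {
    d_min <- min(data$day)
    n_slots <- max(data$day) - d_min + 1L
    map <- tibble::tibble(
      id = rep(ids, each = n_slots),
      orig_day = rep(seq.int(d_min, length.out = n_slots), times = length(ids)),
      day = ((rep(seq_len(n_slots), times = length(ids)) - 1L +
                rep(unname(k), each = n_slots)) %% n_slots) + d_min
    )
    n_days <- rep(n_slots, length(ids))
  } else {
    per_id <- lapply(ids, function(i) {
      days <- sort(unique(data$day[data$id == i]))
      n <- length(days)
      tibble::tibble(
        id = i,
        orig_day = days,
        day = days[((seq_len(n) - 1L + k[[i]]) %% n) + 1L]
      )
    })
    map <- dplyr::bind_rows(per_id)
    n_days <- vapply(
      per_id, nrow, integer(1)
    )
  }

  out <- data |>
    tibble::as_tibble() |>
    dplyr::select(-dplyr::any_of("orig_day")) |> # provenance is per-randomization
    dplyr::rename(orig_day = "day") |>
    dplyr::left_join(map, by = c("id", "orig_day")) |>
    shift_timestamps() |>
    dplyr::relocate("day", .after = "id")

  plan <- tibble::tibble(id = ids, k = unname(k), n_days = n_days)
  new_randomized(out, plan = plan, method = "wrap", s = s)
}

#' Path shuffling: per-individual permutation of day labels
#'
#' The classical trajectory data-stream randomization: each individual's day
#' labels are permuted uniformly at random (independently per individual),
#' leaving within-day movement untouched. This decouples temporal synchrony
#' between individuals while preserving each individual's space use, but can
#' create an unlimited number of overnight "teleportations". With `window`,
#' the ordered tracked days are cut into contiguous segments of that many days
#' and permuted only within each segment, preserving coarse temporal
#' structure.
#'
#' @inheritParams wrap_around
#' @param window Optional segment length in days (> 0); `NULL` (default)
#'   shuffles across the whole tracking period.
#' @return A tibble with provenance column `orig_day` and attributes `"plan"`
#'   (tibble: `id`, `orig_day`, `day`) and `"method"`; see [wrap_around()].
#' @export
path_shuffle <- function(data, window = NULL) {
  assert_tracks(data, cols = c("id", "day"))
  if (!is.null(window) && !is_count(window)) {
    abort("`window` must be a single integer >= 1 (or NULL).")
  }
  if (nrow(data) == 0L) {
    out <- dplyr::mutate(tibble::as_tibble(data), orig_day = integer(0))
    return(new_randomized(out, plan = tibble::tibble(
      id = character(0), orig_day = integer(0), day = integer(0)
    ), method = "shuffle", window = window))
  }

  ids <- sort(unique(data$id))
  map <- dplyr::bind_rows(lapply(ids, function(i) {
    days <- sort(unique(data$day[data$id == i]))
    n <- length(days)
    seg <- if (is.null(window)) rep(1L, n) else ceiling(seq_len(n) / window)
    new_days <- days
    for (g in unique(seg)) {
      idx <- which(seg == g)
      new_days[idx] <- days[idx][sample.int(length(idx))]
    }
    tibble::tibble(id = i, orig_day = days, day = new_days)
  }))

  out <- data |>
    tibble::as_tibble() |>
    dplyr::select(-dplyr::any_of("orig_day")) |> # provenance is per-randomization
    dplyr::rename(orig_day = "day") |>
    dplyr::left_join(map, by = c("id", "orig_day")) |>
    shift_timestamps() |>
    dplyr::relocate("day", .after = "id")

  new_randomized(out, plan = map, method = "shuffle", window = window)
}

new_randomized <- function(out, plan, method, ...) {
  attr(out, "plan") <- plan
  attr(out, "method") <- method
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- unique(c("randomized_tracks", class(out)))
  out
}

# Keep times of day intact under whole-day relabelling.
shift_timestamps <- function(data) {
  if ("timestamp" %in% names(data)) {
    data$timestamp <- data$timestamp + (data$day - data$orig_day) * 86400
  }
  data
}

#' Extract the randomization plan from a randomized dataset
#'
#' @param r A dataset returned by [wrap_around()] or [path_shuffle()].
#' @return The provenance plan tibble (per-individual shift `k` for
#'   wrap-around; the `orig_day -> day` map for shuffling).
#' @export
randomization_plan <- function(r) {
  plan <- attr(r, "plan")
  if (is.null(plan)) {
    abort("`r` carries no randomization plan; was it produced by wrap_around() or path_shuffle()?")
  }
  plan
}

#' Count teleportation events per individual
#'
#' A teleportation is a pair of adjacent calendar days whose contents were not
#' adjacent (in the same order) in the original trajectory — the randomized
#' track ends one day somewhere and resumes the next day somewhere unreachable.
#' Wrap-around produces at most one per individual (exactly one unless the
#' drawn shift is the identity); shuffling can produce up to `n_days - 1`.
#'
#' @param r A randomized dataset with provenance (`orig_day` column).
#' @return A tibble with columns `id` and `teleportations`.
#' @export
count_teleportations <- function(r) {
  assert_tracks(r, cols = c("id", "day"))
  if (!"orig_day" %in% names(r)) {
    abort("`r` has no `orig_day` provenance column; cannot count teleportations.")
  }
  r |>
    dplyr::distinct(.data$id, .data$day, .data$orig_day) |>
    dplyr::group_by(.data$id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      teleportations = {
        pos <- match(.data$orig_day, sort(unique(.data$orig_day)))
        if (length(pos) < 2L) 0L else sum(diff(pos) != 1L)
      },
      .groups = "drop"
    )
}

#' Downsample within-day fixes to a lower observation frequency
#'
#' Emulates sparser tracking by retaining evenly spaced steps within each day:
#' step indices `ceiling(1 + (j - 1) * steps_per_day / points_per_day)` for
#' `j = 1..points_per_day` (e.g. 50 to 25 keeps steps 1, 3, ..., 49; 50 to 5
#' keeps 1, 11, 21, 31, 41).
#'
#' @param data A fix table with columns `id`, `day`, `step`.
#' @param points_per_day Number of fixes to retain per day.
#' @param steps_per_day Full within-day resolution; defaults to the maximum
#'   `step` present.
#' @return The filtered tibble.
#' @export
downsample_tracks <- function(data, points_per_day, steps_per_day = NULL) {
  assert_tracks(data, cols = c("id", "day", "step"))
  steps_per_day <- steps_per_day %||% max(data$step, 0L)
  if (!is_count(points_per_day)) {
    abort("`points_per_day` must be a single integer >= 1.")
  }
  if (points_per_day > steps_per_day) {
    abort("`points_per_day` cannot exceed `steps_per_day`.")
  }
  keep <- unique(ceiling(
    1 + (seq_len(points_per_day) - 1) * steps_per_day / points_per_day
  ))
  dplyr::filter(tibble::as_tibble(data), .data$step %in% keep)
}
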