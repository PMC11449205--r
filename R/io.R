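#' Declare a movement-file dialect
#'
#' Movement files are delimited text in one of two dialects: `day_step`
#' (columns id, day, step, x, y — the simulator's native format) or
#' `timestamp` (id, ISO-8601 UTC timestamp, x, y — the GPS-tooling format).
#' Coordinates are either projected metres (Euclidean distances downstream)
#' or lon/lat degrees (great-circle distances). The dialect is always
#' declared, never guessed from the file.
#'
#' @param time `"day_step"` or `"timestamp"`.
#' @param coords `"projected"` or `"lonlat"`.
#' @param delim Field delimiter (default `","`).
#' @param columns Named list mapping the canonical names (`id`, `day`,
#'   `step`, `timestamp`, `x`, `y`) to the column names in the file.
#' @return An object of class `movement_dialect`.
#' @export
movement_dialect <- function(time = c("day_step", "timestamp"),
                             coords = c("projected", "lonlat"),
                             delim = ",", columns = list()) {
  time <- match.arg(time)
  coords <- match.arg(coords)
  default_cols <- list(id = "id", day = "day", step = "step",
                       timestamp = "timestamp", x = "x", y = "y")
  columns <- utils::modifyList(default_cols, columns)
  structure(
    list(time = time, coords = coords, delim = delim, columns = columns),
    class = "movement_dialect"
  )
}

#' Read a movement file into a fix table
#'
#' Parses a delimited movement file under an explicit [movement_dialect()],
#' renames columns to the canonical names, checks types, rejects duplicate
#' fixes (same individual at the same time) naming the offending lines, and
#' returns fixes sorted chronologically within individual.
#'
#' @param path File path.
#' @param dialect A [movement_dialect()].
#' @return A tibble of fixes (`id`, `day`, `step`, `x`, `y` or `id`,
#'   `timestamp`, `x`, `y`), with the dialect attached as attribute
#'   `"dialect"`.
#' @export
read_movement <- function(path, dialect = movement_dialect()) {
  stopifnot(inherits(dialect, "movement_dialect"))
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_delim(path, delim = dialect$delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)

  want <- if (dialect$time == "day_step") {
    c("id", "day", "step", "x", "y")
  } else {
    c("id", "timestamp", "x", "y")
  }
  file_cols <- unlist(dialect$columns[want], use.names = FALSE)
  missing_cols <- setdiff(file_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Column(s) not found in ", path, ": ",
      paste0("`", missing_cols, "`", collapse = ", "), "."
    ))
  }
  data <- raw[file_cols]
  names(data) <- want

  if (nrow(data) == 0L) {
    warn(paste0("Empty movement file: ", path))
    data$id <- as.character(data$id)
    if (dialect$time == "day_step") {
      data$day <- as.integer(data$day)
      data$step <- as.integer(data$step)
    } else {
      data$timestamp <- as.POSIXct(as.character(data$timestamp), tz = "UTC")
    }
    for (col in c("x", "y")) data[[col]] <- as.numeric(data[[col]])
    out <- tibble::as_tibble(data)
    attr(out, "dialect") <- dialect
    return(out)
  }
  data$id <- as.character(data$id)
  if (dialect$time == "day_step") {
    for (col in c("day", "step", "x", "y")) {
      if (!is.numeric(data[[col]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(data[[col]]))))
        abort(paste0(
          "Malformed `", col, "` values at data line(s) ",
          paste(utils::head(bad, 5), collapse = ", "), " of ", path, "."
        ))
      }
    }
    data$day <- as.integer(data$day)
    data$step <- as.integer(data$step)
    key <- c("id", "day", "step")
  } else {
    if (!inherits(data$timestamp, "POSIXct")) {
      parsed <- as.POSIXct(data$timestamp, tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
      if (anyNA(parsed)) {
        bad <- which(is.na(parsed))
        abort(paste0(
          "Malformed timestamp(s) at data line(s) ",
          paste(utils::head(bad, 5), collapse = ", "), " of ", path, "."
        ))
      }
      data$timestamp <- parsed
    }
    key <- c("id", "timestamp")
  }

  dup <- duplicated(data[key])
  if (any(dup)) {
    abort(paste0(
      "Duplicate fix(es) (same individual and time) at data line(s) ",
      paste(utils::head(which(dup), 5), collapse = ", "), " of ", path, "."
    ))
  }

  data <- dplyr::arrange(tibble::as_tibble(data),
                         !!!rlang::syms(intersect(key, names(data))))
  attr(data, "dialect") <- dialect
  data
}

#' Write a fix table as a delimited movement file
#'
#' Inverse of [read_movement()]: writes the canonical columns (plus
#' `orig_day`, if present, as provenance) under the dialect's column names
#' and delimiter. A write/read round trip reproduces the fixes exactly.
#'
#' @param data Fix table.
#' @param path Output file.
#' @param dialect A [movement_dialect()].
#' @return `path`, invisibly.
#' @export
write_movement <- function(data, path, dialect = movement_dialect()) {
  stopifnot(inherits(dialect, "movement_dialect"))
  want <- if (dialect$time == "day_step") {
    c("id", "day", "step", "x", "y")
  } else {
    c("id", "timestamp", "x", "y")
  }
  assert_tracks(data, cols = want)
  out <- data[c(want, intersect("orig_day", names(data)))]
  names(out)[seq_along(want)] <- unlist(dialect$columns[want], use.names = FALSE)
  readr::write_delim(out, path, delim = dialect$delim)
  invisible(path)
}

#' Snap jittery timestamps to a regular grid
#'
#' GPS tags transmit "approximately" on schedule; downstream interval logic
#' needs an exact grid. Each timestamp is snapped to the nearest multiple of
#' `interval` (anchored at the UTC epoch) when within `tolerance` seconds of
#' it; fixes farther from the grid are dropped, and when several of an
#' individual's fixes snap to the same grid point only the nearest is kept.
#' Drop counts are attached as attribute `"regularization"`.
#'
#' @param data Timestamped fix table (`id`, `timestamp`, `x`, `y`).
#' @param interval Grid spacing, seconds (default 600 = 10 min).
#' @param tolerance Maximum snap distance, seconds (default 120 = 2 min).
#' @return The regularized tibble.
#' @export
regularize_timestamps <- function(data, interval = 600, tolerance = 120) {
  assert_tracks(data, cols = c("id", "timestamp"))
  if (!is.numeric(interval) || interval <= 0) abort("`interval` must be > 0.")
  if (!is.numeric(tolerance) || tolerance < 0) abort("`tolerance` must be >= 0.")

  tt <- as.numeric(data$timestamp)
  grid <- round(tt / interval) * interval
  offset <- abs(tt - grid)
  keep <- offset <= tolerance
  n_dropped_tolerance <- sum(!keep)

  out <- data[keep, , drop = FALSE]
  out$timestamp <- as.POSIXct(grid[keep], origin = "1970-01-01", tz = "UTC")
  out$.offset <- offset[keep]
  out <- out |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$id, .data$timestamp) |>
    dplyr::slice_min(.data$.offset, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  n_dropped_duplicate <- sum(keep) - nrow(out)
  out$.offset <- NULL
  out <- dplyr::arrange(out, .data$id, .data$timestamp)
  attr(out, "regularization") <- list(
    interval = interval, tolerance = tolerance,
    n_dropped_tolerance = n_dropped_tolerance,
    n_dropped_duplicate = n_dropped_duplicate
  )
  out
}

#' Assign day indices to timestamped fixes
#'
#' Day-unit randomization of timestamped data needs a `day` column. A "day"
#' is a UTC calendar date by default; `day_start_hour` moves the boundary
#' (e.g. 12 for species whose biological day spans midnight UTC). Days are
#' indexed 1-based from the first date in the dataset.
#'
#' @param data Timestamped fix table.
#' @param day_start_hour Hour (0-23) at which a day begins (default 0).
#' @return `data` with an integer `day` column added.
#' @export
assign_days <- function(data, day_start_hour = 0) {
  assert_tracks(data, cols = c("id", "timestamp"))
  if (!is.numeric(day_start_hour) || day_start_hour < 0 || day_start_hour >= 24) {
    abort("`day_start_hour` must lie in [0, 24).")
  }
  date <- as.Date(data$timestamp - day_start_hour * 3600, tz = "UTC")
  data$day <- as.integer(date - min(date)) + 1L
  dplyr::relocate(tibble::as_tibble(data), "day", .after = "id")
}
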