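# Shared fixture builders. All fixtures are generated in code at test time.

# A hand-laid fix table: `days` days, `steps` steps/day per individual, with
# coordinates encoding (id, day, step) so relabelling is easy to audit.
grid_tracks <- function(ids = c("a", "b"), days = 5, steps = 2) {
  tidyr::expand_grid(id = ids, day = seq_len(days), step = seq_len(steps)) |>
    dplyr::mutate(
      x = match(id, ids) * 1000 + day * 10 + step,
      y = day * 100 + step
    )
}

# Two individuals on a straight line at controllable separation per step.
pair_tracks <- function(sep_by_step, day = 1) {
  steps <- seq_along(sep_by_step)
  dplyr::bind_rows(
    tibble::tibble(id = "a", day = day, step = steps, x = 0, y = 0),
    tibble::tibble(id = "b", day = day, step = steps, x = sep_by_step, y = 0)
  )
}

# Small simulated dataset reused across tests.
small_sim <- function(seed = 99, ...) {
  simulate_tracks(sim_config(n_agents = 5, n_days = 6, steps_per_day = 8,
                             seed = seed, ...))
}

# Brute-force rotation oracle: contents of calendar slots after shifting the
# ordered day sequence 1..n by k on a conveyor belt.
rotate_oracle <- function(n, k) {
  slots <- integer(n)
  for (i in seq_len(n)) {
    slots[((i - 1 + k) %% n) + 1] <- i
  }
  slots
}

# Brute-force degree/strength from an edge list.
metrics_oracle <- function(nodes, edges) {
  deg <- setNames(numeric(length(nodes)), nodes)
  str <- deg
  for (r in seq_len(nrow(edges))) {
    a <- edges$id_a[r]; b <- edges$id_b[r]; w <- edges$weight[r]
    if (w > 0) {
      deg[a] <- deg[a] + 1; deg[b] <- deg[b] + 1
      str[a] <- str[a] + w; str[b] <- str[b] + w
    }
  }
  tibble::tibble(id = nodes, degree = unname(deg), strength = unname(str))
}

# Timestamped synthetic two-bird fixture on a regular grid: bird a flies east
# at speed_a (m/s), bird b parallel at speed_b offset by gap_m to the north.
# With equal speeds the pair distance is exactly gap_m at every fix.
flight_fixture <- function(speed_a, speed_b, gap_m, n_fixes = 4,
                           interval = 600,
                           t0 = as.POSIXct("2022-06-01 12:00:00", tz = "UTC")) {
  tt <- t0 + (seq_len(n_fixes) - 1) * interval
  dplyr::bind_rows(
    tibble::tibble(id = "a", timestamp = tt,
                   x = (seq_len(n_fixes) - 1) * speed_a * interval, y = 0),
    tibble::tibble(id = "b", timestamp = tt,
                   x = (seq_len(n_fixes) - 1) * speed_b * interval, y = gap_m)
  )
}
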