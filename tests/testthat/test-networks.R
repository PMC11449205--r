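test_that("the co-location threshold is twice the mean step length", {
  expect_identical(interaction_threshold(sim_config()), 14)
  expect_identical(interaction_threshold(sim_config(step_mean = 0.5)), 1)
  expect_identical(interaction_threshold(sim_config(step_mean = 10)), 20)
})

test_that("co-location uses a strict distance inequality", {
  tr <- pair_tracks(sep_by_step = c(13.9, 14.0, 14.1))
  rec <- detect_colocation(tr, threshold = 14)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$step, 1L)
  expect_equal(rec$id_a, "a")
  expect_equal(rec$id_b, "b")
})

test_that("co-location records every close pair at a time point", {
  # three mutually close agents: all three pairs fire
  tr <- dplyr::bind_rows(
    tibble::tibble(id = c("a", "b", "c"), day = 1, step = 1,
                   x = c(0, 1, 2), y = 0)
  )
  rec <- detect_colocation(tr, threshold = 14)
  expect_equal(nrow(rec), 3L)
  expect_setequal(paste(rec$id_a, rec$id_b), c("a b", "a c", "b c"))
  # brute force over all pairs and times on a random simulation
  tr2 <- small_sim(seed = 12)
  rec2 <- detect_colocation(tr2, threshold = 40)
  brute <- tr2 |>
    dplyr::inner_join(tr2, by = c("day", "step"),
                      suffix = c("_a", "_b"), relationship = "many-to-many") |>
    dplyr::filter(id_a < id_b,
                  sqrt((x_a - x_b)^2 + (y_a - y_b)^2) < 40) |>
    dplyr::arrange(id_a, id_b, day, step)
  expect_equal(nrow(rec2), nrow(brute))
  expect_equal(
    dplyr::arrange(rec2, id_a, id_b, day, step)[c("id_a", "id_b", "day", "step")],
    brute[c("id_a", "id_b", "day", "step")],
    ignore_attr = TRUE
  )
})

test_that("missing fixes are skipped, not treated as distance zero", {
  tr <- pair_tracks(sep_by_step = c(1, 1, 1))
  tr <- dplyr::filter(tr, !(id == "b" & step == 2))
  rec <- detect_colocation(tr, threshold = 14)
  expect_setequal(rec$step, c(1L, 3L))
})

test_that("enlarging the threshold never removes a record", {
  tr <- small_sim(seed = 13)
  small <- detect_colocation(tr, threshold = 20)
  big <- detect_colocation(tr, threshold = 60)
  expect_gte(nrow(big), nrow(small))
  expect_equal(nrow(dplyr::anti_join(
    small, big, by = c("id_a", "id_b", "day", "step")
  )), 0L)
})

test_that("co-movement needs two consecutive close steps within a day", {
  # close at steps 3 and 4: one record, at step 4
  tr <- pair_tracks(sep_by_step = c(99, 99, 5, 5, 99))
  rec <- detect_comovement(tr, threshold = 14)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$step, 4L)

  # close at one isolated step (a path-crossing): no record
  tr2 <- pair_tracks(sep_by_step = c(99, 5, 99))
  expect_equal(nrow(detect_comovement(tr2, threshold = 14)), 0L)

  # close at the last step of day 1 and the first of day 2: no chaining
  tr3 <- dplyr::bind_rows(
    pair_tracks(sep_by_step = c(99, 5), day = 1),
    pair_tracks(sep_by_step = c(5, 99), day = 2)
  )
  expect_equal(nrow(detect_comovement(tr3, threshold = 14)), 0L)
})

test_that("co-movement records are a subset of co-location records", {
  tr <- small_sim(seed = 14)
  thr <- 50
  co <- detect_colocation(tr, thr)
  cm <- detect_comovement(tr, thr)
  expect_equal(nrow(dplyr::anti_join(
    cm[c("id_a", "id_b", "day", "step")], co,
    by = c("id_a", "id_b", "day", "step")
  )), 0L)
})

test_that("flight interactions need speed, proximity and persistence", {
  # both flying at 6 m/s, 800 m apart at both intervals: one record
  both <- flight_fixture(speed_a = 6, speed_b = 6, gap_m = 800, n_fixes = 3)
  rec <- detect_flight_interactions(both)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$timestamp,
               as.POSIXct("2022-06-01 12:20:00", tz = "UTC"))
  expect_equal(rec$rule, "flight")

  # one bird below 5 m/s: not flying, no record
  slow <- flight_fixture(speed_a = 6, speed_b = 4, gap_m = 800, n_fixes = 3)
  expect_equal(nrow(detect_flight_interactions(slow)), 0L)

  # too far apart: no record
  apart <- flight_fixture(speed_a = 6, speed_b = 6, gap_m = 1500, n_fixes = 3)
  expect_equal(nrow(detect_flight_interactions(apart)), 0L)

  # proximity at a single interval: consecutive clause fails
  one <- flight_fixture(speed_a = 6, speed_b = 6, gap_m = 800, n_fixes = 3)
  one$y[one$id == "b"][3] <- 5000
  expect_equal(nrow(detect_flight_interactions(one)), 0L)

  # a gap in the grid breaks the run
  gap <- flight_fixture(speed_a = 6, speed_b = 6, gap_m = 800, n_fixes = 4)
  gap <- dplyr::filter(gap, timestamp != as.POSIXct("2022-06-01 12:10:00",
                                                    tz = "UTC"))
  rec_gap <- detect_flight_interactions(gap)
  expect_equal(nrow(rec_gap), 1L) # only the 12:20/12:30 run survives
  expect_error(
    detect_flight_interactions(dplyr::bind_rows(both, both[1, ])),
    "Duplicate"
  )
})

test_that("lon/lat flight detection uses great-circle distances", {
  # ~0.009 degrees latitude is ~1 km; walk two birds east at 6 m/s
  t0 <- as.POSIXct("2022-06-01 12:00:00", tz = "UTC")
  deg_per_step <- 6 * 600 / 111320 # metres to degrees longitude at equator
  tr <- dplyr::bind_rows(
    tibble::tibble(id = "a", timestamp = t0 + (0:2) * 600,
                   x = (0:2) * deg_per_step, y = 0),
    tibble::tibble(id = "b", timestamp = t0 + (0:2) * 600,
                   x = (0:2) * deg_per_step, y = 0.0072) # ~800 m north
  )
  rec <- detect_flight_interactions(tr, coords = "lonlat")
  expect_equal(nrow(rec), 1L)
  far <- dplyr::mutate(tr, y = ifelse(id == "b", 0.02, y)) # ~2.2 km north
  expect_equal(nrow(detect_flight_interactions(far, coords = "lonlat")), 0L)
})

test_that("count and SRI weightings follow their definitions", {
  rec <- tibble::tibble(
    id_a = rep("a", 3), id_b = rep("b", 3),
    day = 1L, step = 1:3, rule = "colocation"
  )
  # both individuals tracked at 10 shared periods
  tracking <- grid_tracks(ids = c("a", "b"), days = 2, steps = 5)
  counted <- build_network(rec, tracking = tracking, weighting = "count")
  expect_equal(counted$edges$weight, 3)
  sri <- build_network(rec, tracking = tracking, weighting = "sri")
  expect_equal(sri$edges$weight, 0.3)
  expect_error(build_network(rec, weighting = "sri"), "tracking")

  # no records: an edgeless network over every tracked node
  none <- build_network(rec[0, ], tracking = tracking)
  expect_equal(nrow(none$edges), 0L)
  expect_setequal(none$nodes, c("a", "b"))
  expect_equal(node_metrics(none)$degree, c(0L, 0L))

  # SRI uses only jointly tracked periods in the denominator
  partial <- dplyr::filter(tracking, !(id == "b" & step %in% 1:2))
  sri2 <- build_network(rec, tracking = partial, weighting = "sri")
  expect_equal(sri2$edges$weight, 3 / 6) # b tracked at 6 of the 10 periods
  expect_true(all(sri2$edges$weight >= 0 & sri2$edges$weight <= 1))

  expect_error(build_network(tibble::tibble(id_a = "b", id_b = "a")), "canonical")
  expect_error(build_network(tibble::tibble(id_a = "a", id_b = "a")), "Self")
})

test_that("degree and strength match the brute-force adjacency oracle", {
  # worked example: edges a-b (2), a-c (1)
  net <- structure(list(
    nodes = c("a", "b", "c"),
    edges = tibble::tibble(id_a = c("a", "a"), id_b = c("b", "c"),
                           weight = c(2, 1)),
    weighting = "count"
  ), class = "social_network")
  nm <- node_metrics(net)
  expect_equal(nm$degree[nm$id == "a"], 2L)
  expect_equal(nm$strength[nm$id == "a"], 3)

  # random small graphs against the oracle
  set.seed(88)
  for (trial in 1:10) {
    n <- sample(3:8, 1)
    nodes <- letters[seq_len(n)]
    pairs <- t(utils::combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.5
    edges <- tibble::tibble(
      id_a = pairs[keep, 1], id_b = pairs[keep, 2],
      weight = sample(0:5, sum(keep), replace = TRUE)
    )
    net <- structure(list(nodes = nodes, edges = edges, weighting = "count"),
                     class = "social_network")
    expect_equal(node_metrics(net), metrics_oracle(nodes, edges))
    # handshake identities
    nm <- node_metrics(net)
    expect_equal(sum(nm$degree), 2 * sum(edges$weight > 0))
    expect_equal(sum(nm$strength), 2 * sum(edges$weight))
  }

  # complete graph on 4 nodes with unit weights
  pairs4 <- t(utils::combn(letters[1:4], 2))
  k4 <- structure(list(
    nodes = letters[1:4],
    edges = tibble::tibble(id_a = pairs4[, 1], id_b = pairs4[, 2], weight = 1),
    weighting = "count"
  ), class = "social_network")
  nm4 <- node_metrics(k4)
  expect_true(all(nm4$degree == 3L))
  expect_true(all(nm4$strength == 3))
  g4 <- glance(k4)
  expect_equal(g4$mean_degree, 3)
  expect_equal(g4$mean_strength, 3)
})

test_that("detection is symmetric under relabelling of individuals", {
  tr <- small_sim(seed = 17)
  ids <- sort(unique(tr$id))
  map <- setNames(rev(ids), ids) # reverse the id order
  flipped <- dplyr::mutate(tr, id = unname(map[id]))
  rec <- detect_colocation(tr, 40)
  rec_f <- detect_colocation(flipped, 40)
  relabelled <- tibble::tibble(
    id_a = pmin(unname(map[rec$id_a]), unname(map[rec$id_b])),
    id_b = pmax(unname(map[rec$id_a]), unname(map[rec$id_b])),
    day = rec$day, step = rec$step
  ) |> dplyr::arrange(id_a, id_b, day, step)
  expect_equal(
    relabelled,
    dplyr::arrange(rec_f[c("id_a", "id_b", "day", "step")],
                   id_a, id_b, day, step)
  )
})

test_that("networks export to igraph and GraphML", {
  tr <- small_sim(seed = 18)
  net <- build_network(detect_colocation(tr, 60), tracking = tr)
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), length(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})
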