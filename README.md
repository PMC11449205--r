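# pathwrap

Null models for the spatial–social interface: does proximity between
GPS-tracked animals reflect **social attraction**, or is it a by-product of
**spatial constraints** on their movements?

`pathwrap` implements the **wrap-around** trajectory randomization — shift
each individual's whole movement path by a random number of days
`k ~ U{-s, ..., s}` and re-attach the overhang at the other end, like a
conveyor belt — alongside the classical **path shuffling** null (per-individual
permutation of day labels). Both destroy temporal synchrony between
individuals while preserving each individual's space use; the wrap-around
additionally preserves day-to-day path continuity everywhere except one
junction, so each randomized individual has at most **one** impossible
overnight jump ("teleportation") instead of potentially one per night.

The observed proximity network is then tested against the randomization null:
for a population statistic `m` (mean degree or mean strength),

```
Z = (m_obs - mean(m_null)) / sd(m_null)
```

with two-tailed significance when `m_obs` falls outside the central 95% of
the null iterations — attraction above, avoidance below.

The package is aimed at movement ecologists and animal social network
analysts, and contains:

- `wrap_around()`, `path_shuffle()`, `count_teleportations()`,
  `downsample_tracks()` — trajectory data-stream randomizations with full
  provenance;
- `simulate_tracks()` + `sim_config()` — a biased-correlated random walk
  agent-based model with static, locally drifting, or directionally drifting
  home-range centres and optional nearest-neighbour social attraction, used
  to validate the methods against populations with known social rules;
- `detect_colocation()`, `detect_comovement()`,
  `detect_flight_interactions()`, `build_network()`, `node_metrics()` —
  interaction detection (simulation and empirical GPS rules) and weighted
  network construction (counts or simple ratio index);
- `compare_to_null()`, `null_metric_distribution()`, `run_experiment_grid()`,
  `false_positive_rate()`, `false_negative_rate()` — the permutation
  inference harness;
- readers/writers for delimited movement files, timestamp regularization for
  jittery GPS schedules, and a command-line interface
  (`inst/cli/pathwrap.R`).

Everything takes and returns tibbles, pipes cleanly, and is reproducible
from a single seed.

## Worked example

Simulate a sociable population (15 agents, 25 days, 50 steps/day, static
home ranges, social weight 0.75), build its co-location network, and test the
observed mean strength against 100 wrap-around randomizations with shifts up
to 5 days:

```r
library(pathwrap)

cfg <- sim_config(n_agents = 15, n_days = 25, steps_per_day = 50,
                  hr_scenario = "static", social = TRUE,
                  social_weight = 0.75, seed = 2024)
tracks <- simulate_tracks(cfg)

thr <- interaction_threshold(cfg) # 14: twice the mean step length
net <- build_network(detect_colocation(tracks, thr),
                     nodes = sort(unique(tracks$id)))
glance(net)
#> # A tibble: 1 × 5
#>   n_nodes n_edges total_weight mean_degree mean_strength
#>     <int>   <int>        <dbl>       <dbl>         <dbl>
#> 1      15      11         4726        1.47          630.

set.seed(1)
null <- null_metric_distribution(tracks, method = "wrap",
                                 n_iterations = 100, threshold = thr, s = 5)
compare_to_null(glance(net)$mean_strength, null$mean_strength)
#> <null_comparison>
#>   observed 630.1 vs null 493.5 +/- 25.34 (100 iterations)
#>   z = 5.393, two-tailed tail fraction = 0
#>   SIGNIFICANT at alpha = 0.05 (above)
```

The observed mean strength (630 interaction-periods per agent) sits more than
5 null standard deviations above the randomization mean (494): the simulated
social attraction is detected as significant attraction, not a spatial
artefact. The wrap-around structure is auditable — every individual carries
at most one teleportation:

```r
set.seed(1)
count_teleportations(wrap_around(tracks, s = 5))
#> # A tibble: 15 × 2
#>   id    teleportations
#>   <chr>          <int>
#> 1 A001               1
#> 2 A002               1
#> # ...
```

Non-sociable control populations go through the same pipeline via
`run_experiment_grid()`, whose replicate results feed
`false_positive_rate()` / `false_negative_rate()`.

For timestamped field data the pipeline is: `read_movement()` (timestamp
dialect) → `regularize_timestamps()` (snap "approximately every 10 min"
fixes to an exact grid) → `detect_flight_interactions()` (flying faster than
5 m/s within 1 km for two consecutive 10-min intervals) →
`build_network(..., weighting = "sri")` → `assign_days()` +
`wrap_around(period = "individual")` per-individual over each animal's own
tracked days → `compare_to_null()`.

## Command line

```sh
Rscript inst/cli/pathwrap.R simulate  --out tracks.csv --seed 1
Rscript inst/cli/pathwrap.R randomize --in tracks.csv --out null.csv \
        --method wrap --shift-range 10 --seed 1 --plan plan.csv
Rscript inst/cli/pathwrap.R network   --in tracks.csv --out edges.csv --threshold 14
Rscript inst/cli/pathwrap.R compare   --in tracks.csv --out cmp.csv \
        --method wrap --shift-range 10 --iterations 100 --seed 1
```

Each subcommand writes a JSON run manifest (`<out>.manifest.json`) recording
the options, seed, package version and record counts needed to re-execute
the run.

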