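---
title: "Wrap-around randomization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrap-around randomization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwrap)
```

## The problem

Animals interact where their movements put them. When two GPS-tracked
individuals are repeatedly found close together, that proximity can reflect
genuine social attraction, or it can be a by-product of spatial constraints —
shared resources, barriers, overlapping home ranges. Telling the two apart
requires a reference ("null") model that preserves how each individual uses
space while destroying the temporal synchrony between individuals that social
attraction produces.

The classical data-stream approach, *path shuffling*, permutes the day labels
of each individual's trajectory. It preserves each day's movement path and
each individual's overall space use, but it breaks day-to-day continuity
everywhere: a shuffled animal may end one day in one place and "teleport" to
somewhere unreachable the next morning. For central-place foragers that
return to the same roost nightly this hardly matters; for animals that drift
between sleeping sites it makes the null data biologically impossible and can
bias the test.

The *wrap-around* randomization implemented here replaces the permutation
with a circular time shift: each individual's whole trajectory is shifted by
`k` days, drawn uniformly from the integers `[-s, s]`, and the overhang is
re-attached at the other end like a conveyor belt. Day-to-day continuity is
preserved everywhere except at a single junction, so each randomized
individual has **at most one** teleportation (exactly one unless `k = 0`),
while relative shifts between individuals still destroy their synchrony.
`count_teleportations()` verifies the bound on any randomized dataset.

## The test

For either method the inference is the same permutation logic:

1. detect interactions in the observed data — two individuals interact at a
   time point when they are closer than a threshold distance (for the
   simulator, twice the mean step length; `interaction_threshold()`);
2. build the weighted interaction network and compute the population mean
   degree (unique partners) and mean strength (summed edge weights),
   isolates included;
3. repeat the randomization (100 iterations by default), rebuilding the
   network each time, to obtain the null distribution of each population
   mean (`null_metric_distribution()`);
4. compare observed to null (`compare_to_null()`): the Z-score is
   `(observed - mean(null)) / sd(null)`, and significance is declared
   two-tailed when the observed mean falls outside the central 95% of the
   null values. Sociality can thus be detected as attraction (above) or
   avoidance (below).

`detection_likelihood()` reports the two-tailed empirical tail fraction
`2 * min(frac(null >= obs), frac(null <= obs))`. Over replicate simulated
experiments, `false_positive_rate()` is the fraction of non-sociable runs
declared significant and `false_negative_rate()` the fraction of sociable
runs missed.

## The movement model

The validation harness needs populations with *known* social structure, so
the package ships the agent-based model it is validated against. Agents move
by a biased-correlated random walk (BCRW) in discrete time:

* **Step lengths** are gamma distributed with mean 7 and standard deviation 5
  (arbitrary length units). Mean/sd is converted to shape/scale by moment
  matching (`gamma_params()`: shape `(m/s)^2`, scale `s^2/m`).
* **Step directions** are Von Mises draws centred on the bearing from the
  agent's current position to its *bias target*, with concentration
  `kappa_step`.
* **Bias target.** Non-social agents target their home-range centre. Social
  agents that perceive a conspecific within the perception distance (1000
  units) target the weighted average
  `w * nearest_neighbour + (1 - w) * centre`, with social weight `w = 0.75`
  by default (varied 0.1–1 in the validation experiments).
* **Home-range centres** themselves drift once per simulated day by their own
  random walk, with gamma step lengths of mean `7 * factor` and sd 0.75
  times that mean. Three scenarios: `static` (factor 0.01 — effectively
  fixed), `local` (factor 10, uniform daily headings — tortuous wandering),
  and `directional` (factor 10, Von Mises-persistent headings — a steady
  march). The scenarios span central-place foraging through nomadic and
  migratory-like movement.
* **Initialization.** Centres are drawn uniformly from a square whose side is
  two-thirds of the perception distance, so all agents can initially
  perceive one another; each agent starts at its centre with a uniform
  heading.

The standard population is 30 agents, 50 days, 50 steps per day. Interactions
use the co-location rule (distance < 14 units, i.e. twice the mean step
length); a stricter co-movement rule requiring closeness at two consecutive
within-day steps is available for sensitivity analyses, and a
timestamped in-flight rule (speed > 5 m/s, within 1 km, two consecutive
10-min intervals, simple-ratio-index edge weights) supports empirical GPS
pipelines.

### Parameters the model does not pin down

Two Von Mises concentrations are described only qualitatively in the
literature this model follows ("semi-linear" paths; "heavily concentrated"
directional drift). The package fixes them as explicit, documented defaults:

* `kappa_step = 4` — gives visibly correlated but noisy paths; at this value
  the mean resultant length of step directions about the target bearing is
  about 0.86.
* `kappa_hr_directional = 20` — successive home-range headings correlate
  above 0.95, producing near-linear centre marches.

Both are ordinary configuration fields, so sensitivity to them can be probed
directly.

### Design choices that were genuinely open

* **Pure bias rather than heading blending.** The Von Mises mean is exactly
  the bearing to the bias target; path correlation emerges from the
  persistence of the target, not from mixing in the previous heading. A
  `heading_blend` weight (default 0) exposes true BCRW mixing for users who
  want it; the off state keeps the model minimal and every test sharp.
* **Daily home-range updates.** Centres move once per day, not per step:
  agents are biased toward their centre *for the current day*, and the
  scenarios are defined by day-scale drift.
* **Synchronous stepping.** At each step every agent perceives the others'
  positions from the previous step and all update together; results cannot
  depend on agent iteration order.
* **Nearest-neighbour ties** break to the lowest individual id, so a seeded
  run is bit-reproducible.
* **One RNG stream.** All randomness flows from a single seeded generator in
  a fixed order (vectorised across agents), which makes `simulate_tracks()`
  bit-identical for identical seeds without per-agent stream bookkeeping.
* **Unbounded plane.** No landscape, boundaries, or reflection; spatial
  structure comes entirely from home-range attraction.

## Randomization conventions

* **`k = 0` is a legal draw.** The shift is uniform on the *integers*
  `[-s, s]`, which includes the identity; with many individuals one identity
  draw still leaves that individual decoupled from the shifted rest. No
  re-drawing.
* **Per-individual wrap is the default.** Each individual wraps around its
  own tracked days, skipping gaps (`period = "individual"`); this matches how
  the method is applied to field data where tracking durations differ. The
  alternative — shifting across the full shared calendar, landing individuals
  on days they were not tracked — is available as `period = "global"`, and
  both conventions matter when trajectories contain gaps.
* **Slots are 1-based** and the junction falls between the slots holding the
  last and first original days.
* **Shuffling** uses one uniform random permutation per individual
  (Fisher–Yates semantics), identity permitted; the windowed variant permutes
  within contiguous segments of the ordered tracked days.
* **Downsampling** keeps steps `ceiling(1 + (j-1) * steps_per_day /
  points_per_day)` — deterministic and evenly spread even when the stride is
  fractional.
* **Timestamped data** are randomized in day units after `assign_days()`
  (UTC calendar dates by default; the day boundary is movable via
  `day_start_hour` for species active across midnight). Timestamps shift by
  whole days so times of day are never altered.

## Numerical and degenerate-case conventions

* "Closer than" is strict (`<`) for the simulation thresholds; the empirical
  "within 1 km" flight rule is inclusive (`<=`). The boundary has measure
  zero for continuous coordinates, but the conventions are fixed and tested.
* A zero-variance null (possible at `s = 0`, where every iteration is the
  identity) yields an undefined Z-score (`NA`) and falls back to strict
  range comparison for significance — reported, never silently significant.
* Missing fixes at a time point simply remove that pair-time from
  consideration (and from the simple-ratio-index denominator).
* Co-movement chains do not cross day boundaries: days are the randomization
  unit, so a chain spanning the junction would be an artefact. The empirical
  flight rule chains across the full timestamp grid instead, breaking only
  at genuine gaps.
* Empirical significance uses the type-7 sample quantile at 2.5%/97.5%; the
  tail fraction uses exhaustive counting. Both are checked against
  brute-force oracles in the test suite.

## What the validation shows — and at what scale

The test suite re-derives the method's headline behaviour from scratch at
desk scale (sizes chosen to keep the full suite a few minutes long, as the
package's own standard conditions for its checks):

* step-length moments recovered to three standard errors at 2 × 10⁵ draws;
* the teleportation bound (≤ 1 per individual, 0 only for identity shifts)
  over 50 seeded wraps of a full 30 × 50 × 50 simulation at `s = 20`;
* true positives: a sociable static-home-range population (weight 0.75,
  15 agents, 25 days, 50 steps/day) has observed mean strength above the
  97.5th percentile of both 50-iteration nulls;
* false-positive control: 20 replicate non-sociable static experiments with
  wrap-around at `s` = 20% of the period declare significance in at most 5%
  of replicates;
* method ordering: in at least 80% of 10 replicate non-sociable
  *directional* runs (20 agents, 30 days — enough interactions for a stable
  population mean), path shuffling's null deviates farther from the observed
  mean strength than wrap-around at `s = 1`, the mechanism that makes
  wrap-around the safer null when animals shift their activity centres.

The synthetic generator emulates spatially constrained, socially attracted
movement with clean, complete, regular sampling. It does not emulate GPS
error, irregular gaps, heterogeneous individuals, landscape/resource
dynamics, or density change over a season — so passing tests demonstrate the
statistical machinery, not robustness to every field complication. In
particular, when the landscape itself changes quickly (ephemeral food,
variable uplift), any trajectory randomization can mistake aggregation at
fleeting resources for social attraction; choosing a small shift range
matched to the timescale of resource turnover mitigates but does not remove
this.

## Known limitations

* Only degree and strength are computed; other network measures respond
  differently to randomization and are out of scope.
* Replicate-level false-positive/negative rates require repeated observed
  simulations (`n_replicates`); a single observed run per condition gives
  only the per-iteration tail fraction.
* The wrap-around's power is bounded by `s`: at `s = 1` each individual has
  three possible start days, so some pairs retain their original alignment;
  at the other extreme `s = n/2` approaches (but never equals) path
  shuffling's marginal behaviour while still preserving continuity.
* Empirical mode ships as functions plus a documented recipe (see the
  README); no field dataset is bundled.
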