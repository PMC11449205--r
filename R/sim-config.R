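#' Simulation configuration for the biased-correlated random walk model
#'
#' Bundles every parameter of the agent-based movement model: population size
#' and tracking duration, the gamma step-length distribution, the Von Mises
#' directional concentration, the social-attraction rule, and the behaviour of
#' the mobile home-range centres. Defaults reproduce the model's standard
#' study conditions: 30 agents tracked for 50 days at 50 steps per day, step
#' lengths with mean 7 and standard deviation 5 (arbitrary length units), a
#' social perception distance of 1000 units, a social weight of 0.75, and
#' home-range drift steps whose mean is the agent step mean scaled by 0.01
#' (static) or 10 (local/directional drift) with a standard deviation of 0.75
#' times that mean. Agents start at home-range centres drawn uniformly from a
#' square whose side is two-thirds of the perception distance, so every agent
#' can initially perceive every other.
#'
#' @param n_agents Number of agents (>= 1).
#' @param n_days Number of simulated days (>= 1).
#' @param steps_per_day Movement steps per day (>= 1).
#' @param step_mean,step_sd Mean and standard deviation of the gamma
#'   step-length distribution, in length units.
#' @param kappa_step Von Mises concentration of agent step directions about
#'   the bearing to the current bias target. Larger values give straighter,
#'   more goal-directed paths; the default 4 gives visibly correlated but
#'   noisy ("semi-linear") paths.
#' @param social Logical; if `TRUE` agents are attracted to their nearest
#'   perceived conspecific.
#' @param social_weight Mixing fraction in \[0, 1\] pulling the bias target
#'   toward the nearest in-range neighbour (1 = pure social attraction,
#'   0 = pure home-range attraction).
#' @param perception_distance Radius (length units) within which conspecifics
#'   are perceived.
#' @param hr_scenario Home-range behaviour: `"static"` (centre effectively
#'   fixed), `"local"` (centre drifts with uniformly random daily headings,
#'   giving tortuous wandering), or `"directional"` (centre drifts with
#'   heavily concentrated headings, giving a persistent directional march).
#' @param hr_step_mean_factor Multiplier of `step_mean` giving the mean daily
#'   home-range drift step. Defaults to 0.01 for `"static"` and 10 for the
#'   two changing scenarios.
#' @param hr_step_sd_factor Standard deviation of the home-range drift step as
#'   a fraction of its mean (default 0.75).
#' @param kappa_hr_directional Von Mises concentration of successive
#'   home-range headings in the `"directional"` scenario (default 20, a
#'   heavily concentrated distribution).
#' @param start_square_side Side (length units) of the square from which
#'   initial home-range centres are drawn uniformly. Default
#'   `2/3 * perception_distance`.
#' @param heading_blend Optional fraction in \[0, 1\] blending the previous
#'   step heading into the Von Mises mean direction (0, the default, means the
#'   mean direction is purely the bearing to the bias target; path correlation
#'   then emerges from the persistence of the target itself).
#' @param seed Optional integer seed stored with the configuration and used by
#'   [simulate_tracks()].
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [simulate_tracks()], [interaction_threshold()]
#' @examples
#' cfg <- sim_config(n_agents = 5, n_days = 3, steps_per_day = 10, seed = 1)
#' cfg
#' @export
sim_config <- function(n_agents = 30,
                       n_days = 50,
                       steps_per_day = 50,
                       step_mean = 7,
                       step_sd = 5,
                       kappa_step = 4,
                       social = FALSE,
                       social_weight = 0.75,
                       perception_distance = 1000,
                       hr_scenario = c("static", "local", "directional"),
                       hr_step_mean_factor = NULL,
                       hr_step_sd_factor = 0.75,
                       kappa_hr_directional = 20,
                       start_square_side = NULL,
                       heading_blend = 0,
                       seed = NULL) {
  hr_scenario <- match.arg(hr_scenario)
  if (is.null(hr_step_mean_factor)) {
    hr_step_mean_factor <- if (hr_scenario == "static") 0.01 else 10
  }
  if (is.null(start_square_side)) {
    start_square_side <- 2 / 3 * perception_distance
  }

  for (nm in c("n_agents", "n_days", "steps_per_day")) {
    if (!is_count(get(nm))) {
      abort(paste0("`", nm, "` must be a single integer >= 1."))
    }
  }
  if (!is.numeric(step_mean) || step_mean <= 0) abort("`step_mean` must be > 0.")
  if (!is.numeric(step_sd) || step_sd <= 0) abort("`step_sd` must be > 0.")
  if (!is.numeric(kappa_step) || kappa_step < 0) abort("`kappa_step` must be >= 0.")
  if (!is.logical(social) || length(social) != 1L || is.na(social)) {
    abort("`social` must be TRUE or FALSE.")
  }
  if (!is.numeric(social_weight) || social_weight < 0 || social_weight > 1) {
    abort("`social_weight` must lie in [0, 1].")
  }
  if (!is.numeric(perception_distance) || perception_distance <= 0) {
    abort("`perception_distance` must be > 0.")
  }
  if (!is.numeric(hr_step_mean_factor) || hr_step_mean_factor <= 0) {
    abort("`hr_step_mean_factor` must be > 0.")
  }
  if (!is.numeric(hr_step_sd_factor) || hr_step_sd_factor <= 0) {
    abort("`hr_step_sd_factor` must be > 0.")
  }
  if (!is.numeric(kappa_hr_directional) || kappa_hr_directional < 0) {
    abort("`kappa_hr_directional` must be >= 0.")
  }
  if (!is.numeric(start_square_side) || start_square_side <= 0) {
    abort("`start_square_side` must be > 0.")
  }
  if (!is.numeric(heading_blend) || heading_blend < 0 || heading_blend > 1) {
    abort("`heading_blend` must lie in [0, 1].")
  }
  if (!is.null(seed) && !is_count(seed, min = 0L)) {
    abort("`seed` must be a single non-negative integer (or NULL).")
  }

  structure(
    list(
      n_agents = as.integer(n_agents),
      n_days = as.integer(n_days),
      steps_per_day = as.integer(steps_per_day),
      step_mean = step_mean,
      step_sd = step_sd,
      kappa_step = kappa_step,
      social = social,
      social_weight = social_weight,
      perception_distance = perception_distance,
      hr_scenario = hr_scenario,
      hr_step_mean_factor = hr_step_mean_factor,
      hr_step_sd_factor = hr_step_sd_factor,
      kappa_hr_directional = kappa_hr_directional,
      start_square_side = start_square_side,
      heading_blend = heading_blend,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d agents x %d days x %d steps/day\n",
    x$n_agents, x$n_days, x$steps_per_day
  ))
  cat(sprintf(
    "  step lengths: gamma(mean = %g, sd = %g); kappa_step = %g\n",
    x$step_mean, x$step_sd, x$kappa_step
  ))
  cat(sprintf(
    "  home ranges: %s (drift mean factor %g, sd factor %g)\n",
    x$hr_scenario, x$hr_step_mean_factor, x$hr_step_sd_factor
  ))
  if (x$social) {
    cat(sprintf(
      "  social: weight %g within perception distance %g\n",
      x$social_weight, x$perception_distance
    ))
  } else {
    cat("  social: off\n")
  }
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' Serializes a [sim_config()] to a flat key-value YAML file (field names match
#' the `sim_config()` arguments) and back, so runs can be declared in files and
#' reproduced from the command line.
#'
#' @param path File path.
#' @param cfg A `sim_config` object.
#' @return `read_sim_config()` returns a `sim_config`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown configuration key(s): ",
      paste0("`", unknown, "`", collapse = ", "), "."
    ))
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}
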