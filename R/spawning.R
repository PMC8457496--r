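#' Simulation configuration for the dispersal IBM
#'
#' @param year simulated year (must match the provider's).
#' @param timestep model time step in seconds; must divide one day
#'   (default 600 s).
#' @param total_eggs total annual egg production spread over all spawning
#'   grounds; default 1.89e13.
#' @param n_particles super-individuals released per spawning ground; each
#'   carries `total_eggs * egg_share / n_particles` eggs. Default 10^4;
#'   desk-scale experiments typically use far fewer.
#' @param spawn_threshold spawning-trigger temperature, deg C (default 10).
#' @param spawn_halfwidth half-width of the spawning window in days
#'   (default 50: release runs from peak-50 to peak+50).
#' @param spawn_shape temporal shape of egg release within the window:
#'   `"gaussian"` (default, sd `spawn_sigma` truncated at the window) or
#'   `"uniform"`.
#' @param spawn_sigma SD (days) of the Gaussian release shape (default 25).
#' @param stage_parameters stage table, see [default_stage_parameters()].
#' @param rng_seed integer seed; every random draw in [simulate_dispersal()]
#'   flows from it.
#' @param mortality_mode `"weight"` (deterministic survival weights,
#'   default) or `"stochastic"` (Bernoulli culling).
#' @param max_days drift horizon: days simulated beyond the last release
#'   (default 150).
#' @param release_depth initial particle depth, m (default 5).
#' @param surface_layer confinement depth for egg/yolk-sac surface keeping,
#'   m (default 10).
#' @param integrator horizontal advection scheme, `"rk4"` (default) or
#'   `"euler"`.
#' @param settlement_rule `"end_of_stage"` (settle only if inside a nursery
#'   at metamorphosis completion, default) or `"during_mtl"` (settle on
#'   first nursery entry any time during the metamorphosing stage).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(year = 2014L, timestep = 600,
                              total_eggs = 1.89e13, n_particles = 1e4,
                              spawn_threshold = 10, spawn_halfwidth = 50,
                              spawn_shape = c("gaussian", "uniform"),
                              spawn_sigma = 25,
                              stage_parameters = default_stage_parameters(),
                              rng_seed = 1L,
                              mortality_mode = c("weight", "stochastic"),
                              max_days = 150, release_depth = 5,
                              surface_layer = 10,
                              integrator = c("rk4", "euler"),
                              settlement_rule = c("end_of_stage",
                                                  "during_mtl")) {
  .assert(86400 %% timestep == 0, "timestep must divide one day (86400 s)")
  .assert(n_particles >= 1, "n_particles must be >= 1")
  structure(list(
    year = as.integer(year), timestep = timestep, total_eggs = total_eggs,
    n_particles = n_particles, spawn_threshold = spawn_threshold,
    spawn_halfwidth = spawn_halfwidth,
    spawn_shape = match.arg(spawn_shape), spawn_sigma = spawn_sigma,
    stage_parameters = stage_parameters, rng_seed = as.integer(rng_seed),
    mortality_mode = match.arg(mortality_mode), max_days = max_days,
    release_depth = release_depth, surface_layer = surface_layer,
    integrator = match.arg(integrator),
    settlement_rule = match.arg(settlement_rule)), class = "simulation_config")
}

#' Temperature-triggered spawning schedule
#'
#' The peak spawning day of a ground is the first day of the year on which
#' its spatial-mean surface temperature reaches the trigger (10 deg C by
#' default); release spans the window peak +/- 50 days (101 calendar days).
#' Daily egg quantities follow the configured temporal shape and sum to
#' `total_eggs * egg_share`. If the window would start before day 1 it is
#' clipped at the start of the year (with a warning) and the total is
#' preserved over the clipped window.
#'
#' @param ground a [spawning_ground()].
#' @param daily_mean_temperature one value per day of the year
#'   ([ground_mean_temperature()]).
#' @param config a [simulation_config()].
#' @return data frame with `day` (day of year), `date`, `eggs`; zero rows
#'   (with a warning) when the temperature never reaches the trigger.
#' @export
spawning_schedule <- function(ground, daily_mean_temperature, config) {
  ndays <- length(daily_mean_temperature)
  .assert(ndays >= 365, "need one full year of daily mean temperatures")
  origin <- as.Date(sprintf("%d-01-01", config$year))
  hit <- which(daily_mean_temperature >= config$spawn_threshold)
  if (length(hit) == 0) {
    warning(sprintf("ground %s: temperature never reaches %g deg C; empty schedule",
                    ground$code, config$spawn_threshold), call. = FALSE)
    return(data.frame(day = integer(), date = as.Date(character()),
                      eggs = numeric()))
  }
  peak <- hit[1]
  lo <- peak - config$spawn_halfwidth
  hi <- min(ndays, peak + config$spawn_halfwidth)
  if (lo < 1) {
    warning(sprintf("ground %s: spawning window clipped at the start of the year (peak day %d)",
                    ground$code, peak), call. = FALSE)
    lo <- 1
  }
  days <- lo:hi
  w <- if (config$spawn_shape == "gaussian") {
    exp(-(days - peak)^2 / (2 * config$spawn_sigma^2))
  } else {
    rep(1, length(days))
  }
  eggs <- w / sum(w) * config$total_eggs * ground$egg_share
  data.frame(day = days, date = origin + (days - 1), eggs = eggs)
}
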