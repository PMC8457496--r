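#' Idealized analytic flow-field provider
#'
#' Builds a deterministic, analytic implementation of the flow-field
#' interface the dispersal simulator runs on. The field emulates the
#' qualitative structure of a shelf sea with a southern coastline: a steady
#' along-coast residual current (the large-scale anticlockwise circulation
#' that sets the overall drift direction), an oscillating semidiurnal tidal
#' current, a seasonal sinusoidal sea-surface temperature with a weak
#' latitudinal gradient, a surface-to-bottom parabolic eddy-diffusivity
#' profile, and a bathymetry deepening linearly offshore. It is a stand-in
#' forcing for desk-scale experiments, not a hydrodynamic hindcast: any
#' provider implementing the same closure list (velocity, temperature,
#' diffusivity + derivative, bathymetry, tidal phase, day/night) can be
#' substituted, e.g. one interpolating archived model currents.
#'
#' Time is measured in seconds since 00:00 on January 1 of `year`.
#' Depth is in metres, positive downward.
#'
#' @param config named list overriding any default: `year` (2014),
#'   `lon_range` (-1..6), `lat_range` (50..54.5), `residual_u` (eastward
#'   along-coast speed, 0.05 m/s), `tidal_amplitude` (0.5 m/s),
#'   `tidal_period` (M2, 12.42 h in s), `sst_mean` (11 deg C at 51 N),
#'   `sst_amplitude` (6 deg C), `sst_min_doy` (day of year of the SST
#'   minimum, 15), `sst_lat_gradient` (-0.2 deg C per degree north),
#'   `k_max` (0.01 m^2/s), `k_background` (1e-4 m^2/s), `coast_lat`
#'   (50.4), `coast_depth` (5 m), `bathy_slope` (40 m per degree
#'   latitude), `day_start`/`day_end` (hours, 6 and 18).
#' @return Object of class `flow_field`: list of vectorized closures
#'   `velocity(lon, lat, depth, time)` -> list(u, v) m/s;
#'   `surface_temperature(lon, lat, time)` -> deg C;
#'   `diffusivity(depth, lon, lat, time)` -> list(K, dKdz);
#'   `bathymetry(lon, lat)` -> m; `tidal_phase(time, lon, lat)` ->
#'   "rising"/"falling"; `day_night(time, lon, lat)` -> "day"/"night";
#'   plus `year`, `origin` (Date), `time_range` (s), `domain`, `config`.
#' @export
generate_ideal_field <- function(config = list()) {
  cfg <- utils::modifyList(list(
    year = 2014L,
    lon_range = c(-1, 6), lat_range = c(50, 54.5),
    residual_u = 0.05, tidal_amplitude = 0.5, tidal_period = 12.42 * 3600,
    sst_mean = 11, sst_amplitude = 6, sst_min_doy = 15,
    sst_lat_gradient = -0.2,
    k_max = 0.01, k_background = 1e-4,
    coast_lat = 50.4, coast_depth = 5, bathy_slope = 40,
    day_start = 6, day_end = 18), config)
  .assert(cfg$residual_u >= 0 && cfg$tidal_amplitude >= 0,
          "current speeds must be >= 0")
  year_sec <- 365 * 86400 + (if (is_leap(cfg$year)) 86400 else 0)
  origin <- as.Date(sprintf("%d-01-01", cfg$year))

  sst <- function(lon, lat, time) {
    doy <- time / 86400 + 1
    cfg$sst_mean + cfg$sst_lat_gradient * (lat - 51) -
      cfg$sst_amplitude * cos(2 * pi * (doy - cfg$sst_min_doy) / 365.25)
  }
  # the default SST trajectory must cross the 10 deg C spawning trigger
  mid_lat <- mean(cfg$lat_range)
  tcheck <- sst(0, mid_lat, (0:364) * 86400)
  .assert(any(tcheck < 10) == FALSE || any(tcheck >= 10),
          "SST never reaches 10 deg C: spawning would never trigger")

  bathymetry <- function(lon, lat) {
    pmax(1, cfg$coast_depth + cfg$bathy_slope * (lat - cfg$coast_lat))
  }
  velocity <- function(lon, lat, depth, time) {
    tide <- cfg$tidal_amplitude * sin(2 * pi * time / cfg$tidal_period)
    n <- max(length(lon), length(lat), length(time))
    list(u = rep_len(cfg$residual_u + tide, n), v = rep_len(0, n))
  }
  diffusivity <- function(depth, lon, lat, time) {
    H <- bathymetry(lon, lat)
    s <- depth / H
    K <- cfg$k_background + 4 * cfg$k_max * s * (1 - s)
    dK <- 4 * cfg$k_max * (1 - 2 * s) / H
    list(K = pmax(K, 0), dKdz = dK)
  }
  tidal_phase <- function(time, lon, lat) {
    ifelse(sin(2 * pi * time / cfg$tidal_period) >= 0, "rising", "falling")
  }
  day_night <- function(time, lon, lat) {
    h <- (time / 3600) %% 24
    ifelse(h >= cfg$day_start & h < cfg$day_end, "day", "night")
  }
  structure(list(
    velocity = velocity,
    surface_temperature = sst,
    diffusivity = diffusivity,
    bathymetry = bathymetry,
    tidal_phase = tidal_phase,
    day_night = day_night,
    year = cfg$year, origin = origin, time_range = c(0, 2 * year_sec),
    domain = list(lon = cfg$lon_range, lat = cfg$lat_range),
    config = cfg), class = "flow_field")
}

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow-field provider: year %d, lon %g..%g, lat %g..%g\n",
              x$year, x$domain$lon[1], x$domain$lon[2],
              x$domain$lat[1], x$domain$lat[2]))
  invisible(x)
}

#' Daily spatial-mean temperature over a ground
#'
#' Averages the provider's surface temperature over a regular grid of
#' points inside the ground polygon, at noon of every day of the year.
#' This is the series the spawning-phenology rule scans for the first
#' 10 deg C crossing.
#'
#' @param provider a `flow_field`.
#' @param ground a [spawning_ground()] (or any polygon list).
#' @param n_side grid resolution per axis.
#' @return numeric vector, one mean temperature per day of the year.
#' @export
ground_mean_temperature <- function(provider, ground, n_side = 8) {
  g <- grid_in_polygon(ground, n_side)
  ndays <- if (is_leap(provider$year)) 366 else 365
  vapply(seq_len(ndays), function(d) {
    t <- (d - 1) * 86400 + 43200
    mean(provider$surface_temperature(g$lon, g$lat, t))
  }, numeric(1))
}
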