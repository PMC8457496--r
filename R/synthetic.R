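# truncated-normal draws by rejection (truncation at lo, open below)
.rnorm_trunc <- function(n, mean, sd, lo = 0) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lo)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lo]
  }
  out
}

#' Configuration for the synthetic otolith-reading generator
#'
#' Defaults emulate the observed cohort structure of juvenile sole in the
#' southern North Sea: hatching between April 1 and May 15, larval-phase
#' counts Normal(23.2, 2.7^2) days, metamorphosis counts Normal(11.2,
#' 3.5^2) days (both truncated positive and rounded to whole increments),
#' per-station mean growth rates spanning 0.53-0.65 mm/day with
#' individual SD 0.07, and capture between August 15 and October 15.
#'
#' @param stations data frame with one row per station: `station`,
#'   `country`, `latitude`, `longitude`, `mu_growth` (mm/day). Default
#'   three stations spanning the observed growth-rate range.
#' @param n_fish fish generated per station (default 20).
#' @param year cohort year (default 2014).
#' @param hatch_window,capture_window `Date` pairs; defaults April 1 -
#'   May 15 and August 15 - October 15 of `year`.
#' @param larval_mean,larval_sd,meta_mean,meta_sd moments of the phase
#'   duration distributions (days).
#' @param growth_sd individual SD around the station mean growth rate.
#' @param larval_ring_fraction fraction of otoliths whose larval rings are
#'   readable (individual larval counts present). Default 1 so the
#'   zero-noise round trip covers every fish; lower it to emulate the
#'   realistic sparse-reading situation.
#' @param reading_noise_sd SD (days) of the reading error added to each
#'   increment count before rounding; default 0.
#' @param or_noise_sd SD (mm) of the otolith-radius residual around the
#'   linear length-radius relation; default 0.02.
#' @param rng_seed integer seed.
#' @return list of class `otolith_gen_config`.
#' @export
otolith_gen_config <- function(stations = NULL, n_fish = 20, year = 2014L,
                               hatch_window = NULL, capture_window = NULL,
                               larval_mean = 23.2, larval_sd = 2.7,
                               meta_mean = 11.2, meta_sd = 3.5,
                               growth_sd = 0.07,
                               larval_ring_fraction = 1,
                               reading_noise_sd = 0, or_noise_sd = 0.02,
                               rng_seed = 1L) {
  if (is.null(stations))
    stations <- data.frame(
      station = c("SYN-BE1", "SYN-BE2", "SYN-NL1"),
      country = c("BE", "BE", "NL"),
      latitude = c(51.23, 51.35, 53.48),
      longitude = c(2.80, 3.00, 6.49),
      mu_growth = c(0.65, 0.59, 0.53),
      stringsAsFactors = FALSE)
  if (is.null(hatch_window))
    hatch_window <- as.Date(sprintf(c("%d-04-01", "%d-05-15"), year))
  if (is.null(capture_window))
    capture_window <- as.Date(sprintf(c("%d-08-15", "%d-10-15"), year))
  .assert(all(c(larval_sd, meta_sd, growth_sd) > 0) &&
            reading_noise_sd >= 0 && or_noise_sd >= 0,
          "scale parameters must be positive")
  structure(list(stations = stations, n_fish = n_fish, year = as.integer(year),
                 hatch_window = hatch_window, capture_window = capture_window,
                 larval_mean = larval_mean, larval_sd = larval_sd,
                 meta_mean = meta_mean, meta_sd = meta_sd,
                 growth_sd = growth_sd,
                 larval_ring_fraction = larval_ring_fraction,
                 reading_noise_sd = reading_noise_sd,
                 or_noise_sd = or_noise_sd, rng_seed = as.integer(rng_seed)),
            class = "otolith_gen_config")
}

#' Generate a synthetic otolith dataset with known ground truth
#'
#' Draws, for each fish, a hatch date, integer larval and metamorphosis
#' phase durations, and a growth rate; settlement follows by construction
#' and the post-settlement count is the gap to the station's capture date.
#' Standard length is growth rate times age; otolith radius inverts the
#' linear length-radius relation (SL = 24.1 + 57.74 OR) plus noise.
#' Reading noise perturbs the increment counts before rounding. With zero
#' reading noise the full ageing/back-calculation pipeline recovers every
#' hatch and settlement date exactly -- the primary round-trip property of
#' the package.
#'
#' @param config an [otolith_gen_config()].
#' @return list of class `synthetic_otoliths`: `dataset` (a
#'   [sole_dataset()]), `truth` (data frame of true dates, durations and
#'   growth rates per fish), and the `config`.
#' @export
generate_otolith_dataset <- function(config = otolith_gen_config()) {
  stopifnot(inherits(config, "otolith_gen_config"))
  set.seed(config$rng_seed)
  st <- config$stations
  n_st <- nrow(st)
  sampling_date <- config$capture_window[1] +
    floor(runif(n_st) * (as.numeric(diff(config$capture_window)) + 1))
  stations <- data.frame(
    station = st$station, country = st$country, year = config$year,
    latitude = st$latitude, longitude = st$longitude,
    sampling_date = sampling_date, survey = "synthetic",
    overwinter = FALSE, stringsAsFactors = FALSE)
  fish_l <- truth_l <- read_l <- vector("list", n_st)
  for (i in seq_len(n_st)) {
    n <- config$n_fish
    hatch <- config$hatch_window[1] +
      floor(runif(n) * (as.numeric(diff(config$hatch_window)) + 1))
    L <- pmax(1, round_half_up(.rnorm_trunc(n, config$larval_mean,
                                            config$larval_sd)))
    M <- pmax(1, round_half_up(.rnorm_trunc(n, config$meta_mean,
                                            config$meta_sd)))
    settlement <- hatch + L + M
    post <- as.numeric(sampling_date[i] - settlement)
    if (any(post < 0))
      stop("capture window earlier than feasible settlement", call. = FALSE)
    g <- .rnorm_trunc(n, st$mu_growth[i], config$growth_sd, lo = 0.1)
    age <- as.numeric(sampling_date[i] - hatch)
    sl <- g * age
    or <- pmax(0.05, (sl - 24.1) / 57.74 + rnorm(n, 0, config$or_noise_sd))
    has_larval <- runif(n) < config$larval_ring_fraction
    noisy <- function(x) {
      if (config$reading_noise_sd == 0) return(x)
      pmax(0, round_half_up(x + rnorm(length(x), 0, config$reading_noise_sd)))
    }
    id <- sprintf("%s-%03d", st$station[i], seq_len(n))
    fish_l[[i]] <- data.frame(fish_id = id, station = st$station[i],
                              year = config$year, standard_length = sl,
                              selected_for_ageing = TRUE,
                              stringsAsFactors = FALSE)
    read_l[[i]] <- data.frame(
      fish_id = id, otolith_radius = or,
      larval_count = ifelse(has_larval, noisy(L), NA_real_),
      metamorphosis_count = noisy(M), post_settlement_count = noisy(post),
      n_readers = 2L, stringsAsFactors = FALSE)
    truth_l[[i]] <- data.frame(
      fish_id = id, station = st$station[i], hatch_date = hatch,
      settlement_date = settlement, larval_days = L, metamorphosis_days = M,
      post_settlement_days = post, age_days = age, growth_rate = g,
      stringsAsFactors = FALSE)
  }
  structure(list(
    dataset = sole_dataset(stations, do.call(rbind, fish_l),
                           do.call(rbind, read_l)),
    truth = do.call(rbind, truth_l),
    config = config), class = "synthetic_otoliths")
}

#' @export
print.synthetic_otoliths <- function(x, ...) {
  cat("synthetic otolith dataset (seed", x$config$rng_seed, "):\n  ")
  print(x$dataset)
  invisible(x)
}

#' Bundled simulation scenarios with known qualitative outcomes
#'
#' Three constructed configurations used throughout the test suite and the
#' validation examples:
#' \describe{
#'   \item{`straight_to_nursery`}{A single spawning ground upstream of a
#'     single wide nursery under steady eastward flow, constant 12 deg C,
#'     no diffusion: every particle settles in the target nursery.}
#'   \item{`two_source_mixing`}{Two spawning grounds at different
#'     latitudes under a strong meridional temperature gradient, so their
#'     spawning peaks (first 10 deg C crossing) are offset by roughly
#'     three weeks: the pooled arrival curve is bimodal, emulating
#'     arrival in two batches from two source grounds.}
#'   \item{`cold_year`}{The `straight_to_nursery` geometry with seasonal
#'     temperature forcing, plus a cold variant whose seasonal cycle is
#'     delayed by 20 days: the spawning peak shifts by exactly 20 days.}
#' }
#'
#' @param name scenario name.
#' @param n_particles super-individuals per ground (default 150; scenario
#'   scale, not production scale).
#' @param rng_seed seed stored in the scenario's simulation config.
#' @return list with `name`, `provider` (or `providers` for `cold_year`),
#'   `config`, `grounds`, `nurseries`, and scenario-specific `expected`
#'   quantities derivable from the configuration.
#' @export
scenario_fixture <- function(name = c("straight_to_nursery",
                                      "two_source_mixing", "cold_year"),
                             n_particles = 150, rng_seed = 1L) {
  name <- match.arg(name)
  band <- function(lon1, lon2, lat1 = 50.55, lat2 = 50.75)
    list(lon = c(lon1, lon2, lon2, lon1), lat = c(lat1, lat1, lat2, lat2))
  if (name == "straight_to_nursery") {
    fld <- list(year = 2014L, sst_amplitude = 0, sst_mean = 12,
                sst_lat_gradient = 0, residual_u = 0.05,
                tidal_amplitude = 0, k_max = 0, k_background = 0)
    g <- band(0, 0.4)
    nz <- band(1.5, 5, 50.45, 50.85)
    return(list(
      name = name,
      provider = generate_ideal_field(fld),
      config = simulation_config(year = 2014L, timestep = 1800,
                                 n_particles = n_particles,
                                 rng_seed = rng_seed, max_days = 120),
      grounds = list(spawning_ground("SRC", g$lon, g$lat, egg_share = 1)),
      nurseries = list(nursery_ground("TGT", nz$lon, nz$lat)),
      expected = list(settlement_fraction = 1)))
  }
  if (name == "two_source_mixing") {
    fld <- list(year = 2014L, sst_lat_gradient = -1.0, residual_u = 0.05,
                tidal_amplitude = 0, k_max = 0, k_background = 0,
                bathy_slope = 5, lat_range = c(50, 54.5))
    provider <- generate_ideal_field(fld)
    gA <- band(0, 0.4, 50.55, 50.75)          # warm, early-spawning source
    gB <- band(0, 0.4, 52.55, 52.75)          # cold source, ~3 weeks later
    nz <- list(lon = c(1.5, 5.5, 5.5, 1.5), lat = c(50.45, 50.45, 52.85, 52.85))
    cfg <- simulation_config(year = 2014L, timestep = 1800,
                             n_particles = n_particles, rng_seed = rng_seed,
                             spawn_halfwidth = 10, spawn_sigma = 5,
                             max_days = 150)
    grounds <- list(spawning_ground("EC", gA$lon, gA$lat, 0.5),
                    spawning_ground("BC", gB$lon, gB$lat, 0.5))
    peaks <- vapply(grounds, function(g) {
      tm <- ground_mean_temperature(provider, g)
      which(tm >= cfg$spawn_threshold)[1]
    }, numeric(1))
    return(list(
      name = name, provider = provider, config = cfg, grounds = grounds,
      nurseries = list(nursery_ground("TGT", nz$lon, nz$lat)),
      expected = list(release_offset_days = diff(peaks))))
  }
  # cold_year
  base_cfg <- list(year = 2014L, residual_u = 0.05, tidal_amplitude = 0,
                   k_max = 0, k_background = 0, sst_lat_gradient = 0)
  cold_cfg <- utils::modifyList(base_cfg, list(sst_min_doy = 15 + 20))
  g <- band(0, 0.4)
  nz <- band(1.5, 5, 50.45, 50.85)
  list(
    name = name,
    providers = list(baseline = generate_ideal_field(base_cfg),
                     cold = generate_ideal_field(cold_cfg)),
    config = simulation_config(year = 2014L, timestep = 1800,
                               n_particles = n_particles,
                               rng_seed = rng_seed, max_days = 120),
    grounds = list(spawning_ground("SRC", g$lon, g$lat, egg_share = 1)),
    nurseries = list(nursery_ground("TGT", nz$lon, nz$lat)),
    expected = list(peak_shift_days = 20))
}
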