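#' Run the observed-side pipeline: ages, dates, distributions, summaries
#'
#' Sequences the otolith analysis: age estimation from increment counts,
#' calendar back-calculation of hatching and settlement dates, per-station
#' summary statistics (ages, PLD, growth, mean dates) and weekly arrival
#' distributions per country and year. Stations sampled after an
#' overwintering period are carried through ageing but excluded from
#' back-calculation and summaries by default (their increment record is
#' unreliable); pass `exclude_overwinter = FALSE` to keep them.
#'
#' @param dataset a [sole_dataset()].
#' @param exclude_overwinter drop overwintering stations from
#'   back-calculation and summaries (default `TRUE`).
#' @param week_convention `"iso"` or `"jan1"`.
#' @param yolk_sac_offset optional days added to every PLD, see
#'   [estimate_ages()].
#' @param borrow_pooled see [estimate_ages()].
#' @return Object of class `observed_report`: list with `ages`, `dates`
#'   (per-fish hatch/settlement), `station_summary` (per-station n, mean
#'   age, PLD, growth rate, mean dates), `distributions` (named list of
#'   [weekly_arrival_distribution()]s, one per country-year), `excluded`
#'   (stations dropped, with reasons), and `settings`.
#' @export
run_observed_pipeline <- function(dataset, exclude_overwinter = TRUE,
                                  week_convention = c("iso", "jan1"),
                                  yolk_sac_offset = 0,
                                  borrow_pooled = TRUE) {
  week_convention <- match.arg(week_convention)
  ages <- estimate_ages(dataset, borrow_pooled = borrow_pooled,
                        yolk_sac_offset = yolk_sac_offset)
  usable <- if (exclude_overwinter) !ages$unreliable else
    rep(TRUE, nrow(ages))
  usable <- usable & !is.na(ages$pld)
  .assert(any(usable), "no usable stations after exclusions")
  excluded <- unique(ages$station[!usable])

  st <- dataset$stations
  m <- match(paste(ages$station, ages$year), paste(st$station, st$year))
  dates <- cbind(
    data.frame(fish_id = ages$fish_id, station = ages$station,
               year = ages$year, country = st$country[m],
               stringsAsFactors = FALSE),
    back_calculate_dates(st$sampling_date[m],
                         ifelse(usable, ages$age_at_capture, NA),
                         ifelse(usable, ages$pld, NA)))

  fi <- dataset$fish[match(ages$fish_id, dataset$fish$fish_id), ]
  rd <- dataset$readings[match(ages$fish_id, dataset$readings$fish_id), ]
  gr <- growth_rate(fi$standard_length, ages$age_at_capture)
  mean_date <- function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) return(as.Date(NA))
    as.Date(round_half_up(mean(as.numeric(d))), origin = "1970-01-01")
  }
  skey <- paste(ages$station, ages$year)
  station_summary <- do.call(rbind, lapply(unique(skey[usable]), function(k) {
    i <- which(skey == k & usable)
    j <- m[i][1]
    data.frame(
      station = st$station[j], year = st$year[j], country = st$country[j],
      n = length(i),
      age_mean = mean(ages$age_at_capture[i]), age_sd = sd(ages$age_at_capture[i]),
      pld_mean = mean(ages$pld[i]), pld_sd = sd(ages$pld[i]),
      sl_mean = mean(fi$standard_length[i]),
      or_mean = mean(rd$otolith_radius[i]),
      growth_mean = mean(gr[i], na.rm = TRUE),
      growth_sd = sd(gr[i]),
      settlement_date = mean_date(dates$settlement_date[i]),
      hatch_date = mean_date(dates$hatch_date[i]),
      stringsAsFactors = FALSE)
  }))

  ckey <- paste(st$country[m], ages$year, sep = "_")
  cells <- unique(ckey[usable])
  distributions <- lapply(cells, function(k) {
    i <- which(ckey == k & usable)
    weekly_arrival_distribution(dates$settlement_date[i],
                                year = ages$year[i][1],
                                nursery = st$country[m][i][1],
                                convention = week_convention)
  })
  names(distributions) <- cells

  structure(list(ages = ages, dates = dates,
                 station_summary = station_summary,
                 distributions = distributions,
                 excluded = excluded,
                 settings = list(exclude_overwinter = exclude_overwinter,
                                 week_convention = week_convention,
                                 yolk_sac_offset = yolk_sac_offset,
                                 borrow_pooled = borrow_pooled)),
            class = "observed_report")
}

#' @export
print.observed_report <- function(x, ...) {
  cat("observed-side pipeline report\n")
  cat(sprintf("  %d fish aged over %d stations; %d station(s) excluded\n",
              nrow(x$ages), nrow(x$station_summary), length(x$excluded)))
  print(x$station_summary[, c("station", "year", "n", "age_mean",
                              "pld_mean", "settlement_date", "hatch_date")],
        row.names = FALSE)
  invisible(x)
}

#' Full observed-versus-modelled validation run
#'
#' Executes the two validation modes: (1) year-specific -- for every
#' country-year arrival distribution in the observations, a dispersal
#' simulation for that year is compared curve-to-curve; (2) long-term --
#' the per-year predicted curves are averaged and each observed curve is
#' compared against the average. Also confronts observed and simulated
#' pelagic larval durations. Cells where the simulation produced no
#' arrival for the required nursery are reported absent and the run
#' continues.
#'
#' @param dataset a [sole_dataset()] of otolith readings.
#' @param config a [simulation_config()]; its `year` is replaced per
#'   simulated year.
#' @param provider a `flow_field`, rebuilt per year from its own config,
#'   or a `function(year)` returning a provider.
#' @param grounds,nurseries as in [simulate_dispersal()].
#' @param nursery_map named character vector mapping observed country
#'   codes to model nursery codes (default: identity).
#' @param ... passed to [run_observed_pipeline()].
#' @return Object of class `pipeline_report`: `observed` (the
#'   [run_observed_pipeline()] report), `simulations` (per year),
#'   `year_specific` and `longterm` comparison lists (entries `NA` where
#'   absent), `pld_comparison`, and a `provenance` block (seed, sizes,
#'   package version).
#' @export
run_full_validation <- function(dataset, config, provider, grounds,
                                nurseries, nursery_map = NULL, ...) {
  obs <- run_observed_pipeline(dataset, ...)
  years <- sort(unique(vapply(obs$distributions, `[[`, integer(1), "year")))
  make_provider <- if (is.function(provider)) provider else function(yr)
    generate_ideal_field(utils::modifyList(provider$config, list(year = yr)))

  sims <- lapply(years, function(yr) {
    cfg <- config
    cfg$year <- as.integer(yr)
    simulate_dispersal(cfg, make_provider(yr), grounds, nurseries)
  })
  names(sims) <- as.character(years)

  map_nursery <- function(country) {
    if (is.null(nursery_map)) country else unname(nursery_map[country])
  }
  pred_cell <- function(yr, nursery) {
    sim <- sims[[as.character(yr)]]
    arr <- sim$arrivals
    arr <- arr[arr$nursery %in% nursery, , drop = FALSE]
    if (nrow(arr) == 0) return(NULL)
    predicted_arrival_distribution(arr, convention =
                                     obs$settings$week_convention)
  }

  year_specific <- lapply(names(obs$distributions), function(cell) {
    d <- obs$distributions[[cell]]
    p <- pred_cell(d$year, map_nursery(as.character(d$nursery)))
    if (is.null(p)) return(NA)
    compare_distributions(d, p)
  })
  names(year_specific) <- names(obs$distributions)

  longterm <- lapply(names(obs$distributions), function(cell) {
    d <- obs$distributions[[cell]]
    per_year <- Filter(Negate(is.null), lapply(years, function(yr)
      pred_cell(yr, map_nursery(as.character(d$nursery)))))
    if (length(per_year) == 0) return(NA)
    for (i in seq_along(per_year)) per_year[[i]]$nursery <- d$nursery
    compare_distributions(d, longterm_average_distribution(per_year))
  })
  names(longterm) <- names(obs$distributions)

  all_arrivals <- do.call(rbind, lapply(sims, `[[`, "arrivals"))
  usable <- !obs$ages$unreliable & !is.na(obs$ages$pld)
  pldcmp <- if (nrow(all_arrivals) > 0)
    compare_pld(obs$ages$pld[usable], all_arrivals) else NA

  structure(list(
    observed = obs, simulations = sims,
    year_specific = year_specific, longterm = longterm,
    pld_comparison = pldcmp,
    provenance = list(
      package = as.character(utils::packageVersion("soledrift")),
      rng_seed = config$rng_seed, years = years,
      n_particles = config$n_particles, timestep = config$timestep)),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("observed-vs-modelled validation report\n")
  for (cell in names(x$year_specific)) {
    cmp <- x$year_specific[[cell]]
    if (identical(cmp, NA)) {
      cat(sprintf("  %s: no simulated arrivals (comparison absent)\n", cell))
    } else {
      cat(sprintf("  %s: year-specific overlap %.2f, lag %s\n", cell,
                  cmp$overlap, if (is.na(cmp$peak_lag)) "NA" else
                    sprintf("%+d wk", cmp$peak_lag)))
    }
  }
  if (!identical(x$pld_comparison, NA)) print(x$pld_comparison)
  invisible(x)
}

#' Canonical JSON rendering of a pipeline report
#'
#' Machine-checkable report body: comparison statistics, station
#' summaries, accounting and provenance, with dates in ISO-8601.
#' Regenerating the report from the same inputs and seed yields a
#' byte-identical string (no timestamps).
#'
#' @param report a `pipeline_report`.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when written to file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  cmp_block <- function(cmp) {
    if (identical(cmp, NA)) return(list(absent = TRUE))
    list(peak_lag = cmp$peak_lag, overlap = cmp$overlap,
         shared_week_range = cmp$shared_week_range)
  }
  ss <- report$observed$station_summary
  ss$settlement_date <- format(ss$settlement_date)
  ss$hatch_date <- format(ss$hatch_date)
  body <- list(
    station_summary = ss,
    year_specific = lapply(report$year_specific, cmp_block),
    longterm = lapply(report$longterm, cmp_block),
    pld = if (identical(report$pld_comparison, NA)) list(absent = TRUE) else
      list(observed_mean = report$pld_comparison$observed_mean,
           predicted_excl_ysl = report$pld_comparison$predicted_excl_ysl$mean,
           predicted_incl_ysl = report$pld_comparison$predicted_incl_ysl$mean,
           difference = report$pld_comparison$difference),
    accounting = lapply(report$simulations, `[[`, "accounting"),
    provenance = report$provenance)
  js <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Build a simulation configuration from a YAML file
#'
#' Reads a flat YAML mapping of [simulation_config()] arguments; an
#' optional `stage_parameters` block (list of per-stage mappings with
#' `stage`, `duration_a`, `duration_b`) overrides the shipped duration
#' coefficients, and `stage_set` selects `"default"` or `"short"`.
#'
#' @param path YAML file path.
#' @return a [simulation_config()].
#' @export
simulation_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  set <- y$stage_set %||% "default"
  overrides <- if (!is.null(y$stage_parameters))
    do.call(rbind, lapply(y$stage_parameters, as.data.frame)) else NULL
  y$stage_set <- NULL
  y$stage_parameters <- default_stage_parameters(set, overrides)
  do.call(simulation_config, y)
}
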