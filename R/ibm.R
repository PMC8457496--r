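#' Classify settlement positions against the nursery grounds
#'
#' A metamorphosing larva completing development settles if its position
#' lies inside a nursery polygon whose local bathymetry is shallower than
#' the nursery's maximum settling depth; otherwise it is lost. Nurseries
#' are tested in declared order; a warning is raised if any point falls in
#' more than one polygon (the first match wins).
#'
#' @param lon,lat positions (decimal degrees).
#' @param bathymetry local water depth at each position (m).
#' @param nurseries list of [nursery_ground()] objects.
#' @return character vector of nursery codes, `NA` where the position
#'   settles nowhere (lost).
#' @export
detect_settlement <- function(lon, lat, bathymetry, nurseries) {
  n <- length(lon)
  out <- rep(NA_character_, n)
  matches <- integer(n)
  for (nur in nurseries) {
    inside <- point_in_polygon(lon, lat, nur) & bathymetry < nur$max_depth
    matches <- matches + inside
    take <- inside & is.na(out)
    out[take] <- nur$code
  }
  if (any(matches > 1))
    warning("overlapping nursery polygons: first match in declared order used",
            call. = FALSE)
  out
}

# velocity in degrees/s at (lon, lat, t); depth enters the provider call
.vel_deg <- function(provider, lon, lat, depth, t) {
  v <- provider$velocity(lon, lat, depth, t)
  list(dlon = v$u / (111320 * cos(lat * pi / 180)),
       dlat = v$v / 110540)
}

# advance positions horizontally over dt seconds (RK4 or explicit Euler)
.advect <- function(provider, lon, lat, depth, t, dt, integrator) {
  if (integrator == "euler") {
    k1 <- .vel_deg(provider, lon, lat, depth, t)
    return(list(lon = lon + k1$dlon * dt, lat = lat + k1$dlat * dt))
  }
  k1 <- .vel_deg(provider, lon, lat, depth, t)
  k2 <- .vel_deg(provider, lon + 0.5 * dt * k1$dlon,
                 lat + 0.5 * dt * k1$dlat, depth, t + 0.5 * dt)
  k3 <- .vel_deg(provider, lon + 0.5 * dt * k2$dlon,
                 lat + 0.5 * dt * k2$dlat, depth, t + 0.5 * dt)
  k4 <- .vel_deg(provider, lon + dt * k3$dlon, lat + dt * k3$dlat,
                 depth, t + dt)
  list(lon = lon + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon),
       lat = lat + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat))
}

.STAGES <- c("EGG", "YSL", "FFL", "MTL")

#' Advance a set of pelagic particles by one time step
#'
#' The single-timestep kernel of the simulator, exposed for testing and
#' custom drivers. Applies, in order: horizontal advection (RK4 by
#' default; no horizontal random walk -- vertical shear dispersal is the
#' dominant horizontal spreading mechanism), stage-specific vertical
#' behaviour plus the Visser-corrected vertical random walk, mortality
#' (survival-weight decay or Bernoulli culling), and development
#' accumulation `dt / duration(T)` with carry-over of the remainder at
#' stage transitions. Metamorphosing larvae completing development are
#' classified settled or lost via [detect_settlement()].
#'
#' @param state particle state list (see [simulate_dispersal()]); vectors
#'   `lon`, `lat`, `depth`, `age`, `stage` (1-4), `dev`, `weight`,
#'   `status`, matrix `stage_days`, and bookkeeping columns.
#' @param t current model time (seconds since Jan 1 of the simulated
#'   year).
#' @param provider a flow-field provider ([generate_ideal_field()]).
#' @param config a [simulation_config()].
#' @param nurseries list of [nursery_ground()]s.
#' @return the updated state list.
#' @keywords internal
#' @export
step_particles <- function(state, t, provider, config, nurseries) {
  act <- which(state$status == "pelagic")
  if (length(act) == 0) return(state)
  dt <- config$timestep
  dt_days <- dt / 86400
  par <- config$stage_parameters
  lon <- state$lon[act]; lat <- state$lat[act]; depth <- state$depth[act]
  stage <- state$stage[act]

  Tloc <- provider$surface_temperature(lon, lat, t)
  .assert(all(Tloc > 0), "provider temperature must stay > 0 deg C")

  # --- horizontal advection
  newpos <- .advect(provider, lon, lat, depth, t, dt, config$integrator)
  out <- newpos$lon < provider$domain$lon[1] |
    newpos$lon > provider$domain$lon[2] |
    newpos$lat < provider$domain$lat[1] |
    newpos$lat > provider$domain$lat[2]
  # beaching: one reflection (stay put), then lost
  dry <- !out & provider$bathymetry(newpos$lon, newpos$lat) <= 0
  again <- dry & state$beached[act]
  state$beached[act][dry] <- TRUE
  keep_old <- dry & !again
  newpos$lon[keep_old] <- lon[keep_old]
  newpos$lat[keep_old] <- lat[keep_old]
  lost_now <- out | again
  lon <- newpos$lon; lat <- newpos$lat

  # --- vertical: behaviour + Visser random walk, reflective boundaries
  H <- provider$bathymetry(lon, lat)
  w <- behaviour_velocity(.STAGES[stage],
                          provider$day_night(t, lon, lat),
                          provider$tidal_phase(t, lon, lat),
                          depth = depth, params = par,
                          surface_layer = config$surface_layer)
  depth <- depth - w * dt                       # w positive up, depth down
  grad <- provider$diffusivity(depth, lon, lat, t)$dKdz
  zmid <- pmin(pmax(depth + 0.5 * grad * dt, 0), H)
  Kmid <- provider$diffusivity(zmid, lon, lat, t)$K
  draws <- runif(length(act), -1, 1)
  depth <- depth + grad * dt + draws * sqrt(2 * pmax(Kmid, 0) * dt * 3)
  depth <- reflect_depth(depth, H)

  # --- mortality at the pre-transition stage
  mrate <- mortality_rate(.STAGES[stage], Tloc, par)
  psurv <- exp(-mrate * dt_days)
  dead_now <- rep(FALSE, length(act))
  if (config$mortality_mode == "weight") {
    state$weight[act] <- state$weight[act] * psurv
  } else {
    dead_now <- runif(length(act)) > psurv
  }

  # --- development with remainder carry-over across transitions
  a <- par$duration_a[stage]; b <- par$duration_b[stage]
  dur <- a * Tloc^b
  dev <- state$dev[act] + dt_days / dur
  idx <- cbind(act, stage)
  state$stage_days[idx] <- state$stage_days[idx] + dt_days
  completed_mtl <- rep(FALSE, length(act))
  repeat {
    over <- which(dev >= 1 & !completed_mtl)
    if (length(over) == 0) break
    adv <- over[stage[over] < 4L]
    fin <- over[stage[over] >= 4L]
    completed_mtl[fin] <- TRUE
    if (length(adv)) {
      leftover <- (dev[adv] - 1) * (par$duration_a[stage[adv]] *
                                      Tloc[adv]^par$duration_b[stage[adv]])
      stage[adv] <- stage[adv] + 1L
      dur_new <- par$duration_a[stage[adv]] * Tloc[adv]^par$duration_b[stage[adv]]
      dev[adv] <- leftover / dur_new
    } else break
  }

  # --- settlement
  settle_now <- completed_mtl
  if (config$settlement_rule == "during_mtl") {
    inside_any <- rep(FALSE, length(act))
    mtl <- stage == 4L
    if (any(mtl)) {
      code <- detect_settlement(lon[mtl], lat[mtl], H[mtl], nurseries)
      inside_any[mtl] <- !is.na(code)
    }
    settle_now <- settle_now | inside_any
  }

  state$lon[act] <- lon; state$lat[act] <- lat; state$depth[act] <- depth
  state$stage[act] <- stage; state$dev[act] <- pmin(dev, 1)
  state$age[act] <- state$age[act] + dt_days

  if (any(settle_now)) {
    s <- act[settle_now]
    code <- detect_settlement(state$lon[s], state$lat[s],
                              provider$bathymetry(state$lon[s], state$lat[s]),
                              nurseries)
    ok <- !is.na(code)
    state$status[s[ok]] <- "settled"
    state$nursery[s[ok]] <- code[ok]
    state$arrival_t[s[ok]] <- t + dt
    state$status[s[!ok]] <- "lost"
  }
  state$status[act[lost_now & state$status[act] == "pelagic"]] <- "lost"
  state$status[act[dead_now & state$status[act] == "pelagic"]] <- "dead"
  state
}

#' Run the stage-structured larval dispersal simulation
#'
#' Releases super-individual eggs at the spawning grounds on the
#' temperature-triggered schedule ([spawning_schedule()]), steps every
#' pelagic particle through advection, vertical behaviour and diffusion,
#' temperature-dependent development and mortality, and records arrivals
#' of metamorphosing larvae at the nursery grounds. Each particle stands
#' for `total_eggs * egg_share / n_particles` eggs. The run is fully
#' reproducible from `config$rng_seed`.
#'
#' @param config a [simulation_config()].
#' @param provider a flow-field provider covering the simulated period.
#' @param grounds list of [spawning_ground()]s; egg shares must sum to 1.
#' @param nurseries list of [nursery_ground()]s.
#' @param trajectories if `TRUE`, daily particle positions are recorded
#'   and returned (memory scales with particles x days).
#' @return Object of class `sole_simulation`: list with `arrivals` (data
#'   frame: `particle_id`, `nursery`, `natal_ground`, `arrival_date`,
#'   `release_date`, `survival_weight`, `eggs`, per-stage realized
#'   durations `d_egg`, `d_ysl`, `d_ffl`, `d_mtl` and `pld_total`),
#'   `accounting` (released / pelagic / settled / lost / dead counts and
#'   egg-weighted equivalents), `schedules`, `particles` (final state) and
#'   the `config`.
#' @export
simulate_dispersal <- function(config, provider, grounds, nurseries,
                               trajectories = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  .assert(config$year == provider$year,
          "config year does not match provider year")
  if (config$total_eggs > 0)
    .assert(abs(sum(vapply(grounds, `[[`, numeric(1), "egg_share")) - 1) < 1e-9,
            "spawning-ground egg shares must sum to 1")
  set.seed(config$rng_seed)

  # spawning schedules per ground
  schedules <- lapply(grounds, function(g)
    spawning_schedule(g, ground_mean_temperature(provider, g), config))
  names(schedules) <- vapply(grounds, `[[`, character(1), "code")

  empty_arrivals <- data.frame(
    particle_id = integer(), nursery = character(),
    natal_ground = character(), arrival_date = as.Date(character()),
    release_date = as.Date(character()), survival_weight = numeric(),
    eggs = numeric(), d_egg = numeric(), d_ysl = numeric(),
    d_ffl = numeric(), d_mtl = numeric(), pld_total = numeric())
  if (config$total_eggs <= 0 || all(vapply(schedules, nrow, integer(1)) == 0)) {
    return(structure(list(
      arrivals = empty_arrivals,
      accounting = list(released = 0L, pelagic = 0L, settled = 0L,
                        lost = 0L, dead = 0L, eggs_released = 0,
                        eggs_settled = 0),
      schedules = schedules, particles = NULL, trajectory = NULL,
      config = config), class = "sole_simulation"))
  }

  # allocate particles to release days, proportional to egg quantity
  # (largest-remainder rounding), equal egg load per particle
  rel_t <- numeric(0); natal <- character(0); lon0 <- numeric(0)
  lat0 <- numeric(0); eggs_pp <- numeric(0)
  for (g in grounds) {
    sch <- schedules[[g$code]]
    if (nrow(sch) == 0) next
    quota <- config$n_particles * sch$eggs / sum(sch$eggs)
    cnt <- floor(quota)
    rem <- config$n_particles - sum(cnt)
    if (rem > 0) {
      extra <- order(quota - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1
    }
    days <- rep(sch$day, cnt)
    pos <- sample_in_polygon(length(days), g)
    rel_t <- c(rel_t, (days - 1) * 86400 + 43200)
    natal <- c(natal, rep(g$code, length(days)))
    lon0 <- c(lon0, pos$lon); lat0 <- c(lat0, pos$lat)
    eggs_pp <- c(eggs_pp, rep(sum(sch$eggs) / length(days), length(days)))
  }
  n <- length(rel_t)

  t0 <- min(rel_t)
  t_end <- max(rel_t) + config$max_days * 86400
  .assert(t0 >= provider$time_range[1] && t_end <= provider$time_range[2],
          "provider time coverage insufficient for the simulated period")

  # Visser stability check on the deepest column of the domain
  deep <- expand.grid(lon = seq(provider$domain$lon[1],
                                provider$domain$lon[2], length.out = 5),
                      lat = seq(provider$domain$lat[1],
                                provider$domain$lat[2], length.out = 5))
  hb <- provider$bathymetry(deep$lon, deep$lat)
  j <- which.max(hb)
  Kcol <- function(z) provider$diffusivity(z, deep$lon[j], deep$lat[j], t0)$K
  bound <- visser_stability_bound(Kcol, H = hb[j])
  .assert(config$timestep <= bound,
          sprintf("timestep %g s exceeds the Visser stability bound %g s for this diffusivity field",
                  config$timestep, bound))

  state <- list(
    id = seq_len(n), lon = lon0, lat = lat0,
    depth = rep(config$release_depth, n),
    age = numeric(n), stage = rep(1L, n), dev = numeric(n),
    weight = rep(1, n), eggs = eggs_pp, natal = natal,
    release_t = rel_t, status = rep("pending", n),
    beached = rep(FALSE, n),
    stage_days = matrix(0, n, 4, dimnames = list(NULL, .STAGES)),
    nursery = rep(NA_character_, n), arrival_t = rep(NA_real_, n))

  traj <- if (trajectories) list() else NULL
  t <- t0
  while (t < t_end) {
    state$status[state$status == "pending" & state$release_t <= t] <- "pelagic"
    if (!any(state$status %in% c("pending", "pelagic"))) break
    state <- step_particles(state, t, provider, config, nurseries)
    t <- t + config$timestep
    if (trajectories && (t - t0) %% 86400 == 0) {
      keep <- state$status == "pelagic"
      if (any(keep))
        traj[[length(traj) + 1]] <- data.frame(
          time = t, particle_id = state$id[keep], lon = state$lon[keep],
          lat = state$lat[keep], depth = state$depth[keep],
          stage = .STAGES[state$stage[keep]])
    }
  }

  origin <- as.Date(sprintf("%d-01-01", config$year))
  settled <- which(state$status == "settled")
  arrivals <- if (length(settled)) data.frame(
    particle_id = state$id[settled],
    nursery = state$nursery[settled],
    natal_ground = state$natal[settled],
    arrival_date = origin + floor(state$arrival_t[settled] / 86400),
    release_date = origin + floor(state$release_t[settled] / 86400),
    survival_weight = state$weight[settled],
    eggs = state$eggs[settled],
    d_egg = state$stage_days[settled, 1],
    d_ysl = state$stage_days[settled, 2],
    d_ffl = state$stage_days[settled, 3],
    d_mtl = state$stage_days[settled, 4],
    pld_total = rowSums(state$stage_days[settled, 2:4, drop = FALSE]),
    stringsAsFactors = FALSE) else empty_arrivals

  acct <- list(
    released = n,
    pelagic = sum(state$status %in% c("pending", "pelagic")),
    settled = sum(state$status == "settled"),
    lost = sum(state$status == "lost"),
    dead = sum(state$status == "dead"),
    eggs_released = sum(state$eggs),
    eggs_settled = sum(state$eggs[settled] * state$weight[settled]))

  structure(list(arrivals = arrivals, accounting = acct,
                 schedules = schedules, particles = state,
                 trajectory = if (trajectories && length(traj))
                   do.call(rbind, traj) else NULL,
                 config = config), class = "sole_simulation")
}

#' @export
print.sole_simulation <- function(x, ...) {
  a <- x$accounting
  cat("sole larval dispersal simulation\n")
  cat(sprintf("  released %d particles: %d settled, %d lost, %d dead, %d still pelagic\n",
              a$released, a$settled, a$lost, a$dead, a$pelagic))
  if (nrow(x$arrivals)) {
    s <- predicted_pld_summary(x, include_ysl = FALSE)
    cat(sprintf("  realized PLD (excl. yolk sac): %.1f +/- %.1f days\n",
                s$mean, s$sd))
  }
  invisible(x)
}

#' @export
summary.sole_simulation <- function(object, ...) {
  tab <- if (nrow(object$arrivals))
    table(object$arrivals$nursery, object$arrivals$natal_ground) else NULL
  out <- list(accounting = object$accounting, arrivals_by_route = tab)
  class(out) <- "summary.sole_simulation"
  out
}

#' @export
print.summary.sole_simulation <- function(x, ...) {
  str(x$accounting, give.head = FALSE)
  if (!is.null(x$arrivals_by_route)) {
    cat("arrivals (nursery x natal ground):\n")
    print(x$arrivals_by_route)
  }
  invisible(x)
}

#' Weekly arrival distribution predicted by the simulator
#'
#' Bins simulated nursery arrivals by week, weighted either by the
#' surviving egg numbers each super-individual carries
#' (`"survival_weight"`) or by raw particle counts (`"count"`), and
#' normalizes. Optionally decomposes the curve by natal spawning ground;
#' the components are normalized against the same total so they sum
#' week-wise to the pooled curve.
#'
#' @param sim a `sole_simulation`, or its `arrivals` data frame.
#' @param nursery restrict to one nursery code (default: all pooled).
#' @param weights `"survival_weight"` (default) or `"count"`.
#' @param by_natal if `TRUE`, attach the per-natal-ground decomposition as
#'   attribute `"by_natal"` (a named list of week/frequency data frames on
#'   the common axis).
#' @param convention week-numbering convention, see [week_number()].
#' @return an `arrival_distribution`.
#' @export
predicted_arrival_distribution <- function(sim, nursery = NULL,
                                           weights = c("survival_weight",
                                                       "count"),
                                           by_natal = FALSE,
                                           convention = c("iso", "jan1")) {
  weights <- match.arg(weights)
  convention <- match.arg(convention)
  arr <- if (inherits(sim, "sole_simulation")) sim$arrivals else sim
  if (!is.null(nursery)) arr <- arr[arr$nursery %in% nursery, , drop = FALSE]
  .assert(nrow(arr) > 0, "no arrivals to bin")
  w <- if (weights == "survival_weight") arr$survival_weight * arr$eggs
       else rep(1, nrow(arr))
  year <- as.integer(format(arr$arrival_date[1], "%Y"))
  wk <- week_number(arr$arrival_date, convention)
  dist <- .arrival_distribution(wk, w, year,
                                nursery %||% "all", n = nrow(arr),
                                convention = convention)
  if (by_natal) {
    tot <- sum(w)
    comp <- lapply(split(seq_len(nrow(arr)), arr$natal_ground), function(i) {
      f <- vapply(dist$week_numbers,
                  function(x) sum(w[i][wk[i] == x]), numeric(1)) / tot
      data.frame(week = dist$week_numbers, frequency = f)
    })
    attr(dist, "by_natal") <- comp
  }
  dist
}

#' Realized pelagic larval duration of simulated arrivals
#'
#' Sums the per-stage realized durations of each settled particle over the
#' larval stages and averages. Otolith-based PLD readings start at the
#' hatch check and typically miss the yolk-sac days (no increments are
#' deposited before first feeding), so the default excludes the yolk-sac
#' stage; `include_ysl = TRUE` gives the complete pelagic duration.
#'
#' @param sim a `sole_simulation` or an arrivals data frame.
#' @param include_ysl include the yolk-sac stage? Default `FALSE`.
#' @return list with `mean`, `sd`, `n`, `include_ysl`.
#' @export
predicted_pld_summary <- function(sim, include_ysl = FALSE) {
  arr <- if (inherits(sim, "sole_simulation")) sim$arrivals else sim
  .assert(nrow(arr) > 0, "no arrivals recorded")
  pld <- arr$d_ffl + arr$d_mtl + if (include_ysl) arr$d_ysl else 0
  list(mean = mean(pld), sd = if (length(pld) > 1) sd(pld) else 0,
       n = length(pld), include_ysl = include_ysl)
}
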