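test_that("stage duration follows the temperature power law", {
  p0 <- list(duration_a = 10, duration_b = 0)
  expect_equal(stage_duration(c(5, 15, 25), p0), rep(10, 3))
  expect_equal(stage_duration(10, list(duration_a = 100, duration_b = -1)), 10)
  pars <- default_stage_parameters()
  for (i in seq_len(nrow(pars)))
    expect_equal(stage_duration(12, pars[i, ]),
                 pars$duration_a[i] * 12^pars$duration_b[i])
  expect_error(stage_duration(0, p0), "temperature")
  # durations strictly decrease with T whenever b < 0
  Tgrid <- seq(4, 22, by = 0.5)
  for (i in seq_len(nrow(pars))) {
    d <- stage_duration(Tgrid, pars[i, ])
    expect_true(all(diff(d) < 0))
  }
})

test_that("mortality rules: temperature power for eggs/yolk-sac, constant after", {
  expect_equal(mortality_rate("FFL", c(5, 12, 20)), rep(0.035, 3))
  expect_equal(mortality_rate("MTL", 8), 0.035)
  expect_equal(mortality_rate("EGG", 10), 0.0004 * 10^3.0293)
  expect_equal(mortality_rate("YSL", 14), 0.0004 * 14^3.0293)
  expect_lt(mortality_rate("EGG", 0.01), 1e-9)
  Tgrid <- seq(4, 22, by = 0.5)
  expect_true(all(diff(mortality_rate("EGG", Tgrid)) > 0))
})

test_that("behaviour velocities return the four migration rates exactly", {
  expect_identical(behaviour_velocity("FFL", "night", "rising"), 0.003)
  expect_identical(behaviour_velocity("FFL", "day", "rising"), -0.001)
  expect_identical(behaviour_velocity("MTL", "day", "rising"), 0.001)
  expect_identical(behaviour_velocity("MTL", "night", "falling"), -0.003)
  # eggs keep to the surface layer: passive above, buoyant below
  expect_identical(behaviour_velocity("EGG", "day", "rising", depth = 5), 0)
  expect_identical(behaviour_velocity("EGG", "day", "rising", depth = 15),
                   0.001)
})

test_that("Visser step: no diffusion means no displacement", {
  z <- c(1, 5, 12)
  z2 <- visser_step(z, K = function(z) rep(0, length(z)),
                    dKdz = function(z) rep(0, length(z)),
                    dt = 600, H = 20, draws = c(-1, 0.3, 1))
  expect_equal(z2, z)
})

test_that("Visser step under constant K reproduces the random-walk variance", {
  set.seed(31)
  K <- 0.005; dt <- 300; n <- 40000
  z0 <- rep(500, n)  # far from the boundaries of a deep column
  z1 <- visser_step(z0, K = function(z) rep(K, length(z)),
                    dKdz = function(z) rep(0, length(z)), dt = dt, H = 1000)
  expect_equal(var(z1 - z0), 2 * K * dt, tolerance = 0.03)
  expect_equal(mean(z1 - z0), 0, tolerance = 0.05)
})

test_that("the stability guard rejects steps that under-resolve K curvature", {
  H <- 30; Kmax <- 0.01
  K <- function(z) 4 * Kmax * (z / H) * (1 - z / H)
  dKdz <- function(z) 4 * Kmax * (1 - 2 * z / H) / H
  bound <- visser_stability_bound(K, H)        # H^2 / (8 Kmax) analytically
  expect_equal(bound, H^2 / (8 * Kmax), tolerance = 1e-6)
  expect_error(visser_step(15, K, dKdz, dt = 2 * bound, H = H),
               "stability bound")
})

test_that("well-mixed condition holds under parabolic K (screening size)", {
  set.seed(7)
  H <- 30; Kmax <- 0.01; bg <- 1e-4
  K <- function(z) bg + 4 * Kmax * (z / H) * (1 - z / H)
  dKdz <- function(z) 4 * Kmax * (1 - 2 * z / H) / H
  n <- 3000
  z <- runif(n, 0, H)
  for (s in seq_len(1500)) z <- visser_step(z, K, dKdz, dt = 600, H = H)
  counts <- table(cut(z, seq(0, H, length.out = 11)))
  p <- suppressWarnings(chisq.test(as.numeric(counts))$p.value)
  expect_gt(p, 0.01)
})

test_that("point-in-polygon settlement matches an independent ray-casting oracle", {
  nur <- nursery_ground("BE", lon = c(2, 3.2, 3.0, 2.1),
                        lat = c(51.0, 51.1, 51.6, 51.5))
  set.seed(44)
  g <- data.frame(lon = runif(600, 1.8, 3.4), lat = runif(600, 50.9, 51.7))
  got <- detect_settlement(g$lon, g$lat, rep(10, nrow(g)), list(nur))
  want <- ray_cast_inside(g$lon, g$lat, nur$lon, nur$lat)
  # random points land on an edge with probability zero, so the two
  # boundary conventions cannot disagree here
  expect_identical(!is.na(got), want)
  # depth rule: inside the polygon but too deep -> lost
  expect_identical(detect_settlement(2.5, 51.3, 15, list(nur)), "BE")
  expect_true(is.na(detect_settlement(2.5, 51.3, 40, list(nur))))
  # overlapping polygons: warning, first declared match wins
  nur2 <- nursery_ground("NL", nur$lon, nur$lat)
  expect_warning(code <- detect_settlement(2.5, 51.3, 10, list(nur, nur2)),
                 "overlapping")
  expect_identical(code, "BE")
})

# a minimal constant-environment provider for closed-form kernel checks
quiet_provider <- function(Tconst = 12, year = 2014L) {
  structure(list(
    velocity = function(lon, lat, depth, time)
      list(u = rep(0, length(lon)), v = rep(0, length(lon))),
    surface_temperature = function(lon, lat, time) rep(Tconst, length(lon)),
    diffusivity = function(depth, lon, lat, time)
      list(K = rep(0, length(depth)), dKdz = rep(0, length(depth))),
    bathymetry = function(lon, lat) rep(25, length(lon)),
    tidal_phase = function(time, lon, lat) rep("rising", length(lon)),
    day_night = function(time, lon, lat) rep("day", length(lon)),
    year = year, origin = as.Date(sprintf("%d-01-01", year)),
    time_range = c(0, 2 * 365 * 86400),
    domain = list(lon = c(-1, 6), lat = c(50, 54.5)),
    config = list()), class = "flow_field")
}

blank_state <- function(n = 1, stage = 1L, depth = 5) {
  list(id = seq_len(n), lon = rep(2, n), lat = rep(51, n),
       depth = rep(depth, n), age = numeric(n), stage = rep(stage, n),
       dev = numeric(n), weight = rep(1, n), eggs = rep(1, n),
       natal = rep("SRC", n), release_t = numeric(n),
       status = rep("pelagic", n), beached = rep(FALSE, n),
       stage_days = matrix(0, n, 4), nursery = rep(NA_character_, n),
       arrival_t = rep(NA_real_, n))
}

test_that("kernel closed forms: development, survival decay, traversal time", {
  prov <- quiet_provider(Tconst = 12)
  cfg <- simulation_config(timestep = 600, rng_seed = 1)
  # one step: position unchanged, development advanced by dt/duration
  st <- step_particles(blank_state(), 0, prov, cfg, list())
  expect_equal(st$lon, 2); expect_equal(st$lat, 51); expect_equal(st$depth, 5)
  dur_egg <- 70 / 12
  expect_equal(st$dev, (600 / 86400) / dur_egg)

  # D days at constant T: weight equals exp(-m D) within 1e-9
  D <- 3
  st <- blank_state(stage = 3L)                     # FFL, constant m = 0.035
  nsteps <- D * 86400 / 600
  for (s in seq_len(nsteps)) st <- step_particles(st, (s - 1) * 600, prov, cfg, list())
  expect_equal(st$weight, exp(-0.035 * D), tolerance = 1e-9)

  # time to traverse the egg stage equals a*T^b within one timestep
  st <- blank_state(); t <- 0
  while (st$stage[1] == 1L) {
    st <- step_particles(st, t, prov, cfg, list()); t <- t + 600
  }
  expect_lt(abs(t / 86400 - dur_egg), 600 / 86400 + 1e-9)

  # halving the timestep changes the traversal time by less than one step
  cfg2 <- simulation_config(timestep = 300, rng_seed = 1)
  st <- blank_state(); t2 <- 0
  while (st$stage[1] == 1L) {
    st <- step_particles(st, t2, prov, cfg2, list()); t2 <- t2 + 300
  }
  expect_lt(abs(t2 - t) / 86400, 600 / 86400)
})

test_that("a zero-egg configuration yields an empty, well-formed simulation", {
  sc <- scenario_fixture("straight_to_nursery", n_particles = 10)
  cfg <- sc$config; cfg$total_eggs <- 0
  sim <- suppressWarnings(simulate_dispersal(cfg, sc$provider, sc$grounds,
                                             sc$nurseries))
  expect_identical(nrow(sim$arrivals), 0L)
  expect_identical(sim$accounting$released, 0L)
})

test_that("steady flow into a wide nursery settles every particle", {
  sc <- scenario_fixture("straight_to_nursery", n_particles = 60)
  sim <- suppressWarnings(
    simulate_dispersal(sc$config, sc$provider, sc$grounds, sc$nurseries))
  a <- sim$accounting
  expect_identical(a$settled, a$released)
  expect_true(all(sim$arrivals$nursery == "TGT"))
  # conservation of the particle budget
  expect_identical(a$released, a$pelagic + a$settled + a$lost + a$dead)
  # realized stage durations equal the constant-T closed form
  expect_equal(unique(round(sim$arrivals$d_ffl, 3)), round(300 / 12, 3),
               tolerance = 0.02)
  s <- predicted_pld_summary(sim, include_ysl = FALSE)
  si <- predicted_pld_summary(sim, include_ysl = TRUE)
  expect_equal(s$mean, (300 + 140) / 12, tolerance = 0.02)
  expect_gt(si$mean, s$mean)
})

test_that("the same seed reproduces a run exactly; different seeds perturb it", {
  sc <- scenario_fixture("straight_to_nursery", n_particles = 40)
  run <- function(seed) {
    cfg <- sc$config; cfg$rng_seed <- seed
    suppressWarnings(simulate_dispersal(cfg, sc$provider, sc$grounds,
                                        sc$nurseries))
  }
  s1 <- run(5); s2 <- run(5); s3 <- run(6)
  expect_identical(s1$arrivals, s2$arrivals)
  expect_false(identical(s1$particles$lon, s3$particles$lon))
})

test_that("arrival-curve weighting modes and natal decomposition are additive", {
  sc <- scenario_fixture("two_source_mixing", n_particles = 40)
  sim <- simulate_dispersal(sc$config, sc$provider, sc$grounds, sc$nurseries)
  expect_gt(nrow(sim$arrivals), 0)
  d <- predicted_arrival_distribution(sim, by_natal = TRUE)
  expect_equal(sum(d$frequencies), 1, tolerance = 1e-9)
  comp <- attr(d, "by_natal")
  expect_setequal(names(comp), c("EC", "BC"))
  tot <- Reduce(`+`, lapply(comp, `[[`, "frequency"))
  expect_equal(tot, d$frequencies, tolerance = 1e-9)
  # count weighting matches a brute-force unweighted histogram
  dc <- predicted_arrival_distribution(sim, weights = "count")
  want <- brute_week_hist(sim$arrivals$arrival_date)
  expect_equal(dc$frequencies[match(want$weeks, dc$week_numbers)], want$freq)
})
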