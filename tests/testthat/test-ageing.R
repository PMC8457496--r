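test_that("location mean larval count is the plain mean of present counts", {
  expect_identical(location_mean_larval_count(c(22, 24)), 23)
  expect_identical(location_mean_larval_count(23), 23)
  expect_true(is.na(location_mean_larval_count(c(NA_real_, NA_real_))))
  set.seed(11)
  x <- c(sample(15:30, 12, replace = TRUE), NA, NA)
  expect_equal(location_mean_larval_count(x), sum(x, na.rm = TRUE) / 12)
})

test_that("age estimation is additive over phases, with station-mean fallback", {
  ds <- tiny_dataset(larval = c(22, 24, NA), meta = c(11, 11, 11),
                     post = c(103, 103, 103))
  ages <- estimate_ages(ds)
  # fish 3 has no larval rings: station mean 23 is used and flagged
  expect_equal(ages$pld, c(33, 35, 34))
  expect_equal(ages$age_at_capture, c(136, 138, 137))
  expect_equal(ages$age_at_settlement, ages$pld)
  expect_identical(ages$used_location_mean_larval, c(FALSE, FALSE, TRUE))

  degenerate <- estimate_ages(tiny_dataset(0, 0, 0))
  expect_equal(degenerate$pld, 0)
  expect_equal(degenerate$age_at_capture, 0)

  ow <- estimate_ages(tiny_dataset(23, 11, 103, overwinter = TRUE))
  expect_true(ow$unreliable)
})

test_that("stations without larval readings borrow the pooled country-year mean", {
  st <- data.frame(station = c("A", "B"), country = "BE", year = 2014L,
                   latitude = 51.2, longitude = 2.8,
                   sampling_date = as.Date("2014-09-10"), survey = "t",
                   overwinter = FALSE)
  fish <- data.frame(fish_id = c("a1", "a2", "b1"),
                     station = c("A", "A", "B"), year = 2014L,
                     standard_length = 80, selected_for_ageing = TRUE)
  rd <- data.frame(fish_id = c("a1", "a2", "b1"), otolith_radius = 0.9,
                   larval_count = c(20, 26, NA),
                   metamorphosis_count = 10, post_settlement_count = 100,
                   n_readers = 2L)
  ages <- estimate_ages(sole_dataset(st, fish, rd))
  expect_equal(ages$pld[ages$fish_id == "b1"], 23 + 10)
  ages_strict <- estimate_ages(sole_dataset(st, fish, rd),
                               borrow_pooled = FALSE)
  expect_true(is.na(ages_strict$pld[ages_strict$fish_id == "b1"]))
})

test_that("calendar back-calculation matches the printed station dates", {
  bc <- back_calculate_dates(as.Date(c("2013-09-10", "2014-09-23")),
                             c(137, 149), c(35.89, 32.71))
  expect_identical(bc$hatch_date,
                   as.Date(c("2013-04-26", "2014-04-27")))
  # zero-age identity and the settlement identity
  d <- as.Date("2014-06-01")
  z <- back_calculate_dates(d, 0, 0)
  expect_identical(z$hatch_date, d)
  expect_identical(z$settlement_date, d)
  r <- back_calculate_dates(d, 137.4, 34.5)
  expect_identical(r$hatch_date, d - 137)     # 137.4 rounds down
  expect_identical(r$settlement_date, r$hatch_date + 35)  # 34.5 rounds half up
  expect_error(back_calculate_dates(d, 30, 40), "exceed")
  expect_error(back_calculate_dates(d, -1, -1), "non-negative")
})

test_that("growth rate is the individual length/age ratio", {
  expect_equal(growth_rate(100, 200), 0.5)
  expect_true(is.na(growth_rate(100, 0)))
  set.seed(3)
  g <- 0.6
  age <- sample(100:180, 40, replace = TRUE)
  expect_equal(growth_rate(g * age, age), rep(g, 40))
})

test_that("length-otolith OLS recovers a noiseless line and guards the design", {
  or <- seq(0.6, 1.2, length.out = 20)
  fit <- suppressWarnings(    # lm flags the residual-free fit
    fit_length_otolith_regression(24.1 + 57.74 * or, or))
  expect_equal(fit$intercept, 24.1, tolerance = 1e-9)
  expect_equal(fit$slope, 57.74, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_length_otolith_regression(c(30, 80), c(0.2, 1)), "at least 3")
  expect_error(fit_length_otolith_regression(c(30, 80, 90), rep(0.9, 3)),
               "singular")
})

test_that("OLS slope is recovered within 3 SE under Gaussian residuals", {
  set.seed(42)
  n <- 154
  or <- runif(n, 0.6, 1.2)
  sl <- 24.1 + 57.74 * or + rnorm(n, 0, 10)
  fit <- fit_length_otolith_regression(sl, or)
  se <- summary(fit$fit)$coefficients["or", "Std. Error"]
  expect_lt(abs(fit$slope - 57.74), 3 * se)
})

test_that("the smooth age-length key recovers a known quadratic", {
  set.seed(5)
  age <- seq(60, 200, length.out = 120)
  or <- 0.9 + 1e-5 * age^2 + rnorm(120, 0, 0.005)
  fit <- fit_age_length_key(or, age)
  grid <- seq(65, 195, by = 5)
  truth <- 0.9 + 1e-5 * grid^2
  expect_lt(max(abs(fit$predict_fn(grid) - truth) / truth), 0.05)
  expect_error(fit$predict_fn(300), "outside the observed age range")
})

test_that("the smooth key degrades gracefully and enforces preconditions", {
  set.seed(6)
  age <- seq(60, 200, length.out = 50)
  fit <- fit_age_length_key(rep(0.9, 50) + rnorm(50, 0, 1e-8), age)
  expect_lt(diff(range(fit$predict_fn(seq(60, 200, by = 10)))), 1e-4)
  expect_error(fit_age_length_key(runif(9), seq(10, 200, length.out = 9)),
               "at least 10")
  expect_error(fit_age_length_key(runif(20), rep(100, 20) + runif(20)),
               "age range")
})

test_that("group comparisons delegate to the standard tests", {
  x <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  expect_gt(compare_groups(x, g, "wilcoxon_rank_sum")$p_value, 0.9)
  set.seed(9)
  y <- c(rnorm(50), rnorm(50, 10))
  gg <- rep(c("a", "b"), each = 50)
  expect_lt(compare_groups(y, gg, "t_test")$p_value, 1e-6)
  expect_lt(compare_groups(y, gg, "wilcoxon_rank_sum")$p_value, 1e-6)
  pw <- compare_groups(c(rnorm(20), rnorm(20, 8), rnorm(20)),
                       rep(c("a", "b", "c"), each = 20), "pairwise_wilcoxon")
  expect_true(is.matrix(pw$p_value))
  expect_error(compare_groups(rnorm(10), rep("a", 10)), "two non-empty")
})

test_that("rank-test rejection rate under the null is close to alpha", {
  set.seed(123)
  reject <- vapply(seq_len(1000), function(i) {
    v <- rnorm(45)
    compare_groups(v, rep(c("a", "b", "c"), each = 15),
                   "kruskal_wallis")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})
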