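#' Mean larval increment count for one station
#'
#' Larval rings (hatch check to start of metamorphosis) are readable in only
#' a subset of otoliths, so a station-level mean is derived from the few
#' readable ones and shared by all fish of that station.
#'
#' @param larval_counts numeric vector of larval increment counts for the
#'   station's readings; `NA` marks otoliths whose larval rings could not be
#'   counted.
#' @return The arithmetic mean of the present counts, unrounded.
#'   `NA_real_` when no reading at the station has a larval count (the
#'   explicit "no larval mean" signal; callers may borrow a pooled mean,
#'   see [estimate_ages()]).
#' @export
location_mean_larval_count <- function(larval_counts) {
  x <- larval_counts[!is.na(larval_counts)]
  if (length(x) == 0) return(NA_real_)
  mean(x)
}

#' Estimate ages at settlement and capture from increment counts
#'
#' The pelagic larval duration (PLD) of each fish is its individual larval
#' count when the larval rings were readable, otherwise the station mean
#' larval count, plus the individual metamorphosis count. Age at capture
#' adds the post-settlement count. Ages are kept real-valued: station means
#' are fractional and rounding happens only at calendar subtraction
#' ([back_calculate_dates()]).
#'
#' @param dataset a [sole_dataset()].
#' @param borrow_pooled if `TRUE` (default), stations with no readable
#'   larval rings at all borrow the pooled mean larval count over the same
#'   country and year (flagged in the output); if `FALSE` their PLD is `NA`.
#' @param yolk_sac_offset days added to every PLD to compensate increments
#'   not deposited before first feeding; default 0 (counts taken at face
#'   value).
#' @return data frame with one row per otolith reading: `fish_id`,
#'   `station`, `year`, `pld`, `age_at_capture`, `age_at_settlement`
#'   (equal to `pld`), `used_location_mean_larval`, `unreliable` (fish from
#'   stations sampled after an overwintering period, carried but flagged
#'   for downstream exclusion).
#' @export
estimate_ages <- function(dataset, borrow_pooled = TRUE, yolk_sac_offset = 0) {
  stopifnot(inherits(dataset, "sole_dataset"))
  rd <- dataset$readings
  .assert(nrow(rd) > 0, "dataset has no otolith readings")
  .assert(all(!is.na(rd$metamorphosis_count)) &&
            all(!is.na(rd$post_settlement_count)),
          "metamorphosis_count and post_settlement_count must be present")
  fi <- dataset$fish[match(rd$fish_id, dataset$fish$fish_id), ]
  st <- dataset$stations
  skey <- paste(fi$station, fi$year)
  stkey <- paste(st$station, st$year)
  # per-station mean of readable larval counts
  st_mean <- vapply(stkey, function(k)
    location_mean_larval_count(rd$larval_count[skey == k]), numeric(1))
  if (borrow_pooled) {
    ckey <- paste(st$country, st$year)
    for (i in which(is.na(st_mean))) {
      pool <- rd$larval_count[paste(st$country[match(skey, stkey)],
                                    fi$year) == ckey[i]]
      st_mean[i] <- location_mean_larval_count(pool)
    }
  }
  m <- match(skey, stkey)
  larval <- ifelse(is.na(rd$larval_count), st_mean[m], rd$larval_count)
  pld <- larval + rd$metamorphosis_count + yolk_sac_offset
  age <- pld + rd$post_settlement_count
  data.frame(
    fish_id = rd$fish_id,
    station = fi$station,
    year = fi$year,
    pld = pld,
    age_at_capture = age,
    age_at_settlement = pld,
    used_location_mean_larval = is.na(rd$larval_count),
    unreliable = st$overwinter[m],
    stringsAsFactors = FALSE)
}

#' Back-calculate hatching and settlement dates
#'
#' Hatching date is the sampling date minus the (rounded) age at capture;
#' settlement date is the hatching date plus the rounded PLD, i.e. the
#' sampling date minus the rounded post-settlement time. Rounding is half
#' away from zero, applied only at this final calendar step; Gregorian
#' arithmetic (leap years included) is exact.
#'
#' @param sampling_date `Date` vector (recycled).
#' @param age_at_capture numeric days, `>= 0`.
#' @param pld numeric days, `>= 0`, `<= age_at_capture`.
#' @return data frame with `hatch_date` and `settlement_date` (`Date`),
#'   satisfying `hatch_date + round(pld) == settlement_date`.
#' @export
back_calculate_dates <- function(sampling_date, age_at_capture, pld) {
  .assert(inherits(sampling_date, "Date"), "sampling_date must be a Date")
  ok <- !is.na(age_at_capture) & !is.na(pld)
  .assert(all(age_at_capture[ok] >= 0 & pld[ok] >= 0),
          "ages must be non-negative")
  .assert(all(pld[ok] <= age_at_capture[ok] + 1e-9),
          "pld cannot exceed age_at_capture")
  n <- max(length(sampling_date), length(age_at_capture), length(pld))
  sampling_date <- rep_len(sampling_date, n)
  age_at_capture <- rep_len(age_at_capture, n)
  pld <- rep_len(pld, n)
  hatch <- sampling_date - round_half_up(age_at_capture)
  settlement <- hatch + round_half_up(pld)
  data.frame(hatch_date = hatch, settlement_date = settlement)
}

#' Absolute growth rate
#'
#' Ratio of standard length to age at capture, per fish. Location summaries
#' must average the individual ratios, never take a ratio of means.
#'
#' @param standard_length mm.
#' @param age_at_capture days; zero or missing ages give `NA`.
#' @return mm per day.
#' @export
growth_rate <- function(standard_length, age_at_capture) {
  out <- ifelse(!is.na(age_at_capture) & age_at_capture > 0,
                standard_length / age_at_capture, NA_real_)
  as.numeric(out)
}

#' Linear standard-length / otolith-radius regression
#'
#' Ordinary least squares of standard length (mm) on otolith radius (mm),
#' validating proportionality of somatic and otolith growth in 0-group
#' sole.
#'
#' @param standard_length mm.
#' @param otolith_radius mm.
#' @return Object of class `sole_slor_fit`: list with `intercept` (mm),
#'   `slope` (mm per mm radius), `r_squared`, `sigma` (residual SD) and the
#'   underlying `lm` fit.
#' @export
fit_length_otolith_regression <- function(standard_length, otolith_radius) {
  ok <- complete.cases(standard_length, otolith_radius)
  sl <- standard_length[ok]; or <- otolith_radius[ok]
  .assert(length(sl) >= 3, "need at least 3 paired observations")
  .assert(stats::var(or) > 0, "singular design: all otolith radii identical")
  fit <- lm(sl ~ or)
  structure(list(
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    sigma = summary(fit)$sigma,
    n = length(sl),
    fit = fit), class = "sole_slor_fit")
}

#' @export
print.sole_slor_fit <- function(x, ...) {
  cat(sprintf("SL ~ OR linear fit (n = %d)\n", x$n))
  cat(sprintf("  SL = %.2f + %.2f * OR   (R^2 = %.3f, sigma = %.2f mm)\n",
              x$intercept, x$slope, x$r_squared, x$sigma))
  invisible(x)
}

#' @export
coef.sole_slor_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.sole_slor_fit <- function(object, otolith_radius, ...)
  object$intercept + object$slope * otolith_radius

#' Smooth age-length key for otolith radius
#'
#' Models otolith radius as an intercept plus a penalized smooth function
#' of age (a generalized additive model). Predictions are defined over the
#' observed age range only.
#'
#' @param otolith_radius mm.
#' @param age_at_capture days; must span more than 30 days.
#' @return Object of class `sole_alk_fit`: list with `intercept`,
#'   `deviance_explained`, the observed `age_range`, and `predict_fn(age)`
#'   returning fitted radius (error outside the observed range).
#' @export
fit_age_length_key <- function(otolith_radius, age_at_capture) {
  ok <- complete.cases(otolith_radius, age_at_capture)
  or <- otolith_radius[ok]; age <- age_at_capture[ok]
  .assert(length(or) >= 10, "need at least 10 observations")
  .assert(diff(range(age)) > 30, "degenerate age range (must span > 30 days)")
  fit <- mgcv::gam(or ~ s(age))
  rng <- range(age)
  predict_fn <- function(a) {
    .assert(all(a >= rng[1] & a <= rng[2]),
            "prediction outside the observed age range")
    as.numeric(predict(fit, newdata = data.frame(age = a)))
  }
  structure(list(
    intercept = unname(coef(fit)[1]),
    deviance_explained = summary(fit)$dev.expl,
    age_range = rng,
    n = length(or),
    predict_fn = predict_fn,
    fit = fit), class = "sole_alk_fit")
}

#' @export
print.sole_alk_fit <- function(x, ...) {
  cat(sprintf("OR ~ s(age) smooth fit (n = %d)\n", x$n))
  cat(sprintf("  intercept %.3f mm; deviance explained %.1f%%; ages %.0f-%.0f d\n",
              x$intercept, 100 * x$deviance_explained,
              x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Compare a trait between groups
#'
#' Thin dispatcher over the standard tests used for location/year/country
#' contrasts of growth traits. Assumption checking is the caller's
#' responsibility.
#'
#' @param values numeric trait values.
#' @param grouping factor-like of the same length; at least two non-empty
#'   groups.
#' @param method one of `"kruskal_wallis"`, `"wilcoxon_rank_sum"`,
#'   `"t_test"`, `"pairwise_wilcoxon"`.
#' @return For the first three, a list with `statistic`, `p_value`,
#'   `method`; for `"pairwise_wilcoxon"` the `pairwise.htest` p-value
#'   matrix is returned in `p_value`.
#' @export
compare_groups <- function(values,
                           grouping,
                           method = c("kruskal_wallis", "wilcoxon_rank_sum",
                                      "t_test", "pairwise_wilcoxon")) {
  method <- match.arg(method)
  grouping <- factor(grouping)
  grouping <- droplevels(grouping[!is.na(values)])
  values <- values[!is.na(values)]
  .assert(nlevels(grouping) >= 2, "need at least two non-empty groups")
  two <- function() {
    .assert(nlevels(grouping) == 2, paste0(method, " requires exactly 2 groups"))
    split(values, grouping)
  }
  res <- switch(method,
    kruskal_wallis = kruskal.test(values, grouping),
    wilcoxon_rank_sum = {
      g <- two(); wilcox.test(g[[1]], g[[2]], exact = FALSE)
    },
    t_test = {
      g <- two(); t.test(g[[1]], g[[2]])
    },
    pairwise_wilcoxon = pairwise.wilcox.test(values, grouping, exact = FALSE))
  if (method == "pairwise_wilcoxon")
    return(list(statistic = NA_real_, p_value = res$p.value, method = method))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = method)
}
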