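#' @rdname weekly_arrival_distribution
#' @param date `Date` vector.
#' @param convention `"iso"` for ISO-8601 week numbers (default) or
#'   `"jan1"` for 7-day blocks counted from January 1st.
#' @return `week_number()`: integer week numbers.
#' @export
week_number <- function(date, convention = c("iso", "jan1")) {
  convention <- match.arg(convention)
  if (convention == "iso") {
    as.integer(strftime(date, format = "%V"))
  } else {
    (as.integer(strftime(date, format = "%j")) - 1L) %/% 7L + 1L
  }
}

# internal constructor shared by the observed and predicted sides
.arrival_distribution <- function(weeks, weights, year, nursery, n,
                                  convention) {
  .assert(length(weeks) > 0, "no dates to bin")
  wk <- sort(unique(weeks))
  axis <- seq(min(wk), max(wk))            # interior empty weeks kept as zeros
  freq <- vapply(axis, function(w) sum(weights[weeks == w]), numeric(1))
  tot <- sum(freq)
  .assert(tot > 0, "total weight must be positive")
  structure(list(year = year, nursery = nursery, week_numbers = axis,
                 frequencies = freq / tot, n = n, convention = convention),
            class = "arrival_distribution")
}

#' Weekly arrival (settlement) distribution
#'
#' Groups back-calculated settlement dates by week number to produce the
#' normalized settlement distribution curve. Empty weeks interior to the
#' observed range are carried as zeros; frequencies sum to one.
#'
#' @param dates settlement (arrival) `Date`s, all within one year span.
#' @param year integer label; defaults to the modal calendar year.
#' @param nursery nursery label (free text, e.g. a country code).
#' @return Object of class `arrival_distribution`: list with `year`,
#'   `nursery`, `week_numbers` (ordered integers), `frequencies` (sum to
#'   1), `n` (sample count) and the week `convention`.
#' @export
weekly_arrival_distribution <- function(dates, year = NULL, nursery = NA,
                                        convention = c("iso", "jan1")) {
  convention <- match.arg(convention)
  dates <- dates[!is.na(dates)]
  .assert(length(dates) > 0, "no dates to bin")
  yr <- as.integer(format(dates, "%Y"))
  .assert(diff(range(yr)) <= 1, "dates must fall within one year span")
  if (is.null(year)) year <- as.integer(names(sort(table(yr),
                                                   decreasing = TRUE))[1])
  wk <- week_number(dates, convention)
  .arrival_distribution(wk, rep(1, length(wk)), year, nursery,
                        n = length(dates), convention = convention)
}

#' @export
print.arrival_distribution <- function(x, ...) {
  cat(sprintf("arrival distribution: nursery %s, year %s, n = %s\n",
              x$nursery, x$year, x$n))
  cat(sprintf("  weeks %d-%d (%s), modal week %d\n",
              min(x$week_numbers), max(x$week_numbers), x$convention,
              modal_week(x)$week))
  invisible(x)
}

#' @export
plot.arrival_distribution <- function(x, ..., type = "l",
                                      xlab = "week number",
                                      ylab = "relative frequency") {
  plot(x$week_numbers, x$frequencies, type = type, xlab = xlab, ylab = ylab,
       ...)
  invisible(x)
}

#' Modal week of an arrival distribution
#'
#' @param x an `arrival_distribution`.
#' @return list with `week` (ties broken toward the earlier week) and
#'   `tie` (`TRUE` when the maximum is not unique).
#' @export
modal_week <- function(x) {
  stopifnot(inherits(x, "arrival_distribution"))
  mx <- max(x$frequencies)
  at <- x$week_numbers[x$frequencies >= mx - 1e-12]
  list(week = at[1], tie = length(at) > 1)
}
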