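#' Assemble a sole otolith dataset
#'
#' Bundles station metadata, per-fish measurements and otolith increment
#' readings into a validated dataset. Station identity is the pair
#' (station code, year): the same physical station sampled in different
#' years counts as two stations.
#'
#' @param stations data frame with columns `station`, `country` (one of
#'   `"BE"`, `"NL"`, `"UK"`), `latitude`, `longitude` (decimal degrees),
#'   `sampling_date` (`Date`), `survey`, `overwinter` (logical), and
#'   optionally `sst_at_settlement` (deg C).
#' @param fish data frame with columns `fish_id`, `station`, `year`,
#'   `standard_length` (mm) and optionally `selected_for_ageing`.
#' @param readings data frame with columns `fish_id`, `otolith_radius`
#'   (mm), `larval_count` (days, may be `NA` -- larval rings are readable
#'   in a subset of otoliths only), `metamorphosis_count`,
#'   `post_settlement_count` (days) and optionally `n_readers`.
#' @return An object of class `sole_dataset`: a list with elements
#'   `stations`, `fish`, `readings`.
#' @seealso [read_reading_table()], [generate_otolith_dataset()]
#' @export
sole_dataset <- function(stations, fish, readings) {
  stations <- as.data.frame(stations)
  fish <- as.data.frame(fish)
  readings <- as.data.frame(readings)
  if (nrow(stations)) {
    .assert(all(c("station", "country", "latitude", "longitude",
                  "sampling_date", "overwinter") %in% names(stations)),
            "stations is missing required columns")
    .assert(all(stations$latitude >= 48 & stations$latitude <= 58),
            "station latitude outside [48, 58]")
    .assert(all(stations$longitude >= -4 & stations$longitude <= 9),
            "station longitude outside [-4, 9]")
    .assert(inherits(stations$sampling_date, "Date"),
            "sampling_date must be a Date")
    if (is.null(stations$year))
      stations$year <- as.integer(format(stations$sampling_date, "%Y"))
    key <- paste(stations$station, stations$year)
    .assert(!anyDuplicated(key), "duplicate (station, year) identity")
  }
  if (nrow(fish)) {
    .assert(all(fish$standard_length > 0), "standard_length must be > 0")
    .assert(!anyDuplicated(fish$fish_id), "duplicate fish_id")
    .assert(all(paste(fish$station, fish$year) %in%
                  paste(stations$station, stations$year)),
            "every fish must reference exactly one known station")
    if (is.null(fish$selected_for_ageing)) fish$selected_for_ageing <- TRUE
  }
  if (nrow(readings)) {
    .assert(all(readings$fish_id %in% fish$fish_id),
            "reading references unknown fish_id")
    .assert(all(readings$otolith_radius > 0), "otolith_radius must be > 0")
    cnt <- c(readings$larval_count, readings$metamorphosis_count,
             readings$post_settlement_count)
    .assert(all(is.na(cnt) | cnt >= 0), "increment counts must be >= 0")
    if (is.null(readings$n_readers)) readings$n_readers <- 2L
  }
  structure(list(stations = stations, fish = fish, readings = readings),
            class = "sole_dataset")
}

#' @export
print.sole_dataset <- function(x, ...) {
  cat("sole otolith dataset\n")
  cat("  stations:", nrow(x$stations), " fish:", nrow(x$fish),
      " otolith readings:", nrow(x$readings), "\n")
  if (nrow(x$readings))
    cat("  readings with larval rings:",
        sum(!is.na(x$readings$larval_count)), "\n")
  invisible(x)
}

# accepts ISO-8601 (written form) and dd/mm/yyyy (the form the source
# tables print); returns NA for unparseable input
.parse_date <- function(x) {
  x <- as.character(x)
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  dmy <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out[dmy] <- as.Date(x[dmy], format = "%d/%m/%Y")
  out
}

#' Read a flat otolith reading table
#'
#' Reads a one-row-per-fish CSV (comma-separated, UTF-8) and splits it into
#' the station / fish / reading components of a [sole_dataset()]. Dates are
#' accepted in ISO-8601 (`yyyy-mm-dd`) or `dd/mm/yyyy`; output is always
#' ISO-8601. Missing values are `NA` or `-`, never zero. Rows violating an
#' invariant (non-positive length or radius, negative counts, coordinates
#' outside the southern North Sea box, unparseable dates) are dropped with
#' row-level diagnostics attached as attribute `"rejected"` and raised as a
#' warning.
#'
#' @param path path to a CSV file whose header declares at least
#'   `station, country, latitude, longitude, sampling_date, fish_id,
#'   standard_length, otolith_radius, metamorphosis_count,
#'   post_settlement_count`.
#' @return A [sole_dataset()]; zero data rows give an empty dataset.
#' @export
read_reading_table <- function(path) {
  .assert(file.exists(path), paste0("no such file: ", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", "-", ""))
  required <- c("station", "country", "latitude", "longitude",
                "sampling_date", "fish_id", "standard_length",
                "otolith_radius", "metamorphosis_count",
                "post_settlement_count")
  missing <- setdiff(required, names(raw))
  .assert(length(missing) == 0,
          paste0("format error: missing required column(s): ",
                 paste(missing, collapse = ", ")))
  if (nrow(raw) == 0) {
    return(sole_dataset(
      stations = data.frame(station = character(), country = character(),
                            year = integer(), latitude = numeric(),
                            longitude = numeric(),
                            sampling_date = as.Date(character()),
                            survey = character(), overwinter = logical()),
      fish = data.frame(fish_id = character(), station = character(),
                        year = integer(), standard_length = numeric(),
                        selected_for_ageing = logical()),
      readings = data.frame(fish_id = character(), otolith_radius = numeric(),
                            larval_count = numeric(),
                            metamorphosis_count = numeric(),
                            post_settlement_count = numeric(),
                            n_readers = integer())))
  }
  dates <- .parse_date(raw$sampling_date)
  bad <- character(0)
  flag <- function(i, why) sprintf("row %d: %s", i, why)
  keep <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (is.na(dates[i])) {
      keep[i] <- FALSE
      bad <- c(bad, flag(i, paste0("unparseable date '", raw$sampling_date[i], "'")))
      next
    }
    if (is.na(raw$standard_length[i]) || raw$standard_length[i] <= 0) {
      keep[i] <- FALSE; bad <- c(bad, flag(i, "standard_length not > 0")); next
    }
    if (is.na(raw$otolith_radius[i]) || raw$otolith_radius[i] <= 0) {
      keep[i] <- FALSE; bad <- c(bad, flag(i, "otolith_radius not > 0")); next
    }
    cnt <- c(raw$larval_count[i] %||% NA, raw$metamorphosis_count[i],
             raw$post_settlement_count[i])
    if (any(!is.na(cnt) & cnt < 0)) {
      keep[i] <- FALSE; bad <- c(bad, flag(i, "negative increment count")); next
    }
    if (is.na(raw$latitude[i]) || raw$latitude[i] < 48 || raw$latitude[i] > 58 ||
        is.na(raw$longitude[i]) || raw$longitude[i] < -4 || raw$longitude[i] > 9) {
      keep[i] <- FALSE; bad <- c(bad, flag(i, "coordinates outside domain")); next
    }
  }
  raw <- raw[keep, , drop = FALSE]
  dates <- dates[keep]
  year <- as.integer(format(dates, "%Y"))
  skey <- !duplicated(paste(raw$station, year))
  stations <- data.frame(
    station = raw$station[skey], country = raw$country[skey], year = year[skey],
    latitude = raw$latitude[skey], longitude = raw$longitude[skey],
    sampling_date = dates[skey],
    survey = (raw$survey %||% rep(NA_character_, nrow(raw)))[skey],
    overwinter = as.logical(raw$overwinter %||% rep(FALSE, nrow(raw)))[skey],
    stringsAsFactors = FALSE)
  stations$overwinter[is.na(stations$overwinter)] <- FALSE
  fish <- data.frame(
    fish_id = as.character(raw$fish_id), station = raw$station, year = year,
    standard_length = raw$standard_length,
    selected_for_ageing = as.logical(raw$selected_for_ageing %||%
                                       rep(TRUE, nrow(raw))),
    stringsAsFactors = FALSE)
  readings <- data.frame(
    fish_id = as.character(raw$fish_id),
    otolith_radius = raw$otolith_radius,
    larval_count = as.numeric(raw$larval_count %||% rep(NA_real_, nrow(raw))),
    metamorphosis_count = raw$metamorphosis_count,
    post_settlement_count = raw$post_settlement_count,
    n_readers = as.integer(raw$n_readers %||% rep(2L, nrow(raw))),
    stringsAsFactors = FALSE)
  ds <- sole_dataset(stations, fish, readings)
  if (length(bad)) {
    attr(ds, "rejected") <- bad
    warning(sprintf("%d row(s) rejected:\n%s", length(bad),
                    paste(bad, collapse = "\n")), call. = FALSE)
  }
  ds
}

#' Write a dataset back to the flat reading-table format
#'
#' Inverse of [read_reading_table()]: one row per fish, ISO-8601 dates,
#' `NA` for absent values. Reading a written file reproduces the dataset.
#'
#' @param dataset a [sole_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reading_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "sole_dataset"))
  st <- dataset$stations
  m <- match(paste(dataset$fish$station, dataset$fish$year),
             paste(st$station, st$year))
  rd <- dataset$readings[match(dataset$fish$fish_id, dataset$readings$fish_id), ]
  flat <- data.frame(
    station = dataset$fish$station,
    country = st$country[m],
    latitude = st$latitude[m],
    longitude = st$longitude[m],
    sampling_date = format(st$sampling_date[m], "%Y-%m-%d"),
    survey = st$survey[m],
    overwinter = st$overwinter[m],
    fish_id = dataset$fish$fish_id,
    standard_length = dataset$fish$standard_length,
    selected_for_ageing = dataset$fish$selected_for_ageing,
    otolith_radius = rd$otolith_radius,
    larval_count = rd$larval_count,
    metamorphosis_count = rd$metamorphosis_count,
    post_settlement_count = rd$post_settlement_count,
    n_readers = rd$n_readers,
    stringsAsFactors = FALSE)
  write.csv(flat, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Load the packaged summary-table fixtures
#'
#' Machine-readable transcriptions of the source study's three summary
#' tables: station origins and sample sizes, per-station mean ages / PLDs /
#' back-calculated dates, and per-station growth parameters. The printed
#' `-` for the larval-ring otolith count of the overwintering Belgian
#' station is stored as `NA`, exactly as printed, even though a PLD is
#' printed for the same station in the age table. Column sums reproduce the
#' printed totals: 402 fish sampled, 154 otoliths read, 31 otoliths with
#' countable larval rings.
#'
#' @return A list of class `paper_fixtures` with data frames `table1`
#'   (stations), `table2` (ages and dates), `table3` (growth).
#' @export
load_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "soledrift",
                                  mustWork = TRUE)
  t1 <- read.csv(path("table1_stations.csv"), stringsAsFactors = FALSE,
                 na.strings = c("NA", "-"))
  t2 <- read.csv(path("table2_ages.csv"), stringsAsFactors = FALSE,
                 na.strings = c("NA", "-"))
  t3 <- read.csv(path("table3_growth.csv"), stringsAsFactors = FALSE,
                 na.strings = c("NA", "-"))
  t1$sampling_date <- as.Date(t1$sampling_date)
  t2$settlement_date <- as.Date(t2$settlement_date)
  t2$hatching_date <- as.Date(t2$hatching_date)
  .assert(nrow(t1) == 11 && nrow(t2) == 11 && nrow(t3) == 11,
          "fixture tables must have 11 rows each")
  .assert(sum(t1$n_fish) == 402L, "table1 fish total must be 402")
  .assert(sum(t1$n_otoliths) == 154L, "table1 otolith total must be 154")
  .assert(sum(t1$n_larval_ring_otoliths, na.rm = TRUE) == 31L,
          "table1 larval-ring otolith total must be 31")
  structure(list(table1 = t1, table2 = t2, table3 = t3),
            class = "paper_fixtures")
}

#' @export
print.paper_fixtures <- function(x, ...) {
  cat("summary-table fixtures: 11 stations,",
      sum(x$table1$n_fish), "fish,", sum(x$table1$n_otoliths), "otoliths,",
      sum(x$table1$n_larval_ring_otoliths, na.rm = TRUE),
      "with larval rings\n")
  invisible(x)
}
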