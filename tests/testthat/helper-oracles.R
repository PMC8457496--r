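# independent brute-force oracles used across the suite

# even-odd ray casting, deliberately independent of pracma::inpolygon
ray_cast_inside <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  for (q in seq_along(x)) {
    c_in <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((py[i] > y[q]) != (py[j] > y[q]) &&
          x[q] < (px[j] - px[i]) * (y[q] - py[i]) / (py[j] - py[i]) + px[i])
        c_in <- !c_in
      j <- i
    }
    inside[q] <- c_in
  }
  inside
}

# direct weighted histogram over week numbers, zero-filled axis
brute_week_hist <- function(dates, weights = rep(1, length(dates)),
                            convention = "iso") {
  wk <- soledrift::week_number(dates, convention)
  axis <- seq(min(wk), max(wk))
  f <- vapply(axis, function(w) sum(weights[wk == w]), numeric(1))
  list(weeks = axis, freq = f / sum(f))
}

# tiny dataset builder: one station, explicit counts
tiny_dataset <- function(larval, meta, post, sl = 85, or = 0.9,
                         sampling = as.Date("2014-09-10"),
                         overwinter = FALSE, station = "ST1",
                         country = "BE") {
  n <- length(meta)
  sole_dataset(
    stations = data.frame(station = station, country = country,
                          year = as.integer(format(sampling, "%Y")),
                          latitude = 51.2, longitude = 2.8,
                          sampling_date = sampling, survey = "test",
                          overwinter = overwinter),
    fish = data.frame(fish_id = sprintf("f%02d", seq_len(n)),
                      station = station,
                      year = as.integer(format(sampling, "%Y")),
                      standard_length = rep_len(sl, n),
                      selected_for_ageing = TRUE),
    readings = data.frame(fish_id = sprintf("f%02d", seq_len(n)),
                          otolith_radius = rep_len(or, n),
                          larval_count = larval,
                          metamorphosis_count = meta,
                          post_settlement_count = post,
                          n_readers = 2L))
}
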