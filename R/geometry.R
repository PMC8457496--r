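#' Spawning and nursery ground polygons
#'
#' Grounds are simple lon/lat polygons. Spawning grounds carry the fraction
#' of the total annual egg production released there; nursery grounds carry
#' the maximum settling depth (shallow coastal areas, default 20 m).
#'
#' @param code short ground label (spawning: e.g. `"EC"`, `"BC"`, `"Th"`,
#'   `"N"`, `"Tx"`, `"GB"`; nursery: e.g. `"FR"`, `"BE"`, `"NL"`, `"GE"`,
#'   `"Tha"`, `"No"`).
#' @param lon,lat polygon vertex coordinates (decimal degrees, not
#'   closed -- the closing edge is implicit).
#' @param egg_share fraction of total egg production (spawning grounds).
#' @param max_depth maximum bathymetry (m) at which settlement is possible
#'   (nursery grounds).
#' @return A list of class `spawning_ground` / `nursery_ground`.
#' @export
spawning_ground <- function(code, lon, lat, egg_share) {
  .assert(length(lon) >= 3 && length(lon) == length(lat),
          "polygon needs >= 3 vertices")
  structure(list(code = code, lon = lon, lat = lat, egg_share = egg_share),
            class = "spawning_ground")
}

#' @rdname spawning_ground
#' @export
nursery_ground <- function(code, lon, lat, max_depth = 20) {
  .assert(length(lon) >= 3 && length(lon) == length(lat),
          "polygon needs >= 3 vertices")
  structure(list(code = code, lon = lon, lat = lat, max_depth = max_depth),
            class = "nursery_ground")
}

#' Point-in-polygon membership
#'
#' @param lon,lat query points.
#' @param poly a ground object or any list with `lon`, `lat` vertex
#'   vectors.
#' @return logical vector; boundary points count as inside.
#' @export
point_in_polygon <- function(lon, lat, poly) {
  pracma::inpolygon(lon, lat, poly$lon, poly$lat, boundary = TRUE)
}

# uniform sampling inside a polygon by bounding-box rejection
sample_in_polygon <- function(n, poly) {
  lon <- numeric(0); lat <- numeric(0)
  bb <- c(range(poly$lon), range(poly$lat))
  while (length(lon) < n) {
    m <- max(2 * (n - length(lon)), 16)
    cx <- runif(m, bb[1], bb[2])
    cy <- runif(m, bb[3], bb[4])
    keep <- point_in_polygon(cx, cy, poly)
    lon <- c(lon, cx[keep]); lat <- c(lat, cy[keep])
  }
  list(lon = lon[seq_len(n)], lat = lat[seq_len(n)])
}

# regular grid of points inside a polygon (for ground-mean temperatures)
grid_in_polygon <- function(poly, n_side = 12) {
  gx <- seq(min(poly$lon), max(poly$lon), length.out = n_side)
  gy <- seq(min(poly$lat), max(poly$lat), length.out = n_side)
  g <- expand.grid(lon = gx, lat = gy)
  keep <- point_in_polygon(g$lon, g$lat, poly)
  if (!any(keep)) {
    # degenerate thin polygon: fall back to the vertex centroid
    return(list(lon = mean(poly$lon), lat = mean(poly$lat)))
  }
  list(lon = g$lon[keep], lat = g$lat[keep])
}

#' Export station coordinates as GeoJSON
#'
#' @param stations station data frame of a [sole_dataset()].
#' @param path optional file path; when omitted, the GeoJSON string is
#'   returned.
#' @return GeoJSON FeatureCollection (string), invisibly when written.
#' @export
stations_geojson <- function(stations, path = NULL) {
  feats <- lapply(seq_len(nrow(stations)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(stations$longitude[i],
                                    stations$latitude[i])),
    properties = list(station = stations$station[i],
                      year = stations$year[i],
                      country = stations$country[i])))
  js <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
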