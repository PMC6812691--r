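# Shore-based raft geolocation: convert clifftop inclinometer/compass
# sightings into georeferenced raft positions with distances to shore.
#
# Geometry: an observer on a cliff of height C above mean sea level reads
# the angle of the line of sight below the horizontal (the inclinometer
# "declination" D) to a raft on the sea surface. With the instrument H
# metres above the clifftop and instantaneous tide height T (signed,
# relative to mean sea level), the eye sits C + H - T above the water, and
# the horizontal range is (C + H - T) / tan(D). Earth curvature and
# refraction are ignored by default (< 0.3 m at 2 km from 50-67 m cliffs);
# a curvature-corrected mode is available.

#' Observation stations packaged with the pipeline
#'
#' The four clifftop stations used around the island study site, with
#' cliff heights above mean sea level: Garland Stone (GSN) 64.1 m, Skomer
#' Head (SHD) 66.7 m, South Haven (SHV) 63.7 m, North Haven (NHV) 49.0 m.
#' Published coordinates exist only for Skomer Head; the other three carry
#' NA coordinates and must be supplied by the user (or by the synthetic
#' island generator).
#'
#' @return data.frame with columns `station`, `lat`, `lon`,
#'   `cliff_height_m`.
#' @export
observation_stations <- function() {
  data.frame(
    station = c("GSN", "SHD", "SHV", "NHV"),
    lat = c(NA, 51 + 44 / 60 + 8.9 / 3600, NA, NA),
    lon = c(NA, -(5 + 17 / 60 + 47.0 / 3600), NA, NA),
    cliff_height_m = c(64.1, 66.7, 63.7, 49.0)
  )
}

#' Default inclinometer height above the clifftop
#' @return Height in metres (0.895 m).
#' @export
inclinometer_height <- function() 0.895

#' Observer eye height above the instantaneous sea surface
#'
#' @param C Cliff height above mean sea level, metres (> 0).
#' @param T_ Tide height relative to mean sea level, metres (signed).
#' @param H Instrument height above the clifftop, metres (> 0).
#' @return C + H - T_ in metres.
#' @export
effective_eye_height <- function(C, T_ = 0, H = inclinometer_height()) {
  if (any(!is.finite(C)) || any(C <= 0))
    stop("effective_eye_height: cliff height must be finite and > 0",
         call. = FALSE)
  if (any(!is.finite(H)) || any(H <= 0))
    stop("effective_eye_height: instrument height must be finite and > 0",
         call. = FALSE)
  if (any(!is.finite(T_)) || any(abs(T_) >= 10))
    stop("effective_eye_height: tide height must be finite, |T| < 10 m",
         call. = FALSE)
  h <- C + H - T_
  if (any(h <= 0))
    stop("effective_eye_height: sea surface at or above observer",
         call. = FALSE)
  h
}

#' Horizontal range from eye height and inclinometer declination
#'
#' @param eye_height Observer eye height above the sea surface, metres.
#' @param declination_deg Angle of the line of sight below the horizontal,
#'   degrees, strictly in (0, 90).
#' @param curvature Logical; apply the first-order Earth-curvature
#'   correction (adds range^2 / (2 R) of sea-surface drop). Default FALSE.
#' @return Horizontal range in metres.
#' @export
raft_range <- function(eye_height, declination_deg, curvature = FALSE) {
  if (any(!is.finite(declination_deg)) ||
      any(declination_deg <= 0) || any(declination_deg >= 90))
    stop("raft_range: declination must be in (0, 90) degrees",
         call. = FALSE)
  if (any(!is.finite(eye_height)) || any(eye_height <= 0))
    stop("raft_range: eye height must be finite and > 0", call. = FALSE)
  r <- eye_height / tan(.deg2rad(declination_deg))
  if (curvature) {
    # one fixed-point pass: drop = r^2 / (2R) raises the effective height
    R <- earth_radius()
    r <- (eye_height + r^2 / (2 * R)) / tan(.deg2rad(declination_deg))
  }
  r
}

#' Declination reading implied by a horizontal range
#'
#' Inverse of [raft_range()]; used by the synthetic observation generator.
#'
#' @param eye_height Metres above the sea surface.
#' @param range_m Horizontal range, metres (> 0).
#' @return Declination below the horizontal, degrees in (0, 90).
#' @export
declination_for_range <- function(eye_height, range_m) {
  if (any(!is.finite(range_m)) || any(range_m <= 0))
    stop("declination_for_range: range must be > 0", call. = FALSE)
  .rad2deg(atan2(eye_height, range_m))
}

#' Georeference a shore-based raft observation
#'
#' Projects the sighting from the station position along the (optionally
#' declination-corrected) compass bearing over the range implied by the
#' inclinometer reading and tide height. Rafts at or beyond the 2,000 m
#' boundary are flagged `retained = FALSE` (observation error grows with
#' range).
#'
#' @param obs data.frame of observations with columns `station`,
#'   `timestamp` (POSIXct UTC), `bearing_deg` (magnetic compass bearing),
#'   `declination_deg` (inclinometer angle below horizontal), `count`.
#' @param stations data.frame as [observation_stations()] but with
#'   coordinates filled in.
#' @param tides data.frame with `timestamp` (POSIXct UTC), `height_m`; each
#'   observation uses the nearest tide record in time.
#' @param magnetic_offset Degrees added to magnetic bearings to obtain true
#'   bearings (default 0: bearings taken as-is).
#' @param boundary_m Retention boundary in metres (default 2000); ranges
#'   `>= boundary_m` are flagged not retained.
#' @param instrument_height_m Inclinometer height above the clifftop.
#' @return `obs` with added columns `tide_m`, `range_m`, `lat`, `lon`,
#'   `bearing_true`, `retained`.
#' @export
georeference_rafts <- function(obs, stations, tides,
                               magnetic_offset = 0, boundary_m = 2000,
                               instrument_height_m = inclinometer_height()) {
  need <- c("station", "timestamp", "bearing_deg", "declination_deg",
            "count")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("georeference_rafts: missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(obs$count < 1))
    stop("georeference_rafts: raft counts must be >= 1", call. = FALSE)
  idx <- match(obs$station, stations$station)
  if (anyNA(idx))
    stop("georeference_rafts: unknown station(s): ",
         paste(unique(obs$station[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  st <- stations[idx, , drop = FALSE]
  if (anyNA(st$lat) || anyNA(st$lon))
    stop("georeference_rafts: station coordinates missing", call. = FALSE)
  tide <- vapply(obs$timestamp, function(t)
    match_nearest_time(t, tides)$height_m, numeric(1))
  eye <- effective_eye_height(st$cliff_height_m, tide,
                              instrument_height_m)
  rng <- raft_range(eye, obs$declination_deg)
  brg <- (obs$bearing_deg + magnetic_offset) %% 360
  pos <- destination_point(st$lat, st$lon, brg, rng)
  out <- obs
  out$tide_m <- tide
  out$range_m <- rng
  out$bearing_true <- brg
  out$lat <- pos$lat
  out$lon <- pos$lon
  # snap sub-micrometre float noise before applying the boundary rule, so
  # a raft at exactly the boundary is excluded
  out$retained <- round(rng, 6) < boundary_m
  out
}

#' Densify a polygon boundary
#'
#' Inserts points along each edge so consecutive boundary points are at
#' most `spacing_m` apart (great-circle interpolation along edges, adequate
#' at sub-island scales).
#'
#' @param poly data.frame with `lat`, `lon` vertices (ring; closure
#'   optional).
#' @param spacing_m Maximum spacing between boundary points, metres.
#' @return data.frame of boundary points `lat`, `lon`.
#' @export
densify_boundary <- function(poly, spacing_m = 10) {
  n <- nrow(poly)
  if (is.null(n) || n < 3)
    stop("densify_boundary: polygon needs >= 3 vertices", call. = FALSE)
  # drop explicit closure if present
  if (poly$lat[n] == poly$lat[1] && poly$lon[n] == poly$lon[1]) {
    poly <- poly[-n, , drop = FALSE]; n <- n - 1
  }
  lat <- c(poly$lat, poly$lat[1]); lon <- c(poly$lon, poly$lon[1])
  pts_lat <- numeric(0); pts_lon <- numeric(0)
  for (i in seq_len(n)) {
    d <- haversine_distance(lat[i], lon[i], lat[i + 1], lon[i + 1])
    k <- max(1L, ceiling(d / spacing_m))
    f <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    # linear interpolation in lat/lon is fine at <= spacing scale edges,
    # but use bearing projection for metric fidelity on long edges
    if (d > 0) {
      b <- initial_bearing(lat[i], lon[i], lat[i + 1], lon[i + 1])
      p <- destination_point(lat[i], lon[i], b, f * d)
      pts_lat <- c(pts_lat, p$lat); pts_lon <- c(pts_lon, p$lon)
    } else {
      pts_lat <- c(pts_lat, lat[i]); pts_lon <- c(pts_lon, lon[i])
    }
  }
  data.frame(lat = pts_lat, lon = pts_lon)
}

#' Distance from a point to a shoreline
#'
#' Minimum haversine distance from each point to the densified boundary of
#' the shoreline polygon.
#'
#' @param lat,lon Query point(s), decimal degrees.
#' @param shoreline data.frame with `lat`, `lon` polygon vertices.
#' @param spacing_m Boundary densification spacing, metres (default 10).
#' @return Distance(s) in metres.
#' @export
distance_to_shore <- function(lat, lon, shoreline, spacing_m = 10) {
  b <- densify_boundary(shoreline, spacing_m)
  vapply(seq_along(lat), function(i)
    min(haversine_distance(lat[i], lon[i], b$lat, b$lon)), numeric(1))
}

#' Match a time to the nearest record of a series
#'
#' Returns the row of `series` minimising the absolute time difference;
#' ties break toward the earlier record. Differences beyond `max_gap_s`
#' raise a missing-data warning and set attribute `gap_exceeded`.
#'
#' @param time POSIXct, single value.
#' @param series data.frame with a POSIXct `timestamp` column, sorted.
#' @param max_gap_s Maximum tolerated gap in seconds (default 3 h).
#' @return The matched row (one-row data.frame) with attributes `gap_s` and
#'   `gap_exceeded`.
#' @export
match_nearest_time <- function(time, series, max_gap_s = 3 * 3600) {
  if (is.null(series) || nrow(series) == 0)
    stop("match_nearest_time: empty series", call. = FALSE)
  dt <- abs(as.numeric(series$timestamp) - as.numeric(time))
  i <- which(dt == min(dt))[1]  # earliest among ties (sorted input)
  row <- series[i, , drop = FALSE]
  attr(row, "gap_s") <- dt[i]
  exceeded <- dt[i] > max_gap_s
  if (exceeded)
    warning(sprintf(
      "match_nearest_time: nearest record %.0f s away exceeds max gap %.0f s",
      dt[i], max_gap_s))
  attr(row, "gap_exceeded") <- exceeded
  row
}
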