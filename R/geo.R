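# Great-circle and ellipsoidal geodesy primitives shared by all pipeline
# stages. Convention: WGS84 decimal degrees, bearings in degrees clockwise
# from true north, all internal angle math in radians.

#' Mean Earth radius used for spherical geodesy
#'
#' @return Radius in metres (6,371,000 m).
#' @export
earth_radius <- function() 6371000

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Construct a geographic point
#'
#' Validates and normalises a WGS84 latitude/longitude pair. Longitude is
#' normalised to [-180, 180). Vectorised over both arguments.
#'
#' @param lat Latitude, decimal degrees in [-90, 90].
#' @param lon Longitude, decimal degrees (any real; normalised).
#' @return A data.frame with columns `lat` and `lon`.
#' @export
geo_point <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("geo_point: non-finite coordinates", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("geo_point: latitude outside [-90, 90]", call. = FALSE)
  lon <- ((lon + 180) %% 360) - 180
  data.frame(lat = lat, lon = lon)
}

.check_point <- function(lat, lon, what = "point") {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop(sprintf("%s: non-finite coordinates", what), call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop(sprintf("%s: latitude outside [-90, 90]", what), call. = FALSE)
  invisible(TRUE)
}

#' Great-circle (haversine) distance
#'
#' Distance between two points on a sphere via the haversine formula, which
#' is numerically stable for small separations.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees. Vectorised.
#' @param radius Sphere radius in metres (default [earth_radius()]).
#' @return Distance in metres.
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2,
                               radius = earth_radius()) {
  .check_point(lat1, lon1, "haversine_distance")
  .check_point(lat2, lon2, "haversine_distance")
  if (any(radius <= 0)) stop("haversine_distance: radius must be > 0",
                             call. = FALSE)
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1)
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius * asin(sqrt(a))
}

#' Geodesic distance on the WGS84 ellipsoid (Vincenty inverse)
#'
#' Iterative inverse solution on the WGS84 ellipsoid (a = 6378137 m,
#' f = 1/298.257223563). Convergence tolerance 1e-12 on the auxiliary
#' longitude, at most 200 iterations; near-antipodal pairs for which the
#' iteration fails fall back to the spherical haversine value with a
#' warning.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees. Vectorised.
#' @return Distance in metres.
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  .check_point(lat1, lon1, "geodesic_distance")
  .check_point(lat2, lon2, "geodesic_distance")
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  vapply(seq_len(n), function(i)
    .vincenty1(lat1[i], lon1[i], lat2[i], lon2[i]), numeric(1))
}

.vincenty1 <- function(lat1, lon1, lat2, lon2) {
  if (lat1 == lat2 && lon1 == lon2) return(0)
  a <- 6378137; f <- 1 / 298.257223563; b <- a * (1 - f)
  U1 <- atan((1 - f) * tan(.deg2rad(lat1)))
  U2 <- atan((1 - f) * tan(.deg2rad(lat2)))
  L <- .deg2rad(lon2 - lon1)
  sinU1 <- sin(U1); cosU1 <- cos(U1)
  sinU2 <- sin(U2); cosU2 <- cos(U2)
  lambda <- L
  for (iter in seq_len(200)) {
    sinL <- sin(lambda); cosL <- cos(lambda)
    sinSigma <- sqrt((cosU2 * sinL)^2 +
                     (cosU1 * sinU2 - sinU1 * cosU2 * cosL)^2)
    if (sinSigma == 0) return(0)  # coincident
    cosSigma <- sinU1 * sinU2 + cosU1 * cosU2 * cosL
    sigma <- atan2(sinSigma, cosSigma)
    sinAlpha <- cosU1 * cosU2 * sinL / sinSigma
    cos2Alpha <- 1 - sinAlpha^2
    cos2SigmaM <- if (cos2Alpha == 0) 0 else
      cosSigma - 2 * sinU1 * sinU2 / cos2Alpha
    C <- f / 16 * cos2Alpha * (4 + f * (4 - 3 * cos2Alpha))
    lambdaPrev <- lambda
    lambda <- L + (1 - C) * f * sinAlpha *
      (sigma + C * sinSigma *
         (cos2SigmaM + C * cosSigma * (-1 + 2 * cos2SigmaM^2)))
    if (abs(lambda - lambdaPrev) < 1e-12) {
      u2 <- cos2Alpha * (a^2 - b^2) / b^2
      A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
      B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
      dSigma <- B * sinSigma *
        (cos2SigmaM + B / 4 *
           (cosSigma * (-1 + 2 * cos2SigmaM^2) -
              B / 6 * cos2SigmaM * (-3 + 4 * sinSigma^2) *
              (-3 + 4 * cos2SigmaM^2)))
      return(b * A * (sigma - dSigma))
    }
  }
  warning("geodesic_distance: Vincenty iteration did not converge ",
          "(near-antipodal pair); falling back to spherical distance")
  haversine_distance(lat1, lon1, lat2, lon2)
}

#' Destination point along a great circle
#'
#' Point reached from an origin after travelling a given distance on a
#' given initial bearing over the sphere.
#'
#' @param lat,lon Origin in decimal degrees. Vectorised.
#' @param bearing Initial bearing, degrees clockwise from true north
#'   (any real; reduced modulo 360).
#' @param distance Distance in metres, >= 0.
#' @param radius Sphere radius in metres.
#' @return A data.frame with columns `lat`, `lon`.
#' @export
destination_point <- function(lat, lon, bearing, distance,
                              radius = earth_radius()) {
  .check_point(lat, lon, "destination_point")
  if (any(!is.finite(bearing)) || any(!is.finite(distance)))
    stop("destination_point: non-finite bearing or distance", call. = FALSE)
  if (any(distance < 0))
    stop("destination_point: distance must be >= 0", call. = FALSE)
  phi1 <- .deg2rad(lat)
  lam1 <- .deg2rad(lon)
  theta <- .deg2rad(bearing %% 360)
  delta <- distance / radius
  phi2 <- asin(pmin(pmax(
    sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta), -1), 1))
  lam2 <- lam1 + atan2(sin(theta) * sin(delta) * cos(phi1),
                       cos(delta) - sin(phi1) * sin(phi2))
  geo_point(.rad2deg(phi2), .rad2deg(lam2))
}

#' Initial great-circle bearing
#'
#' Forward azimuth from the first point toward the second, in degrees true
#' within [0, 360).
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees. Vectorised.
#' @return Bearing in degrees true, [0, 360).
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  .check_point(lat1, lon1, "initial_bearing")
  .check_point(lat2, lon2, "initial_bearing")
  if (any(lat1 == lat2 & ((lon1 - lon2) %% 360) == 0))
    stop("initial_bearing: bearing undefined for coincident points",
         call. = FALSE)
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  (.rad2deg(atan2(y, x))) %% 360
}
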