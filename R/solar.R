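# Solar position and day/night labelling. Implements the NOAA solar
# calculator algorithm (low-precision ephemeris, good to ~0.1 degrees of
# elevation / well under a minute of sunrise-sunset time for the decades
# around J2000), which is ample for labelling 5-minute GPS fixes.

# Julian day from POSIXct UTC
.julian_day <- function(time) {
  as.numeric(time) / 86400 + 2440587.5
}

.solar_geometry <- function(jd) {
  t <- (jd - 2451545) / 36525
  L0 <- (280.46646 + t * (36000.76983 + t * 0.0003032)) %% 360
  M <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  e <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  Mr <- .deg2rad(M)
  C <- sin(Mr) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * t) +
    sin(3 * Mr) * 0.000289
  trueLong <- L0 + C
  omega <- .deg2rad(125.04 - 1934.136 * t)
  lambda <- .deg2rad(trueLong - 0.00569 - 0.00478 * sin(omega))
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 -
           t * 0.001813))) / 60) / 60
  eps <- .deg2rad(eps0 + 0.00256 * cos(omega))
  decl <- asin(sin(eps) * sin(lambda))
  y <- tan(eps / 2)^2
  L0r <- .deg2rad(L0)
  eqtime <- 4 * .rad2deg(
    y * sin(2 * L0r) - 2 * e * sin(Mr) +
      4 * e * y * sin(Mr) * cos(2 * L0r) -
      0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr))
  list(declination = decl, eqtime_min = eqtime)
}

#' Solar elevation angle
#'
#' Geometric (unrefracted) elevation of the sun above the horizon for a
#' UTC time and a WGS84 position.
#'
#' @param time POSIXct, UTC. Vectorised.
#' @param lat,lon Position in decimal degrees.
#' @return Elevation in degrees; negative below the horizon.
#' @export
solar_elevation <- function(time, lat, lon) {
  .check_point(lat, lon, "solar_elevation")
  jd <- .julian_day(time)
  g <- .solar_geometry(jd)
  mins <- (jd - floor(jd - 0.5) - 0.5) * 1440  # minutes past UTC midnight
  tst <- (mins + g$eqtime_min + 4 * lon) %% 1440
  ha <- .deg2rad(tst / 4 - 180)
  phi <- .deg2rad(lat)
  .rad2deg(asin(pmin(pmax(
    sin(phi) * sin(g$declination) +
      cos(phi) * cos(g$declination) * cos(ha), -1), 1)))
}

#' Sunrise and sunset times for a date
#'
#' UTC sunrise and sunset using the standard refraction convention: the sun
#' centre at -0.833 degrees elevation (34' refraction + 16' semi-diameter).
#'
#' @param date A Date (or POSIXct whose UTC date is used).
#' @param lat,lon Position in decimal degrees.
#' @return List with POSIXct `sunrise`, `sunset`, `solar_noon` (UTC); NA for
#'   polar day/night.
#' @export
sun_times <- function(date, lat, lon) {
  .check_point(lat, lon, "sun_times")
  midnight <- as.POSIXct(paste(format(as.Date(date), "%Y-%m-%d"),
                               "00:00:00"), tz = "UTC")
  # iterate once: geometry at solar noon rather than midnight
  noon_guess <- midnight + 12 * 3600
  g <- .solar_geometry(.julian_day(noon_guess))
  noon_min <- 720 - 4 * lon - g$eqtime_min
  g <- .solar_geometry(.julian_day(midnight + noon_min * 60))
  noon_min <- 720 - 4 * lon - g$eqtime_min
  phi <- .deg2rad(lat)
  event_min <- function(sign, minutes) {
    # refine with the geometry at the event time itself
    for (k in 1:3) {
      ge <- .solar_geometry(.julian_day(midnight + minutes * 60))
      cosha <- (cos(.deg2rad(90.833)) - sin(phi) * sin(ge$declination)) /
        (cos(phi) * cos(ge$declination))
      if (!is.finite(cosha) || abs(cosha) > 1) return(NA_real_)
      minutes <- (720 - 4 * lon - ge$eqtime_min) +
        sign * 4 * .rad2deg(acos(cosha))
    }
    minutes
  }
  rise <- event_min(-1, noon_min)
  set <- event_min(1, noon_min)
  if (!is.finite(rise) || !is.finite(set)) {
    return(list(sunrise = as.POSIXct(NA), sunset = as.POSIXct(NA),
                solar_noon = midnight + noon_min * 60))
  }
  list(sunrise = midnight + rise * 60,
       sunset = midnight + set * 60,
       solar_noon = midnight + noon_min * 60)
}

#' Label times as day or night
#'
#' Night is defined as solar elevation below -0.833 degrees (the standard
#' sunrise/sunset convention with refraction and solar semi-diameter), so a
#' fix is "day" exactly between local sunrise and sunset.
#'
#' @param time POSIXct UTC. Vectorised.
#' @param lat,lon Position in decimal degrees.
#' @return Character vector, "day" or "night", with the solar elevation in
#'   attribute `elevation`.
#' @export
day_night_label <- function(time, lat, lon) {
  elev <- solar_elevation(time, lat, lon)
  lab <- ifelse(elev < -0.833, "night", "day")
  attr(lab, "elevation") <- elev
  lab
}
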