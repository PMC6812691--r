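# GPS track processing: land-fix removal, between-fix speeds, error
# filtering, behaviour classification, day/night annotation and the
# study-radius flag.

#' Colony reference position
#'
#' Coordinates of the North Haven sub-colony used as the centre of the
#' 5 km GPS study radius.
#'
#' @return Named numeric vector `c(lat, lon)`.
#' @export
colony_position <- function() {
  c(lat = 51 + 44 / 60 + 14.0 / 3600,
    lon = -(5 + 16 / 60 + 55.5 / 3600))
}

#' Remove GPS fixes that fall on land
#'
#' Point-in-polygon test against the island polygon; fixes inside are
#' dropped (behaviour at the colony and on land is not at-sea behaviour).
#'
#' @param track data.frame with columns `bird_id`, `timestamp`, `lat`,
#'   `lon`.
#' @param land data.frame with `lat`, `lon` polygon vertices.
#' @return The track restricted to at-sea fixes; the number removed is in
#'   attribute `n_removed`.
#' @export
remove_land_fixes <- function(track, land) {
  if (nrow(land) < 3)
    stop("remove_land_fixes: land polygon needs >= 3 vertices",
         call. = FALSE)
  inside <- mgcv::in.out(cbind(land$lon, land$lat),
                         cbind(track$lon, track$lat))
  out <- track[!inside, , drop = FALSE]
  attr(out, "n_removed") <- sum(inside)
  out
}

#' Between-fix speeds and bearings
#'
#' For each bird, computes speed (geodesic distance over elapsed time) and
#' initial bearing between consecutive fixes. Duplicate timestamps within a
#' bird are collapsed to the first fix with a warning; a negative time step
#' (unsorted input) is an error.
#'
#' @param track data.frame with `bird_id`, `timestamp` (POSIXct UTC),
#'   `lat`, `lon`.
#' @return data.frame of segments: `bird_id`, `start_time`, `end_time`,
#'   `start_lat`, `start_lon`, `end_lat`, `end_lon`, `dt_s`, `distance_m`,
#'   `speed_ms`, `bearing_deg` (NA for zero-length steps).
#' @export
compute_speeds <- function(track) {
  if (nrow(track) < 2)
    stop("compute_speeds: need at least 2 fixes", call. = FALSE)
  segs <- lapply(split(track, track$bird_id), function(tr) {
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    dup <- duplicated(tr$timestamp)
    if (any(dup)) {
      warning(sprintf(
        "compute_speeds: %d duplicate timestamp(s) for bird %s collapsed",
        sum(dup), tr$bird_id[1]))
      tr <- tr[!dup, , drop = FALSE]
    }
    n <- nrow(tr)
    if (n < 2) return(NULL)
    dt <- as.numeric(tr$timestamp[-1]) - as.numeric(tr$timestamp[-n])
    if (any(dt <= 0))
      stop(sprintf("compute_speeds: non-positive time step for bird %s at %s",
                   tr$bird_id[1],
                   format(tr$timestamp[which(dt <= 0)[1] + 1])),
           call. = FALSE)
    d <- geodesic_distance(tr$lat[-n], tr$lon[-n], tr$lat[-1], tr$lon[-1])
    brg <- rep(NA_real_, n - 1)
    mv <- d > 0
    if (any(mv))
      brg[mv] <- initial_bearing(tr$lat[-n][mv], tr$lon[-n][mv],
                                 tr$lat[-1][mv], tr$lon[-1][mv])
    data.frame(bird_id = tr$bird_id[-n],
               start_time = tr$timestamp[-n], end_time = tr$timestamp[-1],
               start_lat = tr$lat[-n], start_lon = tr$lon[-n],
               end_lat = tr$lat[-1], end_lon = tr$lon[-1],
               dt_s = dt, distance_m = d, speed_ms = d / dt,
               bearing_deg = brg)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Flag implausible speeds as GPS errors
#'
#' Segments faster than `max_speed` are marked `excluded` rather than
#' silently dropped; counts are recorded in attributes `n_kept` /
#' `n_excluded`.
#'
#' @param segments Output of [compute_speeds()].
#' @param max_speed Error threshold in m/s (default 30).
#' @return Segments with a logical `excluded` column.
#' @export
filter_speed_errors <- function(segments, max_speed = 30) {
  if (max_speed <= 0)
    stop("filter_speed_errors: max_speed must be > 0", call. = FALSE)
  segments$excluded <- segments$speed_ms > max_speed
  attr(segments, "n_kept") <- sum(!segments$excluded)
  attr(segments, "n_excluded") <- sum(segments$excluded)
  segments
}

#' Classify segments as rafting or flying
#'
#' Non-excluded segments below the threshold (strictly) are `rafting`,
#' otherwise `flying`; excluded segments stay `excluded`.
#'
#' @param segments Segments with `speed_ms` and (optionally) `excluded`.
#' @param threshold Speed threshold in m/s (default 2.5); typically taken
#'   from [fit_speed_mixture()].
#' @return Segments with a `behaviour` column.
#' @export
classify_behaviour <- function(segments, threshold = 2.5) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("classify_behaviour: threshold must be > 0", call. = FALSE)
  if (is.null(segments$excluded)) segments$excluded <- FALSE
  segments$behaviour <- ifelse(segments$excluded, "excluded",
                               ifelse(segments$speed_ms < threshold,
                                      "rafting", "flying"))
  segments
}

#' Flag points within a radius of a centre
#'
#' @param lat,lon Point(s), decimal degrees.
#' @param centre Named vector `c(lat, lon)`; default [colony_position()].
#' @param radius Radius in metres (default 5000). Strict inequality.
#' @return Logical vector.
#' @export
within_radius <- function(lat, lon, centre = colony_position(),
                          radius = 5000) {
  haversine_distance(lat, lon, centre[["lat"]], centre[["lon"]]) < radius
}

#' Annotate segments with day/night and study-radius flags
#'
#' Day/night is evaluated at the segment's end fix (behaviour is mapped to
#' the end fix of each step; set `at = "start"` for the alternative).
#'
#' @param segments Classified segments.
#' @param centre Study-area centre for the radius flag.
#' @param radius Study radius in metres (default 5000).
#' @param at `"end"` (default) or `"start"`: which fix carries the labels.
#' @return Segments with `day_night` and `within_5km` columns.
#' @export
annotate_segments <- function(segments, centre = colony_position(),
                              radius = 5000, at = c("end", "start")) {
  at <- match.arg(at)
  lat <- if (at == "end") segments$end_lat else segments$start_lat
  lon <- if (at == "end") segments$end_lon else segments$start_lon
  tm <- if (at == "end") segments$end_time else segments$start_time
  segments$day_night <- as.character(day_night_label(tm, lat, lon))
  segments$within_5km <- within_radius(lat, lon, centre, radius)
  segments
}

#' Behaviour and day/night summary
#'
#' Proportions of rafting vs flying among non-excluded segments within the
#' study radius, and the day/night split of rafting.
#'
#' @param segments Classified, annotated segments.
#' @return data.frame with `quantity`, `value` rows: rafting/flying
#'   fractions, night/day fractions of rafting, and the segment counts.
#' @export
behaviour_summary <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0) {
    warning("behaviour_summary: no segments")
    return(data.frame(quantity = character(0), value = numeric(0)))
  }
  keep <- !segments$excluded
  if (!is.null(segments$within_5km)) keep <- keep & segments$within_5km
  s <- segments[keep, , drop = FALSE]
  n <- nrow(s)
  n_raft <- sum(s$behaviour == "rafting")
  n_fly <- sum(s$behaviour == "flying")
  raft <- s[s$behaviour == "rafting", , drop = FALSE]
  n_night <- if (is.null(raft$day_night)) NA_integer_ else
    sum(raft$day_night == "night")
  data.frame(
    quantity = c("prop_rafting", "prop_flying",
                 "prop_rafting_night", "prop_rafting_day",
                 "n_segments", "n_rafting", "n_flying"),
    value = c(n_raft / n, n_fly / n,
              n_night / n_raft, 1 - n_night / n_raft,
              n, n_raft, n_fly))
}

#' Full GPS classification pipeline
#'
#' Land removal, speed computation, 30 m/s error filter, mixture-based (or
#' fixed) threshold, behaviour labels, day/night and radius annotation.
#'
#' @param track data.frame of fixes (`bird_id`, `timestamp`, `lat`, `lon`).
#' @param land Island polygon (`lat`, `lon`), or NULL to skip land removal.
#' @param threshold `"auto"` to fit the speed mixture and use its
#'   equal-posterior threshold, or a numeric m/s value.
#' @param max_speed GPS error speed filter, m/s.
#' @param centre,radius Study-area definition.
#' @param seed Seed for the mixture fit restarts.
#' @return List with `segments` (classified data.frame), `mixture` (the
#'   `speed_mixture` fit or NULL), `threshold`, `summary`, and bookkeeping
#'   counts `n_fixes`, `n_land_removed`, `n_speed_excluded`.
#' @export
classify_tracks <- function(track, land = NULL, threshold = "auto",
                            max_speed = 30, centre = colony_position(),
                            radius = 5000, seed = 1L) {
  n_fixes <- nrow(track)
  n_land <- 0L
  if (!is.null(land)) {
    track <- remove_land_fixes(track, land)
    n_land <- attr(track, "n_removed")
  }
  segs <- compute_speeds(track)
  segs <- filter_speed_errors(segs, max_speed)
  mixture <- NULL
  if (identical(threshold, "auto")) {
    mixture <- fit_speed_mixture(segs$speed_ms[!segs$excluded], seed = seed)
    threshold <- mixture$threshold
  }
  segs <- classify_behaviour(segs, threshold)
  segs <- annotate_segments(segs, centre, radius)
  list(segments = segs, mixture = mixture, threshold = threshold,
       summary = behaviour_summary(segs),
       n_fixes = n_fixes, n_land_removed = n_land,
       n_speed_excluded = sum(segs$excluded))
}
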