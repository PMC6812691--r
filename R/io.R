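# Readers and writers for the pipeline's external formats. CSVs carry
# lat,lon columns in that order (as conventionally logged); GeoJSON is
# lon,lat per the standard — the two conventions meet only inside these
# functions. Timestamps are ISO-8601 UTC throughout.

.parse_time <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (f in fmts) {
    na <- is.na(out)
    if (!any(na)) break
    out[na] <- as.POSIXct(strptime(x[na], f, tz = "UTC"), tz = "UTC")
  }
  out
}

.read_csv_checked <- function(path, required) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop("empty file (header only): ", path, call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

# parse timestamps, split malformed rows into a rejects attribute
.with_times <- function(df, col = "timestamp") {
  t <- suppressWarnings(.parse_time(df[[col]]))
  bad <- is.na(t)
  rejects <- df[bad, , drop = FALSE]
  df <- df[!bad, , drop = FALSE]
  df[[col]] <- t[!bad]
  if (nrow(rejects))
    warning(sprintf("%d row(s) with unparseable timestamps rejected",
                    nrow(rejects)))
  attr(df, "rejects") <- rejects
  df
}

#' Read a GPS track file
#'
#' CSV with columns `bird_id,timestamp,lat,lon` (ISO-8601 UTC). Malformed
#' rows are collected in attribute `rejects`, never silently dropped.
#'
#' @param path File path.
#' @return Sorted data.frame of fixes.
#' @export
read_tracks <- function(path) {
  df <- .read_csv_checked(path, c("bird_id", "timestamp", "lat", "lon"))
  df <- .with_times(df)
  df <- df[order(df$bird_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read shore observation records
#'
#' CSV with columns `station,timestamp,bearing_deg,declination_deg,count`.
#'
#' @param path File path.
#' @return Sorted data.frame; rejects in attribute `rejects`.
#' @export
read_observations <- function(path) {
  df <- .read_csv_checked(path, c("station", "timestamp", "bearing_deg",
                                  "declination_deg", "count"))
  df <- .with_times(df)
  df[order(df$timestamp), , drop = FALSE]
}

#' Read a weather series
#'
#' CSV with columns `timestamp,wind_speed_ms,wind_dir_deg`.
#' @param path File path.
#' @return Sorted data.frame.
#' @export
read_weather <- function(path) {
  df <- .read_csv_checked(path, c("timestamp", "wind_speed_ms",
                                  "wind_dir_deg"))
  df <- .with_times(df)
  df[order(df$timestamp), , drop = FALSE]
}

#' Read a tide series
#'
#' CSV with columns `timestamp,height_m`.
#' @param path File path.
#' @return Sorted data.frame.
#' @export
read_tides <- function(path) {
  df <- .read_csv_checked(path, c("timestamp", "height_m"))
  df <- .with_times(df)
  df[order(df$timestamp), , drop = FALSE]
}

#' Read a shoreline polygon from GeoJSON
#'
#' Accepts a Polygon geometry, a Feature containing one, or a
#' FeatureCollection whose first feature is one. GeoJSON stores lon,lat;
#' the returned data.frame has `lat`, `lon`.
#'
#' @param path GeoJSON file path.
#' @return data.frame of polygon vertices `lat`, `lon`.
#' @export
read_shoreline <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- if (!is.null(g$type) && g$type == "Polygon") g
          else if (!is.null(g$type) && g$type == "Feature") g$geometry
          else if (!is.null(g$type) && g$type == "FeatureCollection")
            list(type = g$features$geometry$type[1],
                 coordinates = g$features$geometry$coordinates[[1]])
          else stop("read_shoreline: unsupported GeoJSON", call. = FALSE)
  co <- geom$coordinates
  ring <- if (is.list(co)) co[[1]] else
    if (length(dim(co)) == 3) co[1, , ] else co
  data.frame(lat = ring[, 2], lon = ring[, 1])
}

#' Write a shoreline polygon as GeoJSON
#'
#' @param shoreline data.frame `lat`, `lon` (ring; closed automatically).
#' @param path Output path.
#' @export
write_shoreline <- function(shoreline, path) {
  n <- nrow(shoreline)
  if (shoreline$lat[n] != shoreline$lat[1] ||
      shoreline$lon[n] != shoreline$lon[1])
    shoreline <- rbind(shoreline, shoreline[1, ])
  ring <- cbind(shoreline$lon, shoreline$lat)
  obj <- list(type = "Polygon", coordinates = list(ring))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Write georeferenced rafts as GeoJSON
#'
#' FeatureCollection of Point features (lon,lat order) with properties
#' `count`, `range_m`, `dist_shore_m`, `retained`.
#'
#' @param rafts Output of [georeference_rafts()], optionally with a
#'   `dist_shore_m` column.
#' @param path Output path.
#' @export
write_rafts_geojson <- function(rafts, path) {
  feats <- lapply(seq_len(nrow(rafts)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(rafts$lon[i], rafts$lat[i])),
         properties = list(
           count = rafts$count[i], range_m = rafts$range_m[i],
           dist_shore_m = if (is.null(rafts$dist_shore_m)) NULL
                          else rafts$dist_shore_m[i],
           retained = rafts$retained[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10, null = "null")
  invisible(path)
}

#' Write a timestamped data.frame as CSV with ISO-8601 UTC timestamps
#'
#' @param df data.frame; POSIXct columns are formatted as UTC.
#' @param path Output path.
#' @export
write_records_csv <- function(df, path) {
  for (nm in names(df))
    if (inherits(df[[nm]], "POSIXct"))
      df[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the full synthetic input bundle
#'
#' Generates tracks, observations, weather, tides, shoreline and ground
#' truth with the synthetic module and writes them under `dir` in the
#' pipeline's input schemas.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return Invisible named vector of file paths.
#' @export
write_fixture_bundle <- function(dir, cfg = sim_config(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_tracks(cfg, seed = seed)
  end <- max(sim$fixes$timestamp)
  tides <- simulate_tides(cfg, cfg$start_date - 3600, end + 3600,
                          seed = seed + 1L)
  wind <- simulate_wind(cfg, cfg$start_date - 3600, end + 3600,
                        seed = seed + 2L)
  rafts <- simulate_raft_field(cfg, n = 100, seed = seed + 3L)
  obs <- simulate_observations(rafts, synthetic_stations(cfg), tides,
                               seed = seed + 4L)
  paths <- c(tracks = file.path(dir, "tracks.csv"),
             observations = file.path(dir, "observations.csv"),
             weather = file.path(dir, "weather.csv"),
             tides = file.path(dir, "tides.csv"),
             shoreline = file.path(dir, "island.geojson"),
             truth = file.path(dir, "truth.csv"))
  write_records_csv(sim$fixes, paths[["tracks"]])
  write_records_csv(obs[c("station", "timestamp", "bearing_deg",
                          "declination_deg", "count")],
                    paths[["observations"]])
  write_records_csv(wind, paths[["weather"]])
  write_records_csv(tides, paths[["tides"]])
  write_shoreline(synthetic_island(cfg), paths[["shoreline"]])
  truth <- data.frame(bird_id = sim$fixes$bird_id,
                      timestamp = sim$fixes$timestamp,
                      true_state = sim$states)
  write_records_csv(truth, paths[["truth"]])
  invisible(paths)
}
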