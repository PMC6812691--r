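# End-to-end analysis: bind the stages into the full rafting report.
# Any stage can fail independently; the bundle records per-stage status
# and partial outputs remain usable.

.stage <- function(name, expr, log) {
  res <- tryCatch(list(ok = TRUE, value = expr, error = NULL),
                  error = function(e)
                    list(ok = FALSE, value = NULL,
                         error = conditionMessage(e)))
  log(sprintf("stage %-12s %s%s", name,
              if (res$ok) "ok" else "FAILED: ",
              if (res$ok) "" else res$error))
  res
}

#' Run the full rafting analysis
#'
#' Executes every pipeline stage on a set of input files: (a) georeference
#' the shore observations and summarise raft counts, sizes and shore
#' distances; (b) classify the GPS tracks and summarise behaviour; (c)
#' test wind-direction effects on rafting direction (circular correlation)
#' for both data streams; (d) fit the raft-size vs wind-speed GLS with
#' MA(4) within-day errors; (e) estimate diel trends in bird counts and
#' shore distance. A machine-readable manifest of headline numbers is
#' returned and, if `out_dir` is given, written as JSON beside the
#' per-record outputs.
#'
#' @param inputs Named list/vector of file paths: `tracks`,
#'   `observations`, `weather`, `tides`, `shoreline`. Missing entries skip
#'   the stages that need them.
#' @param stations Station table with coordinates (default
#'   [synthetic_stations()], matching the synthetic island bundle).
#' @param out_dir Optional output directory for per-record CSV/GeoJSON and
#'   `manifest.json`.
#' @param seed Integer seed for the stochastic stages (mixture restarts,
#'   GLS restarts).
#' @param threshold `"auto"` or a numeric classification speed, m/s.
#' @param quiet Suppress the run log (default FALSE; log always returned).
#' @return Object of class `raft_report`: list with `rafts`, `tracks`
#'   (classification bundle), `circ_obs`, `circ_gps`, `size_fit`,
#'   `trend_counts`, `trend_distance`, `manifest`, `stages`, `log`.
#' @export
run_full_analysis <- function(inputs, stations = synthetic_stations(),
                              out_dir = NULL, seed = 1L,
                              threshold = "auto", quiet = FALSE) {
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  has <- function(k) !is.null(inputs[[k]]) && nzchar(inputs[[k]])
  shoreline <- if (has("shoreline")) read_shoreline(inputs[["shoreline"]])
               else NULL
  tides <- if (has("tides")) read_tides(inputs[["tides"]]) else NULL
  weather <- if (has("weather")) read_weather(inputs[["weather"]])
             else NULL
  centre <- if (!is.null(shoreline))
    c(lat = mean(shoreline$lat), lon = mean(shoreline$lon))
    else colony_position()

  stages <- list()
  rafts <- NULL
  if (has("observations") && !is.null(tides)) {
    stages$geolocate <- .stage("geolocate", {
      obs <- read_observations(inputs[["observations"]])
      r <- georeference_rafts(obs, stations, tides)
      if (!is.null(shoreline))
        r$dist_shore_m <- distance_to_shore(r$lat, r$lon, shoreline)
      r
    }, log)
    rafts <- stages$geolocate$value
  } else log("stage geolocate    skipped (missing observations/tides)")

  track_bundle <- NULL
  if (has("tracks")) {
    stages$classify <- .stage("classify", {
      tr <- read_tracks(inputs[["tracks"]])
      classify_tracks(tr, land = shoreline, threshold = threshold,
                      centre = centre, seed = seed)
    }, log)
    track_bundle <- stages$classify$value
  } else log("stage classify     skipped (missing tracks)")

  circ_obs <- NULL
  if (!is.null(rafts) && !is.null(weather)) {
    stages$circ_obs <- .stage("circ_obs", {
      r <- rafts[rafts$retained, , drop = FALSE]
      wind <- vapply(r$timestamp, function(t)
        match_nearest_time(t, weather)$wind_dir_deg, numeric(1))
      raft_dir <- initial_bearing(centre[["lat"]], centre[["lon"]],
                                  r$lat, r$lon)
      circular_correlation_js(deg_to_circ(raft_dir), deg_to_circ(wind))
    }, log)
    circ_obs <- stages$circ_obs$value
  } else log("stage circ_obs     skipped (needs rafts + weather)")

  circ_gps <- NULL
  if (!is.null(track_bundle) && !is.null(weather)) {
    stages$circ_gps <- .stage("circ_gps", {
      s <- track_bundle$segments
      s <- s[s$behaviour == "rafting" & s$within_5km &
               !is.na(s$bearing_deg), , drop = FALSE]
      wind <- vapply(s$end_time, function(t)
        match_nearest_time(t, weather)$wind_dir_deg, numeric(1))
      circular_correlation_js(deg_to_circ(s$bearing_deg),
                              deg_to_circ(wind))
    }, log)
    circ_gps <- stages$circ_gps$value
  } else log("stage circ_gps     skipped (needs tracks + weather)")

  size_fit <- NULL
  if (!is.null(rafts) && !is.null(weather)) {
    stages$size_model <- .stage("size_model", {
      r <- rafts[rafts$retained, , drop = FALSE]
      r <- r[order(r$timestamp), , drop = FALSE]
      wind <- vapply(r$timestamp, function(t)
        match_nearest_time(t, weather)$wind_speed_ms, numeric(1))
      dat <- data.frame(raft_size = r$count, wind_speed = wind,
                        julian_day = as.integer(format(r$timestamp, "%j")))
      fit_gls_ma(dat, q = 4, seed = seed)
    }, log)
    size_fit <- stages$size_model$value
  } else log("stage size_model   skipped (needs rafts + weather)")

  trend_counts <- NULL; trend_distance <- NULL
  if (!is.null(track_bundle) && !is.null(shoreline)) {
    stages$trends <- .stage("trends", {
      s <- track_bundle$segments
      raft <- s[s$behaviour == "rafting" & s$within_5km, , drop = FALSE]
      tod <- as.numeric(format(raft$end_time, "%H")) +
        as.numeric(format(raft$end_time, "%M")) / 60
      # birds present per half-hour bin (pooled over days)
      bin <- floor(tod * 2) / 2
      cnt <- stats::aggregate(list(n = raft$bird_id),
                              list(tod = bin),
                              function(v) length(unique(v)))
      tc <- fit_poisson_gam(cnt$tod + 0.25, cnt$n)
      raft$dist_shore_m <- distance_to_shore(raft$end_lat, raft$end_lon,
                                             shoreline, spacing_m = 50)
      td <- fit_gaussian_gamm_random_intercept(tod, raft$dist_shore_m,
                                               raft$bird_id)
      list(counts = tc, distance = td)
    }, log)
    if (stages$trends$ok) {
      trend_counts <- stages$trends$value$counts
      trend_distance <- stages$trends$value$distance
    }
  } else log("stage trends       skipped (needs tracks + shoreline)")

  manifest <- .build_manifest(rafts, track_bundle, circ_obs, circ_gps,
                              size_fit, trend_distance, seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(rafts)) {
      write_rafts_geojson(rafts, file.path(out_dir, "rafts.geojson"))
      write_records_csv(rafts, file.path(out_dir, "rafts.csv"))
    }
    if (!is.null(track_bundle))
      write_records_csv(track_bundle$segments,
                        file.path(out_dir, "classified.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 12)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  failed <- vapply(stages, function(s) !s$ok, logical(1))
  out <- list(rafts = rafts, tracks = track_bundle, circ_obs = circ_obs,
              circ_gps = circ_gps, size_fit = size_fit,
              trend_counts = trend_counts,
              trend_distance = trend_distance,
              manifest = manifest, stages = stages, log = log_lines,
              ok = !any(failed))
  class(out) <- "raft_report"
  if (any(failed))
    warning("run_full_analysis: stage(s) failed: ",
            paste(names(stages)[failed], collapse = ", "))
  out
}

.build_manifest <- function(rafts, track_bundle, circ_obs, circ_gps,
                            size_fit, trend_distance, seed) {
  m <- list(seed = seed)
  if (!is.null(rafts)) {
    r <- rafts[rafts$retained, , drop = FALSE]
    m$rafts <- list(
      n_observed = nrow(rafts), n_retained = nrow(r),
      size_min = min(r$count), size_mean = mean(r$count),
      size_sd = stats::sd(r$count), size_max = max(r$count),
      total_birds = sum(r$count))
    if (!is.null(r$dist_shore_m))
      m$rafts <- c(m$rafts, list(
        shore_dist_min = min(r$dist_shore_m),
        shore_dist_mean = mean(r$dist_shore_m),
        shore_dist_sd = stats::sd(r$dist_shore_m)))
  }
  if (!is.null(track_bundle)) {
    sm <- track_bundle$summary
    g <- function(k) sm$value[sm$quantity == k]
    m$behaviour <- list(
      threshold_ms = track_bundle$threshold,
      prop_rafting = g("prop_rafting"), prop_flying = g("prop_flying"),
      prop_rafting_night = g("prop_rafting_night"),
      n_fixes = track_bundle$n_fixes,
      n_land_removed = track_bundle$n_land_removed,
      n_speed_excluded = track_bundle$n_speed_excluded)
    if (!is.null(track_bundle$mixture))
      m$behaviour$mixture <- list(
        mu = track_bundle$mixture$mu, sigma = track_bundle$mixture$sigma,
        lambda = track_bundle$mixture$lambda)
  }
  if (!is.null(circ_obs))
    m$wind_direction_obs <- circ_obs[c("r", "z", "p", "n")]
  if (!is.null(circ_gps))
    m$wind_direction_gps <- circ_gps[c("r", "z", "p", "n")]
  if (!is.null(size_fit)) {
    ct <- size_fit$coefficients
    m$size_model <- list(
      intercept = ct$estimate[1], wind_slope = ct$estimate[2],
      wind_se = ct$std_error[2], wind_p = ct$p_value[2],
      theta = size_fit$theta, sigma = size_fit$sigma,
      AIC = size_fit$AIC, BIC = size_fit$BIC, logLik = size_fit$loglik,
      n = size_fit$n, df_residual = size_fit$df_residual)
  }
  if (!is.null(trend_distance))
    m$diel <- list(bird_sd = trend_distance$bird_sd,
                   dist_range_m = range(trend_distance$curve$fit))
  m
}

#' @export
print.raft_report <- function(x, ...) {
  cat("Rafting analysis report\n")
  for (line in x$log) cat(" ", line, "\n")
  if (!is.null(x$manifest$rafts))
    cat(sprintf("  rafts: %d retained of %d; mean size %.1f\n",
                x$manifest$rafts$n_retained, x$manifest$rafts$n_observed,
                x$manifest$rafts$size_mean))
  if (!is.null(x$manifest$behaviour))
    cat(sprintf("  behaviour: %.1f%% rafting (threshold %.2f m/s), %.1f%% of rafting at night\n",
                100 * x$manifest$behaviour$prop_rafting,
                x$manifest$behaviour$threshold_ms,
                100 * x$manifest$behaviour$prop_rafting_night))
  if (!is.null(x$manifest$size_model))
    cat(sprintf("  size model: wind slope %.3f (p = %.3f)\n",
                x$manifest$size_model$wind_slope,
                x$manifest$size_model$wind_p))
  invisible(x)
}
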