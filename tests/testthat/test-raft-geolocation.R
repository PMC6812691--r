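test_that("effective eye height follows the inclinometer geometry", {
  expect_equal(effective_eye_height(49.0, 0), 49.895)
  expect_equal(effective_eye_height(64.1, 2.0), 62.995)
  # sea at or above the observer is a degenerate geometry
  expect_error(effective_eye_height(4, 4.895), "sea surface")
  expect_error(effective_eye_height(-5, 0), "> 0")
  expect_error(effective_eye_height(49, 11), "tide")
  # strictly decreasing in tide height
  expect_true(effective_eye_height(49, 1) < effective_eye_height(49, 0))
})

test_that("raft range inverts declination and is monotone", {
  expect_equal(raft_range(49.895, 45), 49.895)
  d <- declination_for_range(49.895, 1000)
  expect_equal(d, atan2(49.895, 1000) * 180 / pi)
  expect_equal(raft_range(49.895, d), 1000, tolerance = 1e-9)
  expect_error(raft_range(49.895, 0), "declination")
  expect_error(raft_range(49.895, 90), "declination")
  decl <- seq(0.5, 89.5, by = 0.5)
  expect_true(all(diff(raft_range(50, decl)) < 0))
  # curvature correction is positive and near r^2/(2R)/tan(D) ~ 12.6 m
  # at 2 km from a 50 m cliff
  r0 <- raft_range(50, declination_for_range(50, 2000))
  r1 <- raft_range(50, declination_for_range(50, 2000), curvature = TRUE)
  expect_true(r1 > r0)
  expect_equal(r1 - r0, 2000^2 / (2 * earth_radius()) / (50 / 2000),
               tolerance = 0.02)
})

test_that("georeferencing recovers synthetic raft positions", {
  cfg <- sim_config()
  st <- synthetic_stations(cfg)
  tides <- simulate_tides(cfg, seed = 2)
  rafts <- simulate_raft_field(cfg, n = 60, seed = 9)
  obs <- simulate_observations(rafts, st, tides, seed = 4)
  geo <- georeference_rafts(obs, st, tides)
  err <- haversine_distance(geo$lat, geo$lon, obs$true_lat, obs$true_lon)
  expect_true(all(err < 1))
  expect_equal(geo$range_m, obs$true_range_m, tolerance = 1e-9)
  # retained flag equals the brute-force range filter
  expect_identical(geo$retained, geo$range_m < 2000)
})

test_that("the 2,000 m boundary rule excludes the boundary itself", {
  cfg <- sim_config()
  st <- synthetic_stations(cfg)
  tides <- data.frame(timestamp = cfg$start_date, height_m = 0)
  place <- function(range_m) {
    p <- destination_point(st$lat[1], st$lon[1], 10, range_m)
    data.frame(lat = p$lat, lon = p$lon, count = 5,
               timestamp = cfg$start_date, station = st$station[1])
  }
  obs <- simulate_observations(rbind(place(2000), place(1999.9)), st,
                               tides, max_range_m = 2500)
  geo <- georeference_rafts(obs, st, tides)
  expect_identical(geo$retained, c(FALSE, TRUE))
})

test_that("distance to shore handles vertices, offsets and densification", {
  cfg <- sim_config(island_vertices = 90)
  island <- synthetic_island(cfg)
  # a shoreline vertex is at distance 0
  expect_lt(distance_to_shore(island$lat[5], island$lon[5], island), 1e-6)
  # point at a known offset from the circular island: closed form
  p <- destination_point(cfg$island_centre[["lat"]],
                         cfg$island_centre[["lon"]], 77,
                         cfg$island_radius_m + 750)
  d10 <- distance_to_shore(p$lat, p$lon, island, spacing_m = 10)
  expect_equal(d10, 750, tolerance = 0.01)
  d1 <- distance_to_shore(p$lat, p$lon, island, spacing_m = 1)
  expect_lt(abs(d10 - d1), 10)
  # meridian-aligned segment: point due east at distance d
  seg <- data.frame(lat = c(51.70, 51.72, 51.74), lon = -5.3)
  q <- destination_point(51.72, -5.3, 90, 432)
  expect_equal(distance_to_shore(q$lat, q$lon, seg), 432,
               tolerance = 0.05)
  expect_error(distance_to_shore(51, -5, data.frame(lat = 1, lon = 1)),
               "vertices")
})

test_that("nearest-time matching obeys the tie and gap rules", {
  ts <- as.POSIXct("2016-08-05 00:00:00", tz = "UTC") + c(0, 3600, 7200)
  series <- data.frame(timestamp = ts, height_m = c(1, 2, 3))
  expect_equal(match_nearest_time(ts[2], series)$height_m, 2)
  # midway between records: the earlier one wins
  expect_equal(match_nearest_time(ts[1] + 1800, series)$height_m, 1)
  expect_equal(attr(match_nearest_time(ts[1] + 100, series), "gap_s"), 100)
  expect_warning(
    m <- match_nearest_time(ts[3] + 4 * 3600, series, max_gap_s = 3 * 3600),
    "max gap")
  expect_true(attr(m, "gap_exceeded"))
  expect_error(match_nearest_time(ts[1], series[0, ]), "empty")
})
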