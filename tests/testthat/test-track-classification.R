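make_track <- function(speed_ms, n = 10, dt = 300, bird = "b1",
                       lat0 = 51.7, lon0 = -5.2, bearing = 90) {
  lat <- numeric(n); lon <- numeric(n)
  lat[1] <- lat0; lon[1] <- lon0
  for (i in 2:n) {
    p <- destination_point(lat[i - 1], lon[i - 1], bearing, speed_ms * dt)
    lat[i] <- p$lat; lon[i] <- p$lon
  }
  data.frame(bird_id = bird,
             timestamp = as.POSIXct("2016-08-05", tz = "UTC") +
               seq_len(n) * dt,
             lat = lat, lon = lon)
}

test_that("land fixes are removed per the point-in-polygon oracle", {
  cfg <- sim_config()
  island <- synthetic_island(cfg)
  set.seed(5)
  # fixes scattered across and around the island
  p <- destination_point(cfg$island_centre[["lat"]],
                         cfg$island_centre[["lon"]],
                         runif(300, 0, 360), runif(300, 0, 2500))
  track <- data.frame(bird_id = "b1",
                      timestamp = as.POSIXct("2016-08-05", tz = "UTC") +
                        seq_len(300) * 300,
                      lat = p$lat, lon = p$lon)
  out <- remove_land_fixes(track, island)
  oracle <- vapply(seq_len(300), function(i)
    pip_oracle(track$lon[i], track$lat[i], island$lon, island$lat),
    logical(1))
  expect_equal(nrow(out), sum(!oracle))
  expect_equal(attr(out, "n_removed"), sum(oracle))
  # centroid fix removed, far-offshore fix kept
  centre_fix <- track[1, ]
  centre_fix$lat <- cfg$island_centre[["lat"]]
  centre_fix$lon <- cfg$island_centre[["lon"]]
  expect_equal(nrow(remove_land_fixes(centre_fix, island)), 0)
})

make_track_ellipsoidal <- function(speed_ms, n = 10, dt = 300,
                                   bird = "b1", lat0 = 51.7, lon0 = -5.2,
                                   bearing = 90) {
  # steps laid out on the WGS84 ellipsoid itself, so the measured
  # geodesic speed equals the generating speed exactly
  lat <- numeric(n); lon <- numeric(n)
  lat[1] <- lat0; lon[1] <- lon0
  for (i in 2:n) {
    p <- geosphere::geodesic(c(lon[i - 1], lat[i - 1]), bearing,
                             speed_ms * dt)
    lat[i] <- p[1, "latitude"]; lon[i] <- p[1, "longitude"]
  }
  data.frame(bird_id = bird,
             timestamp = as.POSIXct("2016-08-05", tz = "UTC") +
               seq_len(n) * dt,
             lat = lat, lon = lon)
}

test_that("speeds and bearings are recovered from constructed tracks", {
  skip_if_not_installed("geosphere")
  # 750 m in 300 s is 2.5 m/s
  tr <- make_track_ellipsoidal(2.5, n = 2)
  seg <- compute_speeds(tr)
  expect_equal(seg$dt_s, 300)
  expect_equal(seg$distance_m, 750, tolerance = 1e-6)
  expect_equal(seg$speed_ms, 2.5, tolerance = 1e-6)
  expect_equal(seg$bearing_deg, 90, tolerance = 0.01)
  # stationary pair
  tr2 <- tr; tr2$lat[2] <- tr2$lat[1]; tr2$lon[2] <- tr2$lon[1]
  seg2 <- compute_speeds(tr2)
  expect_equal(seg2$speed_ms, 0)
  expect_true(is.na(seg2$bearing_deg))
  # constant-speed track round trip within 0.1%
  tr3 <- make_track_ellipsoidal(7.3, n = 50, bearing = 215)
  expect_equal(compute_speeds(tr3)$speed_ms, rep(7.3, 49),
               tolerance = 1e-3)
  # duplicate timestamps are collapsed with a warning
  tr4 <- rbind(tr, tr[2, ])
  expect_warning(s4 <- compute_speeds(tr4), "duplicate")
  expect_equal(nrow(s4), 1)
  expect_error(compute_speeds(tr[1, , drop = FALSE]), "at least 2")
})

test_that("the 30 m/s error filter marks but does not drop segments", {
  seg <- data.frame(speed_ms = c(29.9, 30.1, 5, 31, 0.4))
  out <- filter_speed_errors(seg)
  expect_identical(out$excluded, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(nrow(out), 5)
  expect_equal(attr(out, "n_kept"), 3)
  expect_equal(attr(out, "n_excluded"), 2)
})

test_that("behaviour classification is strict at the threshold", {
  seg <- filter_speed_errors(data.frame(speed_ms = c(2.49, 2.5, 2.51, 40)))
  out <- classify_behaviour(seg, 2.5)
  expect_identical(out$behaviour,
                   c("rafting", "flying", "flying", "excluded"))
  expect_error(classify_behaviour(seg, -1), "threshold")
})

test_that("every input fix is accounted for by the pipeline", {
  cfg <- small_cfg()
  sim <- simulate_tracks(cfg, seed = 31)
  island <- synthetic_island(cfg)
  res <- classify_tracks(sim$fixes, land = island, threshold = 2.5)
  tab <- table(res$segments$behaviour)
  n_birds <- length(unique(sim$fixes$bird_id))
  # fixes = land-removed + one per segment + one start fix per bird
  expect_equal(res$n_fixes,
               res$n_land_removed + nrow(res$segments) + n_birds)
  expect_equal(sum(tab), nrow(res$segments))
  expect_true(all(res$segments$behaviour %in%
                    c("rafting", "flying", "excluded")))
})

test_that("classification is invariant to fix-order permutation", {
  cfg <- small_cfg()
  sim <- simulate_tracks(cfg, seed = 8)
  seg1 <- classify_behaviour(compute_speeds(sim$fixes), 2.5)
  set.seed(1)
  shuffled <- sim$fixes[sample.int(nrow(sim$fixes)), ]
  seg2 <- classify_behaviour(compute_speeds(shuffled), 2.5)
  expect_equal(seg1$speed_ms, seg2$speed_ms)
  expect_identical(seg1$behaviour, seg2$behaviour)
})

test_that("within_radius agrees with brute-force distances", {
  ctr <- colony_position()
  expect_true(within_radius(ctr[["lat"]], ctr[["lon"]]))
  p <- destination_point(ctr[["lat"]], ctr[["lon"]], 123, 5001)
  expect_false(within_radius(p$lat, p$lon))
  set.seed(2)
  q <- destination_point(ctr[["lat"]], ctr[["lon"]],
                         runif(100, 0, 360), runif(100, 0, 8000))
  expect_identical(within_radius(q$lat, q$lon),
                   haversine_distance(q$lat, q$lon, ctr[["lat"]],
                                      ctr[["lon"]]) < 5000)
})

test_that("behaviour summary returns the expected fractions", {
  seg <- data.frame(speed_ms = c(rep(1, 17), rep(5, 3)),
                    excluded = FALSE)
  seg <- classify_behaviour(seg, 2.5)
  s <- behaviour_summary(seg)
  expect_equal(s$value[s$quantity == "prop_rafting"], 0.85)
  expect_equal(s$value[s$quantity == "prop_flying"], 0.15)
  expect_warning(behaviour_summary(seg[0, ]), "no segments")
})
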