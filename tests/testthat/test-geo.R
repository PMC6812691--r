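test_that("haversine distance matches closed forms and is metric", {
  R <- earth_radius()
  expect_equal(haversine_distance(12.3, 45.6, 12.3, 45.6), 0)
  # one degree of arc along the equator
  expect_equal(haversine_distance(0, 0, 0, 1), 2 * pi * R / 360,
               tolerance = 1e-10)
  # antipodal points are half a circumference apart
  expect_equal(haversine_distance(0, 0, 0, 180), pi * R, tolerance = 1e-10)

  set.seed(11)
  a <- cbind(runif(200, -80, 80), runif(200, -180, 180))
  b <- cbind(runif(200, -80, 80), runif(200, -180, 180))
  c_ <- cbind(runif(200, -80, 80), runif(200, -180, 180))
  dab <- haversine_distance(a[, 1], a[, 2], b[, 1], b[, 2])
  dba <- haversine_distance(b[, 1], b[, 2], a[, 1], a[, 2])
  expect_equal(dab, dba)
  expect_true(all(dab >= 0 & dab <= pi * R + 1e-6))
  dac <- haversine_distance(a[, 1], a[, 2], c_[, 1], c_[, 2])
  dcb <- haversine_distance(c_[, 1], c_[, 2], b[, 1], b[, 2])
  expect_true(all(dab <= dac + dcb + 1e-6))
  # agrees with the independent spherical oracle
  skip_if_not_installed("geosphere")
  ora <- geosphere::distHaversine(a[, c(2, 1)], b[, c(2, 1)], r = R)
  expect_equal(dab, ora, tolerance = 1e-9)
})

test_that("haversine rejects invalid input", {
  expect_error(haversine_distance(NA, 0, 0, 0), "non-finite")
  expect_error(haversine_distance(95, 0, 0, 0), "latitude")
  expect_error(haversine_distance(0, 0, 0, 1, radius = -1), "radius")
})

test_that("Vincenty geodesic matches the high-precision oracle", {
  expect_equal(geodesic_distance(10, 20, 10, 20), 0)
  # frozen value from an independent geodesic library for (0,0)-(0,1)
  expect_equal(geodesic_distance(0, 0, 0, 1), 111319.4908, tolerance = 1e-7)
  skip_if_not_installed("geosphere")
  set.seed(7)
  lat <- runif(50, -70, 70); lon <- runif(50, -179, 179)
  lat2 <- lat + runif(50, -0.5, 0.5); lon2 <- lon + runif(50, -0.5, 0.5)
  mine <- geodesic_distance(lat, lon, lat2, lon2)
  ora <- geosphere::distVincentyEllipsoid(cbind(lon, lat),
                                          cbind(lon2, lat2))
  expect_equal(mine, ora, tolerance = 1e-9)
})

test_that("geodesic and haversine agree to 0.5% below 10 km", {
  # at the study latitudes; near the equator the meridional radius of
  # curvature differs from the mean radius by ~0.56%
  set.seed(21)
  lat <- runif(300, 40, 60); lon <- runif(300, -180, 180)
  brg <- runif(300, 0, 360); d <- runif(300, 10, 9999)
  p <- destination_point(lat, lon, brg, d)
  geo <- geodesic_distance(lat, lon, p$lat, p$lon)
  hav <- haversine_distance(lat, lon, p$lat, p$lon)
  expect_true(all(abs(geo - hav) / hav < 0.005))
})

test_that("destination point inverts to distance and bearing", {
  expect_equal(destination_point(51.7, -5.3, 123, 0),
               geo_point(51.7, -5.3))
  # eastward along the equator: longitude advances by d/R in degrees
  R <- earth_radius()
  d <- 25000
  p <- destination_point(0, 0, 90, d)
  expect_equal(p$lat, 0, tolerance = 1e-9)
  expect_equal(p$lon, d / R * 180 / pi, tolerance = 1e-9)
  # forward/inverse round trip at the 5 km working scale
  set.seed(3)
  lat <- runif(100, -60, 60); lon <- runif(100, -180, 180)
  brg <- runif(100, 0, 360); dist <- runif(100, 100, 5000)
  q <- destination_point(lat, lon, brg, dist)
  expect_true(all(abs(haversine_distance(lat, lon, q$lat, q$lon) - dist)
                  < 1))
  expect_equal(haversine_distance(lat, lon, q$lat, q$lon), dist,
               tolerance = 1e-6)
  db <- (initial_bearing(lat, lon, q$lat, q$lon) - brg) %% 360
  expect_true(all(pmin(db, 360 - db) < 1e-3))
  skip_if_not_installed("geosphere")
  ora <- geosphere::destPoint(cbind(lon, lat), brg, dist, r = R)
  expect_equal(q$lon, ora[, "lon"], tolerance = 1e-7)
  expect_equal(q$lat, ora[, "lat"], tolerance = 1e-7)
})

test_that("initial bearing handles cardinal cases and rejects coincidence", {
  expect_equal(initial_bearing(0, 0, 1, 0), 0)
  expect_equal(initial_bearing(0, 0, 0, 1), 90)
  expect_equal(initial_bearing(0, 0, -1, 0), 180)
  expect_equal(initial_bearing(0, 0, 0, -1), 270)
  expect_error(initial_bearing(5, 5, 5, 5), "coincident")
})

test_that("geo_point validates and normalises longitude", {
  expect_equal(geo_point(0, 190)$lon, -170)
  expect_equal(geo_point(0, -180)$lon, -180)
  expect_equal(geo_point(0, 180)$lon, -180)
  expect_error(geo_point(91, 0), "latitude")
  expect_error(geo_point(0, Inf), "non-finite")
})
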