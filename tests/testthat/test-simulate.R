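test_that("generators are reproducible and keep the fix cadence", {
  cfg <- small_cfg()
  s1 <- simulate_tracks(cfg, seed = 5)
  s2 <- simulate_tracks(cfg, seed = 5)
  expect_identical(s1, s2)
  s3 <- simulate_tracks(cfg, seed = 6)
  expect_false(identical(s1$fixes$lat, s3$fixes$lat))
  dt <- diff(as.numeric(s1$fixes$timestamp[s1$fixes$bird_id ==
                                             s1$fixes$bird_id[1]]))
  expect_true(all(dt == cfg$fix_interval_s))
})

test_that("pure-rafting tracks classify as rafting throughout", {
  cfg <- small_cfg(p_raft_to_fly = 0)
  sim <- simulate_tracks(cfg, seed = 3)
  expect_true(all(sim$states[!is.na(sim$states)] == "rafting"))
  seg <- classify_behaviour(filter_speed_errors(compute_speeds(sim$fixes)),
                            2.5)
  expect_gt(mean(seg$behaviour == "rafting"), 0.99)
})

test_that("generated speeds re-fit to the generating threshold", {
  cfg <- sim_config(n_birds = 12, hours_per_bird = 24)
  sim <- simulate_tracks(cfg, seed = 2)
  seg <- filter_speed_errors(compute_speeds(sim$fixes))
  m <- fit_speed_mixture(seg$speed_ms[!seg$excluded], seed = 4)
  truth <- closed_form_threshold(c(cfg$raft_mu, cfg$fly_mu),
                                 c(cfg$raft_sd, cfg$fly_sd),
                                 c(0.85, 0.15))
  expect_lt(abs(m$threshold - truth), 0.15)
})

test_that("simulated observations invert exactly without noise", {
  cfg <- sim_config()
  st <- synthetic_stations(cfg)
  tides <- simulate_tides(cfg, seed = 7)
  rafts <- simulate_raft_field(cfg, n = 40, seed = 21)
  obs <- simulate_observations(rafts, st, tides)
  geo <- georeference_rafts(obs, st, tides)
  err <- haversine_distance(geo$lat, geo$lon, obs$true_lat, obs$true_lon)
  expect_lt(max(err), 1)
})

test_that("declination noise propagates per the delta-method bound", {
  cfg <- sim_config()
  st <- synthetic_stations(cfg)
  tides <- data.frame(timestamp = cfg$start_date, height_m = 0)
  p <- destination_point(st$lat[1], st$lon[1], 20, rep(1000, 400))
  rafts <- data.frame(lat = p$lat, lon = p$lon, count = 5,
                      timestamp = cfg$start_date, station = st$station[1])
  obs <- simulate_observations(rafts, st, tides,
                               noise_declination_deg = 0.1, seed = 8,
                               max_range_m = 2500)
  geo <- georeference_rafts(obs, st, tides)
  err <- abs(geo$range_m - obs$true_range_m)
  # delta method: |dr/dD| = r^2/h * (pi/180) per degree; sigma = 0.1 deg
  h <- effective_eye_height(st$cliff_height_m[1], 0)
  sd_pred <- 1000^2 / h * pi / 180 * 0.1
  expect_lt(abs(median(err) - 0.6745 * sd_pred) / (0.6745 * sd_pred), 0.3)
})

test_that("rafts at or beyond the boundary are excluded downstream", {
  cfg <- sim_config()
  st <- synthetic_stations(cfg)
  tides <- data.frame(timestamp = cfg$start_date, height_m = 0)
  p <- destination_point(st$lat[2], st$lon[2], 280, 2000)
  rafts <- data.frame(lat = p$lat, lon = p$lon, count = 9,
                      timestamp = cfg$start_date, station = st$station[2])
  obs <- simulate_observations(rafts, st, tides, max_range_m = 2400)
  geo <- georeference_rafts(obs, st, tides)
  expect_false(any(geo$retained))
})

test_that("size series carries the configured MA structure", {
  # theta = 0: within-day lag-1 autocorrelation of latent residuals ~ 0
  cfg0 <- sim_config(size_theta = rep(0, 4), size_days = 400,
                     rafts_per_day = 12)
  lag1 <- function(d, cfg) {
    e <- d$log_size_latent - cfg$size_beta0 - cfg$size_beta1 * d$wind_speed
    num <- 0; den <- 0
    for (day in split(e, d$julian_day)) {
      n <- length(day)
      if (n < 2) next
      num <- num + sum(day[-1] * day[-n])
      den <- den + sum(day^2)
    }
    num / den
  }
  d0 <- simulate_size_series(cfg0, seed = 5)
  expect_lt(abs(lag1(d0, cfg0)), 0.05)
  # default theta: lag-1 matches the theoretical MA(4) autocorrelation
  cfg1 <- sim_config(size_days = 400, rafts_per_day = 12)
  d1 <- simulate_size_series(cfg1, seed = 5)
  rho1 <- as.numeric(stats::ARMAacf(ma = cfg1$size_theta, lag.max = 1)[2])
  expect_lt(abs(lag1(d1, cfg1) - rho1), 0.05)
})

test_that("a zero wind effect yields nominal slope CI coverage", {
  cfg <- sim_config(size_beta1 = 0, size_days = 15, rafts_per_day = 8)
  cover <- vapply(1:60, function(k) {
    d <- simulate_size_series(cfg, seed = 100 + k)
    f <- fit_gls_ma(d, q = 4, n_starts = 1)
    ct <- f$coefficients
    ct$ci_lower[2] <= 0 && 0 <= ct$ci_upper[2]
  }, logical(1))
  # 95% nominal; binomial error at 60 replicates
  expect_gt(mean(cover), 0.85)
})

test_that("circular pair generator spans independence to near-identity", {
  p <- simulate_circular_pairs(500, dependence_kappa = 500, seed = 3)
  expect_gt(circular_correlation_js(p$alpha, p$beta)$r, 0.95)
  expect_equal(nrow(simulate_circular_pairs(3, seed = 1)), 3)
  expect_error(simulate_circular_pairs(2), "n >= 3")
})
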