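test_that("wet hours count 3-min grid points at 0.05 h each", {
  expect_equal(wet_hours(rep(80, 480), 75), 24)
  expect_equal(wet_hours(rep(50, 480), 75), 0)

  # threshold sinusoid: 241 of 480 grid points satisfy sin >= 0
  m <- seq(0, 1437, by = 3)
  rh <- 75 + 10 * sin(2 * pi * m / 1440)
  expect_equal(wet_hours(rh, 75), 12.05)

  expect_error(wet_hours(rep(80, 100), 75), "full day")
})

test_that("wet hours equal brute-force point counting on random grids", {
  withr::with_seed(99, {
    for (i in 1:20) {
      rh <- runif(480, 0, 100)
      thr <- runif(1, 10, 95)
      count <- 0L
      for (v in rh) if (v >= thr) count <- count + 1L
      expect_identical(wet_hours(rh, thr), count * 0.05)
    }
  })
})

test_that("wet+light hours require co-occurrence and respect bounds", {
  rh80 <- rep(80, 480)
  expect_equal(wetlight_hours(rh80, rep(0, 480)), 0)
  expect_equal(wetlight_hours(rh80, rep(1, 480)), 24)

  par_half <- c(rep(0, 240), rep(5, 240))
  expect_equal(wetlight_hours(rh80, par_half), 12)

  # composition bound on random grids: wetlight <= min(wet, light)
  withr::with_seed(7, {
    for (i in 1:10) {
      rh <- runif(480, 40, 100)
      par <- runif(480, 0, 0.05)
      th <- thresholds()
      wl <- wetlight_hours(rh, par, th)
      expect_lte(wl, wet_hours(rh, th$rh_halite_wet))
      expect_lte(wl, sum(par >= th$par_light) * 0.05)
      expect_lte(wl, 24)
    }
  })
  expect_error(wetlight_hours(rh80, rep(1, 240)), "full day")
})

test_that("raising a threshold never increases wet, wet+light, or day counts", {
  withr::with_seed(31, {
    rh <- runif(480, 0, 100)
    par <- runif(480, 0, 2)
    thr <- sort(runif(5, 10, 95))
    wets <- vapply(thr, function(t) wet_hours(rh, t), numeric(1))
    expect_true(all(diff(wets) <= 0))
    wls <- vapply(thr, function(t) {
      wetlight_hours(rh, par, thresholds(), rh_threshold = t)
    }, numeric(1))
    expect_true(all(diff(wls) <= 0))
  })
})

test_that("strict and inclusive comparisons differ exactly at the threshold", {
  rh <- rep(75, 480)
  expect_equal(wet_hours(rh, 75, strict = FALSE), 24)
  expect_equal(wet_hours(rh, 75, strict = TRUE), 0)
})

test_that("position selects the air vs halite threshold in habitability_days", {
  grid <- dplyr::bind_rows(
    grid_day(function(m) rep(80, length(m)), "RH", position = "top"),
    grid_day(function(m) rep(1, length(m)), "PAR", position = "top"),
    grid_day(function(m) rep(80, length(m)), "RH", position = "air"),
    grid_day(function(m) rep(1, length(m)), "PAR", position = "air")
  )
  hd <- habitability_days(grid)
  expect_equal(hd$wet_hours[hd$position == "top"], 24) # 80 >= 75
  expect_equal(hd$wet_hours[hd$position == "air"], 0)  # 80 < 95
  expect_true(all(hd$wetlight_hours <= hd$wet_hours))
})

test_that("day counts above a threshold follow the daily statistic", {
  # all-dry record
  dry <- simulate_air_series(air_params(
    record_days = 4, rh_mean = 40, rh_amplitude = 10,
    fog_prob_per_night = 0, noise_sd_rh = 0, seed = 2
  ))
  st_dry <- daily_stats(grid_series(dry, variables = "RH"))
  expect_equal(count_days_above(st_dry, "RH", "max", 95)$n_days, 0)

  # exactly k wet days forced by rain
  k_rain <- simulate_air_series(air_params(
    record_days = 6, rh_mean = 40, rh_amplitude = 10,
    fog_prob_per_night = 0, rain_days = c(2, 5), noise_sd_rh = 1, seed = 4
  ))
  st <- daily_stats(grid_series(k_rain, variables = "RH"))
  expect_equal(count_days_above(st, "RH", "max", 95)$n_days, 2)
  expect_error(count_days_above(st, "XYZ", "max", 95), "XYZ")
})

test_that("wet/dry segmentation tiles the record and suppresses short runs", {
  all_wet <- hab_days_fixture(rep(10, 30))
  seg <- segment_wet_periods(all_wet)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$kind, "wet")
  expect_equal(seg$length_days, 30)

  blip <- hab_days_fixture(c(rep(0, 15), 5, rep(0, 14)))
  seg2 <- segment_wet_periods(blip, min_run_days = 3)
  expect_equal(seg2$kind, "dry")
  expect_equal(sum(seg2$kind == "wet"), 0)

  # periods tile the record without overlap
  mixed <- hab_days_fixture(c(rep(8, 12), rep(0, 20), rep(8, 9)))
  seg3 <- segment_wet_periods(mixed)
  expect_equal(sum(seg3$length_days), 41)
  expect_equal(seg3$start_date[-1], seg3$end_date[-nrow(seg3)] + 1)
  expect_equal(seg3$kind, c("wet", "dry", "wet"))

  gap <- mixed[-5, ]
  expect_error(segment_wet_periods(gap), "gap")
})

test_that("regime presets recover their habitability signatures end-to-end", {
  # constant-wet: every day fully wet
  pr <- regime_params("constant_wet", seed = 3)
  pr$air$record_days <- 30L
  top <- simulate_nodule_series(simulate_air_series(pr$air), pr$brine, "top")
  hab <- habitability_from_readings(top)
  expect_true(all(hab$wet_hours == 24))

  # progressive-dry: wet hours non-increasing (within one reading)
  pd <- regime_params("progressive_dry", seed = 3)
  top_pd <- simulate_nodule_series(simulate_air_series(pd$air), pd$brine,
                                   "top")
  hab_pd <- habitability_from_readings(top_pd)
  expect_true(all(diff(hab_pd$wet_hours) <= 0.5 + 1e-9))
  expect_equal(dplyr::last(hab_pd$wet_hours), 0)
})
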