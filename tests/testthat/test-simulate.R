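test_that("air generator reproduces forced fog/dry regimes and is deterministic", {
  foggy <- simulate_air_series(air_params(
    record_days = 5, fog_prob_per_night = 1, fog_rh_peak = 99, seed = 11
  ))
  daily_max <- tapply(foggy$rh_pct, as.Date(foggy$timestamp, tz = "UTC"), max)
  expect_true(all(daily_max >= 95))

  dry <- simulate_air_series(air_params(
    record_days = 5, fog_prob_per_night = 0, rh_mean = 40, rh_amplitude = 10,
    noise_sd_rh = 0, seed = 11
  ))
  daily_max_dry <- tapply(dry$rh_pct, as.Date(dry$timestamp, tz = "UTC"), max)
  expect_true(all(daily_max_dry < 95))
  expect_true(all(dry$rh_pct >= 0 & dry$rh_pct <= 100))
  expect_true(all(dry$par_umol >= 0))

  p <- air_params(record_days = 3, seed = 42)
  expect_identical(simulate_air_series(p), simulate_air_series(p))
})

test_that("rain day indices outside the record are rejected by name", {
  expect_error(air_params(record_days = 10, rain_days = c(3, 12)), "12")
})

test_that("bucket model matches a step-by-step recursion oracle on a two-rain record", {
  air <- simulate_air_series(air_params(
    record_days = 40, rh_mean = 35, rh_amplitude = 10,
    fog_prob_per_night = 0, rain_days = c(5, 20), noise_sd_rh = 0, seed = 1
  ))
  bp <- brine_params(
    initial_reservoir = 0.1, recharge_rate = 0.05, evaporation_rate = 5e-3,
    buffer_offset = 0, interior_noise_sd = 0, relaxation_halflife_h = 24,
    seed = 1
  )
  nod <- simulate_nodule_series(air, bp, position = "middle")

  # independent recursion over the known air input
  res <- bp$initial_reservoir
  prev <- if (res > 0) 75 else air$rh_pct[1]
  oracle <- numeric(nrow(air))
  for (i in seq_len(nrow(air))) {
    res <- if (air$rh_pct[i] >= 75) min(1, res + 0.05 * 0.5) else
      max(0, res - 5e-3 * 0.5)
    if (res > 0) {
      oracle[i] <- 75
      prev <- 75
    } else {
      oracle[i] <- air$rh_pct[i] + (prev - air$rh_pct[i]) * 2^(-0.5 / 24)
      prev <- oracle[i]
    }
  }
  expect_equal(nod$rh_pct, oracle, tolerance = 1e-12)
  expect_true(all(nod$reservoir >= 0 & nod$reservoir <= 1))
  expect_true(all(nod$rh_pct >= 0 & nod$rh_pct <= 100))

  # two isolated rain blocks with strong evaporation: >= 2 distinct returns
  # to the deliquescence point separated by dry spells
  at_deliq <- oracle >= 75
  runs <- rle(at_deliq)
  expect_gte(sum(runs$values), 2)
  expect_gte(sum(!runs$values[-1]), 1)
})

test_that("persistent-brine and exhausted-brine limits hold", {
  air <- simulate_air_series(air_params(
    record_days = 10, rh_mean = 40, rh_amplitude = 10,
    fog_prob_per_night = 0, seed = 2
  ))
  wet_forever <- simulate_nodule_series(
    air,
    brine_params(initial_reservoir = 1, evaporation_rate = 0,
                 buffer_offset = 0, interior_noise_sd = 0.2, seed = 2),
    position = "middle"
  )
  expect_true(all(abs(wet_forever$rh_pct - 75) < 1.5))

  drying <- simulate_nodule_series(
    air,
    brine_params(initial_reservoir = 0.01, recharge_rate = 0,
                 evaporation_rate = 0.05, buffer_offset = 0,
                 interior_noise_sd = 0, relaxation_halflife_h = 6, seed = 2),
    position = "middle"
  )
  expect_equal(drying$rh_pct[1], 75, tolerance = 1)
  expect_lt(mean(tail(drying$rh_pct, 48)), 60)

  # interior T copies air T; PAR attenuated only at the top
  expect_identical(drying$temp_c, air$temp_c)
  expect_true(all(drying$par_umol == 0))
  top <- simulate_nodule_series(air, brine_params(seed = 1), "top")
  expect_equal(top$par_umol, 0.01 * air$par_umol)
})

test_that("nodule simulation rejects non-monotone timestamps", {
  air <- simulate_air_series(air_params(record_days = 1, seed = 1))
  air$timestamp[5] <- air$timestamp[3]
  expect_error(simulate_nodule_series(air, brine_params(), "top"),
               "increasing")
})

test_that("community compositions are normalized, deterministic, and respond to dryness", {
  prm <- community_params(n_taxa = 20, salt_in_fraction = 0.5,
                          dryness_sensitivity = 2,
                          n_replicates_per_site = 3, seed = 5)
  sim <- simulate_community(c(humid = 0, arid = 1), prm)
  sums <- tapply(sim$abundance$abundance, sim$abundance$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_identical(sim, simulate_community(c(humid = 0, arid = 1), prm))
  expect_error(simulate_community(c(a = 0, b = 1),
                                  community_params(n_taxa = 1)),
               "n_taxa")

  # no-effect case: site means converge with many replicates
  null_sim <- simulate_community(
    c(humid = 0, arid = 1),
    community_params(n_taxa = 10, dryness_sensitivity = 0,
                     n_replicates_per_site = 200, seed = 6)
  )
  means <- null_sim$abundance |>
    dplyr::group_by(site, feature) |>
    dplyr::summarise(m = mean(abundance), .groups = "drop") |>
    tidyr::pivot_wider(names_from = site, values_from = m)
  expect_lt(max(abs(means$humid - means$arid)), 0.02)

  # positive effect: salt-in guild higher at the driest site in >= 95% of runs
  hits <- vapply(1:100, function(s) {
    sim_s <- simulate_community(
      c(humid = 0, arid = 1),
      community_params(n_taxa = 20, salt_in_fraction = 0.5,
                       dryness_sensitivity = 2,
                       n_replicates_per_site = 3, seed = s)
    )
    guild <- sim_s$abundance |>
      dplyr::left_join(sim_s$taxa[, c("feature", "salt_in")], by = "feature") |>
      dplyr::group_by(site, sample) |>
      dplyr::summarise(g = sum(abundance[salt_in]), .groups = "drop") |>
      dplyr::group_by(site) |>
      dplyr::summarise(g = mean(g), .groups = "drop")
    guild$g[guild$site == "arid"] > guild$g[guild$site == "humid"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("proteome generator honors length bounds, bias direction, determinism", {
  fixed_len <- simulate_proteome(proteome_params(
    n_proteins = 20, length_range = c(10, 10), seed = 3
  ))
  expect_true(all(nchar(fixed_len$sequence) == 10))

  p <- proteome_params(n_proteins = 50, seed = 9)
  expect_identical(simulate_proteome(p), simulate_proteome(p))

  neutral <- simulate_proteome(proteome_params(
    n_proteins = 500, acidic_bias = 0, seed = 21
  ))
  acidic <- simulate_proteome(proteome_params(
    n_proteins = 500, acidic_bias = 5, seed = 21
  ))
  expect_lt(weighted_mean_pi(acidic), weighted_mean_pi(neutral))
})
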