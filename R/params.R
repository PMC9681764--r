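#' Air microclimate simulation parameters
#'
#' Bundles the knobs of the diurnal air-climate generator: a sinusoidal
#' temperature cycle peaking mid-afternoon, an anti-phased relative-humidity
#' cycle, optional nocturnal fog events that lift RH toward a peak value,
#' forced rain days (RH held at saturation), and a daylight half-sine PAR
#' curve.
#'
#' @param record_days Number of days to simulate (>= 1).
#' @param t_mean,t_amplitude Mean and semi-amplitude of the diurnal air
#'   temperature cycle, degrees C.
#' @param rh_mean,rh_amplitude Mean and semi-amplitude of the diurnal relative
#'   humidity cycle, percent RH. The resulting series is clipped to [0, 100].
#' @param fog_prob_per_night Probability that any given night (00:00-08:00)
#'   carries a fog event.
#' @param fog_rh_peak Peak RH (percent) that a fog event lifts the air toward.
#' @param rain_days Integer vector of day indices (1-based) on which RH is
#'   forced to saturation (>= 99 percent) for the whole day.
#' @param noise_sd_t,noise_sd_rh Gaussian measurement-noise standard
#'   deviations for temperature (degrees C) and RH (percent).
#' @param par_peak Midday peak of photosynthetically active radiation,
#'   umol photons m^-2 s^-1.
#' @param sampling_interval_min Sensor cadence in minutes; must divide 1440.
#' @param seed Integer seed making the generator a pure function of its
#'   parameters.
#'
#' @return An object of class `air_params` (a validated list).
#' @seealso [simulate_air_series()]
#' @export
air_params <- function(record_days = 120,
                       t_mean = 15, t_amplitude = 8,
                       rh_mean = 55, rh_amplitude = 20,
                       fog_prob_per_night = 0.2, fog_rh_peak = 97,
                       rain_days = integer(0),
                       noise_sd_t = 0.5, noise_sd_rh = 2,
                       par_peak = 2000,
                       sampling_interval_min = 30,
                       seed = 1L) {
  stopifnot(is.numeric(record_days), length(record_days) == 1)
  if (record_days < 1) abort("`record_days` must be >= 1.")
  if (1440 %% sampling_interval_min != 0) {
    abort("`sampling_interval_min` must divide 1440.")
  }
  if (fog_prob_per_night < 0 || fog_prob_per_night > 1) {
    abort("`fog_prob_per_night` must be a probability in [0, 1].")
  }
  rain_days <- as.integer(rain_days)
  bad <- rain_days[rain_days < 1 | rain_days > record_days]
  if (length(bad) > 0) {
    abort(sprintf(
      "rain day index out of record: %s (record has %d days)",
      paste(bad, collapse = ", "), as.integer(record_days)
    ))
  }
  structure(
    list(
      record_days = as.integer(record_days),
      t_mean = t_mean, t_amplitude = t_amplitude,
      rh_mean = rh_mean, rh_amplitude = rh_amplitude,
      fog_prob_per_night = fog_prob_per_night, fog_rh_peak = fog_rh_peak,
      rain_days = rain_days,
      noise_sd_t = noise_sd_t, noise_sd_rh = noise_sd_rh,
      par_peak = par_peak,
      sampling_interval_min = as.integer(sampling_interval_min),
      seed = as.integer(seed)
    ),
    class = "air_params"
  )
}

#' Brine reservoir ("bucket") parameters for nodule interiors
#'
#' The interior of a halite nodule is modeled as a dimensionless brine
#' reservoir in [0, 1] that recharges while the outside air is at or above the
#' NaCl deliquescence humidity and evaporates otherwise. While brine persists
#' the interior RH is buffered at the deliquescence point (plus a small
#' positive offset and sensor noise); once the reservoir is exhausted the
#' interior RH relaxes exponentially toward the ambient air RH.
#'
#' @param initial_reservoir Starting reservoir fill, in [0, 1].
#' @param recharge_rate Reservoir units gained per hour while air RH is at or
#'   above `deliquescence_rh`.
#' @param evaporation_rate Reservoir units lost per hour while air is dry.
#' @param deliquescence_rh Equilibrium RH of the saturated brine, percent;
#'   75 for NaCl.
#' @param buffer_offset Mean excess of the buffered interior RH over
#'   `deliquescence_rh`, percent. Keeps buffered readings at or above the
#'   deliquescence threshold despite sensor noise.
#' @param interior_noise_sd Sensor noise on the buffered interior RH, percent.
#' @param relaxation_halflife_h Half-life (hours) of the exponential approach
#'   of interior RH toward air RH after the reservoir is exhausted.
#' @param seed Integer seed for the interior sensor noise.
#'
#' @return An object of class `brine_params`.
#' @seealso [simulate_nodule_series()]
#' @export
brine_params <- function(initial_reservoir = 1,
                         recharge_rate = 0.04,
                         evaporation_rate = 7.5e-4,
                         deliquescence_rh = 75,
                         buffer_offset = 1,
                         interior_noise_sd = 0.2,
                         relaxation_halflife_h = 48,
                         seed = 1L) {
  if (initial_reservoir < 0 || initial_reservoir > 1) {
    abort("`initial_reservoir` must be in [0, 1].")
  }
  if (recharge_rate < 0 || evaporation_rate < 0) {
    abort("rates must be >= 0.")
  }
  if (deliquescence_rh <= 0 || deliquescence_rh >= 100) {
    abort("`deliquescence_rh` must be in (0, 100).")
  }
  if (relaxation_halflife_h <= 0) abort("`relaxation_halflife_h` must be > 0.")
  structure(
    list(
      initial_reservoir = initial_reservoir,
      recharge_rate = recharge_rate,
      evaporation_rate = evaporation_rate,
      deliquescence_rh = deliquescence_rh,
      buffer_offset = buffer_offset,
      interior_noise_sd = interior_noise_sd,
      relaxation_halflife_h = relaxation_halflife_h,
      seed = as.integer(seed)
    ),
    class = "brine_params"
  )
}

#' Community abundance simulation parameters
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param salt_in_fraction Fraction of taxa flagged as salt-in strategists.
#' @param dryness_sensitivity Effect size coupling a per-site dryness index to
#'   the log-abundance of salt-in taxa (0 = no community shift).
#' @param dirichlet_concentration Total concentration of the Dirichlet from
#'   which per-replicate compositions are drawn (> 0; larger = less
#'   replicate-to-replicate noise).
#' @param n_replicates_per_site Nodules sequenced per site.
#' @param seed Integer seed.
#'
#' @return An object of class `community_params`.
#' @seealso [simulate_community()]
#' @export
community_params <- function(n_taxa = 40,
                             salt_in_fraction = 0.3,
                             dryness_sensitivity = 1,
                             dirichlet_concentration = 200,
                             n_replicates_per_site = 4,
                             seed = 1L) {
  if (n_taxa < 2) abort("`n_taxa` must be >= 2.")
  if (salt_in_fraction < 0 || salt_in_fraction > 1) {
    abort("`salt_in_fraction` must be in [0, 1].")
  }
  if (dirichlet_concentration <= 0) {
    abort("`dirichlet_concentration` must be > 0.")
  }
  structure(
    list(
      n_taxa = as.integer(n_taxa),
      salt_in_fraction = salt_in_fraction,
      dryness_sensitivity = dryness_sensitivity,
      dirichlet_concentration = dirichlet_concentration,
      n_replicates_per_site = as.integer(n_replicates_per_site),
      seed = as.integer(seed)
    ),
    class = "community_params"
  )
}

#' Proteome simulation parameters
#'
#' Sequences are drawn i.i.d. from a 20-letter residue composition in which
#' the aspartate and glutamate frequencies are multiplied by
#' `1 + acidic_bias` before renormalization, emulating the acidified
#' proteomes of salt-in halophiles.
#'
#' @param n_proteins Number of protein sequences.
#' @param length_range Length-2 integer vector, min and max residues
#'   (both >= 10).
#' @param acidic_bias Relative over-weighting of D/E (>= 0; 0 = uniform).
#' @param seed Integer seed.
#'
#' @return An object of class `proteome_params`.
#' @seealso [simulate_proteome()]
#' @export
proteome_params <- function(n_proteins = 300,
                            length_range = c(120, 400),
                            acidic_bias = 0,
                            seed = 1L) {
  if (n_proteins < 1) abort("`n_proteins` must be >= 1.")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || any(length_range < 10) ||
      length_range[1] > length_range[2]) {
    abort("`length_range` must be (min, max) with both >= 10 and min <= max.")
  }
  if (acidic_bias < 0) abort("`acidic_bias` must be >= 0.")
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      length_range = length_range,
      acidic_bias = acidic_bias,
      seed = as.integer(seed)
    ),
    class = "proteome_params"
  )
}

#' Habitability thresholds
#'
#' The deliquescence-based habitability criteria: a halite interior is "wet"
#' at RH >= 75 percent (the equilibrium RH of a saturated NaCl brine), the
#' outside air is "wet" at RH >= 95 percent (fog/dew formation), and "light"
#' requires PAR >= 0.01 umol photons m^-2 s^-1, the minimal irradiance usable
#' by highly adapted primary producers.
#'
#' @param rh_halite_wet Wet threshold for nodule-interior RH, percent.
#' @param rh_air_wet Wet threshold for air RH, percent.
#' @param par_light Light threshold, umol photons m^-2 s^-1.
#' @param strict_inequality If `FALSE` (default) comparisons are inclusive
#'   (`>=`); if `TRUE`, strict (`>`).
#'
#' @return An object of class `hab_thresholds`.
#' @export
thresholds <- function(rh_halite_wet = 75, rh_air_wet = 95,
                       par_light = 0.01, strict_inequality = FALSE) {
  if (rh_halite_wet <= 0 || rh_halite_wet >= 100 ||
      rh_air_wet <= 0 || rh_air_wet >= 100) {
    abort("RH thresholds must lie in (0, 100).")
  }
  if (par_light <= 0) abort("`par_light` must be > 0.")
  structure(
    list(
      rh_halite_wet = rh_halite_wet,
      rh_air_wet = rh_air_wet,
      par_light = par_light,
      strict_inequality = isTRUE(strict_inequality)
    ),
    class = "hab_thresholds"
  )
}

#' Named climatic regime presets
#'
#' Three parameterizations of the synthetic generators reproducing the
#' contrasting microclimate regimes observed across coastal and inland Atacama
#' halite fields:
#'
#' * `"constant_wet"` — humid coastal regime: frequent nocturnal fog keeps the
#'   brine reservoir topped up and the nodule interior buffered at the
#'   deliquescence point for the whole record (120 days).
#' * `"cycling"` — high-altiplano regime: a dry atmosphere punctuated by three
#'   two-day precipitation events at days 10, 160 and 280 of a 330-day record;
#'   each recharge sustains roughly 55 wet days, giving three wet periods
#'   separated by long dry spells.
#' * `"progressive_dry"` — hyper-arid regime: no recharge at all, so the
#'   initial reservoir is consumed over roughly 100 days of a 200-day record
#'   after which the interior dries out permanently.
#'
#' @param regime One of `"constant_wet"`, `"cycling"`, `"progressive_dry"`.
#' @param seed Integer seed stored in both parameter sets.
#'
#' @return A list with elements `air` ([air_params()]) and `brine`
#'   ([brine_params()]).
#' @export
regime_params <- function(regime = c("constant_wet", "cycling",
                                     "progressive_dry"),
                          seed = 1L) {
  regime <- match.arg(regime)
  switch(regime,
    constant_wet = list(
      air = air_params(
        record_days = 120, rh_mean = 70, rh_amplitude = 20,
        fog_prob_per_night = 0.7, fog_rh_peak = 99,
        noise_sd_rh = 2, seed = seed
      ),
      brine = brine_params(
        initial_reservoir = 1, recharge_rate = 0.05,
        evaporation_rate = 2e-4, seed = seed
      )
    ),
    cycling = list(
      air = air_params(
        record_days = 330, rh_mean = 35, rh_amplitude = 15,
        fog_prob_per_night = 0, rain_days = c(10, 11, 160, 161, 280, 281),
        noise_sd_rh = 2, seed = seed
      ),
      brine = brine_params(
        initial_reservoir = 1, recharge_rate = 0.04,
        evaporation_rate = 7.5e-4, relaxation_halflife_h = 48, seed = seed
      )
    ),
    progressive_dry = list(
      air = air_params(
        record_days = 200, rh_mean = 40, rh_amplitude = 15,
        fog_prob_per_night = 0, noise_sd_rh = 2, seed = seed
      ),
      brine = brine_params(
        initial_reservoir = 0.5, recharge_rate = 0,
        evaporation_rate = 2e-4, relaxation_halflife_h = 48, seed = seed
      )
    )
  )
}
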