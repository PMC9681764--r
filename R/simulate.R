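#' Simulate an air microclimate sensor series
#'
#' Generates a regular-cadence logger record of air temperature, relative
#' humidity and PAR. Temperature follows a diurnal sinusoid peaking at 15:00;
#' RH is anti-phased with temperature; on fog nights RH is lifted toward
#' `fog_rh_peak` between 00:00 and 08:00; on rain days RH is forced to
#' saturation for the whole day; PAR is a half-sine over 06:00-18:00 scaled by
#' `par_peak` and zero at night. RH is clipped to [0, 100] and PAR to >= 0.
#'
#' @param params An [air_params()] object.
#' @param site,replicate Labels stamped onto the output rows.
#' @param start_date First calendar day of the record (UTC).
#'
#' @return A sensor-series tibble with columns `site`, `position` (always
#'   `"air"`), `replicate`, `timestamp` (POSIXct, UTC), `temp_c`, `rh_pct`,
#'   `par_umol`.
#' @examples
#' head(simulate_air_series(air_params(record_days = 2)))
#' @export
simulate_air_series <- function(params = air_params(),
                                site = "site1", replicate = "r1",
                                start_date = as.Date("2018-02-01")) {
  stopifnot(inherits(params, "air_params"))
  step <- params$sampling_interval_min
  n_per_day <- 1440L %/% step
  n <- params$record_days * n_per_day
  minute <- rep(seq(0L, 1439L, by = step), params$record_days)
  day <- rep(seq_len(params$record_days), each = n_per_day)

  withr::with_seed(params$seed, {
    hour <- minute / 60
    # diurnal cycles: T peaks at 15:00, RH anti-phased
    phase <- cos(2 * pi * (hour - 15) / 24)
    temp <- params$t_mean + params$t_amplitude * phase +
      rnorm(n, 0, params$noise_sd_t)
    rh <- params$rh_mean - params$rh_amplitude * phase +
      rnorm(n, 0, params$noise_sd_rh)

    # nocturnal fog: lift RH toward fog_rh_peak on a half-sine hump 00:00-08:00
    fog_night <- runif(params$record_days) < params$fog_prob_per_night
    in_window <- minute < 480L
    shape <- ifelse(in_window, sin(pi * minute / 480), 0)
    lift <- rh + (params$fog_rh_peak - rh) * shape
    foggy <- fog_night[day] & in_window & lift > rh
    rh[foggy] <- lift[foggy]

    # rain: RH forced to saturation for the full day
    rainy <- day %in% params$rain_days
    rh[rainy] <- pmax(rh[rainy], 99.5)

    rh <- pmin(pmax(rh, 0), 100)

    # PAR: daylight half-sine 06:00-18:00
    par <- params$par_peak * sin(pi * (hour - 6) / 12)
    par[hour < 6 | hour > 18] <- 0
    par <- pmax(par, 0)
  })

  tibble(
    site = site, position = "air", replicate = replicate,
    timestamp = as.POSIXct(start_date, tz = "UTC") +
      ((day - 1) * 1440 + minute) * 60,
    temp_c = temp, rh_pct = rh, par_umol = par
  )
}

#' Simulate a nodule-interior sensor series from an air series
#'
#' Runs the brine-bucket model over an air record: the reservoir recharges at
#' `recharge_rate` per hour whenever air RH is at or above the deliquescence
#' threshold and evaporates at `evaporation_rate` otherwise, clamped to
#' [0, 1]. While the reservoir holds brine the interior RH is buffered at
#' `deliquescence_rh + buffer_offset` plus sensor noise; once exhausted it
#' relaxes exponentially (half-life `relaxation_halflife_h`) toward the
#' current air RH. Interior temperature copies air temperature; interior PAR
#' is zero for middle/bottom positions and 1 percent of air PAR for tops.
#'
#' @param air A sensor-series tibble from [simulate_air_series()] (or read
#'   from a logger export), with strictly increasing timestamps.
#' @param params A [brine_params()] object.
#' @param position `"top"`, `"middle"` or `"bottom"`.
#' @param replicate Replicate label for the output (defaults to the air
#'   series' label).
#'
#' @return A sensor-series tibble with the same timestamps as `air`.
#' @export
simulate_nodule_series <- function(air, params = brine_params(),
                                   position = c("top", "middle", "bottom"),
                                   replicate = NULL) {
  stopifnot(inherits(params, "brine_params"))
  position <- match.arg(position)
  ts <- air$timestamp
  if (any(diff(as.numeric(ts)) <= 0)) {
    abort("air series timestamps must be strictly increasing.")
  }
  n <- nrow(air)
  dt_h <- diff(as.numeric(ts)) / 3600
  dt_h <- c(dt_h[1], dt_h) # first step assumed at cadence

  deliq <- params$deliquescence_rh
  buffered_rh <- deliq + params$buffer_offset
  decay <- 2^(-dt_h / params$relaxation_halflife_h)

  noise <- withr::with_seed(params$seed,
                            rnorm(n, 0, params$interior_noise_sd))

  reservoir <- numeric(n)
  rh_int <- numeric(n)
  res <- params$initial_reservoir
  prev_rh <- if (res > 0) buffered_rh else air$rh_pct[1]
  for (i in seq_len(n)) {
    if (air$rh_pct[i] >= deliq) {
      res <- min(1, res + params$recharge_rate * dt_h[i])
    } else {
      res <- max(0, res - params$evaporation_rate * dt_h[i])
    }
    if (res > 0) {
      rh_int[i] <- buffered_rh + noise[i]
      prev_rh <- buffered_rh
    } else {
      rh_int[i] <- air$rh_pct[i] + (prev_rh - air$rh_pct[i]) * decay[i] +
        noise[i]
      prev_rh <- rh_int[i] - noise[i]
    }
    reservoir[i] <- res
  }
  rh_int <- pmin(pmax(rh_int, 0), 100)
  par_int <- if (position == "top") 0.01 * air$par_umol else rep(0, n)

  tibble(
    site = air$site, position = position,
    replicate = replicate %||% air$replicate,
    timestamp = ts,
    temp_c = air$temp_c,
    rh_pct = rh_int,
    par_umol = par_int,
    reservoir = reservoir
  )
}

#' Simulate community relative abundances across sites
#'
#' Per-taxon mean log-weights are drawn once; salt-in taxa receive an extra
#' `dryness_sensitivity * dryness_index` term at each site, so drier sites
#' shift composition toward the salt-in guild. Replicate compositions are
#' drawn from a Dirichlet with mean `softmax(log-weights)` and total
#' concentration `dirichlet_concentration`. Salt-in taxa are labeled as
#' archaeal *Euryarchaeota*; the remainder are spread over common halite
#' bacterial phyla, so the table exercises the archaea:bacteria ratio and
#' phylum-level statistics downstream.
#'
#' @param dryness_index Named numeric vector: one dimensionless dryness index
#'   per site (larger = drier). All values must be finite.
#' @param params A [community_params()] object.
#'
#' @return A list with `abundance` (tibble `feature`, `sample`, `site`,
#'   `abundance`; per-sample abundances are proportions summing to 1 — pass
#'   through [normalize_relative_abundance()] for percent) and `taxa`
#'   (tibble `feature`, `domain`, `phylum`, `salt_in` ground truth).
#' @export
simulate_community <- function(dryness_index, params = community_params()) {
  stopifnot(inherits(params, "community_params"))
  if (is.null(names(dryness_index)) || any(!is.finite(dryness_index))) {
    abort("`dryness_index` must be a named, finite numeric vector.")
  }
  n_taxa <- params$n_taxa
  sites <- names(dryness_index)

  withr::with_seed(params$seed, {
    n_salt <- round(params$salt_in_fraction * n_taxa)
    salt_in <- seq_len(n_taxa) %in% sample(n_taxa, n_salt)
    base_logw <- rnorm(n_taxa, 0, 1)
    bact_phyla <- sample(
      c("Cyanobacteria", "Bacteroidetes", "Proteobacteria", "Actinobacteria"),
      n_taxa, replace = TRUE
    )
    feature <- sprintf("taxon_%03d", seq_len(n_taxa))

    rows <- purrr::map(sites, function(s) {
      logw <- base_logw +
        params$dryness_sensitivity * dryness_index[[s]] * salt_in
      p <- exp(logw - max(logw))
      p <- p / sum(p)
      alpha <- params$dirichlet_concentration * p
      purrr::map(seq_len(params$n_replicates_per_site), function(r) {
        g <- rgamma(n_taxa, shape = alpha, rate = 1)
        tibble(
          feature = feature,
          sample = sprintf("%s_%d", s, r),
          site = s,
          abundance = g / sum(g)
        )
      })
    })
  })

  list(
    abundance = bind_rows(rows),
    taxa = tibble(
      feature = feature,
      domain = ifelse(salt_in, "Archaea", "Bacteria"),
      phylum = ifelse(salt_in, "Euryarchaeota", bact_phyla),
      salt_in = salt_in
    )
  )
}

AA_LETTERS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Simulate a predicted proteome with tunable acidic-residue bias
#'
#' @param params A [proteome_params()] object.
#'
#' @return A tibble of protein records: `id`, `contig`, `sequence`, `weight`
#'   (uniform abundance weights).
#' @export
simulate_proteome <- function(params = proteome_params()) {
  stopifnot(inherits(params, "proteome_params"))
  freq <- rep(1, 20)
  names(freq) <- AA_LETTERS
  freq[c("D", "E")] <- freq[c("D", "E")] * (1 + params$acidic_bias)
  freq <- freq / sum(freq)

  withr::with_seed(params$seed, {
    span <- params$length_range[2] - params$length_range[1] + 1L
    lens <- params$length_range[1] +
      sample.int(span, params$n_proteins, replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_LETTERS, L, replace = TRUE, prob = freq), collapse = "")
    }, character(1))
  })

  tibble(
    id = sprintf("contig_%04d_orf1", seq_len(params$n_proteins)),
    contig = sprintf("contig_%04d", seq_len(params$n_proteins)),
    sequence = seqs,
    weight = 1
  )
}
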