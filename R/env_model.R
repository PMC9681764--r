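GRID_MINUTES <- seq(0L, 1437L, by = 3L) # half-open day, 480 points

#' Fit a penalized-spline smooth of one variable over one day
#'
#' Smooths value against time-of-day with a cubic penalized regression spline
#' (basis dimension up to 20) and maximum-likelihood smoothness selection, the
#' per-day model used to align 30-min logger readings to a common 3-min grid.
#' Constant days short-circuit to an exact constant.
#'
#' @param minutes Numeric minutes from midnight, in [0, 1440).
#' @param values Observed values; must contain >= 4 non-missing points.
#'
#' @return A function of minutes-from-midnight returning smoothed values
#'   anywhere on [0, 1440).
#' @export
fit_daily_smooth <- function(minutes, values) {
  keep <- is.finite(minutes) & is.finite(values)
  minutes <- minutes[keep]
  values <- values[keep]
  if (length(values) < 4) {
    abort("need at least 4 non-missing readings to model a day.")
  }
  if (any(minutes < 0 | minutes >= 1440)) {
    abort("`minutes` must lie in [0, 1440).")
  }
  if (sd(values) == 0) {
    v <- values[1]
    return(function(t) rep(v, length(t)))
  }
  k <- min(20L, length(values) - 1L)
  dat <- data.frame(minute = minutes, value = values)
  # noiseless days drive the smoothness parameter to its boundary, which
  # mgcv reports as a step failure; the fit itself is fine there
  fit <- suppressWarnings(
    mgcv::gam(value ~ s(minute, bs = "cr", k = k), data = dat, method = "ML")
  )
  function(t) {
    as.numeric(mgcv::predict.gam(fit, newdata = data.frame(minute = t)))
  }
}

sensor_long <- function(series) {
  series |>
    tidyr::pivot_longer(
      cols = c("temp_c", "rh_pct", "par_umol"),
      names_to = "variable", values_to = "value"
    ) |>
    mutate(variable = dplyr::recode(.data$variable,
      temp_c = "T", rh_pct = "RH", par_umol = "PAR"
    ))
}

#' Align a sensor series to the 3-minute daily grid
#'
#' For every calendar day and variable with at least 4 readings, fits
#' [fit_daily_smooth()] and evaluates it at minutes 0, 3, ..., 1437 (480
#' points per day). RH grids are clipped to [0, 100] and PAR grids to >= 0
#' after smoothing. Day-variable series with fewer than 4 readings are
#' omitted with a warning.
#'
#' @param series A sensor-series tibble (`site`, `position`, `replicate`,
#'   `timestamp`, `temp_c`, `rh_pct`, `par_umol`).
#' @param variables Which variables to grid (subset of `"T"`, `"RH"`,
#'   `"PAR"`).
#'
#' @return A gridded tibble: `site`, `position`, `replicate`, `date`,
#'   `variable`, `minute`, `value`, with 480 rows per day-variable.
#' @export
grid_series <- function(series, variables = c("T", "RH", "PAR")) {
  if (nrow(series) == 0) abort("empty sensor series.")
  long <- sensor_long(series) |>
    filter(.data$variable %in% variables, is.finite(.data$value)) |>
    mutate(
      date = as.Date(.data$timestamp, tz = "UTC"),
      minute = as.numeric(.data$timestamp -
                            as.POSIXct(.data$date, tz = "UTC"),
                          units = "mins")
    )

  n_skipped <- 0L
  out <- long |>
    group_by(.data$site, .data$position, .data$replicate,
             .data$date, .data$variable) |>
    group_modify(function(df, key) {
      if (nrow(df) < 4) {
        n_skipped <<- n_skipped + 1L
        return(tibble(minute = numeric(0), value = numeric(0)))
      }
      f <- fit_daily_smooth(df$minute, df$value)
      v <- f(GRID_MINUTES)
      if (key$variable == "RH") v <- pmin(pmax(v, 0), 100)
      if (key$variable == "PAR") v <- pmax(v, 0)
      tibble(minute = as.numeric(GRID_MINUTES), value = v)
    }) |>
    ungroup()
  if (n_skipped > 0) {
    warn(sprintf(
      "%d day-variable series with < 4 readings were omitted from the grid.",
      n_skipped
    ))
  }
  out
}

#' Daily minimum, maximum and mean from gridded days
#'
#' @param grid A gridded tibble from [grid_series()].
#'
#' @return One row per series/date/variable with `min`, `max`, `mean`
#'   computed over the day's grid points.
#' @export
daily_stats <- function(grid) {
  grid |>
    group_by(across(any_of(c("site", "position", "replicate",
                             "date", "variable")))) |>
    summarise(
      min = min(.data$value), max = max(.data$value),
      mean = mean(.data$value), .groups = "drop"
    )
}

#' Pointwise mean of gridded days across replicate nodules
#'
#' Averages grid values over replicates for each site/position/date/variable/
#' minute; replicates missing a day simply do not contribute, and the number
#' that did is recorded in `n_replicates`.
#'
#' @param grid A gridded tibble covering one or more replicates.
#'
#' @return A gridded tibble without the `replicate` column, plus
#'   `n_replicates`.
#' @export
mean_across_replicates <- function(grid) {
  if (nrow(grid) == 0) abort("no replicate grids supplied.")
  grid |>
    group_by(across(any_of(c("site", "position", "date",
                             "variable", "minute")))) |>
    summarise(
      value = mean(.data$value),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}
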