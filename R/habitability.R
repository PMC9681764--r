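above <- function(x, threshold, strict) {
  if (strict) x > threshold else x >= threshold
}

check_day_grid <- function(x, hours_per_point, arg) {
  if (abs(length(x) * hours_per_point - 24) > 1e-9) {
    abort(sprintf(
      "`%s` has %d points at %.3g h/point; a full day is required.",
      arg, length(x), hours_per_point
    ))
  }
}

#' Cumulative wet hours of one gridded day
#'
#' Each grid point at or above the RH threshold contributes its grid spacing
#' (0.05 h for the default 3-min grid); crossing times are never interpolated.
#'
#' @param rh RH values covering one full day (480 points on the 3-min grid).
#' @param threshold Wet RH threshold, percent.
#' @param strict Use strict (`>`) instead of inclusive (`>=`) comparison.
#' @param hours_per_point Hours represented by one grid point.
#'
#' @return Hours in [0, 24].
#' @examples
#' wet_hours(rep(80, 480), 75) # 24
#' @export
wet_hours <- function(rh, threshold = 75, strict = FALSE,
                      hours_per_point = 0.05) {
  check_day_grid(rh, hours_per_point, "rh")
  sum(above(rh, threshold, strict)) * hours_per_point
}

#' Cumulative wet + light hours of one gridded day
#'
#' Counts grid points where the RH threshold and the PAR threshold are met
#' simultaneously; by construction the result never exceeds [wet_hours()] of
#' the same RH grid.
#'
#' @param rh,par RH and PAR values on the same full-day grid.
#' @param th A [thresholds()] object.
#' @param rh_threshold Wet RH threshold to use (defaults to the halite
#'   threshold in `th`).
#' @inheritParams wet_hours
#'
#' @return Hours in [0, 24].
#' @export
wetlight_hours <- function(rh, par, th = thresholds(),
                           rh_threshold = th$rh_halite_wet,
                           hours_per_point = 0.05) {
  check_day_grid(rh, hours_per_point, "rh")
  check_day_grid(par, hours_per_point, "par")
  if (length(rh) != length(par)) abort("`rh` and `par` grids differ in length.")
  s <- th$strict_inequality
  sum(above(rh, rh_threshold, s) & above(par, th$par_light, s)) *
    hours_per_point
}

hab_threshold_for <- function(position, th) {
  ifelse(position == "air", th$rh_air_wet, th$rh_halite_wet)
}

#' Daily habitability windows from gridded days
#'
#' Computes per-day cumulative wet and wet + light hours for every series in
#' a gridded table. The wet RH threshold is chosen from the series' position:
#' air series use `rh_air_wet`, nodule interiors use `rh_halite_wet`.
#' Days missing either the RH or the PAR grid are dropped (wet + light needs
#' both); a mismatch between the two grids' dates within a series is
#' impossible by construction of the join.
#'
#' @param grid A gridded tibble from [grid_series()] (variables `RH` and
#'   `PAR` required).
#' @param th A [thresholds()] object.
#'
#' @return A tibble: `site`, `position`, `replicate`, `date`, `wet_hours`,
#'   `wetlight_hours`.
#' @export
habitability_days <- function(grid, th = thresholds()) {
  wide <- grid |>
    filter(.data$variable %in% c("RH", "PAR")) |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  if (!all(c("RH", "PAR") %in% names(wide))) {
    abort("grid must contain both RH and PAR variables.")
  }
  wide |>
    filter(is.finite(.data$RH), is.finite(.data$PAR)) |>
    group_by(across(any_of(c("site", "position", "replicate", "date")))) |>
    summarise(
      wet_hours = wet_hours(.data$RH,
                            hab_threshold_for(first(.data$position), th),
                            strict = th$strict_inequality),
      wetlight_hours = wetlight_hours(
        .data$RH, .data$PAR, th,
        rh_threshold = hab_threshold_for(first(.data$position), th)
      ),
      .groups = "drop"
    )
}

#' Daily habitability windows from raw readings
#'
#' The same threshold engine applied directly to logger readings, each
#' contributing its sampling interval (0.5 h at the default 30-min cadence)
#' instead of smoothing to the 3-min grid first. Partial days (fewer readings
#' than a full day) are kept; their hours are bounded by the readings
#' present.
#'
#' @param series A sensor-series tibble.
#' @param th A [thresholds()] object.
#'
#' @return A tibble: `site`, `position`, `replicate`, `date`, `wet_hours`,
#'   `wetlight_hours`, `n_readings`.
#' @export
habitability_from_readings <- function(series, th = thresholds()) {
  if (nrow(series) == 0) abort("empty sensor series.")
  step_h <- median(diff(as.numeric(series$timestamp))) / 3600
  s <- th$strict_inequality
  series |>
    mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    group_by(across(any_of(c("site", "position", "replicate", "date")))) |>
    summarise(
      wet_hours = sum(above(
        .data$rh_pct, hab_threshold_for(first(.data$position), th), s
      )) * step_h,
      wetlight_hours = sum(
        above(.data$rh_pct,
              hab_threshold_for(first(.data$position), th), s) &
          above(.data$par_umol, th$par_light, s)
      ) * step_h,
      n_readings = dplyr::n(),
      .groups = "drop"
    )
}

#' Count days whose daily statistic clears a threshold
#'
#' @param stats A daily-stats tibble from [daily_stats()].
#' @param variable `"T"`, `"RH"` or `"PAR"`.
#' @param stat Which daily statistic to threshold.
#' @param threshold Threshold value.
#' @param strict Use strict (`>`) comparison instead of inclusive (`>=`).
#'
#' @return A tibble with any series-identifying columns plus `n_days`.
#' @export
count_days_above <- function(stats, variable, stat = c("max", "min", "mean"),
                             threshold, strict = FALSE) {
  stat <- match.arg(stat)
  if (nrow(stats) == 0) abort("empty daily-stats table.")
  if (!variable %in% stats$variable) {
    abort(sprintf("variable '%s' not present in the daily-stats table.",
                  variable))
  }
  stats |>
    filter(.data$variable == !!variable) |>
    group_by(across(any_of(c("site", "position", "replicate")))) |>
    summarise(
      n_days = sum(above(.data[[stat]], threshold, strict)),
      .groups = "drop"
    )
}

merge_short_runs <- function(state, min_run_days) {
  repeat {
    r <- rle(state)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_run_days)
    if (length(short) == 0) break
    j <- short[which.min(r$lengths[short])]
    # flipping a run's binary state merges it into its neighbors
    r$values[j] <- !r$values[j]
    state <- inverse.rle(r)
  }
  state
}

#' Segment a habitability record into wet and dry periods
#'
#' A day is "wet" when its wet hours reach `wet_day_min_hours`; runs of days
#' shorter than `min_run_days` are absorbed into the surrounding state, so
#' isolated blips do not fragment the record. The returned periods tile the
#' record without gaps or overlap.
#'
#' @param hab_days A habitability tibble for a single series (consecutive
#'   dates; a gap raises an error asking the caller to fill or split), or for
#'   several series identified by `site`/`position`/`replicate` columns, each
#'   segmented independently.
#' @param wet_day_min_hours Minimum daily wet hours for a wet day.
#' @param min_run_days Minimum persistence, in days, of a wet or dry state.
#'
#' @return A tibble: series columns, `start_date`, `end_date`, `kind`
#'   (`"wet"`/`"dry"`), `length_days`.
#' @export
segment_wet_periods <- function(hab_days, wet_day_min_hours = 1,
                                min_run_days = 7) {
  segment_one <- function(df, key) {
    df <- arrange(df, .data$date)
    if (nrow(df) > 1 && any(diff(as.integer(df$date)) != 1)) {
      abort(paste(
        "gap in dates: habitability record must be consecutive;",
        "fill missing days or split the record before segmenting."
      ))
    }
    state <- merge_short_runs(df$wet_hours >= wet_day_min_hours,
                              min_run_days)
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    tibble(
      start_date = df$date[starts],
      end_date = df$date[ends],
      kind = ifelse(r$values, "wet", "dry"),
      length_days = r$lengths
    )
  }
  hab_days |>
    group_by(across(any_of(c("site", "position", "replicate")))) |>
    group_modify(segment_one) |>
    ungroup()
}
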