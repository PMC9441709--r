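# Energy-based noise metrics. All averaging of decibel levels happens on
# the energy scale (10^(L/10)); arithmetic dBA means appear nowhere in this
# module. Clock conventions (Ghana Standards Authority day definition):
#   day   06:00-21:59 (16 h)     night 22:00-05:59 (8 h)
# and for Lden: day 06:00-18:59 (13 h), evening 19:00-21:59 (3 h, +5 dBA),
# night 22:00-05:59 (8 h, +10 dBA).

day_hours <- function() 6:21
night_hours <- function() c(22, 23, 0:5)
den_day_hours <- function() 6:18
den_evening_hours <- function() 19:21

db_to_energy <- function(l) 10^(l / 10)
energy_to_db <- function(e) 10 * log10(e)

#' Equivalent continuous sound level (LAeq)
#'
#' The constant level carrying the same acoustic energy as the fluctuating
#' signal: `10 log10( sum(w_i 10^(L_i/10)) / sum(w_i) )`. Unweighted input
#' uses equal weights.
#'
#' @param levels Numeric vector of levels (dBA).
#' @param weights Optional positive durations, same length as `levels`.
#' @return LAeq in dBA (scalar).
#' @examples
#' laeq(c(50, 60)) # 57.40 dBA, well above the arithmetic mean
#' @export
laeq <- function(levels, weights = NULL) {
  if (length(levels) == 0) stop("laeq: empty input", call. = FALSE)
  if (any(!is.finite(levels))) stop("laeq: levels must be finite", call. = FALSE)
  if (is.null(weights)) {
    return(energy_to_db(mean(db_to_energy(levels))))
  }
  if (length(weights) != length(levels) || any(weights <= 0)) {
    stop("laeq: weights must be positive and match levels", call. = FALSE)
  }
  energy_to_db(sum(weights * db_to_energy(levels)) / sum(weights))
}

# hour-of-day and date from POSIXct without strftime (Ghana is UTC with no
# daylight saving, so integer arithmetic on the epoch is exact)
ts_hour <- function(ts) as.integer((as.numeric(ts) %/% 3600) %% 24)
ts_date <- function(ts) as.Date(floor(as.numeric(ts) / 86400), origin = "1970-01-01")

#' Aggregate minute levels to hourly LAeq
#'
#' Energy-averages each site's minutes within clock hours. Hours with no
#' minutes are omitted (not imputed); `n_minutes` records completeness.
#'
#' @param minutes Tibble with `site_id`, `timestamp` (POSIXct),
#'   `laeq_1min_dba`.
#' @return Tibble with `site_id`, `date`, `hour` (0-23), `laeq_1hr_dba`,
#'   `n_minutes`.
#' @export
hourly_levels <- function(minutes) {
  stopifnot(all(c("site_id", "timestamp", "laeq_1min_dba") %in% names(minutes)))
  if (nrow(minutes) == 0) {
    return(tibble::tibble(site_id = character(), date = as.Date(character()),
                          hour = integer(), laeq_1hr_dba = numeric(),
                          n_minutes = integer()))
  }
  minutes |>
    dplyr::mutate(date = ts_date(.data$timestamp),
                  hour = ts_hour(.data$timestamp),
                  energy = db_to_energy(.data$laeq_1min_dba)) |>
    dplyr::summarise(laeq_1hr_dba = energy_to_db(mean(.data$energy)),
                     n_minutes = dplyr::n(),
                     .by = c("site_id", "date", "hour")) |>
    dplyr::arrange(.data$site_id, .data$date, .data$hour)
}

#' Long-term hourly profile per site
#'
#' The annual-average LAeq for each hour of the day: the energy mean of that
#' hour's daily LAeq values across all measured days (equivalent-continuous
#' semantics, not an arithmetic dBA mean).
#'
#' @param hourly Output of [hourly_levels()].
#' @return Tibble `site_id`, `hour`, `laeq_1hr_dba`, `n_days`.
#' @export
hourly_profile <- function(hourly) {
  hourly |>
    dplyr::summarise(
      laeq_1hr_dba = energy_to_db(mean(db_to_energy(.data$laeq_1hr_dba))),
      n_days = dplyr::n(),
      .by = c("site_id", "hour")
    ) |>
    dplyr::arrange(.data$site_id, .data$hour)
}

#' Aggregate a 24-hour profile into noise metrics
#'
#' Computes LAeq_24hr, L_day (06:00-21:59), L_night (22:00-05:59) and
#' L_den. L_den penalizes evening energy (19:00-21:59) by +5 dBA and night
#' energy (22:00-05:59) by +10 dBA before the 24 h energy average, so
#' `L_den >= LAeq_24hr` whenever the evening/night hours carry any energy.
#' A flat profile at X dBA gives `L_den = X + 6.305`.
#'
#' @param levels_by_hour Numeric length 24: long-term average LAeq_1hr for
#'   hours 0 through 23. `-Inf` marks an hour with no energy.
#' @return One-row tibble: `laeq_24hr`, `l_den`, `l_day`, `l_night` (dBA).
#' @export
period_metrics <- function(levels_by_hour) {
  if (length(levels_by_hour) != 24) {
    stop("period_metrics: need exactly 24 hourly values", call. = FALSE)
  }
  m <- period_metrics_matrix(matrix(levels_by_hour, nrow = 1))
  tibble::as_tibble(m)
}

# Vectorised core: `mat` is n x 24 (columns = hours 0..23). Returns a data
# frame with one row per input row. -Inf levels contribute zero energy.
period_metrics_matrix <- function(mat) {
  stopifnot(ncol(mat) == 24)
  e <- 10^(mat / 10)
  hours <- 0:23
  day <- hours %in% day_hours()
  night <- hours %in% night_hours()
  dday <- hours %in% den_day_hours()
  deve <- hours %in% den_evening_hours()
  laeq_24hr <- energy_to_db(rowMeans(e))
  l_day <- energy_to_db(rowMeans(e[, day, drop = FALSE]))
  l_night <- energy_to_db(rowMeans(e[, night, drop = FALSE]))
  den_e <- rowSums(e[, dday, drop = FALSE]) +
    rowSums(e[, deve, drop = FALSE]) * 10^0.5 +
    rowSums(e[, night, drop = FALSE]) * 10
  l_den <- energy_to_db(den_e / 24)
  data.frame(laeq_24hr = laeq_24hr, l_den = l_den,
             l_day = l_day, l_night = l_night)
}

#' Intermittency ratio of a minute-level series
#'
#' The percentage of a period's total sound energy contributed by event
#' minutes: minutes whose level meets or exceeds a threshold K set
#' `offset_c` dBA above the period's LAeq. High IR means an eventful
#' soundscape (sirens, horns, passing aircraft); low IR a steady drone.
#'
#' @param minutes Minute-level tibble (may contain several sites).
#' @param period `"day"` (06:00-21:59) or `"night"` (22:00-05:59).
#' @param offset_c Threshold offset above the period LAeq (dBA, default 3).
#' @return Tibble `site_id`, `period`, `ir_pct` (0-100), `laeq_period`,
#'   `threshold_dba`.
#' @export
intermittency_ratio <- function(minutes, period = c("day", "night"),
                                offset_c = 3) {
  period <- match.arg(period)
  hrs <- if (period == "day") day_hours() else night_hours()
  sub <- minutes |>
    dplyr::mutate(hour = ts_hour(.data$timestamp)) |>
    dplyr::filter(.data$hour %in% hrs)
  if (nrow(sub) == 0) {
    stop("intermittency_ratio: no minutes in the ", period, " period",
         call. = FALSE)
  }
  sub |>
    dplyr::summarise(
      laeq_period = energy_to_db(mean(db_to_energy(.data$laeq_1min_dba))),
      ir_pct = {
        e <- db_to_energy(.data$laeq_1min_dba)
        k <- energy_to_db(mean(e)) + offset_c
        min(max(100 * sum(e[.data$laeq_1min_dba >= k]) / sum(e), 0), 100)
      },
      .by = "site_id"
    ) |>
    dplyr::mutate(period = period,
                  threshold_dba = .data$laeq_period + offset_c) |>
    dplyr::select("site_id", "period", "ir_pct", "laeq_period",
                  "threshold_dba")
}

#' Per-site noise metrics table
#'
#' Convenience wrapper: minute logs in, one row per site out with the four
#' long-term metrics and day/night intermittency ratios.
#'
#' @param minutes Minute-level tibble.
#' @param offset_c IR threshold offset (dBA).
#' @return Tibble `site_id`, `laeq_24hr`, `l_den`, `l_day`, `l_night`,
#'   `ir_day`, `ir_night`.
#' @export
site_noise_metrics <- function(minutes, offset_c = 3) {
  prof <- hourly_profile(hourly_levels(minutes))
  met <- prof |>
    tidyr::complete(.data$site_id, hour = 0:23,
                    fill = list(laeq_1hr_dba = -Inf)) |>
    dplyr::arrange(.data$site_id, .data$hour) |>
    dplyr::summarise(
      res = list(period_metrics(.data$laeq_1hr_dba)),
      .by = "site_id"
    ) |>
    tidyr::unnest("res")
  ir_d <- intermittency_ratio(minutes, "day", offset_c) |>
    dplyr::select("site_id", ir_day = "ir_pct")
  ir_n <- intermittency_ratio(minutes, "night", offset_c) |>
    dplyr::select("site_id", ir_night = "ir_pct")
  met |>
    dplyr::left_join(ir_d, by = "site_id") |>
    dplyr::left_join(ir_n, by = "site_id")
}
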