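# Molar constants exactly as used in the quotient definitions.
.molar <- list(co2 = 44, o2 = 32, ammonia = 18, seconds_per_hour = 3600)

#' Convert a concentration slope to a mass-specific rate
#'
#' The chamber rate equation:
#' `rate = sign * slope * (RespirVol - FishVol) * 3600 / FishWeight`,
#' with `sign = -1` for O2 (the chamber is depleted) and `+1` for CO2 and
#' NH3-N (which accumulate).  For ammonia, pass the tank water volume via
#' `volume` since samples are drawn from the holding tank.
#'
#' @param slope Concentration slope, mg/L/s (signed as measured).
#' @param chamber A [chamber_spec()].
#' @param fish A [fish_lot()].
#' @param channel `"O2"`, `"CO2"` or `"NH3N"`.
#' @param volume Water volume containing the fish, L; defaults to the
#'   sealed chamber volume (use `chamber$tank_volume` for ammonia).
#'
#' @return Mass-specific rate, mg/kg/h.
#' @examples
#' rate_from_slope(-5e-4, chamber_spec(), fish_lot(), "O2")  # 1436.4
#' @export
rate_from_slope <- function(slope, chamber, fish, channel,
                            volume = chamber$respir_vol) {
  channel <- match_channel(channel)
  net_vol <- volume - fish$total_volume
  if (net_vol <= 0) stop("water volume must exceed fish volume",
                         call. = FALSE)
  if (fish$total_weight <= 0) stop("fish weight must be positive",
                                   call. = FALSE)
  sgn <- if (channel == "O2") -1 else 1
  sgn * slope * net_vol * .molar$seconds_per_hour / fish$total_weight
}

#' Respiratory quotient
#'
#' Molar ratio of CO2 excreted to O2 consumed:
#' `RQ = (VCO2 / 44) / (VO2 / 32)`.
#'
#' @param vco2,vo2 Mass-specific rates, mg/kg/h.
#' @return Dimensionless RQ; `NA` where `vo2` is zero or missing.
#' @examples
#' respiratory_quotient(44, 32)  # 1
#' @export
respiratory_quotient <- function(vco2, vo2) {
  out <- (vco2 / .molar$co2) / (vo2 / .molar$o2)
  out[!is.na(vo2) & vo2 == 0] <- NA_real_
  out
}

#' Ammonia quotient
#'
#' Molar ratio of ammonia-nitrogen excreted to O2 consumed:
#' `AQ = (VN / 18) / (VO2 / 32)` (divisor 18, the ammonium molar mass).
#'
#' @param vn,vo2 Mass-specific rates, mg/kg/h.
#' @return Dimensionless AQ; `NA` where `vo2` is zero or missing.
#' @examples
#' ammonia_quotient(18, 32)  # 1
#' @export
ammonia_quotient <- function(vn, vo2) {
  out <- (vn / .molar$ammonia) / (vo2 / .molar$o2)
  out[!is.na(vo2) & vo2 == 0] <- NA_real_
  out
}

#' Ammonia excretion rates from bi-hourly tank samples
#'
#' Two-point slopes between consecutive tank samples, fed through the
#' rate equation with the tank water volume.  Each rate is labelled at
#' the midpoint of its sampling interval.
#'
#' @param times Sample times, s (strictly increasing).
#' @param values Ammonia-N concentrations, mg/L.
#' @param chamber A [chamber_spec()] (supplies `tank_volume`).
#' @param fish A [fish_lot()].
#'
#' @return data.frame with `time_h` (interval midpoints, h) and `vn`
#'   (mg/kg/h).
#' @export
ammonia_rate_series <- function(times, values, chamber, fish) {
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (length(times) < 2) stop("need at least two samples", call. = FALSE)
  slope <- diff(values) / diff(times)
  mid <- (times[-1] + times[-length(times)]) / 2
  data.frame(
    time_h = mid / 3600,
    vn = rate_from_slope(slope, chamber, fish, "NH3N",
                         volume = chamber$tank_volume)
  )
}

#' Aggregate cycle-level rates to the reporting grids
#'
#' Averages cycle-level VO2/VCO2 into hourly means (hour `h` covers
#' `[h, h+1)`, labelled `h + 0.5`), computes RQ from the hourly means,
#' and pairs each bi-hourly ammonia rate with the mean VO2 of its 2-h
#' window to give AQ.  Hours whose cycles are all missing propagate as
#' missing hours.
#'
#' @param vo2 data.frame `time_h`, `rate` of cycle-level oxygen rates.
#' @param vco2 data.frame `time_h`, `rate` of cycle-level CO2 rates.
#' @param vn data.frame `time_h`, `vn` from [ammonia_rate_series()]
#'   (or NULL).
#' @param hours Total duration, h.
#'
#' @return List with `hourly` (`time_h`, `vo2`, `vco2`, `rq`) and
#'   `bihourly` (`time_h`, `vn`, `aq`; NULL when `vn` is NULL).
#' @export
hourly_aggregate <- function(vo2, vco2, vn = NULL, hours = NULL) {
  if (nrow(vo2) == 0) stop("empty input", call. = FALSE)
  if (is.null(hours)) hours <- ceiling(max(vo2$time_h, na.rm = TRUE))
  hour_mean <- function(df) {
    h <- factor(floor(df$time_h), levels = 0:(hours - 1))
    means <- tapply(df$rate, h, mean, na.rm = TRUE)
    as.numeric(ifelse(is.nan(means), NA, means))
  }
  hourly <- data.frame(
    time_h = seq_len(hours) - 0.5,
    vo2 = hour_mean(vo2),
    vco2 = hour_mean(vco2)
  )
  hourly$rq <- respiratory_quotient(hourly$vco2, hourly$vo2)
  bihourly <- NULL
  if (!is.null(vn)) {
    win <- floor(vn$time_h / 2)
    vo2_win <- vapply(win, function(w) {
      sel <- hourly$time_h >= 2 * w & hourly$time_h < 2 * (w + 1)
      mean(hourly$vo2[sel], na.rm = TRUE)
    }, numeric(1))
    bihourly <- data.frame(time_h = vn$time_h, vn = vn$vn,
                           aq = ammonia_quotient(vn$vn, vo2_win))
  }
  list(hourly = hourly, bihourly = bihourly)
}

#' Run the full rate pipeline on a trace set
#'
#' For every tank: cycle slopes from the O2 and CO2 traces
#' ([cycle_slope_series()]), conversion to mass-specific rates
#' ([rate_from_slope()]), bi-hourly ammonia rates
#' ([ammonia_rate_series()]) and aggregation to the hourly/bi-hourly
#' reporting grids with quotients ([hourly_aggregate()]).
#'
#' @param ts A `trace_set` from [generate_dataset()] or [read_traces()].
#' @param n Slope stencil size (3, 5 or 7).
#'
#' @return An object of class `rate_series`: list with `hourly`
#'   (`tank_id`, `time_h`, `vo2`, `vco2`, `rq`), `bihourly` (`tank_id`,
#'   `time_h`, `vn`, `aq`) and `meta` (copied from the trace set plus
#'   `n`).
#' @examples
#' ts <- generate_dataset("control", days = 1, tanks = 1, seed = 1)
#' rs <- estimate_rates(ts)
#' head(rs$hourly)
#' @export
estimate_rates <- function(ts, n = 7) {
  stopifnot(inherits(ts, "trace_set"))
  chamber <- ts$meta$chamber
  fish <- ts$meta$fish
  hours <- ts$meta$days * 24
  tanks <- unique(ts$traces$tank_id)
  hourly <- list()
  bihourly <- list()
  for (tk in tanks) {
    tank <- ts$traces[ts$traces$tank_id == tk, ]
    cyc_rate <- function(channel) {
      tr <- tank[tank$channel == channel, ]
      sl <- cycle_slope_series(tr$time_s, tr$conc, chamber, n)
      data.frame(time_h = sl$mid_time_s / 3600,
                 rate = rate_from_slope(sl$slope, chamber, fish, channel))
    }
    vn_tr <- tank[tank$channel == "NH3N", ]
    vn <- if (nrow(vn_tr) >= 2) {
      ammonia_rate_series(vn_tr$time_s, vn_tr$conc, chamber, fish)
    } else NULL
    agg <- hourly_aggregate(cyc_rate("O2"), cyc_rate("CO2"), vn, hours)
    agg$hourly <- cbind(tank_id = tk, agg$hourly)
    hourly[[tk]] <- agg$hourly
    if (!is.null(agg$bihourly)) {
      bihourly[[tk]] <- cbind(tank_id = tk, agg$bihourly)
    }
  }
  structure(
    list(hourly = do.call(rbind, c(hourly, list(make.row.names = FALSE))),
         bihourly = if (length(bihourly)) {
           do.call(rbind, c(bihourly, list(make.row.names = FALSE)))
         },
         meta = c(ts$meta[setdiff(names(ts$meta), "profile")],
                  list(n = n, group = ts$meta$group))),
    class = "rate_series"
  )
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf(
    "<rate_series> group '%s': %d hourly and %d bi-hourly records\n",
    x$meta$group, nrow(x$hourly),
    if (is.null(x$bihourly)) 0L else nrow(x$bihourly)))
  invisible(x)
}

#' Seven-day (or full-duration) group means of the five parameters
#'
#' Tank means first (the tank is the unit of replication), then the
#' across-tank mean and SD.
#'
#' @param rs A `rate_series` from [estimate_rates()].
#' @return data.frame with one row per parameter (`OR`, `CR`, `AE`,
#'   `RQ`, `AQ`): `mean`, `sd`, `n_tanks`.
#' @export
group_means <- function(rs) {
  tank_stat <- function(df, col) {
    tapply(df[[col]], df$tank_id, mean, na.rm = TRUE)
  }
  per_tank <- list(
    OR = tank_stat(rs$hourly, "vo2"),
    CR = tank_stat(rs$hourly, "vco2"),
    AE = tank_stat(rs$bihourly, "vn"),
    RQ = tank_stat(rs$hourly, "rq"),
    AQ = tank_stat(rs$bihourly, "aq")
  )
  data.frame(
    parameter = names(per_tank),
    mean = vapply(per_tank, mean, numeric(1)),
    sd = vapply(per_tank, stats::sd, numeric(1)),
    n_tanks = vapply(per_tank, length, numeric(1)),
    row.names = NULL
  )
}
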