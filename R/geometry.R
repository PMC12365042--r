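#' Describe the fish held in one chamber
#'
#' A "lot" is the group of fish sealed together in one respirometry
#' chamber.  Rates are tank-level: the chamber equations use the combined
#' mass and displacement volume of the lot, and the tank mean is the unit
#' of replication downstream.
#'
#' @param n_fish Number of fish in the chamber (>= 1).
#' @param mean_weight Mean wet weight per fish, kg.
#' @param mean_volume Mean displacement volume per fish, L.
#' @param body_length Mean body length, cm (metadata only).
#'
#' @return An object of class `fish_lot` with elements `n_fish`,
#'   `mean_weight`, `mean_volume`, `body_length`, and the derived totals
#'   `total_weight` (kg, the FishWeight of the rate equations) and
#'   `total_volume` (L, the FishVol).
#' @examples
#' fish_lot()                      # five juvenile zebrafish
#' fish_lot(1, mean_weight = 3e-4) # a single small fish
#' @export
fish_lot <- function(n_fish = 5, mean_weight = 5e-4, mean_volume = 1e-3,
                     body_length = 3.5) {
  stopifnot(n_fish >= 1, n_fish == round(n_fish))
  if (!(mean_weight > 0) || !(mean_volume > 0)) {
    stop("fish weight and volume must be strictly positive", call. = FALSE)
  }
  structure(
    list(
      n_fish = as.integer(n_fish),
      mean_weight = mean_weight,
      mean_volume = mean_volume,
      body_length = body_length,
      total_weight = n_fish * mean_weight,
      total_volume = n_fish * mean_volume
    ),
    class = "fish_lot"
  )
}

#' @export
print.fish_lot <- function(x, ...) {
  cat(sprintf("<fish_lot> %d fish, %.3f g total, %.3f mL displacement\n",
              x$n_fish, 1000 * x$total_weight, 1000 * x$total_volume))
  invisible(x)
}

#' Respirometry chamber and sampling geometry
#'
#' The chamber runs intermittent-flow cycles: each `cycle_length` seconds
#' the chamber is flushed and then sealed, and concentrations recorded
#' every `sensor_interval` seconds over the final `measure_window` seconds
#' supply one slope estimate per cycle.  Ammonia is sampled from the
#' holding tank (volume `tank_volume`), not the sealed chamber.
#'
#' @param respir_vol Sealed chamber volume, L.
#' @param cycle_length Full flush+measure cycle, s.
#' @param measure_window Sealed measurement window at the end of each
#'   cycle, s; must not exceed `cycle_length` and must be a multiple of
#'   `sensor_interval`.
#' @param sensor_interval Spacing of raw sensor readings, s.
#' @param tank_volume Holding-tank water volume used for ammonia
#'   accumulation, L.
#' @param fish Optional [fish_lot()] used to check that the chamber is
#'   larger than the fish it holds.
#'
#' @return An object of class `chamber_spec`.
#' @examples
#' chamber_spec()
#' @export
chamber_spec <- function(respir_vol = 2, cycle_length = 450,
                         measure_window = 300, sensor_interval = 15,
                         tank_volume = 5, fish = NULL) {
  stopifnot(respir_vol > 0, cycle_length > 0, tank_volume > 0)
  if (measure_window > cycle_length) {
    stop("measure_window must not exceed cycle_length", call. = FALSE)
  }
  if (measure_window %% sensor_interval != 0) {
    stop("sensor_interval must divide measure_window", call. = FALSE)
  }
  if (!is.null(fish) && respir_vol <= fish$total_volume) {
    stop("chamber volume must exceed the fish volume", call. = FALSE)
  }
  structure(
    list(
      respir_vol = respir_vol,
      cycle_length = cycle_length,
      measure_window = measure_window,
      sensor_interval = sensor_interval,
      tank_volume = tank_volume
    ),
    class = "chamber_spec"
  )
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf(
    "<chamber_spec> %.2f L chamber, %g s cycle (last %g s measured every %g s), %.1f L tank\n",
    x$respir_vol, x$cycle_length, x$measure_window, x$sensor_interval,
    x$tank_volume))
  invisible(x)
}

#' Photoperiod schedule
#'
#' Defaults encode a 16 h light : 8 h dark cycle with lights on at 04:00
#' and off at 20:00.  Clock times are decimal hours from 0 up to 24.
#'
#' @param lights_on Clock hour at which photophase starts.
#' @param lights_off Clock hour at which scotophase starts.
#' @param cycle_length Length of the full cycle, h.
#'
#' @return An object of class `photoperiod_schedule` with a derived
#'   `light_fraction`.
#' @examples
#' sched <- photoperiod_schedule()
#' sched$light_fraction  # 16/24
#' @export
photoperiod_schedule <- function(lights_on = 4, lights_off = 20,
                                 cycle_length = 24) {
  stopifnot(cycle_length > 0)
  if (lights_on == lights_off) {
    stop("lights_on and lights_off must differ", call. = FALSE)
  }
  light <- (lights_off - lights_on) %% cycle_length
  structure(
    list(
      lights_on = lights_on,
      lights_off = lights_off,
      cycle_length = cycle_length,
      light_fraction = light / cycle_length
    ),
    class = "photoperiod_schedule"
  )
}

#' @export
print.photoperiod_schedule <- function(x, ...) {
  cat(sprintf(
    "<photoperiod_schedule> %gL:%gD, lights on %05.2f / off %05.2f\n",
    x$light_fraction * x$cycle_length,
    (1 - x$light_fraction) * x$cycle_length, x$lights_on, x$lights_off))
  invisible(x)
}

# Channels recognised throughout the package.
.channels <- c("O2", "CO2", "NH3N")

match_channel <- function(channel) {
  match.arg(channel, .channels)
}
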