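# Run code with a private, seeded RNG stream, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# mg/L per second slope implied by a mass-specific rate in an effective
# water volume (chamber minus fish, or tank minus fish for ammonia).
slope_from_rate <- function(rate, effective_vol, fish_weight) {
  rate * fish_weight / (effective_vol * 3600)
}

#' Simulate sensor readings for one sealed measurement cycle
#'
#' Generates the concentration readings of a single intermittent-flow
#' cycle: readings every `sensor_interval` seconds across the final
#' `measure_window` seconds of the cycle, starting from `start_conc`
#' (the post-flush ambient level).  The noiseless slope is the inverse of
#' the chamber rate equation: `rate * FishWeight / ((RespirVol - FishVol)
#' * 3600)`, negative for O2 (depletion) and positive for CO2
#' (accumulation).  Gaussian sensor noise is added per reading.
#'
#' @param rate True mass-specific rate, mg/kg/h (may be a vector giving
#'   the rate at each reading time, for slowly varying rates).
#' @param chamber A [chamber_spec()].
#' @param fish A [fish_lot()].
#' @param start_conc Concentration at the first reading, mg/L.
#' @param channel `"O2"` or `"CO2"`.
#' @param noise_sd Gaussian noise SD per reading, mg/L.
#' @param cycle_start Cycle start time, s since experiment start.
#'
#' @return A data.frame with columns `time_s` and `conc`.
#' @examples
#' cyc <- synth_cycle(1436.4, chamber_spec(), fish_lot(), 8, "O2",
#'                    noise_sd = 0)
#' head(cyc)
#' @export
synth_cycle <- function(rate, chamber, fish, start_conc, channel,
                        noise_sd = 0, cycle_start = 0) {
  channel <- match.arg(channel, c("O2", "CO2"))
  stopifnot(all(rate >= 0), start_conc > 0)
  offs <- seq(chamber$cycle_length - chamber$measure_window,
              chamber$cycle_length - chamber$sensor_interval,
              by = chamber$sensor_interval)
  n <- length(offs)
  sgn <- if (channel == "O2") -1 else 1
  slope <- slope_from_rate(rate, chamber$respir_vol - fish$total_volume,
                           fish$total_weight)
  slope <- rep_len(slope, n)
  # trapezoid accumulation of the (possibly time-varying) slope
  inc <- c(0, (slope[-n] + slope[-1]) / 2 * chamber$sensor_interval)
  conc <- start_conc + sgn * cumsum(inc)
  if (any(conc <= 0)) {
    stop("concentration would become non-positive within the cycle; ",
         "rate or geometry is unphysical", call. = FALSE)
  }
  if (noise_sd > 0) conc <- conc + stats::rnorm(n, 0, noise_sd)
  data.frame(time_s = cycle_start + offs, conc = conc)
}

#' Simulate bi-hourly tank ammonia-nitrogen samples
#'
#' Ammonia-nitrogen accumulates in the holding tank (no flush) at the
#' rate implied by inverting the ammonia rate equation with the tank
#' water volume in the chamber-volume slot.  Samples are drawn every two
#' hours with Gaussian measurement noise.
#'
#' @param profile A [treatment_profile()].
#' @param fish A [fish_lot()].
#' @param chamber A [chamber_spec()] (supplies `tank_volume`).
#' @param days Duration, days.
#' @param schedule A [photoperiod_schedule()].
#' @param start_clock Clock hour at `t = 0`.
#' @param start_conc Ambient ammonia-N at `t = 0`, mg/L.
#' @param tank_effect Multiplier on the true rate for this tank.
#' @param noise_sd Noise SD per sample, mg/L; defaults to the profile's.
#'
#' @return A data.frame with columns `time_s` and `conc` on a bi-hourly
#'   grid (including t = 0).
#' @export
synth_ammonia_samples <- function(profile, fish, chamber, days = 7,
                                  schedule = photoperiod_schedule(),
                                  start_clock = 8, start_conc = 0.1,
                                  tank_effect = 1, noise_sd = NULL) {
  stopifnot(days > 0)
  if (is.null(noise_sd)) noise_sd <- profile$noise_sd[["NH3N"]]
  hours <- days * 24
  dt <- 0.01
  grid <- seq(0, hours, by = dt)
  rate <- tank_effect * true_rate(grid, profile, schedule, "NH3N",
                                  start_clock)
  # mg/L accumulated per hour in the tank water surrounding the fish
  dconc <- rate * fish$total_weight /
    (chamber$tank_volume - fish$total_volume)
  n <- length(grid)
  cum <- c(0, cumsum((dconc[-n] + dconc[-1]) / 2 * dt))
  sample_h <- seq(0, hours, by = 2)
  idx <- round(sample_h / dt) + 1
  conc <- start_conc + cum[idx]
  if (noise_sd > 0) conc <- conc + stats::rnorm(length(conc), 0, noise_sd)
  data.frame(time_s = sample_h * 3600, conc = conc)
}

# All O2/CO2 cycles of one tank, vectorised over cycles.
simulate_gas_channel <- function(profile, fish, chamber, schedule, channel,
                                 days, start_clock, start_conc,
                                 tank_effect) {
  n_cycles <- floor(days * 24 * 3600 / chamber$cycle_length)
  offs <- seq(chamber$cycle_length - chamber$measure_window,
              chamber$cycle_length - chamber$sensor_interval,
              by = chamber$sensor_interval)
  k <- length(offs)
  starts <- (seq_len(n_cycles) - 1) * chamber$cycle_length
  times <- outer(starts, offs, "+")                     # cycles x readings
  rate <- tank_effect *
    true_rate(as.vector(times) / 3600, profile, schedule, channel,
              start_clock)
  sgn <- if (channel == "O2") -1 else 1
  slope <- matrix(
    slope_from_rate(rate, chamber$respir_vol - fish$total_volume,
                    fish$total_weight),
    nrow = n_cycles)
  inc <- (slope[, -k, drop = FALSE] + slope[, -1, drop = FALSE]) / 2 *
    chamber$sensor_interval
  tri <- upper.tri(diag(k - 1), diag = TRUE) * 1  # row-wise cumsum
  conc <- start_conc + sgn * cbind(0, inc %*% tri)
  if (any(conc <= 0)) {
    stop("concentration would become non-positive within a cycle; ",
         "rate or geometry is unphysical", call. = FALSE)
  }
  sd <- profile$noise_sd[[channel]]
  if (sd > 0) conc <- conc + stats::rnorm(length(conc), 0, sd)
  data.frame(time_s = as.vector(t(times)), conc = as.vector(t(conc)))
}

#' Generate a full synthetic respirometry dataset
#'
#' Simulates `tanks` replicate tanks for one experimental group over
#' `days` days: per-tank O2 and CO2 chamber cycle traces plus bi-hourly
#' tank ammonia-N samples, with per-tank lognormal rate multipliers and
#' per-reading sensor noise.  Reproducible given `seed`.  The true rate
#' trajectories are retained in the `truth` element for recovery tests.
#'
#' @param scenario `"control"`, `"phe"`, `"pyr"`, or a custom
#'   [treatment_profile()].
#' @param days Duration, days (>= 1).
#' @param tanks Number of replicate tanks.
#' @param seed Integer seed; every random draw flows from it.
#' @param fish,chamber,schedule Geometry and photoperiod; defaults match
#'   the study (five juvenile zebrafish, 2 L chamber, 450 s cycle,
#'   16L:8D).
#' @param start_clock Clock hour at `t = 0` (study starts 08:00).
#' @param start_conc Named ambient concentrations at flush, mg/L.
#'
#' @return An object of class `trace_set`: list with `traces` (long
#'   data.frame `time_s`, `tank_id`, `channel`, `conc`), `meta`
#'   (geometry, schedule, group, seed, start clock) and `truth`
#'   (calibration targets, per-tank effects, per-tank true duration
#'   means).
#' @examples
#' ts <- generate_dataset("control", days = 1, tanks = 1, seed = 1)
#' head(ts$traces)
#' @export
generate_dataset <- function(scenario = "control", days = 7, tanks = 3,
                             seed = 1, fish = fish_lot(),
                             chamber = chamber_spec(),
                             schedule = photoperiod_schedule(),
                             start_clock = 8,
                             start_conc = c(O2 = 8, CO2 = 0.6,
                                            NH3N = 0.1)) {
  stopifnot(days >= 1, tanks >= 1)
  profile <- if (inherits(scenario, "treatment_profile")) {
    scenario
  } else {
    preset_profile(scenario, schedule, start_clock)
  }
  hours <- days * 24
  with_seed(seed, {
    tank_effects <- stats::rlnorm(tanks, 0, profile$tank_effect_sd)
    traces <- vector("list", tanks * 3)
    truth_means <- matrix(NA_real_, tanks, 3,
                          dimnames = list(NULL, .channels))
    i <- 0
    for (tk in seq_len(tanks)) {
      id <- sprintf("tank%d", tk)
      for (ch in c("O2", "CO2")) {
        dat <- simulate_gas_channel(profile, fish, chamber, schedule, ch,
                                    days, start_clock,
                                    start_conc[[ch]], tank_effects[tk])
        i <- i + 1
        traces[[i]] <- data.frame(time_s = dat$time_s, tank_id = id,
                                  channel = ch, conc = dat$conc)
      }
      amm <- synth_ammonia_samples(profile, fish, chamber, days, schedule,
                                   start_clock, start_conc[["NH3N"]],
                                   tank_effects[tk])
      i <- i + 1
      traces[[i]] <- data.frame(time_s = amm$time_s, tank_id = id,
                                channel = "NH3N", conc = amm$conc)
      truth_means[tk, ] <- tank_effects[tk] * vapply(.channels, function(ch) {
        profile$base[[ch]] *
          mean_rate_shape(profile, schedule, ch, hours, start_clock)
      }, numeric(1))
    }
    structure(
      list(
        traces = do.call(rbind, traces),
        meta = list(group = profile$group, days = days, tanks = tanks,
                    seed = seed, fish = fish, chamber = chamber,
                    schedule = schedule, start_clock = start_clock,
                    start_conc = start_conc, profile = profile),
        truth = list(targets = attr(profile, "targets"),
                     tank_effects = tank_effects,
                     tank_means = truth_means)
      ),
      class = "trace_set"
    )
  })
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf(
    "<trace_set> group '%s': %d tanks x %d days, %d readings (seed %s)\n",
    x$meta$group, x$meta$tanks, x$meta$days, nrow(x$traces),
    format(x$meta$seed)))
  invisible(x)
}
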