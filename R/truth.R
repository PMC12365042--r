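#' Smoothed square-wave diel signal
#'
#' Returns a periodic signal equal to +1 at mid-photophase and -1 at
#' mid-scotophase, with logistic transitions of about one hour at the
#' light switches.  Metabolic observations in diurnal fish plateau within
#' each phase rather than tracking a sinusoid, so a smoothed square wave
#' is used as the canonical diel shape.
#'
#' @param t Hours since experiment start (vectorised).
#' @param schedule A [photoperiod_schedule()].
#' @param start_clock Clock hour at `t = 0` (experiments start at 08:00).
#' @param transition Width parameter of the logistic edges, h; the
#'   10-90 percent transition takes about `4.4 * transition` hours.
#'
#' @return Numeric vector between -1 and 1.
#' @examples
#' diel_signal(c(4, 16))  # mid-photophase vs scotophase
#' @export
diel_signal <- function(t, schedule = photoperiod_schedule(),
                        start_clock = 8, transition = 0.25) {
  clock <- (start_clock + t) %% schedule$cycle_length
  on <- schedule$lights_on
  off <- schedule$lights_off
  gate <- function(c) {
    stats::plogis((c - on) / transition) - stats::plogis((c - off) / transition)
  }
  # periodic wrap so edges near midnight behave
  g <- gate(clock) + gate(clock - schedule$cycle_length) +
    gate(clock + schedule$cycle_length)
  2 * g - 1
}

# Exposure time-course multiplier for one channel.  O2 suppression under
# treatment is constant (absorbed into the calibrated base); CO2 shows a
# progressive late-stage decay; NH3-N ramps to an elevated plateau within
# the surge window.
timecourse_multiplier <- function(t, profile, channel) {
  channel <- match_channel(channel)
  if (channel == "CO2") {
    onset <- profile$cr_suppression[["onset_h"]]
    term <- profile$cr_suppression[["terminal"]]
    tau <- profile$cr_suppression[["tau_h"]]
    m <- rep(1, length(t))
    late <- t > onset
    if (term < 1 && any(late)) {
      m[late] <- term + (1 - term) * exp(-(t[late] - onset) / tau)
    }
    m
  } else if (channel == "NH3N") {
    dur <- profile$ae_surge[["duration_h"]]
    plateau <- profile$ae_surge[["plateau"]]
    if (plateau == 1 || dur <= 0) {
      rep(1, length(t))
    } else {
      1 + (plateau - 1) * pmin(t / dur, 1)
    }
  } else {
    rep(1, length(t))
  }
}

#' True underlying metabolic rate of a treatment profile
#'
#' The noiseless rate the simulator encodes:
#' `base * timecourse(t) * (1 + A * s(t))`, where `s(t)` is the smoothed
#' square-wave diel signal ([diel_signal()]), `A` the channel's diel
#' amplitude, and the time-course multiplier carries the exposure dynamics
#' (ammonia surge, late CO2 suppression; identically 1 for controls).
#'
#' @param t Hours since experiment start (vectorised).
#' @param profile A [treatment_profile()] or preset from
#'   [preset_profile()].
#' @param schedule A [photoperiod_schedule()].
#' @param channel One of `"O2"`, `"CO2"`, `"NH3N"`.
#' @param start_clock Clock hour at `t = 0`.
#'
#' @return True rate(s) in mg/kg/h.
#' @examples
#' pr <- preset_profile("control")
#' true_rate(c(4, 16), pr, channel = "O2")
#' @export
true_rate <- function(t, profile, schedule = photoperiod_schedule(),
                      channel = "O2", start_clock = 8) {
  stopifnot(all(t >= 0))
  channel <- match_channel(channel)
  base <- profile$base[[channel]]
  amp <- profile$diel_amplitude[[channel]]
  s <- diel_signal(t, schedule, start_clock, profile$diel_transition)
  base * timecourse_multiplier(t, profile, channel) * (1 + amp * s)
}

# Time average of timecourse(t) * (1 + A s(t)) over [0, hours], on a fine
# trapezoid grid.  Used to calibrate preset bases so the noiseless
# duration mean equals a target rate.
mean_rate_shape <- function(profile, schedule, channel, hours = 168,
                            start_clock = 8, dt = 0.005) {
  t <- seq(0, hours, by = dt)
  amp <- profile$diel_amplitude[[channel]]
  y <- timecourse_multiplier(t, profile, channel) *
    (1 + amp * diel_signal(t, schedule, start_clock, profile$diel_transition))
  w <- rep(1, length(t))
  w[c(1, length(t))] <- 0.5
  sum(w * y) / sum(w)
}
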