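#' Weighted finite-difference slope at a point
#'
#' Estimates the concentration slope (mg/L/s) at one reading as a
#' weighted average of `(n-1)/2` nested central differences.  The weights
#' fall linearly with the half-width of the difference: `{1}` for
#' `n = 3`, `{2, 1}` for `n = 5`, `{3, 2, 1}` for `n = 7` (innermost
#' difference weighted most), and the weighted sum is divided by the
#' weight total (1, 3 and 6 respectively) so the result stays a slope.
#' Central differences are exact for quadratics at the centre point, so
#' the estimator is unbiased through second order.
#'
#' @param values Concentrations, mg/L.
#' @param times Strictly increasing times, s.
#' @param center_index Index of the reading at which the slope is taken;
#'   must have `(n-1)/2` neighbours on each side.
#' @param n Stencil size: 3, 5 or 7.
#'
#' @return Slope in mg/L/s.
#' @examples
#' t <- 0:6
#' weighted_slope(2 + 0.5 * t, t, 4, n = 7)  # exactly 0.5
#' @export
weighted_slope <- function(values, times, center_index, n = 7) {
  if (!n %in% c(3, 5, 7)) stop("n must be 3, 5 or 7", call. = FALSE)
  k <- (n - 1L) / 2L
  m <- length(values)
  stopifnot(length(times) == m)
  if (center_index - k < 1 || center_index + k > m) {
    stop("center_index needs ", k, " neighbours on each side",
         call. = FALSE)
  }
  if (anyDuplicated(times)) stop("duplicate timestamps", call. = FALSE)
  j <- seq_len(k)
  hi <- center_index + j
  lo <- center_index - j
  diffs <- (values[hi] - values[lo]) / (times[hi] - times[lo])
  w <- rev(j)  # innermost difference gets the largest weight
  sum(w * diffs) / sum(w)
}

#' One weighted slope per intermittent-flow cycle
#'
#' Partitions a concentration series into consecutive cycles of
#' `chamber$cycle_length` seconds from `t = 0`, keeps the readings in the
#' final `chamber$measure_window` seconds of each cycle (the sealed
#' measurement phase), and evaluates [weighted_slope()] at the window's
#' central reading (ties broken toward the earlier reading).  The stencil
#' falls back from `n` to 5 then 3 where the window is short; cycles with
#' fewer than 3 usable readings are flagged missing rather than
#' fabricated.
#'
#' @param times Reading times, s since experiment start (strictly
#'   increasing).
#' @param values Concentrations, mg/L.
#' @param chamber A [chamber_spec()].
#' @param n Requested stencil size (3, 5 or 7).
#'
#' @return A data.frame with one row per cycle: `cycle_index` (0-based),
#'   `mid_time_s` (time of the centre reading; NA when missing), `slope`
#'   (mg/L/s, NA when missing), `n_used` and logical `ok`.
#' @examples
#' ch <- chamber_spec()
#' cyc <- synth_cycle(1436.4, ch, fish_lot(), 8, "O2", noise_sd = 0)
#' cycle_slope_series(cyc$time_s, cyc$conc, ch)
#' @export
cycle_slope_series <- function(times, values, chamber, n = 7) {
  stopifnot(length(times) == length(values))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (max(times) < chamber$cycle_length - chamber$sensor_interval) {
    stop("series must span at least one full cycle", call. = FALSE)
  }
  cyc <- floor(times / chamber$cycle_length)
  n_cycles <- max(cyc) + 1
  win_start <- chamber$cycle_length - chamber$measure_window
  # fast path: complete regular grid (one reading every sensor_interval
  # across every window), as produced by the simulator
  offs <- seq(win_start, chamber$cycle_length - chamber$sensor_interval,
              by = chamber$sensor_interval)
  k <- length(offs)
  if (length(times) == n_cycles * k && k >= 3) {
    expected <- rep((seq_len(n_cycles) - 1) * chamber$cycle_length,
                    each = k) + offs
    if (isTRUE(all.equal(times, expected, tolerance = 1e-9,
                         check.attributes = FALSE))) {
      v <- matrix(values, nrow = k)           # readings x cycles
      center <- floor((k + 1) / 2)
      side <- min(center - 1, k - center)
      n_used <- max(c(3, 5, 7)[c(3, 5, 7) <= min(n, 2 * side + 1)])
      kk <- (n_used - 1) / 2
      w <- rev(seq_len(kk))
      num <- 0
      for (j in seq_len(kk)) {
        num <- num + w[j] * (v[center + j, ] - v[center - j, ]) /
          (2 * j * chamber$sensor_interval)
      }
      return(data.frame(cycle_index = seq_len(n_cycles) - 1,
                        mid_time_s = expected[center + (seq_len(n_cycles) - 1) * k],
                        slope = num / sum(w),
                        n_used = n_used, ok = TRUE))
    }
  }
  out <- data.frame(cycle_index = seq_len(n_cycles) - 1,
                    mid_time_s = NA_real_, slope = NA_real_,
                    n_used = NA_integer_, ok = FALSE)
  idx_by_cycle <- split(seq_along(times), factor(cyc, levels = 0:(n_cycles - 1)))
  for (ci in seq_len(n_cycles)) {
    idx <- idx_by_cycle[[ci]]
    if (length(idx) == 0) next
    in_win <- times[idx] - (ci - 1) * chamber$cycle_length >= win_start
    idx <- idx[in_win]
    m <- length(idx)
    if (m < 3) next
    center <- floor((m + 1) / 2)  # tie toward the earlier reading
    side <- min(center - 1, m - center)
    n_used <- max(c(3, 5, 7)[c(3, 5, 7) <= min(n, 2 * side + 1)])
    out$slope[ci] <- weighted_slope(values[idx], times[idx], center, n_used)
    out$mid_time_s[ci] <- times[idx][center]
    out$n_used[ci] <- n_used
    out$ok[ci] <- TRUE
  }
  out
}
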