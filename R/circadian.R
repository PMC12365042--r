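#' Label times as photophase or scotophase
#'
#' Maps hours-since-start onto the wall clock and flags each time as
#' photophase iff its clock time lies in `[lights_on, lights_off)`.
#'
#' @param times_h Hours since experiment start.
#' @param schedule A [photoperiod_schedule()].
#' @param start_clock Clock hour at `t = 0`.
#'
#' @return Factor with levels `photophase`, `scotophase`.
#' @examples
#' label_phases(c(4, 14))  # clock 12:00 and 22:00 from an 08:00 start
#' @export
label_phases <- function(times_h, schedule = photoperiod_schedule(),
                         start_clock = 8) {
  clock <- (start_clock + times_h) %% schedule$cycle_length
  on <- schedule$lights_on %% schedule$cycle_length
  off <- schedule$lights_off %% schedule$cycle_length
  light <- if (on < off) clock >= on & clock < off else clock >= on | clock < off
  factor(ifelse(light, "photophase", "scotophase"),
         levels = c("photophase", "scotophase"))
}

#' Overall / light / dark mean and SD of a series
#'
#' @param values Numeric series (NA allowed).
#' @param phases Phase factor from [label_phases()], same length.
#' @return data.frame with rows `overall`, `photophase`, `scotophase`
#'   and columns `mean`, `sd`, `n`.
#' @export
phase_summary <- function(values, phases) {
  stopifnot(length(values) == length(phases))
  if (!all(c("photophase", "scotophase") %in% phases[!is.na(values)])) {
    stop("both phases must be represented", call. = FALSE)
  }
  one <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v[!is.na(v)]),
                       n = sum(!is.na(v)))
  out <- rbind(overall = one(values),
               photophase = one(values[phases == "photophase"]),
               scotophase = one(values[phases == "scotophase"]))
  data.frame(phase = rownames(out), out, row.names = NULL)
}

#' Autocorrelation of an hourly series for rhythm detection
#'
#' Detrends, mean-centres and computes the normalised autocorrelation at
#' integer-hour lags.  Missing values are handled pairwise: products
#' involving a missing point are dropped, with the denominator kept at
#' the full series length so that `acf[1] = 1` (lag 0) and
#' `|acf| <= 1` always hold.
#'
#' Two detrending modes are offered because exposure induces drifts that
#' mask the rhythm: `"linear"` removes a fitted straight line, which
#' handles monotone drift; `"baseline"` removes a centred moving average
#' over one full cycle (`baseline_window` points), which also absorbs
#' *non-linear* trends such as a saturating onset ramp -- a linear fit
#' leaves those as a low-frequency ACF tilt that can displace the diel
#' peak by an hour.
#'
#' @param values Hourly series.
#' @param max_lag Largest lag, h.
#' @param detrend `"linear"`, `"baseline"` or `"none"`.  `TRUE`/`FALSE`
#'   are accepted as aliases for `"linear"`/`"none"`.
#' @param baseline_window Width of the moving-average baseline, h (odd;
#'   default one circadian cycle plus one hour).
#'
#' @return An object of class `rhythm_acf`: list with `lags` (0:max_lag),
#'   `acf`, and `arrhythmic` (TRUE when the series has no variance).
#' @examples
#' x <- cos(2 * pi * (0:167) / 24)
#' r <- rhythm_acf(x)
#' r$acf[r$lags == 24]  # ~1
#' @export
rhythm_acf <- function(values, max_lag = 72, detrend = "linear",
                       baseline_window = 25) {
  if (is.logical(detrend)) detrend <- if (detrend) "linear" else "none"
  detrend <- match.arg(detrend, c("linear", "baseline", "none"))
  n <- length(values)
  if (n < 2 * max_lag) {
    stop("need at least 2 * max_lag points", call. = FALSE)
  }
  idx <- seq_len(n)
  z <- values
  ok <- !is.na(z)
  if (detrend == "linear" && sum(ok) > 2) {
    fit <- stats::lm.fit(cbind(1, idx[ok]), z[ok])
    z[ok] <- fit$residuals
  } else if (detrend == "baseline") {
    half <- floor(baseline_window / 2)
    base <- vapply(idx, function(i) {
      w <- max(1, i - half):min(n, i + half)
      mean(z[w], na.rm = TRUE)
    }, numeric(1))
    z[ok] <- z[ok] - base[ok]
  }
  z[ok] <- z[ok] - mean(z[ok])
  z0 <- ifelse(ok, z, 0)  # missing points contribute nothing
  c0 <- sum(z0^2) / n
  # zero variance up to numerical noise (constant or perfectly detrended)
  tol <- 1e-20 + 1e-16 * stats::var(values[ok])
  if (!any(ok) || is.na(c0) || c0 <= tol) {
    return(structure(list(lags = 0:max_lag,
                          acf = c(1, rep(NA_real_, max_lag)),
                          arrhythmic = TRUE),
                     class = "rhythm_acf"))
  }
  r <- vapply(0:max_lag, function(k) {
    a <- z0[seq_len(n - k)]
    b <- z0[seq_len(n - k) + k]
    sum(a * b) / n / c0
  }, numeric(1))
  structure(list(lags = 0:max_lag, acf = r, arrhythmic = FALSE),
            class = "rhythm_acf")
}

#' @export
plot.rhythm_acf <- function(x, ...) {
  graphics::plot(x$lags, x$acf, type = "h", xlab = "lag (h)",
                 ylab = "autocorrelation", ...)
  graphics::abline(h = 0, col = "grey")
  graphics::abline(v = 24, lty = 3, col = "red")
  invisible(x)
}

#' Dominant circadian period from an autocorrelation function
#'
#' The lag of the largest positive local maximum of the ACF within the
#' search band.  The band default of 18--30 h brackets the circadian
#' range while excluding the 12-h harmonic.
#'
#' @param acf_obj A `rhythm_acf` from [rhythm_acf()].
#' @param search_band Lag band, h.
#'
#' @return List with `period` (h, or NA) and `amplitude` (ACF value at
#'   the period) and `arrhythmic` flag.
#' @examples
#' dominant_period(rhythm_acf(cos(2 * pi * (0:167) / 24)))$period  # 24
#' @export
dominant_period <- function(acf_obj, search_band = c(18, 30)) {
  stopifnot(inherits(acf_obj, "rhythm_acf"))
  if (max(acf_obj$lags) < search_band[2]) {
    stop("ACF must be computed to at least the band upper bound",
         call. = FALSE)
  }
  if (acf_obj$arrhythmic) {
    return(list(period = NA_real_, amplitude = NA_real_,
                arrhythmic = TRUE))
  }
  r <- acf_obj$acf
  lag <- acf_obj$lags
  in_band <- which(lag >= search_band[1] & lag <= search_band[2])
  in_band <- in_band[in_band > 1 & in_band < length(r)]
  is_max <- r[in_band] > 0 &
    r[in_band] > r[in_band - 1] & r[in_band] >= r[in_band + 1]
  if (!any(is_max, na.rm = TRUE)) {
    return(list(period = NA_real_, amplitude = NA_real_,
                arrhythmic = TRUE))
  }
  cand <- in_band[which(is_max)]
  best <- cand[which.max(r[cand])]
  list(period = lag[best], amplitude = r[best], arrhythmic = FALSE)
}

#' Hourly tank-mean profile of the five metabolic parameters
#'
#' Averages the rate series across tanks onto a single hourly grid.
#' Bi-hourly AE/AQ values (labelled at interval midpoints) are linearly
#' interpolated onto the hourly grid.  This is the input to the rhythm
#' and SOM analyses.
#'
#' @param rs A `rate_series` from [estimate_rates()].
#' @return data.frame `time_h`, `phase`, `OR`, `CR`, `AE`, `RQ`, `AQ`.
#' @export
metabolic_profile <- function(rs) {
  hours <- rs$meta$days * 24
  grid <- seq_len(hours) - 0.5
  tmean <- function(df, col) {
    out <- tapply(df[[col]], df$time_h, mean, na.rm = TRUE)
    data.frame(time_h = as.numeric(names(out)), value = as.numeric(out))
  }
  on_grid <- function(df) {
    df$value[match(grid, df$time_h)]
  }
  interp <- function(df) {
    ok <- !is.na(df$value)
    stats::approx(df$time_h[ok], df$value[ok], xout = grid, rule = 2)$y
  }
  out <- data.frame(
    time_h = grid,
    phase = label_phases(grid, rs$meta$schedule, rs$meta$start_clock),
    OR = on_grid(tmean(rs$hourly, "vo2")),
    CR = on_grid(tmean(rs$hourly, "vco2")),
    AE = interp(tmean(rs$bihourly, "vn")),
    RQ = on_grid(tmean(rs$hourly, "rq")),
    AQ = interp(tmean(rs$bihourly, "aq"))
  )
  out
}

#' Rhythm summary for every metabolic parameter of a dataset
#'
#' @param rs A `rate_series`.
#' @param max_lag,search_band,detrend Passed to [rhythm_acf()] and
#'   [dominant_period()].  The default detrend is the moving-average
#'   baseline, which is robust to the non-linear exposure trends the
#'   treated groups carry.
#' @return data.frame with one row per parameter: `parameter`,
#'   `dominant_period_h`, `amplitude`, `arrhythmic`.
#' @export
rhythm_summary <- function(rs, max_lag = 72, search_band = c(18, 30),
                           detrend = "baseline") {
  prof <- metabolic_profile(rs)
  params <- c("OR", "CR", "AE", "RQ", "AQ")
  rows <- lapply(params, function(p) {
    dp <- dominant_period(rhythm_acf(prof[[p]], max_lag, detrend),
                          search_band)
    data.frame(parameter = p, dominant_period_h = dp$period,
               amplitude = dp$amplitude, arrhythmic = dp$arrhythmic)
  })
  do.call(rbind, rows)
}
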