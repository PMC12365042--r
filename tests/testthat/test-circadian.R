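test_that("phase labels follow the wall clock", {
  # 08:00 start: t = 4 h is noon (light), t = 14 h is 22:00 (dark)
  expect_equal(as.character(label_phases(c(4, 14))),
               c("photophase", "scotophase"))
  # full week of integer stamps: 16 light + 8 dark labels per day
  ph <- label_phases(0:167)
  expect_equal(unname(table(ph)["photophase"]), 112, ignore_attr = TRUE)
  expect_equal(unname(table(ph)["scotophase"]), 56, ignore_attr = TRUE)
  # boundary convention: lights-on instant is light, lights-off is dark
  expect_equal(as.character(label_phases(c(20, 12), start_clock = 8)),
               c("photophase", "scotophase"))
})

test_that("phase summary splits means by label", {
  t <- 0:47
  ph <- label_phases(t)
  const <- phase_summary(rep(3.5, 48), ph)
  expect_equal(const$mean, rep(3.5, 3))
  toy <- ifelse(ph == "photophase", 1, 0)
  s <- phase_summary(toy, ph)
  expect_equal(s$mean[s$phase == "photophase"], 1)
  expect_equal(s$mean[s$phase == "scotophase"], 0)
  expect_error(phase_summary(rep(1, 3), factor(rep("photophase", 3),
               levels = c("photophase", "scotophase"))), "both phases")
})

test_that("rhythm ACF matches stats::acf on complete series", {
  set.seed(21)
  x <- as.numeric(arima.sim(list(ar = 0.7), 200))
  ours <- rhythm_acf(x, max_lag = 40, detrend = "none")
  ref <- as.numeric(stats::acf(x, lag.max = 40, plot = FALSE,
                               demean = TRUE)$acf)
  expect_equal(ours$acf, ref, tolerance = 1e-12)
})

test_that("a pure 24-h cosine yields the oracle ACF values", {
  x <- cos(2 * pi * (0:167) / 24)
  r <- rhythm_acf(x, detrend = "none")
  ref <- as.numeric(stats::acf(x, lag.max = 72, plot = FALSE)$acf)
  expect_equal(r$acf, ref, tolerance = 1e-12)
  # strong positive peak at one period, trough at the half period
  expect_equal(r$acf[r$lags == 24], (168 - 24) / 168, tolerance = 0.01)
  expect_lt(r$acf[r$lags == 12], -0.8)
  expect_equal(dominant_period(r)$period, 24)
})

test_that("ACF is normalised and bounded, with or without gaps", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(160) + 0.5 * sin(2 * pi * (1:160) / 24)
    x[sample(160, 12)] <- NA
    r <- rhythm_acf(x, max_lag = 72,
                    detrend = sample(c("linear", "baseline", "none"), 1))
    expect_equal(r$acf[1], 1)
    expect_true(all(abs(r$acf) <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("white noise stays inside the confidence band", {
  set.seed(77)
  x <- rnorm(168)
  r <- rhythm_acf(x, max_lag = 72, detrend = "linear")
  band <- 2 / sqrt(168)
  inside <- mean(abs(r$acf[-1]) < band)
  expect_gte(inside, 0.95)
  expect_true(is.na(dominant_period(r)$period) ||
                dominant_period(r)$amplitude < band * 1.5)
})

test_that("constant series are arrhythmic", {
  r <- rhythm_acf(rep(2, 168))
  expect_true(r$arrhythmic)
  dp <- dominant_period(r)
  expect_true(dp$arrhythmic)
  expect_true(is.na(dp$period))
})

test_that("dominant period requires coverage of the search band", {
  r <- rhythm_acf(cos(2 * pi * (0:167) / 24), max_lag = 25)
  expect_error(dominant_period(r, search_band = c(18, 30)), "band")
})

test_that("baseline detrending absorbs a saturating ramp", {
  # ramp + rhythm: the linear residual tilts the ACF, the baseline
  # residual does not
  t <- 0:167
  x <- 4 * pmin(t / 48, 1) + 0.6 * cos(2 * pi * (t - 12) / 24)
  expect_equal(
    dominant_period(rhythm_acf(x, detrend = "baseline"))$period, 24)
  # the linear residual tilts the ACF and misplaces the peak
  expect_false(isTRUE(all.equal(
    dominant_period(rhythm_acf(x, detrend = "linear"))$period, 24)))
})

test_that("the tank-mean profile aligns grids and phases", {
  pr <- treatment_profile(base = c(O2 = 1200, CO2 = 110, NH3N = 50),
                          diel_amplitude = c(O2 = 0, CO2 = 0, NH3N = 0),
                          noise_sd = c(O2 = 0, CO2 = 0, NH3N = 0),
                          tank_effect_sd = 0)
  rs <- estimate_rates(generate_dataset(pr, days = 2, tanks = 2, seed = 3))
  prof <- metabolic_profile(rs)
  expect_equal(nrow(prof), 48)
  expect_equal(prof$time_h, (1:48) - 0.5)
  expect_equal(prof$OR, rep(1200, 48), tolerance = 1e-9)
  expect_equal(prof$AE, rep(50, 48), tolerance = 1e-6)  # interpolated
  expect_equal(as.character(prof$phase), as.character(label_phases(prof$time_h)))
})
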