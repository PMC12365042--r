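test_that("true rate reduces to the base when diel modulation is off", {
  pr <- treatment_profile(base = c(O2 = 1000, CO2 = 100, NH3N = 50),
                          diel_amplitude = c(O2 = 0, CO2 = 0, NH3N = 0))
  t <- c(0, 5.5, 23, 100.2)
  for (ch in c("O2", "CO2", "NH3N")) {
    expect_equal(true_rate(t, pr, channel = ch),
                 rep(pr$base[[ch]], length(t)))
  }
  expect_error(true_rate(1, pr, channel = "N2O"))
})

test_that("ammonia excretion surges within the first 48 h of exposure", {
  pr <- preset_profile("phe")
  expect_gt(true_rate(60, pr, channel = "NH3N"),
            true_rate(0, pr, channel = "NH3N"))
  # the multiplier itself saturates at the plateau
  expect_gt(true_rate(49, pr, channel = "NH3N") /
              true_rate(1, pr, channel = "NH3N"), 5)
})

test_that("preset bases are calibrated so true means hit their targets", {
  # independent oracle: adaptive quadrature of the true-rate curve
  sched <- photoperiod_schedule()
  for (g in c("control", "phe", "pyr")) {
    pr <- preset_profile(g)
    targets <- attr(pr, "targets")
    for (ch in c("O2", "CO2", "NH3N")) {
      mu <- integrate(function(t) true_rate(t, pr, sched, ch),
                      0, 168, subdivisions = 2000L,
                      rel.tol = 1e-8)$value / 168
      expect_equal(mu, targets[[ch]], tolerance = 5e-3)
    }
  }
})

test_that("diel means honour the photoperiod: light above dark", {
  sched <- photoperiod_schedule()
  t <- seq(0, 168, by = 0.05)
  ph <- label_phases(t, sched)
  for (g in c("control", "phe", "pyr")) {
    pr <- preset_profile(g)
    for (ch in c("O2", "CO2", "NH3N")) {
      r <- true_rate(t, pr, sched, ch)
      expect_gt(mean(r[ph == "photophase"]), mean(r[ph == "scotophase"]))
    }
  }
})

test_that("a zero-rate noiseless cycle is flat at the start concentration", {
  cyc <- synth_cycle(0, chamber_spec(), fish_lot(), 8, "O2", noise_sd = 0)
  expect_equal(cyc$conc, rep(8, 20))
  expect_equal(diff(cyc$time_s), rep(15, 19))
})

test_that("noiseless cycles carry the algebraically inverted slope", {
  ch <- chamber_spec()
  fish <- fish_lot()
  cyc <- synth_cycle(1436.4, ch, fish, 8, "O2", noise_sd = 0)
  slope <- unname(coef(lm(conc ~ time_s, cyc))[2])
  expect_equal(slope, -5e-4, tolerance = 1e-12)
  expect_error(synth_cycle(1e7, ch, fish, 0.05, "O2"), "non-positive")
})

test_that("noiseless simulate/estimate round trip recovers the rate", {
  ch <- chamber_spec()
  fish <- fish_lot()
  for (rate in c(250, 1436.4)) {
    cyc <- synth_cycle(rate, ch, fish, 8, "O2", noise_sd = 0)
    sl <- cycle_slope_series(cyc$time_s, cyc$conc, ch)
    rec <- rate_from_slope(sl$slope, ch, fish, "O2")
    expect_equal(rec, rate, tolerance = 1e-9)
  }
})

test_that("tank ammonia accumulation inverts exactly without noise", {
  fish <- fish_lot()
  ch <- chamber_spec()
  pr <- treatment_profile(base = c(O2 = 1000, CO2 = 100, NH3N = 60),
                          diel_amplitude = c(O2 = 0, CO2 = 0, NH3N = 0))
  amm <- synth_ammonia_samples(pr, fish, ch, days = 2, noise_sd = 0)
  out <- ammonia_rate_series(amm$time_s, amm$conc, ch, fish)
  expect_equal(out$vn, rep(60, nrow(out)), tolerance = 1e-6)
  # zero excretion leaves the tank concentration constant
  pr0 <- treatment_profile(base = c(O2 = 1000, CO2 = 100, NH3N = 0),
                           diel_amplitude = c(O2 = 0, CO2 = 0, NH3N = 0))
  amm0 <- synth_ammonia_samples(pr0, fish, ch, days = 1, noise_sd = 0)
  expect_equal(amm0$conc, rep(amm0$conc[1], length(amm0$conc)))
})

test_that("phenanthrene ammonia increments grow after the surge", {
  set.seed(2)
  pr <- preset_profile("phe")
  amm <- synth_ammonia_samples(pr, fish_lot(), chamber_spec(), days = 7)
  inc <- diff(amm$conc)
  h <- amm$time_s[-1] / 3600
  expect_gt(mean(inc[h > 48]), mean(inc[h <= 12]))
})

test_that("dataset generation is deterministic in the seed", {
  a <- generate_dataset("control", days = 1, tanks = 2, seed = 7)
  b <- generate_dataset("control", days = 1, tanks = 2, seed = 7)
  c <- generate_dataset("control", days = 1, tanks = 2, seed = 8)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth$tank_effects, b$truth$tank_effects)
  expect_false(isTRUE(all.equal(a$traces$conc, c$traces$conc)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(generate_dataset("control", days = 1, tanks = 1, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("noiseless flat presets produce constant hourly rates", {
  pr <- treatment_profile(base = c(O2 = 1200, CO2 = 110, NH3N = 50),
                          diel_amplitude = c(O2 = 0, CO2 = 0, NH3N = 0),
                          noise_sd = c(O2 = 0, CO2 = 0, NH3N = 0),
                          tank_effect_sd = 0)
  rs <- estimate_rates(generate_dataset(pr, days = 1, tanks = 1, seed = 1))
  expect_equal(rs$hourly$vo2, rep(1200, 24), tolerance = 1e-9)
  expect_equal(rs$hourly$vco2, rep(110, 24), tolerance = 1e-9)
  expect_equal(rs$bihourly$vn, rep(50, 12), tolerance = 1e-6)
})

test_that("noiseless presets recover their targets through the pipeline", {
  for (g in c("control", "phe")) {
    pr <- noiseless_profile(g)
    rs <- estimate_rates(generate_dataset(pr, days = 7, tanks = 1,
                                          seed = 1))
    gm <- group_means(rs)
    targets <- attr(pr, "targets")
    expect_equal(gm$mean[gm$parameter == "OR"], targets[["O2"]],
                 tolerance = 5e-3)
    expect_equal(gm$mean[gm$parameter == "CR"], targets[["CO2"]],
                 tolerance = 5e-3)
    expect_equal(gm$mean[gm$parameter == "AE"], targets[["NH3N"]],
                 tolerance = 5e-3)
  }
})
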