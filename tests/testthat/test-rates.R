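test_that("weighted slope is exact on affine and quadratic series", {
  t <- 0:6
  for (n in c(3, 5, 7)) {
    expect_equal(weighted_slope(2 + 0.5 * t, t, 4, n), 0.5)
    # central differences are exact for quadratics at the centre (t = 3)
    expect_equal(weighted_slope(t^2, t, 4, n), 6)
  }
})

test_that("weighted slope matches direct evaluation of the stencil", {
  # independent brute-force evaluation of the weighted-difference formula
  x <- c(2.31, 2.07, 2.22, 1.95, 1.81, 1.90, 1.62)
  t <- c(0, 14, 31, 45, 62, 75, 91)
  d <- function(j) (x[4 + j] - x[4 - j]) / (t[4 + j] - t[4 - j])
  expect_equal(weighted_slope(x, t, 4, 3), d(1))
  expect_equal(weighted_slope(x, t, 4, 5), (2 * d(1) + d(2)) / 3)
  expect_equal(weighted_slope(x, t, 4, 7), (3 * d(1) + 2 * d(2) + d(3)) / 6)
})

test_that("weighted slope rejects bad stencils and inputs", {
  t <- 0:6
  expect_error(weighted_slope(t, t, 4, 4), "n must be")
  expect_error(weighted_slope(t, t, 1, 3), "neighbours")
  expect_error(weighted_slope(t, c(0, 1, 1, 3, 4, 5, 6), 4, 3),
               "duplicate")
})

test_that("cycle slopes recover piecewise-linear segments", {
  ch <- chamber_spec()
  offs <- seq(150, 435, by = 15)
  t <- c(offs, 450 + offs)
  v <- c(8 - 4e-4 * offs, 8 - 6e-4 * offs)
  out <- cycle_slope_series(t, v, ch)
  expect_equal(out$slope, c(-4e-4, -6e-4))
  expect_true(all(out$ok))
  expect_equal(out$n_used, c(7, 7))
})

test_that("a cycle with a missing window is flagged, neighbours intact", {
  ch <- chamber_spec()
  offs <- seq(150, 435, by = 15)
  t <- c(offs, 900 + offs)       # cycle 1 (450-900 s) entirely absent
  v <- 8 - 2e-4 * t
  out <- cycle_slope_series(t, v, ch)
  expect_equal(nrow(out), 3)
  expect_false(out$ok[2])
  expect_true(is.na(out$slope[2]))
  expect_equal(out$slope[c(1, 3)], c(-2e-4, -2e-4))
})

test_that("fast regular-grid path agrees with the generic path", {
  ch <- chamber_spec()
  offs <- seq(150, 435, by = 15)
  set.seed(4)
  t <- c(offs, 450 + offs, 900 + offs)
  v <- 8 - 5e-4 * t + rnorm(length(t), 0, 0.01)
  fast <- cycle_slope_series(t, v, ch)
  # perturb a timestamp outside every stencil to force the generic path
  t2 <- t
  t2[1] <- t2[1] + 1e-3
  slow <- cycle_slope_series(t2, v, ch)
  expect_equal(fast$slope[2:3], slow$slope[2:3])
  expect_equal(fast$mid_time_s, slow$mid_time_s)
})

test_that("noisy cycle slopes land within propagated noise bounds", {
  ch <- chamber_spec()
  fish <- fish_lot()
  sd_noise <- 0.01
  true_slope <- -5e-4
  # analytic SD of the n = 7 weighted slope on a 15-s grid
  dt <- ch$sensor_interval
  sd_slope <- sd_noise * sqrt(2 * sum((3:1)^2 / (2 * (1:3) * dt)^2)) / 6
  set.seed(99)
  err <- replicate(400, {
    cyc <- synth_cycle(1436.4, ch, fish, 8, "O2", noise_sd = sd_noise)
    cycle_slope_series(cyc$time_s, cyc$conc, ch)$slope - true_slope
  })
  expect_lt(abs(mean(err)), 3 * sd_slope / sqrt(400))   # unbiased
  expect_equal(sd(err), sd_slope, tolerance = 0.15)     # calibrated SD
  expect_true(all(abs(err) < 5 * sd_slope))
})

test_that("rate conversion reproduces the worked chamber-equation values", {
  ch <- chamber_spec()
  fish <- fish_lot()   # 0.0025 kg, 0.005 L in a 2 L chamber
  expect_equal(rate_from_slope(-5e-4, ch, fish, "O2"), 1436.4)
  expect_equal(rate_from_slope(1e-5, ch, fish, "CO2"), 28.728)
  expect_equal(rate_from_slope(0, ch, fish, "CO2"), 0)
})

test_that("rate conversion is linear in slope and inverse in weight", {
  ch <- chamber_spec()
  f1 <- fish_lot()
  f2 <- fish_lot(mean_weight = 2 * f1$mean_weight)
  s <- -3.7e-4
  expect_equal(rate_from_slope(2 * s, ch, f1, "O2"),
               2 * rate_from_slope(s, ch, f1, "O2"))
  expect_equal(rate_from_slope(s, ch, f2, "O2"),
               rate_from_slope(s, ch, f1, "O2") / 2)
  expect_error(rate_from_slope(s, chamber_spec(respir_vol = 0.004),
                               f1, "O2"), "exceed")
})

test_that("quotients match hand-evaluated molar ratios", {
  expect_equal(respiratory_quotient(44, 32), 1)
  expect_equal(respiratory_quotient(0, 32), 0)
  expect_true(is.na(respiratory_quotient(44, 0)))
  expect_equal(ammonia_quotient(18, 32), 1)
  # group-mean evaluations, hand-computed: (x/44)/(y/32), (x/18)/(y/32)
  expect_equal(respiratory_quotient(127.97, 1778.57), 0.05233,
               tolerance = 1e-4)
  expect_equal(ammonia_quotient(690.60, 444.46), 2.7623, tolerance = 1e-4)
  expect_equal(ammonia_quotient(56.44, 1778.57), 0.05641, tolerance = 1e-4)
})

test_that("quotients are invariant to rescaling the fish weight", {
  ch <- chamber_spec()
  f1 <- fish_lot()
  f2 <- fish_lot(mean_weight = 3 * f1$mean_weight)
  rq1 <- respiratory_quotient(rate_from_slope(2e-5, ch, f1, "CO2"),
                              rate_from_slope(-5e-4, ch, f1, "O2"))
  rq2 <- respiratory_quotient(rate_from_slope(2e-5, ch, f2, "CO2"),
                              rate_from_slope(-5e-4, ch, f2, "O2"))
  expect_equal(rq1, rq2)
})

test_that("hourly aggregation equals the brute-force window mean", {
  set.seed(11)
  times <- (seq_len(16) - 1) * 450 / 3600 + 450 / 2 / 3600  # 2 h of cycles
  vals <- rnorm(16, 100, 5)
  agg <- hourly_aggregate(data.frame(time_h = times, rate = vals),
                          data.frame(time_h = times, rate = vals / 10),
                          hours = 2)
  expect_equal(agg$hourly$vo2, c(mean(vals[1:8]), mean(vals[9:16])))
  expect_equal(agg$hourly$vco2, agg$hourly$vo2 / 10)
  expect_equal(agg$hourly$rq,
               respiratory_quotient(agg$hourly$vco2, agg$hourly$vo2))
})

test_that("hours whose cycles are all missing stay missing", {
  times <- c(0.25, 0.75, 2.25, 2.75)  # nothing lands in hour 1
  agg <- hourly_aggregate(data.frame(time_h = times, rate = rep(10, 4)),
                          data.frame(time_h = times, rate = rep(1, 4)),
                          hours = 3)
  expect_true(is.na(agg$hourly$vo2[2]))
  expect_equal(agg$hourly$vo2[c(1, 3)], c(10, 10))
  expect_error(hourly_aggregate(data.frame(time_h = numeric(),
                                           rate = numeric()),
                                data.frame(time_h = numeric(),
                                           rate = numeric())),
               "empty")
})

test_that("ammonia rates label interval midpoints and invert the tank equation", {
  ch <- chamber_spec()
  fish <- fish_lot()
  t <- c(0, 7200, 14400)
  conc <- c(0.1, 0.2, 0.35)
  out <- ammonia_rate_series(t, conc, ch, fish)
  expect_equal(out$time_h, c(1, 3))
  expected <- diff(conc) / 7200 * (ch$tank_volume - fish$total_volume) *
    3600 / fish$total_weight
  expect_equal(out$vn, expected)
})

test_that("cycle slopes agree with least squares on dense linear data", {
  ch <- chamber_spec()
  offs <- seq(150, 435, by = 15)
  v <- 8 - 4.2e-4 * offs
  ws <- cycle_slope_series(offs, v, ch)$slope
  ols <- unname(coef(lm(v ~ offs))[2])
  expect_equal(ws, ols, tolerance = 1e-9)
})
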