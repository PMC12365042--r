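# Shared fixtures.  Datasets are generated once per test run and cached,
# so several test files can reuse the same simulated study.

.fixture_cache <- new.env(parent = emptyenv())

study_data <- function(group, seed, days = 7, tanks = 3, ...) {
  key <- paste(group, seed, days, tanks, sep = "_")
  if (!exists(key, envir = .fixture_cache)) {
    ts <- generate_dataset(group, days = days, tanks = tanks, seed = seed,
                           ...)
    assign(key, list(ts = ts, rs = estimate_rates(ts)),
           envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The three reference datasets used by the study-level tests.
ref_seed <- c(control = 101L, phe = 102L, pyr = 103L)

# A noiseless, single-tank profile for exact-recovery checks.
noiseless_profile <- function(group = "control") {
  pr <- preset_profile(group)
  pr$noise_sd[] <- 0
  pr$tank_effect_sd <- 0
  pr
}

table1_targets <- list(
  control = c(OR = 1778.57, CR = 127.97, AE = 56.44),
  phe     = c(OR = 444.46,  AE = 690.60),
  pyr     = c(OR = 534.26,  AE = 413.96)
)
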