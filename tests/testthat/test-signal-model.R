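# Observation model: chirp phases, interference, peaks, simulator.

test_that("phase_sweep matches its closed form and degenerates to a pure tone", {
  # constant-frequency limit: phi(t) = 2*pi*f*t exactly
  t <- seq(0, 2, length.out = 51)
  expect_equal(phase_sweep(10, 10, 2, 51), 2 * pi * 10 * t)

  # zero-time phase and hand-evaluated chirp endpoint:
  # f 100 -> 50 over 1 s gives phi(1) = 2*pi * mean frequency * duration
  phi <- phase_sweep(100, 50, 1, 101)
  expect_identical(phi[1], 0)
  expect_equal(phi[101], 2 * pi * 75)

  expect_error(phase_sweep(-1, 50, 1, 10), "positive")
  expect_error(phase_sweep(10, 50, 0, 10), "positive")
  expect_error(phase_sweep(10, 50, 1, 1), "n_samples")
})

test_that("phase_sweep is continuous with linearly varying instantaneous frequency", {
  for (ff in c(40, 100, 260)) {
    phi <- phase_sweep(100, ff, 0.5, 2000)
    d1 <- diff(phi)
    expect_true(all(d1 > 0))
    # linear chirp: second differences of the quadratic phase are constant
    d2 <- diff(d1)
    expect_equal(max(d2), min(d2), tolerance = 1e-6)
    # instantaneous frequency endpoints
    dt <- 0.5 / 1999
    expect_equal(d1[1] / (2 * pi * dt), 100, tolerance = 1e-2)
    expect_equal(d1[1999] / (2 * pi * dt), ff, tolerance = 1e-2)
  }
})

test_that("synth_interference respects coupling coefficients and scan mode", {
  scan0 <- scan_program(100, 50, 60, 30, beta = 0, gamma = 0,
                        duration = 1, n_samples = 500)
  expect_identical(synth_interference(scan0), numeric(500))

  # mode masking: RF mode output equals the RF term alone however large gamma
  rf_only <- scan_program(100, 50, 60, 30, beta = 0.7, gamma = 99,
                          duration = 1, n_samples = 500, mode = "RF")
  expected <- 0.7 * sin(phase_sweep(100, 50, 1, 500))
  expect_equal(synth_interference(rf_only), expected)

  # constant-frequency amplitude bound: dense sampling reaches beta * A_RF
  tone <- scan_program(5, 5, 60, 30, a_rf = 2, beta = 0.4, gamma = 0,
                       duration = 1, n_samples = 100001, mode = "RF")
  expect_equal(max(abs(synth_interference(tone))), 0.8, tolerance = 1e-6)
})

test_that("synth_clean_signal sums Gaussian peaks linearly", {
  expect_identical(synth_clean_signal(list(), 100), numeric(100))

  one <- synth_clean_signal(list(peak_spec(40, 3, 2.5)), 100)
  expect_equal(max(one), 2.5)
  expect_equal(which.max(one), 41L)  # 0-based center 40

  # linearity oracle: two well-separated peaks sum to twice one peak's mass
  p <- function(center) peak_spec(center, 4, 1.3)
  two <- synth_clean_signal(list(p(100), p(400)), 500)
  single <- synth_clean_signal(list(p(100)), 500)
  expect_equal(sum(two), 2 * sum(single), tolerance = 1e-9)

  expect_error(synth_clean_signal(list(peak_spec(500, 3, 1)), 100),
               "outside")
})

test_that("simulate_spectrum composes components additively and deterministically", {
  prof <- default_profile(2048)
  quiet <- scan_program(100, 50, 60, 30, beta = 0, gamma = 0,
                        duration = 1, n_samples = 2048)
  sim0 <- simulate_spectrum(prof$peaks, quiet, 0, seed = 5)
  expect_identical(sim0$spectrum$intensities, sim0$truth$clean)

  scan <- prof$scan
  a <- simulate_spectrum(prof$peaks, scan, 0.3, seed = 11)
  b <- simulate_spectrum(prof$peaks, scan, 0.3, seed = 11)
  expect_identical(a$spectrum$intensities, b$spectrum$intensities)

  # additivity: subtracting the truth components leaves the noise draw
  # (up to one rounding step of the floating-point sum)
  resid <- a$spectrum$intensities - a$truth$clean - a$truth$interference
  expect_equal(resid, a$truth$noise, tolerance = 1e-12)

  expect_error(simulate_spectrum(prof$peaks, scan, -1, seed = 1), "noise_sigma")
})

test_that("simulate_spectrum leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_spectrum(list(), default_profile(512)$scan, 1, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("constructors enforce their invariants", {
  expect_error(ms_spectrum(1), "at least 2")
  expect_error(ms_spectrum(c(1, 2), mass_axis = c(2, 2)), "monotone")
  expect_error(scan_program(0, 50, 60, 30), "positive")
  expect_error(peak_spec(10, 0, 1), "width_sigma")
  expect_error(peak_spec(10, 1, -1), "amplitude")
  s <- ms_spectrum(c(1, 2, 3), mass_axis = c(10.5, 11.5, 12.5))
  expect_length(s, 3L)
})
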