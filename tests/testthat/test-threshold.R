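# Median-based thresholds, hard/soft filtering, and the EBW/WB denoisers.

test_that("mad_sigma matches its definition and is consistent for Gaussians", {
  expect_identical(mad_sigma(numeric(10) + 0), 0)
  expect_equal(mad_sigma(rep(0.6745, 5)), 1)
  expect_equal(mad_sigma(c(-0.6745, 0.6745, 0.6745)), 1)
  # Monte-Carlo consistency on 1e5 standard-normal draws
  expect_equal(mad_sigma(seeded_normal(1e5, 42)), 1, tolerance = 0.05)
  expect_error(mad_sigma(numeric(0)), "empty")
})

test_that("level_threshold is the universal rule with the median-based scale", {
  expect_identical(level_threshold(numeric(64)), 0)
  v <- rep(0.6745, 100)
  expect_equal(level_threshold(v), sqrt(2 * log(100)))
  # seeded unit-normal band, N = 4096: T ~ sqrt(2 ln 4096) ~ 4.08
  expect_equal(level_threshold(seeded_normal(4096, 8)),
               sqrt(2 * log(4096)), tolerance = 0.05)
  expect_error(level_threshold(3), "at least 2")
})

test_that("hard and soft filtering follow their definitions", {
  expect_identical(apply_threshold(c(3, -1, 2), 1.5, "hard"), c(3, 0, 2))
  expect_identical(apply_threshold(c(3, -1, 2), 1.5, "soft"), c(1.5, 0, 0.5))
  # T = 0 is the identity for hard filtering away from exact zeros
  v <- c(0.3, -2, 5, -0.001)
  expect_identical(apply_threshold(v, 0, "hard"), v)
  # a coefficient exactly at T is zeroed under both rules
  expect_identical(apply_threshold(c(1.5, -1.5, 2), 1.5, "hard"), c(0, 0, 2))
  expect_error(apply_threshold(v, -1), "non-negative")
})

test_that("hard thresholding is idempotent", {
  v <- seeded_normal(512, 12)
  t1 <- apply_threshold(v, 1.2, "hard")
  expect_identical(apply_threshold(t1, 1.2, "hard"), t1)
})

test_that("a clean noiseless transient passes through the default denoiser", {
  prof <- default_profile(200000)
  clean <- synth_clean_signal(prof$peaks, 200000)
  fit <- ebw_denoise(clean, "rbio5.5", 11, 1:6, "hard")
  expect_lt(max(abs(fitted(fit) - clean)) / max(clean), 1e-6)
})

test_that("denoising pure white noise strictly reduces energy", {
  x <- seeded_normal(16384, 31)
  fit <- ebw_denoise(x, "db4", 8, 1:6, "hard")
  expect_lt(sum(fitted(fit)^2), sum(x^2))
  # and per filtered level the band energy never grows
  lev <- fit$levels
  expect_true(all(fit$energy_after$per_level_energy[lev] <=
                    fit$energy_before$per_level_energy[lev]))
})

test_that("filtering is confined to the requested levels", {
  prof <- default_profile(16384)
  sim <- simulate_spectrum(prof$peaks, prof$scan, prof$noise_sigma, 3)
  x <- sim$spectrum$intensities
  fit <- ebw_denoise(x, "db4", 6, levels = 1, rule = "hard")
  ref <- wt_decompose(x, "db4", 6)
  out <- wt_decompose(fitted(fit), "db4", 6)
  scale <- max(abs(x))
  for (i in 2:6) {
    expect_lt(max(abs(out$details[[i]] - ref$details[[i]])) / scale, 1e-8)
  }
  expect_lt(max(abs(out$approx - ref$approx)) / scale, 1e-8)
  expect_identical(fit$coefficients_zeroed[2:6], rep(NA_integer_, 5))
})

test_that("the denoiser is deterministic and records its plan", {
  x <- seeded_normal(4096, 55)
  f1 <- ebw_denoise(x, "sym5", 6, 1:4, "soft")
  f2 <- ebw_denoise(x, "sym5", 6, 1:4, "soft")
  expect_identical(fitted(f1), fitted(f2))
  expect_identical(residuals(f1), x - fitted(f1))
  co <- coef(f1)
  expect_length(co, 6L)
  expect_true(all(co[1:4] >= 0))
  expect_true(all(is.na(co[5:6])))
  expect_error(ebw_denoise(x, "db4", 6, levels = 0:2), "levels")
})

test_that("ESER auto-selection plugs into the denoiser", {
  prof <- default_profile(4096)
  sim <- simulate_spectrum(prof$peaks, prof$scan, prof$noise_sigma, 9)
  fit <- ebw_denoise(sim$spectrum, wavelet = "auto", level = 6, levels = 1:4,
                     candidates = c("db2", "db4", "rbio3.5", "sym4"))
  expect_true(fit$wavelet %in% c("db2", "db4", "rbio3.5", "sym4"))
  expect_s3_class(fit$selection, "wavelet_selection")
})

test_that("the WB comparator uses one blind threshold over four levels", {
  z <- numeric(64)
  expect_equal(fitted(wb_denoise(z)), z)
  x <- seeded_normal(8192, 77)
  w1 <- wb_denoise(x)
  w2 <- wb_denoise(x)
  expect_identical(fitted(w1), fitted(w2))
  expect_identical(w1$wavelet, "db4")
  expect_identical(w1$level, 4L)
  expect_identical(length(unique(w1$thresholds)), 1L)
  expect_error(wb_denoise(rnorm(8)), "at least 16")
})

test_that("denoising improves recovery of the known clean signal", {
  prof <- default_profile(65536)
  sim <- simulate_spectrum(prof$peaks, prof$scan, prof$noise_sigma, 101)
  x <- sim$spectrum$intensities
  fit <- ebw_denoise(x, "rbio5.5", 11, 1:6, "hard")
  expect_lt(rmse(fitted(fit), sim$truth$clean), rmse(x, sim$truth$clean))
})
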