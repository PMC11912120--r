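# Multilevel DWT: depth rule, band lengths, frozen transform oracle,
# perfect reconstruction, energy accounting.

test_that("wt_max_level implements floor(log2(L))", {
  expect_identical(wt_max_level(200000), 17L)
  expect_identical(wt_max_level(2048), 11L)
  expect_identical(wt_max_level(2), 1L)
  expect_error(wt_max_level(1), ">= 2")
})

test_that("periodized band lengths follow the ceil(L/2) recursion", {
  d <- wt_decompose(rep(1, 200000), "rbio5.5", 11)
  lens <- vapply(d$details, length, integer(1))
  expected <- integer(11)
  L <- 200000
  for (i in 1:11) {
    L <- ceiling(L / 2)
    expected[i] <- as.integer(L)
  }
  expect_identical(lens, expected)
  expect_identical(lens[1], 100000L)   # the printed 200,000 / 2^1
  expect_identical(length(d$approx), 98L)
})

test_that("Haar details of a constant signal vanish", {
  d <- wt_decompose(rep(3.7, 64), "haar", 1)
  expect_equal(d$details[[1]], numeric(32))
})

test_that("transform coefficients match an independently computed reference", {
  # Expected values computed once with an independent DWT implementation
  # (PyWavelets 1.9.0, mode='periodization'/'symmetric') on this fixture.
  x <- fixture16()

  d <- wt_decompose(x, "db2", 2)
  expect_equal(d$approx,
               c(3.02063293868264, 2.54186706131736, 1.57251587736527,
                 1.61498412263473), tolerance = 1e-12)
  expect_equal(d$details[[2]],
               c(-1.23100952641916, 2.06474364905389, -1.20244327267068,
                 0.710215500982063), tolerance = 1e-12)
  expect_equal(d$details[[1]],
               c(3.12192134690922, 3.16464292680921, -2.43215215425292,
                 7.22710610863776, -0.845807489428577, -4.88968829987559,
                 5.21785769909912, -0.310831810693282), tolerance = 1e-12)

  b <- wt_decompose(x, "bior3.5", 2)
  expect_equal(b$approx,
               c(0.33929443359375, 6.8486328125, -5.35491943359375,
                 6.9169921875), tolerance = 1e-12)
  expect_equal(b$details[[2]],
               c(-0.5986328125, 6.826171875, 0.3701171875, -6.09765625),
               tolerance = 1e-12)

  s <- wt_decompose(x, "db2", 2, mode = "symmetric")
  expect_equal(s$approx,
               c(2.96650635094611, 3.44362976320958, 1.8470349302036,
                 0.805328955640706, 3.71979128114971, 2.875),
               tolerance = 1e-12)
  expect_equal(s$details[[1]],
               c(-1.22474487139159, -4.40672538673105, 0.263464637947905,
                 -1.54826867776974, -4.75563318447894, 3.63955943711426,
                 -0.104025531181522, -2.56960807964367, 0.918558653543692),
               tolerance = 1e-12)
})

test_that("round trips are perfect across families, depths, modes and odd lengths", {
  wavelets <- c("haar", "db2", "db4", "db15", "sym5", "sym12", "coif4",
                "bior1.3", "bior3.5", "bior6.8", "rbio2.4", "rbio5.5")
  x <- seeded_normal(4096, 101)
  x_odd <- seeded_normal(1037, 102)
  for (w in wavelets) {
    for (mode in c("periodized", "symmetric")) {
      xr <- wt_reconstruct(wt_decompose(x, w, 6, mode = mode))
      expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-8)
      xr2 <- wt_reconstruct(wt_decompose(x_odd, w, 4, mode = mode))
      expect_lt(max(abs(xr2 - x_odd)) / max(abs(x_odd)), 1e-8)
    }
  }
})

test_that("zeroed and constant decompositions reconstruct as expected", {
  # all bands zeroed -> zero signal
  d <- wt_decompose(seeded_normal(256, 7), "rbio5.5", 4)
  d$approx <- d$approx * 0
  d$details <- lapply(d$details, function(v) v * 0)
  expect_equal(wt_reconstruct(d), numeric(256))

  # constant signal with details dropped stays constant (haar)
  d2 <- wt_decompose(rep(2.5, 128), "haar", 3)
  d2$details <- lapply(d2$details, function(v) v * 0)
  expect_equal(wt_reconstruct(d2), rep(2.5, 128))
})

test_that("energy profile conserves energy for orthogonal wavelets and scales quadratically", {
  x <- seeded_normal(8192, 21)
  d <- wt_decompose(x, "db4", 8)
  ep <- energy_profile(d)
  expect_lt(abs(ep$total_energy - sum(x^2)) / sum(x^2), 1e-10)
  expect_equal(sum(ep$per_level_fraction), 1, tolerance = 1e-9)

  # homogeneity oracle: scaling the signal by c scales every band by c^2
  ep3 <- energy_profile(wt_decompose(3 * x, "db4", 8))
  expect_equal(ep3$per_level_energy, 9 * ep$per_level_energy,
               tolerance = 1e-12)

  ez <- energy_profile(wt_decompose(numeric(64), "db4", 3))
  expect_true(ez$degenerate)
  expect_identical(unname(ez$per_level_fraction), numeric(4))
})

test_that("structural errors are reported", {
  expect_error(wt_decompose(seeded_normal(64, 1), "nosuch", 2), "unknown wavelet")
  expect_error(wt_decompose(seeded_normal(64, 1), "db2", 7), "exceeds")
  d <- wt_decompose(seeded_normal(64, 1), "db2", 3)
  d$details[[2]] <- d$details[[2]][-1]
  expect_error(wt_reconstruct(d), "length mismatch")
})
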