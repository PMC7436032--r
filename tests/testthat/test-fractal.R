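test_that("db4 detail variances match an independent multiresolution
           reference", {
  # expected values computed with PyWavelets (wavedec, db4, symmetric
  # extension, 5 levels) on the identical seed-42 standard normal series
  set.seed(42)
  x <- rnorm(300)
  prof <- waveletDetailVariances(x, levels = 5)
  expect_equal(prof$variance,
               c(0.891577048593783, 1.324364320682116, 0.728281802880985,
                 0.862916703273132, 0.778326061947397),
               tolerance = 1e-12)
})

test_that("exact dyadic variance lines recover their slope with r2 = 1", {
  prof <- structure(list(level = 1:5, variance = 3 * 2^(1:5),
                         wavelet = "db4", n = 512L),
                    class = "wavelet_variance_profile")
  sl <- spectralSlope(prof)
  expect_equal(sl$beta, 1, tolerance = 1e-12)
  expect_equal(sl$r2, 1, tolerance = 1e-12)

  flat <- structure(list(level = 1:5, variance = rep(0.7, 5),
                         wavelet = "db4", n = 512L),
                    class = "wavelet_variance_profile")
  expect_equal(spectralSlope(flat)$beta, 0, tolerance = 1e-12)
})

test_that("white noise has a flat wavelet variance profile (beta near 0)", {
  set.seed(17)
  betas <- replicate(20, {
    prof <- waveletDetailVariances(rnorm(2048), levels = 5)
    spectralSlope(prof)$beta
  })
  expect_lt(abs(mean(betas)), 0.1)
})

test_that("degenerate and too-short inputs are rejected", {
  expect_error(waveletDetailVariances(numeric(100), levels = 5), "too short")
  expect_error(waveletDetailVariances(rep(0, 400), levels = 5), "degenerate")
  err <- tryCatch(waveletDetailVariances(rnorm(100), levels = 5),
                  error = conditionMessage)
  expect_match(err, "256")   # the minimum length is named
})

test_that("variance profile is invariant to constant offsets and scales as
           amplitude squared", {
  set.seed(23)
  x <- coloredNoise(512, 1.5)
  p1 <- waveletDetailVariances(removeOffset(x))
  p2 <- waveletDetailVariances(removeOffset(x + 42))
  expect_equal(p1$variance, p2$variance, tolerance = 1e-9)
  p3 <- waveletDetailVariances(3 * x)
  expect_equal(p3$variance, 9 * p1$variance, tolerance = 1e-9)
  # slope (and hence D) is unchanged by amplitude scaling
  expect_equal(spectralSlope(p3)$beta, spectralSlope(p1)$beta,
               tolerance = 1e-9)
})

test_that("the dimension-Hurst-beta identities hold exactly", {
  expect_equal(fractalDimension(2.01)$dimension, 1.495)
  expect_equal(fractalDimension(2.01)$hurst, 0.505)
  expect_equal(fractalDimension(3)$dimension, 1)    # smooth limit
  expect_equal(fractalDimension(1)$dimension, 2)    # complex limit
  for (b in c(0.5, 1.3, 2.2, 3.4)) {
    est <- fractalDimension(b)
    expect_equal(est$dimension + est$hurst, 2)
    expect_equal(2 * est$hurst + 1, est$beta)
    expect_identical(est$in_range, b > 1 && b < 3)
  }
})

test_that("spectral-synthesis noise recovers its exponent", {
  # scaled-down recovery check; the full grid runs in the acceptance suite
  set.seed(99)
  for (b_true in c(1.2, 2.4)) {
    est <- replicate(8, {
      prof <- waveletDetailVariances(coloredNoise(4096, b_true))
      spectralSlope(prof)$beta
    })
    expect_lt(abs(mean(est) - b_true), 0.15)
  }
})

test_that("reconstructed-detail variances tell the same spectral story", {
  set.seed(31)
  x <- coloredNoise(1024, 2)
  pc <- waveletDetailVariances(x, variance_target = "coefficients")
  pr <- waveletDetailVariances(x, variance_target = "reconstructed")
  # reconstructed detail signals are orthogonal pieces of x, so their
  # variances are smaller but the log-variance trend has the same sign
  expect_true(all(pr$variance > 0))
  expect_gt(cor(log2(pc$variance), log2(pr$variance)), 0.9)
})

test_that("tremor raises x/z fractal dimensions; identical arms agree", {
  base <- armModel(swingAmplitude = 6, noiseBeta = 2.2, noiseAmplitude = 0.8)
  trem <- armModel(swingAmplitude = 6, noiseBeta = 2.2, noiseAmplitude = 0.8,
                   tremorHz = 6, tremorAmplitude = 120)
  d_of <- function(model, seed) {
    fd <- trialFractalDimensions(
      trimSteadyState(simulateRecording(model, seed = seed)))
    c(x = fd$x$dimension, y = fd$y$dimension, z = fd$z$dimension)
  }
  d0 <- rowMeans(vapply(1:6, function(s) d_of(base, s), numeric(3)))
  d1 <- rowMeans(vapply(1:6, function(s) d_of(trem, s + 100), numeric(3)))
  expect_gt(d1[["x"]], d0[["x"]] + 0.05)
  expect_gt(d1[["z"]], d0[["z"]] + 0.05)

  # identical left/right models give matching dimensions up to Monte Carlo
  da <- rowMeans(vapply(1:8, function(s) d_of(base, s), numeric(3)))
  db <- rowMeans(vapply(1:8, function(s) d_of(base, s + 500), numeric(3)))
  expect_lt(max(abs(da - db)), 0.06)
})
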