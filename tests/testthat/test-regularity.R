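test_that("autocorrelation is self-normalised and matches the brute-force
           definition", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(16:512, 1)
    y <- rnorm(n)
    r <- unbiasedAutocorrelation(y)
    expect_equal(r[1], 1)
    expect_lt(max(abs(r - bruteAutocorrelation(y))), 1e-9)
  }
  expect_error(unbiasedAutocorrelation(rep(2, 50)), "zero-variance")
  expect_error(unbiasedAutocorrelation(c(1, 2)), "at least 4")
})

test_that("a two-harmonic gait-like tone has closed-form cycle and
           half-cycle peaks", {
  # step fundamental at 2 Hz plus a cycle component at 1 Hz: the
  # autocorrelation is (cos(4 pi tau) + g^2 cos(2 pi tau)) / (1 + g^2),
  # so the full-cycle peak (lag 1 s) is 1 and the half-cycle peak (lag
  # 0.5 s) is (1 - g^2) / (1 + g^2)
  fs <- 50
  g <- 0.5
  t <- seq_len(20 * fs) / fs
  y <- sin(2 * pi * 2 * t) + g * sin(2 * pi * t + 0.3)
  r <- unbiasedAutocorrelation(y)
  expect_equal(r[fs + 1], 1, tolerance = 1e-2)
  pk <- regularityPeaks(r, fs)
  expect_true(pk$found)
  expect_equal(pk$peak_b_lag_s * fs, fs, tolerance = 1)
  expect_equal(pk$peak_b_amplitude, 1, tolerance = 1e-2)
  expect_equal(pk$peak_a_lag_s * fs, fs / 2, tolerance = 1)
  expect_equal(pk$peak_a_amplitude, (1 - g^2) / (1 + g^2), tolerance = 1e-2)
})

test_that("peak amplitudes are invariant to amplitude scaling", {
  set.seed(8)
  y <- sin(2 * pi * (1:500) / 50) + 0.3 * rnorm(500)
  r1 <- unbiasedAutocorrelation(y)
  r2 <- unbiasedAutocorrelation(5.7 * y)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("symmetric half-cycles raise the half-cycle peak toward the cycle
           peak; asymmetric half-cycles depress it", {
  peaksFor <- function(anterior, seed = 3) {
    model <- armModel(swingAmplitude = 6, anteriorFraction = anterior,
                      noiseAmplitude = 0.15)
    rec <- trimSteadyState(simulateRecording(model, seed = seed))
    y <- removeOffset(channels(rec)[, "ay_low"])
    regularityPeaks(unbiasedAutocorrelation(y), sampleRate(rec))
  }
  sym <- peaksFor(0.5)    # anterior == posterior: parkinsonian tendency
  asym <- peaksFor(0.2)   # anterior-dominant: normal walk
  expect_true(sym$found && asym$found)
  expect_equal(sym$peak_a_amplitude, sym$peak_b_amplitude, tolerance = 0.05)
  expect_lt(asym$peak_a_amplitude, asym$peak_b_amplitude - 0.2)
  expect_lt(asym$peak_a_amplitude, sym$peak_a_amplitude)
  # the half-cycle peak sits near half the cycle lag
  expect_equal(asym$peak_a_lag_s / asym$peak_b_lag_s, 0.5, tolerance = 0.2)
})

test_that("half-cycle peak rises monotonically with half-phase similarity", {
  vals <- vapply(c(0.2, 0.3, 0.4, 0.5), function(af) {
    model <- armModel(swingAmplitude = 6, anteriorFraction = af,
                      noiseAmplitude = 0.15)
    rec <- trimSteadyState(simulateRecording(model, seed = 11))
    y <- removeOffset(channels(rec)[, "ay_low"])
    regularityPeaks(unbiasedAutocorrelation(y), 50)$peak_a_amplitude
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("a 1 Hz cycle at 50 Hz puts the cycle peak at lag 50 +- 1", {
  model <- armModel(cycleHz = 1, swingAmplitude = 6, anteriorFraction = 0.3,
                    noiseAmplitude = 0.1)
  rec <- simulateRecording(model, seed = 2)
  y <- removeOffset(channels(rec)[, "ay_low"])
  pk <- regularityPeaks(unbiasedAutocorrelation(y), 50)
  expect_equal(pk$peak_b_lag_s * 50, 50, tolerance = 1)
})

test_that("signals without a periodic structure report missing peaks", {
  set.seed(21)
  r <- unbiasedAutocorrelation(rnorm(40))   # too short for the cycle window
  pk <- regularityPeaks(r, 50)
  expect_false(pk$found)
  expect_true(is.na(pk$peak_b_amplitude))
})
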