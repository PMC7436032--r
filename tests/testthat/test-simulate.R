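test_that("simulated recordings are reproducible and valid", {
  model <- armModel(swingAmplitude = 5, tremorHz = 6, tremorAmplitude = 80,
                    noiseAmplitude = 0.5)
  r1 <- simulateRecording(model, seed = 77)
  r2 <- simulateRecording(model, seed = 77)
  expect_identical(channels(r1), channels(r2))
  expect_true(validObject(r1))
  r3 <- simulateRecording(model, seed = 78)
  expect_false(identical(channels(r1), channels(r3)))
})

test_that("the dual-sensor relation holds exactly: common mode, gravity and
           tremor cancel", {
  model <- armModel(swingAmplitude = 6, anteriorFraction = 0.35,
                    tremorHz = 7, tremorAmplitude = 150,
                    noiseAmplitude = 0, gravityOffset = c(0.2, 0.3, 0.9))
  rec <- simulateRecording(model, seed = 5)
  diff_g <- channels(rec)[, 1:3] - channels(rec)[, 4:6]
  alpha <- diff_g * 9.80665 / sensorSeparation(rec)
  expect_lt(max(abs(alpha - rec@metadata$alpha_true)), 1e-9)
  # and the noise-free cycle is visible at the expected lag
  y <- removeOffset(channels(rec)[, "ay_low"])
  pk <- regularityPeaks(unbiasedAutocorrelation(y), 50)
  expect_equal(pk$peak_b_lag_s, 1, tolerance = 0.05)
})

test_that("colored noise is standardised and its spectrum steepens with
           beta", {
  set.seed(13)
  x <- coloredNoise(4096, 2)
  expect_equal(sd(x), 1, tolerance = 1e-9)
  expect_equal(length(x), 4096L)
  # spectral slopes via the wavelet route are ordered by beta
  b_hat <- vapply(c(0.5, 1.5, 2.5), function(b) {
    mean(replicate(5, spectralSlope(waveletDetailVariances(
      coloredNoise(2048, b)))$beta))
  }, numeric(1))
  expect_true(all(diff(b_hat) > 0))
})

test_that("each simulator knob moves its targeted feature", {
  rms_of <- function(model, seed = 3) {
    rec <- trimSteadyState(simulateRecording(model, seed = seed))
    rmsAmplitude(removeOffset(accelMagnitude(angularAcceleration(rec))))
  }
  # swing amplitude -> RMS
  expect_gt(rms_of(armModel(swingAmplitude = 8, noiseAmplitude = 0.3)),
            rms_of(armModel(swingAmplitude = 4, noiseAmplitude = 0.3)))
  # amplitude ratio -> ASA
  r_big <- rms_of(armModel(swingAmplitude = 6, noiseAmplitude = 0))
  r_sml <- rms_of(armModel(swingAmplitude = 3, noiseAmplitude = 0))
  expect_gt(armSwingAsymmetry(r_big, r_sml), armSwingAsymmetry(r_big, r_big))
  # noise beta -> estimated spectral exponent (on the wrist y channel)
  beta_of <- function(nb, seed = 9) {
    model <- armModel(swingAmplitude = 5, noiseBeta = nb, noiseAmplitude = 2)
    rec <- trimSteadyState(simulateRecording(model, seed = seed))
    spectralSlope(waveletDetailVariances(
      removeOffset(channels(rec)[, "ay_low"])))$beta
  }
  expect_gt(mean(vapply(1:4, function(s) beta_of(2.6, s), numeric(1))),
            mean(vapply(1:4, function(s) beta_of(1.0, s), numeric(1))))
})

test_that("cohorts are reproducible, correctly sized and labelled", {
  scen <- referenceScenario(seed = 5)
  scen@nControl <- 3L; scen@nPatient <- 2L
  scen@trialsPerSubject <- 2L; scen@durationS <- 8
  s1 <- simulateCohort(scen)
  s2 <- simulateCohort(scen)
  expect_identical(
    lapply(s1, function(s) lapply(recordings(s), channels)),
    lapply(s2, function(s) lapply(recordings(s), channels)))
  expect_length(s1, 5L)
  grp <- vapply(s1, groupLabel, character(1))
  expect_equal(sum(grp == "control"), 3L)
  sides <- vapply(s1[grp == "patient"], affectedSide, character(1))
  expect_true(all(sides %in% c("left", "right")))
  expect_true(all(vapply(s1[grp == "control"], affectedSide,
                         character(1)) == "none"))
  # every subject has both arms x trials
  expect_true(all(vapply(s1, function(s) length(recordings(s)), integer(1))
                  == 4L))
  expect_true(all(vapply(s1, validObject, logical(1))))
})

test_that("trial length must cover at least four gait cycles", {
  expect_error(simulateRecording(armModel(cycleHz = 0.3), duration_s = 10),
               "4 gait cycles")
})

test_that("scenario YAML round trip honours overrides and rejects bad keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_control: 4", "n_patient: 3", "seed: 9",
               "duration_s: 8",
               "patient_mas:",
               "  swingAmplitude: 2.5",
               "  tremorHz: 7",
               "  tremorAmplitude: 50"), path)
  scen <- scenarioFromYaml(path)
  expect_equal(scen@nControl, 4L)
  expect_equal(scen@patientArms$mas@swingAmplitude, 2.5)
  expect_equal(scen@patientArms$mas@tremorHz, 7)
  expect_equal(scen@durationS, 8)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("control_left:", "  swinginess: 3"), bad)
  expect_error(scenarioFromYaml(bad), "swinginess")
})
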