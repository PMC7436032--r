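# shared fixtures: everything is generated in code at test time

# random but valid recording: small-amplitude noise channels around a gravity
# offset, n samples at 50 Hz
randomRecording <- function(n = 500, seed = NULL, subject = "T01",
                            arm = "left", trial = 1L, sd = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  ch <- matrix(rnorm(6 * n, sd = sd), ncol = 6)
  ch[, c(3, 6)] <- ch[, c(3, 6)] + 1   # gravity mostly on z
  WristRecording(subject, arm, trial, ch)
}

# recording whose wrist ("low") channels carry prescribed axis signals, with
# the "high" channels chosen so the dual-sensor difference is zero
recordingWithLowSignal <- function(x = NULL, y = NULL, z = NULL, n = 500,
                                   sample_rate = 50) {
  zeros <- numeric(n)
  low <- cbind(x %||% zeros, y %||% zeros, z %||% zeros)
  ch <- cbind(low, low)
  WristRecording("T01", "left", 1L, ch, sampleRate = sample_rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force unbiased autocorrelation: the O(N^2) definition, the oracle
# against which the FFT implementation is checked
bruteAutocorrelation <- function(y) {
  n <- length(y)
  raw <- vapply(0:(n - 1L), function(k)
    sum(y[seq_len(n - k)] * y[seq_len(n - k) + k]) / (n - k), numeric(1))
  raw / raw[1L]
}

# exhaustive two-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled sample to the two groups (exact null distribution of U)
bruteMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# a small two-group session list for pipeline tests (fast: short trials)
tinySessions <- function(seed = 7L, n_per_group = 3L, trials = 2L,
                         duration = 8) {
  scen <- cohortScenario(
    nControl = n_per_group, nPatient = n_per_group,
    controlArms = list(
      left = armModel(swingAmplitude = 6, noiseAmplitude = 0.4),
      right = armModel(swingAmplitude = 5.4, noiseAmplitude = 0.4)),
    patientArms = list(
      las = armModel(swingAmplitude = 4.5, anteriorFraction = 0.46,
                     tremorHz = 6, tremorAmplitude = 60,
                     noiseAmplitude = 0.4),
      mas = armModel(swingAmplitude = 3.4, anteriorFraction = 0.46,
                     tremorHz = 6, tremorAmplitude = 100,
                     noiseAmplitude = 0.4)),
    trialsPerSubject = trials, durationS = duration, seed = seed)
  simulateCohort(scen)
}
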