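#' 1/f^beta coloured noise by spectral synthesis
#'
#' Builds a real series whose power spectrum follows \eqn{1/f^\beta}:
#' Fourier amplitudes are set to \eqn{f^{-\beta/2}} with independent uniform
#' phases, the spectrum is made Hermitian and inverse-transformed, and the
#' result is standardised to unit variance. beta = 0 gives white noise,
#' beta = 2 a random-walk-like profile.
#'
#' @param n number of samples.
#' @param beta spectral exponent (>= 0).
#' @return numeric vector of length \code{n} with unit standard deviation.
#' @export
coloredNoise <- function(n, beta) {
  stopifnot(n >= 8L, is.finite(beta), beta >= 0)
  nf <- n %/% 2L
  f <- seq_len(nf) / n
  amp <- f^(-beta / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- spec
  if (n %% 2L == 0L)
    full[nf + 1L] <- complex(real = amp[nf] * sign(cos(ph[nf])))
  full[n:(n - nf + 2L)] <- Conj(spec[seq_len(nf - 1L)])
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sd(x)
}

# distances (m) from the shoulder pivot to the two wristband sensors; their
# difference is the sensor separation entering the dual-sensor difference
R_SENSOR_HIGH <- 0.55

# radial offset (m) of the sensors from the forearm's long axis; sets how
# strongly pronation-supination tremor shows up in the wrist channels
R_TREMOR <- 0.03

#' Simulate one wristband recording
#'
#' Constructs a known angular-acceleration waveform per axis and emits the
#' two sensor channels consistent with the dual-sensor geometry, so the
#' analysis-side difference recovers the injected waveform exactly in the
#' noise-free case.
#'
#' The waveform per arm is:
#' \itemize{
#'   \item Y axis: the swing harmonic - a fundamental at the step frequency
#'     (twice the gait cycle, since the wrist acceleration pattern repeats
#'     every half cycle) plus a cycle-frequency component whose relative
#'     strength \code{|2 anteriorFraction - 1|} encodes the anterior/
#'     posterior imbalance. At \code{anteriorFraction = 0.5} the component
#'     vanishes and the half-cycle autocorrelation peak equals the
#'     full-cycle one.
#'   \item X and Z axes: smaller cycle-frequency swing components.
#'   \item All axes: 1/f^beta noise scaled relative to the axis' swing
#'     amplitude.
#' }
#' Both sensors additionally see the same common-mode content: the trunk's
#' locomotor bob, broadband jostling, the static gravity projection and -
#' when the model carries one - the "coin-counting" tremor, a
#' pronation-supination oscillation about the forearm (Y) axis whose
#' tangential acceleration lies in the XZ plane and is identical at the two
#' sensors. All of it cancels in the dual-sensor difference but shapes the
#' single-sensor (energy, regularity, fractal) features, which is exactly
#' how tremor can raise a patient's high-band energy without raising the
#' swing RMS.
#'
#' @param model an [ArmModel-class].
#' @param duration_s trial length in seconds (>= 4 gait cycles).
#' @param sample_rate_hz sampling frequency.
#' @param seed optional integer seed; the same seed reproduces the recording
#'   bit for bit.
#' @param subject_id,arm,trial identifiers stamped on the recording.
#' @param sensor_separation_m distance between the two sensors.
#' @return a [WristRecording-class]; the injected angular-acceleration matrix
#'   is attached as \code{metadata$alpha_true} (rad/s^2).
#' @export
simulateRecording <- function(model, duration_s = 10, sample_rate_hz = 50,
                              seed = NULL, subject_id = "sim", arm = "left",
                              trial = 1L, sensor_separation_m = 0.1) {
  stopifnot(is(model, "ArmModel"))
  validObject(model)
  if (duration_s * model@cycleHz < 4)
    stop("trial must cover at least 4 gait cycles")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1L) / sample_rate_hz
  f <- model@cycleHz
  A <- model@swingAmplitude
  gamma <- abs(2 * model@anteriorFraction - 1)
  phase <- runif(1, 0, 2 * pi)

  # quasi-periodic cycle phase: nominal advance plus a slow random walk
  # (cycle-to-cycle timing variability)
  cyc <- 2 * pi * f * t + phase
  if (model@cycleDrift > 0)
    cyc <- cyc + cumsum(rnorm(n, 0, model@cycleDrift))

  # swing: fundamental at the step frequency + asymmetry component at the
  # cycle frequency, normalised so the RMS is independent of gamma
  y_swing <- A / sqrt(1 + gamma^2) *
    (sin(2 * cyc) + gamma * sin(cyc))
  axis_scale <- c(x = 0.45, y = 1, z = 0.30)
  x_swing <- axis_scale["x"] * A * sin(cyc + pi / 2)
  z_swing <- axis_scale["z"] * A * sin(cyc + 0.4)

  beta <- rep_len(model@noiseBeta, 3L)
  namp <- rep_len(model@noiseAmplitude, 3L)
  noise <- vapply(seq_len(3L), function(j) {
    if (namp[j] == 0 || A == 0) return(numeric(n))
    coloredNoise(n, beta[j]) * namp[j] * axis_scale[j] * A
  }, numeric(n))

  alpha <- cbind(x = x_swing + noise[, 1L],
                 y = y_swing + noise[, 2L],
                 z = z_swing + noise[, 3L])

  # "coin-counting" tremor: pronation-supination about the forearm (Y)
  # axis. Both sensors lie on that axis at the same small radial offset, so
  # the tremor's tangential acceleration (in the XZ plane) is common-mode
  # for the sensor pair: fully visible in the wrist channels, cancelled by
  # the dual-sensor difference.
  tremor_x <- tremor_z <- 0
  if (length(model@tremorHz) && model@tremorAmplitude > 0) {
    amp_g <- model@tremorAmplitude * R_TREMOR / STANDARD_GRAVITY
    tremor_x <- amp_g * sin(2 * pi * model@tremorHz * t + runif(1, 0, 2 * pi))
    tremor_z <- 0.8 * amp_g *
      sin(2 * pi * model@tremorHz * t + runif(1, 0, 2 * pi))
  }

  # common-mode translational acceleration (g), identical at both sensors:
  # the trunk's locomotor bob, broadband jostling, and the tremor above. It
  # rides on every wrist channel (and so enters the single-sensor features)
  # but cancels exactly in the dual-sensor difference.
  common <- cbind(0.08 * sin(2 * pi * f * t + phase + 1.1) +
                    0.05 * coloredNoise(n, 2) + tremor_x,
                  0.008 * sin(4 * pi * f * t + 2 * phase + 0.7) +
                    0.015 * coloredNoise(n, 2),
                  0.15 * sin(4 * pi * f * t + 2 * phase + 2.3) +
                    0.07 * coloredNoise(n, 2) + tremor_z)
  gravity <- matrix(model@gravityOffset, n, 3L, byrow = TRUE)
  r_high <- R_SENSOR_HIGH
  r_low <- r_high + sensor_separation_m
  low <- common + gravity + (r_low * alpha) / STANDARD_GRAVITY
  high <- common + gravity + (r_high * alpha) / STANDARD_GRAVITY
  ch <- cbind(low, high)
  colnames(ch) <- CHANNEL_NAMES
  WristRecording(subject_id, arm, trial, ch,
                 sampleRate = sample_rate_hz,
                 sensorSeparation = sensor_separation_m,
                 metadata = list(alpha_true = alpha))
}

#' Construct a CohortScenario
#'
#' @param nControl,nPatient group sizes (defaults 11 and 10, the scale of a
#'   single-site clinical gait study).
#' @param controlArms list of [ArmModel-class]s named \code{left},
#'   \code{right}.
#' @param patientArms list of [ArmModel-class]s named \code{las}, \code{mas}.
#' @param trialsPerSubject walking trials per subject (default 6).
#' @param durationS trial duration in seconds (default 10, a 10 m walk).
#' @param sampleRateHz sampling frequency (default 50).
#' @param seed integer RNG seed.
#' @param jitter named list of between-subject variability SDs:
#'   \code{amplitude} (lognormal sdlog, shared across arms),
#'   \code{arm_amplitude} (lognormal sdlog, per arm), \code{cadence}
#'   (normal SD of cycleHz, shared), \code{anterior} (normal SD),
#'   \code{snr} (lognormal sdlog of a subject-level multiplier on the
#'   noise amplitudes - people differ in gait smoothness),
#'   \code{noise_beta} (normal SD), \code{tremor_amplitude} (lognormal
#'   sdlog), \code{tremor_hz_range} (length-2 uniform range per subject).
#' @return a validated [CohortScenario-class].
#' @export
cohortScenario <- function(nControl = 11L, nPatient = 10L,
                           controlArms, patientArms,
                           trialsPerSubject = 6L, durationS = 10,
                           sampleRateHz = 50, seed = 1L,
                           jitter = list()) {
  jit <- modifyList(list(amplitude = 0.08, arm_amplitude = 0.04,
                         cadence = 0.06, anterior = 0.03, snr = 0.12,
                         noise_beta = 0.12, tremor_amplitude = 0.15,
                         tremor_hz_range = c(5.5, 7.5)), jitter)
  new("CohortScenario", nControl = as.integer(nControl),
      nPatient = as.integer(nPatient), controlArms = controlArms,
      patientArms = patientArms,
      trialsPerSubject = as.integer(trialsPerSubject),
      durationS = as.numeric(durationS),
      sampleRateHz = as.numeric(sampleRateHz), seed = as.integer(seed),
      jitter = jit)
}

#' Reference two-group scenario
#'
#' The default study conditions of the simulator: 11 controls and 10
#' patients, six 10 s trials at 50 Hz. Controls swing with a mild natural
#' left/right imbalance and a clear anterior-dominant half-phase; patients
#' show bilaterally reduced swing (more on the most affected side, roughly
#' doubling the asymmetry index), near-equal anterior/posterior half-phases,
#' higher cycle-to-cycle timing variability, a 5-10 Hz pronation-supination
#' tremor sized so the extra high-band energy roughly offsets the lost
#' locomotor energy, and a less steep noise spectrum on the X and Z axes
#' (more complex signals there). The groups' Y-axis noise exponents are
#' chosen so Y-axis complexity is matched between groups, the study's null
#' condition on that axis.
#'
#' @param seed integer RNG seed for the cohort.
#' @return a [CohortScenario-class].
#' @export
referenceScenario <- function(seed = 1L) {
  control_left <- armModel(cycleHz = 1.0, swingAmplitude = 6.1,
                           anteriorFraction = 0.30, cycleDrift = 0.008,
                           noiseBeta = c(1.85, 1.60, 2.10),
                           noiseAmplitude = c(1.6, 0.8, 1.6))
  control_right <- armModel(cycleHz = 1.0, swingAmplitude = 7.0,
                            anteriorFraction = 0.30, cycleDrift = 0.008,
                            noiseBeta = c(1.85, 1.60, 2.10),
                            noiseAmplitude = c(1.6, 0.8, 1.6))
  patient_las <- armModel(cycleHz = 1.0, swingAmplitude = 4.85,
                          anteriorFraction = 0.44, cycleDrift = 0.0165,
                          tremorHz = 6, tremorAmplitude = 54,
                          noiseBeta = c(1.55, 1.645, 1.75),
                          noiseAmplitude = c(2.4, 0.8, 2.4))
  patient_mas <- armModel(cycleHz = 1.0, swingAmplitude = 3.6,
                          anteriorFraction = 0.44, cycleDrift = 0.0165,
                          tremorHz = 6, tremorAmplitude = 118,
                          noiseBeta = c(1.55, 1.645, 1.75),
                          noiseAmplitude = c(2.4, 0.8, 2.4))
  cohortScenario(nControl = 11L, nPatient = 10L,
                 controlArms = list(left = control_left,
                                    right = control_right),
                 patientArms = list(las = patient_las, mas = patient_mas),
                 seed = seed, jitter = list(amplitude = 0.07))
}

# jittered copy of an arm model for one subject/arm
jitterModel <- function(model, jit, subj_amp, subj_cadence, subj_anterior,
                        subj_beta_shift, subj_snr, subj_tremor_hz,
                        subj_tremor_amp) {
  m <- model
  m@swingAmplitude <- model@swingAmplitude * subj_amp *
    rlnorm(1, 0, jit$arm_amplitude)
  m@cycleHz <- max(0.5, subj_cadence)
  m@anteriorFraction <- min(0.98, max(0.02,
    model@anteriorFraction + subj_anterior))
  m@noiseBeta <- pmin(3, pmax(0, model@noiseBeta + subj_beta_shift))
  m@noiseAmplitude <- model@noiseAmplitude * subj_snr
  if (length(model@tremorHz)) {
    m@tremorHz <- subj_tremor_hz
    m@tremorAmplitude <- model@tremorAmplitude * subj_tremor_amp
  }
  m
}

#' Simulate a full cohort
#'
#' Draws per-subject parameter jitter around the scenario's group models
#' (shared across a subject's two arms where the trait is subject-level:
#' overall amplitude, cadence, anterior balance, noise exponents, tremor
#' frequency) plus a small independent per-arm amplitude jitter, then
#' simulates every trial of every subject. Patients alternate left/right
#' affected sides. Fully reproducible from the scenario seed.
#'
#' @param scenario a [CohortScenario-class].
#' @return named list of [SubjectSession-class] objects
#'   (controls \code{C01..}, patients \code{P01..}).
#' @export
simulateCohort <- function(scenario) {
  stopifnot(is(scenario, "CohortScenario"))
  validObject(scenario)
  set.seed(scenario@seed)
  jit <- scenario@jitter
  n_total <- scenario@nControl + scenario@nPatient
  sessions <- vector("list", n_total)
  sides <- rep_len(c("left", "right"), scenario@nPatient)
  idx <- 0L
  for (g in c("control", "patient")) {
    n_g <- if (g == "control") scenario@nControl else scenario@nPatient
    for (i in seq_len(n_g)) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", if (g == "control") "C" else "P", i)
      base <- if (g == "control") scenario@controlArms else scenario@patientArms
      ref_cadence <- base[[1L]]@cycleHz
      subj_amp <- rlnorm(1, 0, jit$amplitude)
      subj_cadence <- rnorm(1, ref_cadence, jit$cadence)
      subj_anterior <- rnorm(1, 0, jit$anterior)
      subj_beta_shift <- rnorm(length(base[[1L]]@noiseBeta), 0, jit$noise_beta)
      subj_snr <- rlnorm(1, 0, jit$snr)
      subj_tremor_hz <- runif(1, jit$tremor_hz_range[1], jit$tremor_hz_range[2])
      subj_tremor_amp <- rlnorm(1, 0, jit$tremor_amplitude)
      side <- if (g == "patient") sides[i] else "none"
      arm_models <- if (g == "control") {
        list(left = base$left, right = base$right)
      } else if (side == "left") {
        list(left = base$mas, right = base$las)
      } else {
        list(left = base$las, right = base$mas)
      }
      recs <- list()
      for (a in c("left", "right")) {
        m <- jitterModel(arm_models[[a]], jit, subj_amp, subj_cadence,
                         subj_anterior, subj_beta_shift, subj_snr,
                         subj_tremor_hz, subj_tremor_amp)
        for (tr in seq_len(scenario@trialsPerSubject)) {
          recs[[length(recs) + 1L]] <- simulateRecording(
            m, duration_s = scenario@durationS,
            sample_rate_hz = scenario@sampleRateHz,
            subject_id = sid, arm = a, trial = tr)
        }
      }
      sessions[[idx]] <- SubjectSession(sid, g, recs, affectedSide = side)
    }
  }
  names(sessions) <- vapply(sessions, subjectId, character(1))
  sessions
}
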