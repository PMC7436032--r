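#' WristRecording: one arm's dual-sensor acceleration trace for one trial
#'
#' Container for a single walking trial recorded by one wristband carrying two
#' triaxial accelerometers: a "low" sensor closest to the wrist and a "high"
#' sensor mounted a fixed distance (default 0.1 m) proximal along the forearm.
#' Channels are stored in units of g, in the fixed column order
#' \code{ax_low, ay_low, az_low, ax_high, ay_high, az_high}.
#'
#' @slot subjectId character scalar, subject identifier.
#' @slot arm \code{"left"} or \code{"right"}.
#' @slot trial integer trial index (>= 1).
#' @slot sampleRate sampling frequency in Hz (> 0; wristbands record at 50 Hz).
#' @slot sensorSeparation distance between the two accelerometers in metres.
#' @slot channels numeric matrix (samples x 6) in g.
#' @slot metadata list of free-form provenance entries (e.g. applied trims).
#'
#' @seealso [WristRecording()] for the validating constructor.
#' @export
setClass("WristRecording",
  slots = c(
    subjectId = "character",
    arm = "character",
    trial = "integer",
    sampleRate = "numeric",
    sensorSeparation = "numeric",
    channels = "matrix",
    metadata = "list"
  )
)

setValidity("WristRecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "'subjectId' must be a non-empty string")
  if (length(object@arm) != 1L || !object@arm %in% c("left", "right"))
    msg <- c(msg, "'arm' must be \"left\" or \"right\"")
  if (length(object@trial) != 1L || is.na(object@trial) || object@trial < 1L)
    msg <- c(msg, "'trial' must be a positive integer")
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "'sampleRate' must be a positive number")
  if (length(object@sensorSeparation) != 1L ||
      !is.finite(object@sensorSeparation) || object@sensorSeparation <= 0)
    msg <- c(msg, "'sensorSeparation' must be a positive number")
  ch <- object@channels
  if (!is.numeric(ch) || ncol(ch) != 6L ||
      !identical(colnames(ch), CHANNEL_NAMES))
    msg <- c(msg, sprintf("'channels' must be a numeric matrix with columns %s",
                          paste(CHANNEL_NAMES, collapse = ", ")))
  else {
    if (nrow(ch) < 2L)
      msg <- c(msg, "'channels' must contain at least 2 samples")
    if (anyNA(ch) || !all(is.finite(ch)))
      msg <- c(msg, "'channels' must be finite and non-missing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WristRecording
#'
#' Validates and assembles a [WristRecording-class] object. Samples whose
#' absolute value exceeds the 3 g sensor range are flagged with a warning and
#' recorded in \code{metadata$range_exceedances}, but are not an error.
#'
#' @param subjectId subject identifier.
#' @param arm \code{"left"} or \code{"right"}.
#' @param trial trial index (>= 1).
#' @param channels numeric matrix (samples x 6) in g; columns either already
#'   named \code{ax_low ... az_high} or given in that order.
#' @param sampleRate sampling frequency in Hz.
#' @param sensorSeparation distance between the two sensors in metres.
#' @param metadata optional list of provenance entries.
#' @return a validated [WristRecording-class].
#' @examples
#' ch <- matrix(rnorm(600, sd = 0.1), ncol = 6)
#' rec <- WristRecording("S01", "left", 1, ch)
#' duration(rec)
#' @export
WristRecording <- function(subjectId, arm, trial, channels,
                           sampleRate = 50, sensorSeparation = 0.1,
                           metadata = list()) {
  channels <- as.matrix(channels)
  if (is.null(colnames(channels))) {
    if (ncol(channels) != 6L)
      stop("'channels' must have 6 columns (",
           paste(CHANNEL_NAMES, collapse = ", "), ")")
    colnames(channels) <- CHANNEL_NAMES
  } else {
    if (!all(CHANNEL_NAMES %in% colnames(channels)))
      stop("missing channel(s): ",
           paste(setdiff(CHANNEL_NAMES, colnames(channels)), collapse = ", "))
    channels <- channels[, CHANNEL_NAMES, drop = FALSE]
  }
  storage.mode(channels) <- "double"
  n_exceed <- sum(abs(channels) > SENSOR_RANGE_G)
  if (n_exceed > 0L) {
    warning(sprintf("%d sample(s) exceed the %g g sensor range; flagged",
                    n_exceed, SENSOR_RANGE_G))
    metadata$range_exceedances <- n_exceed
  }
  new("WristRecording", subjectId = as.character(subjectId),
      arm = as.character(arm), trial = as.integer(trial),
      sampleRate = as.numeric(sampleRate),
      sensorSeparation = as.numeric(sensorSeparation),
      channels = channels, metadata = metadata)
}

#' SubjectSession: all walking trials for both arms of one subject
#'
#' Groups the [WristRecording-class] objects of a single gait-analysis session
#' (by protocol, six 10 m walks per subject) together with the group label and,
#' for patients, the clinically most affected body side.
#'
#' @slot subjectId character scalar.
#' @slot group \code{"patient"} or \code{"control"}.
#' @slot affectedSide \code{"left"}, \code{"right"}, \code{"symmetric"}
#'   (patients) or \code{"none"} (controls).
#' @slot recordings list of [WristRecording-class] for this subject.
#' @export
setClass("SubjectSession",
  slots = c(
    subjectId = "character",
    group = "character",
    affectedSide = "character",
    recordings = "list"
  )
)

setValidity("SubjectSession", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "'subjectId' must be a non-empty string")
  if (!object@group %in% c("patient", "control"))
    msg <- c(msg, "'group' must be \"patient\" or \"control\"")
  if (!object@affectedSide %in% c("left", "right", "symmetric", "none"))
    msg <- c(msg, "'affectedSide' must be left/right/symmetric/none")
  if (object@group == "control" && object@affectedSide != "none")
    msg <- c(msg, "controls must have affectedSide = \"none\"")
  if (object@group == "patient" && object@affectedSide == "none")
    msg <- c(msg, "patients must have a known affectedSide")
  ok <- vapply(object@recordings, function(r) is(r, "WristRecording"), logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "'recordings' must all be WristRecording objects")
  else if (length(object@recordings)) {
    ids <- vapply(object@recordings, function(r) r@subjectId, character(1))
    if (!all(ids == object@subjectId))
      msg <- c(msg, "all recordings must belong to this subject")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SubjectSession
#'
#' @param subjectId subject identifier.
#' @param group \code{"patient"} or \code{"control"}.
#' @param recordings list of [WristRecording-class] objects for the subject.
#' @param affectedSide clinically most affected side for patients
#'   (\code{"left"}, \code{"right"} or \code{"symmetric"}); controls use the
#'   default \code{"none"}.
#' @return a validated [SubjectSession-class].
#' @export
SubjectSession <- function(subjectId, group, recordings,
                           affectedSide = "none") {
  new("SubjectSession", subjectId = as.character(subjectId),
      group = as.character(group), affectedSide = as.character(affectedSide),
      recordings = recordings)
}

#' ArmModel: generative model of one arm's swing dynamics
#'
#' Parameters of the synthetic angular-acceleration waveform used by
#' [simulateRecording()]: a quasi-periodic swing harmonic (fundamental at the
#' step frequency, i.e. twice per gait cycle, plus a cycle-frequency component
#' controlled by the anterior/posterior balance), an optional 5-10 Hz tremor
#' sinusoid confined to the XZ plane, and 1/f^beta coloured noise.
#'
#' @slot cycleHz full arm-swing (gait) cycle frequency in Hz.
#' @slot swingAmplitude peak angular acceleration of the swing, rad/s^2.
#' @slot anteriorFraction relative strength of the anterior vs posterior
#'   half-phase in (0, 1); 0.5 means the two half-phases are identical.
#' @slot cycleDrift standard deviation (radians of cycle phase per sample) of
#'   the random phase walk that makes the swing quasi-periodic rather than
#'   strictly periodic; larger values mean higher cycle-to-cycle variability.
#' @slot tremorHz tremor frequency in Hz (length 0 = no tremor; must lie in
#'   [5, 10] when present).
#' @slot tremorAmplitude peak angular acceleration of the
#'   pronation-supination tremor about the forearm axis, rad/s^2.
#' @slot noiseBeta spectral exponent of the 1/f^beta noise, length 1 or 3
#'   (per axis x, y, z), each in [0, 3].
#' @slot noiseAmplitude noise standard deviation relative to each axis'
#'   swing amplitude, length 1 or 3 (per axis x, y, z).
#' @slot gravityOffset static per-axis gravity projection in g (length 3).
#' @export
setClass("ArmModel",
  slots = c(
    cycleHz = "numeric",
    swingAmplitude = "numeric",
    anteriorFraction = "numeric",
    cycleDrift = "numeric",
    tremorHz = "numeric",
    tremorAmplitude = "numeric",
    noiseBeta = "numeric",
    noiseAmplitude = "numeric",
    gravityOffset = "numeric"
  )
)

setValidity("ArmModel", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@cycleHz) || object@cycleHz <= 0)
    msg <- c(msg, "'cycleHz' must be a positive number")
  if (!num1(object@swingAmplitude) || object@swingAmplitude < 0)
    msg <- c(msg, "'swingAmplitude' must be >= 0")
  if (!num1(object@anteriorFraction) ||
      object@anteriorFraction <= 0 || object@anteriorFraction >= 1)
    msg <- c(msg, "'anteriorFraction' must lie in (0, 1)")
  if (!num1(object@cycleDrift) || object@cycleDrift < 0)
    msg <- c(msg, "'cycleDrift' must be >= 0")
  if (length(object@tremorHz) > 1L)
    msg <- c(msg, "'tremorHz' must have length 0 or 1")
  if (length(object@tremorHz) == 1L &&
      (object@tremorHz < 5 || object@tremorHz > 10))
    msg <- c(msg, "'tremorHz' must lie in [5, 10] Hz (parkinsonian tremor band)")
  if (!num1(object@tremorAmplitude) || object@tremorAmplitude < 0)
    msg <- c(msg, "'tremorAmplitude' must be >= 0")
  if (!length(object@noiseBeta) %in% c(1L, 3L) ||
      any(!is.finite(object@noiseBeta)) ||
      any(object@noiseBeta < 0 | object@noiseBeta > 3))
    msg <- c(msg, "'noiseBeta' must be length 1 or 3 with values in [0, 3]")
  if (!length(object@noiseAmplitude) %in% c(1L, 3L) ||
      any(!is.finite(object@noiseAmplitude)) || any(object@noiseAmplitude < 0))
    msg <- c(msg, "'noiseAmplitude' must be length 1 or 3 with values >= 0")
  if (length(object@gravityOffset) != 3L || any(!is.finite(object@gravityOffset)))
    msg <- c(msg, "'gravityOffset' must be 3 finite numbers (g)")
  if (length(msg)) msg else TRUE
})

#' Construct an ArmModel
#'
#' @param cycleHz gait cycle frequency in Hz (default 1).
#' @param swingAmplitude swing peak angular acceleration in rad/s^2.
#' @param anteriorFraction anterior/posterior balance in (0, 1); 0.5 =
#'   symmetric half-phases, the parkinsonian tendency.
#' @param cycleDrift cycle-phase random-walk SD in radians per sample;
#'   parkinsonian gait shows higher cycle-to-cycle variability.
#' @param tremorHz tremor frequency in Hz, or \code{NULL} for no tremor.
#' @param tremorAmplitude peak pronation-supination angular acceleration in
#'   rad/s^2 (a 6 Hz tremor of ~10 degrees corresponds to roughly 200).
#' @param noiseBeta spectral exponent(s) of the coloured noise (length 1 or 3).
#' @param noiseAmplitude noise SD relative to the axis swing amplitude
#'   (length 1 or 3).
#' @param gravityOffset static gravity projection per axis in g.
#' @return a validated [ArmModel-class].
#' @examples
#' ctrl <- armModel(swingAmplitude = 6, anteriorFraction = 0.32)
#' pd   <- armModel(swingAmplitude = 3.5, anteriorFraction = 0.48,
#'                  tremorHz = 6, tremorAmplitude = 1.5)
#' @export
armModel <- function(cycleHz = 1.0, swingAmplitude = 6.0,
                     anteriorFraction = 0.32, cycleDrift = 0.008,
                     tremorHz = NULL,
                     tremorAmplitude = 0, noiseBeta = 2.0,
                     noiseAmplitude = 0.25,
                     gravityOffset = c(0.05, 0.10, 0.98)) {
  new("ArmModel", cycleHz = cycleHz, swingAmplitude = swingAmplitude,
      anteriorFraction = anteriorFraction, cycleDrift = cycleDrift,
      tremorHz = if (is.null(tremorHz)) numeric(0) else as.numeric(tremorHz),
      tremorAmplitude = tremorAmplitude, noiseBeta = as.numeric(noiseBeta),
      noiseAmplitude = as.numeric(noiseAmplitude),
      gravityOffset = as.numeric(gravityOffset))
}

#' CohortScenario: full specification of a simulated two-group cohort
#'
#' @slot nControl,nPatient group sizes.
#' @slot controlArms list of two [ArmModel-class]s named \code{left}, \code{right}.
#' @slot patientArms list of two [ArmModel-class]s named \code{las}, \code{mas}
#'   (less / most affected side).
#' @slot trialsPerSubject number of walking trials per subject (default 6).
#' @slot durationS trial duration in seconds (default 10).
#' @slot sampleRateHz sampling frequency (default 50).
#' @slot seed integer RNG seed making the cohort reproducible.
#' @slot jitter named list of between-subject variability parameters, see
#'   [cohortScenario()].
#' @export
setClass("CohortScenario",
  slots = c(
    nControl = "integer",
    nPatient = "integer",
    controlArms = "list",
    patientArms = "list",
    trialsPerSubject = "integer",
    durationS = "numeric",
    sampleRateHz = "numeric",
    seed = "integer",
    jitter = "list"
  )
)

setValidity("CohortScenario", function(object) {
  msg <- character()
  if (object@nControl < 1L || object@nPatient < 1L)
    msg <- c(msg, "group sizes must be >= 1")
  if (!identical(sort(names(object@controlArms)), c("left", "right")) ||
      !all(vapply(object@controlArms, function(m) is(m, "ArmModel"), logical(1))))
    msg <- c(msg, "'controlArms' must be ArmModels named left, right")
  if (!identical(sort(names(object@patientArms)), c("las", "mas")) ||
      !all(vapply(object@patientArms, function(m) is(m, "ArmModel"), logical(1))))
    msg <- c(msg, "'patientArms' must be ArmModels named las, mas")
  if (object@trialsPerSubject < 1L)
    msg <- c(msg, "'trialsPerSubject' must be >= 1")
  if (object@durationS <= 0 || object@sampleRateHz <= 0)
    msg <- c(msg, "'durationS' and 'sampleRateHz' must be positive")
  if (length(msg)) msg else TRUE
})

#' CohortTable: per-subject arm swing features after LAS/MAS relabeling
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"features"}
#' holds the arm swing variables (rows, in canonical order, see
#' [armSwingVariables()]) by subject (columns). \code{colData} carries
#' \code{subject_id}, \code{group} and \code{affected_side}.
#'
#' @seealso [buildCohort()], [compareCohort()]
#' @export
setClass("CohortTable", contains = "SummarizedExperiment")

setValidity("CohortTable", function(object) {
  msg <- character()
  if (!"features" %in% assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  else if (!identical(rownames(object), armSwingVariables()))
    msg <- c(msg, "assay rows must be the canonical arm swing variables, in order")
  cd <- colData(object)
  need <- c("subject_id", "group", "affected_side")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  else if (!all(cd$group %in% c("patient", "control")))
    msg <- c(msg, "'group' must be patient/control")
  if (length(msg)) msg else TRUE
})
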