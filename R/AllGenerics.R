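#' @rdname WristRecording-accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname WristRecording-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname WristRecording-accessors
#' @export
setGeneric("arm", function(x) standardGeneric("arm"))

#' @rdname WristRecording-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname WristRecording-accessors
#' @export
setGeneric("trialIndex", function(x) standardGeneric("trialIndex"))

#' @rdname WristRecording-accessors
#' @export
setGeneric("sensorSeparation", function(x) standardGeneric("sensorSeparation"))

#' @rdname WristRecording-accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname SubjectSession-accessors
#' @export
setGeneric("recordings", function(x) standardGeneric("recordings"))

#' @rdname SubjectSession-accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname SubjectSession-accessors
#' @export
setGeneric("affectedSide", function(x) standardGeneric("affectedSide"))

#' Accessors for WristRecording
#'
#' @param x a [WristRecording-class].
#' @return \code{channels}: the samples x 6 matrix in g; \code{sampleRate},
#'   \code{sensorSeparation}, \code{duration} (seconds): numeric scalars;
#'   \code{arm}, \code{subjectId}: character scalars; \code{trialIndex}:
#'   integer.
#' @name WristRecording-accessors
NULL

#' @rdname WristRecording-accessors
setMethod("channels", "WristRecording", function(x) x@channels)

#' @rdname WristRecording-accessors
setMethod("sampleRate", "WristRecording", function(x) x@sampleRate)

#' @rdname WristRecording-accessors
setMethod("arm", "WristRecording", function(x) x@arm)

#' @rdname WristRecording-accessors
setMethod("subjectId", "WristRecording", function(x) x@subjectId)

#' @rdname WristRecording-accessors
setMethod("trialIndex", "WristRecording", function(x) x@trial)

#' @rdname WristRecording-accessors
setMethod("sensorSeparation", "WristRecording", function(x) x@sensorSeparation)

#' @rdname WristRecording-accessors
setMethod("duration", "WristRecording",
          function(x) nrow(x@channels) / x@sampleRate)

setMethod("show", "WristRecording", function(object) {
  cat(sprintf("WristRecording '%s' %s arm, trial %d\n", object@subjectId,
              object@arm, object@trial))
  cat(sprintf("  %d samples @ %g Hz (%.2f s), sensor separation %g m\n",
              nrow(object@channels), object@sampleRate,
              duration(object), object@sensorSeparation))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Accessors for SubjectSession
#'
#' @param x a [SubjectSession-class].
#' @return \code{recordings}: list of [WristRecording-class]; \code{groupLabel},
#'   \code{affectedSide}, \code{subjectId}: character scalars.
#' @name SubjectSession-accessors
NULL

#' @rdname SubjectSession-accessors
setMethod("recordings", "SubjectSession", function(x) x@recordings)

#' @rdname SubjectSession-accessors
setMethod("groupLabel", "SubjectSession", function(x) x@group)

#' @rdname SubjectSession-accessors
setMethod("affectedSide", "SubjectSession", function(x) x@affectedSide)

#' @rdname SubjectSession-accessors
setMethod("subjectId", "SubjectSession", function(x) x@subjectId)

setMethod("show", "SubjectSession", function(object) {
  arms <- vapply(object@recordings, function(r) r@arm, character(1))
  cat(sprintf("SubjectSession '%s' (%s, affected side: %s)\n",
              object@subjectId, object@group, object@affectedSide))
  cat(sprintf("  %d recordings (%d left, %d right)\n",
              length(arms), sum(arms == "left"), sum(arms == "right")))
})

setMethod("show", "ArmModel", function(object) {
  cat(sprintf("ArmModel: %.2f Hz cycle, swing %.2f rad/s^2, anterior %.2f\n",
              object@cycleHz, object@swingAmplitude, object@anteriorFraction))
  if (length(object@tremorHz))
    cat(sprintf("  tremor %.1f Hz, amplitude %.2f rad/s^2\n",
                object@tremorHz, object@tremorAmplitude))
  cat(sprintf("  noise beta %s (relative amplitude %.2f)\n",
              paste(format(object@noiseBeta), collapse = "/"),
              object@noiseAmplitude))
})

setMethod("show", "CohortScenario", function(object) {
  cat(sprintf("CohortScenario: %d controls, %d patients, %d trials x %g s @ %g Hz (seed %d)\n",
              object@nControl, object@nPatient, object@trialsPerSubject,
              object@durationS, object@sampleRateHz, object@seed))
})
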