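#' Trim a recording to its steady-state portion
#'
#' Removes the first \code{head_s} and last \code{tail_s} seconds of a trial.
#' Walking along a short aisle includes gait-initiation and stopping
#' transients; features are meant to describe steady-state swing, so a small
#' symmetric trim (default 1 s each side of a 10 m walk) is applied before
#' feature extraction. Sample values are never altered, only the extent.
#'
#' @param rec a [WristRecording-class].
#' @param head_s seconds to drop from the start (>= 0).
#' @param tail_s seconds to drop from the end (>= 0).
#' @return the trimmed [WristRecording-class]; \code{metadata$trim} records
#'   the cumulative trim applied.
#' @examples
#' ch <- matrix(rnorm(3600, sd = 0.1), ncol = 6)
#' rec <- WristRecording("S01", "left", 1, ch)  # 12 s at 50 Hz
#' duration(trimSteadyState(rec, 1, 1))         # 10 s
#' @export
trimSteadyState <- function(rec, head_s = 1, tail_s = 1) {
  stopifnot(is(rec, "WristRecording"), head_s >= 0, tail_s >= 0)
  if (head_s == 0 && tail_s == 0) return(rec)
  n <- nrow(rec@channels)
  fs <- rec@sampleRate
  drop_head <- round(head_s * fs)
  drop_tail <- round(tail_s * fs)
  if (drop_head + drop_tail >= n - 1L)
    stop(sprintf("over-trimming: %g + %g s leaves fewer than 2 of %d samples",
                 head_s, tail_s, n))
  kept <- rec@channels[(drop_head + 1L):(n - drop_tail), , drop = FALSE]
  prev <- rec@metadata$trim %||% c(head_s = 0, tail_s = 0)
  rec@metadata$trim <- c(head_s = unname(prev["head_s"]) + head_s,
                         tail_s = unname(prev["tail_s"]) + tail_s)
  rec@channels <- kept
  validObject(rec)
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove the constant offset from a signal
#'
#' Subtracts the arithmetic mean, centring the series at zero. Accelerometer
#' channels carry the gravity projection as a near-constant offset; removing
#' the mean over the (trimmed) trial is the minimal way to take it out before
#' RMS, autocorrelation, spectral and wavelet analysis. Idempotent, and a
#' constant series maps to all zeros.
#'
#' @param x numeric vector (length >= 2) or matrix (columns centred
#'   independently).
#' @return the centred vector/matrix.
#' @examples
#' removeOffset(c(1, 1, 1, 1))
#' @export
removeOffset <- function(x) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) >= 2)
    return(sweep(x, 2L, colMeans(x)))
  }
  stopifnot(is.numeric(x), length(x) >= 2)
  x - mean(x)
}
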