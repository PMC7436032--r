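#' Angular acceleration from the dual-sensor difference
#'
#' Two accelerometers a known distance L apart on the same forearm measure the
#' same translational and gravitational acceleration but different tangential
#' components; their samplewise difference divided by L isolates the angular
#' acceleration of the arm about its pivot,
#' \code{alpha = (A_low - A_high) / L} per axis, cancelling common-mode
#' content exactly. Channels stored in g are converted to m/s^2 first, so the
#' result is in rad/s^2.
#'
#' @param rec a [WristRecording-class].
#' @return numeric matrix (samples x 3) with columns \code{x}, \code{y},
#'   \code{z} in rad/s^2; the sampling rate is attached as attribute
#'   \code{sample_rate_hz}.
#' @examples
#' ch <- matrix(0, 100, 6); ch[, 2] <- 0.1; ch[, 5] <- 0.0  # ay differs
#' rec <- WristRecording("S01", "left", 1, ch)
#' head(angularAcceleration(rec))  # ay column = 0.1 g * 9.80665 / 0.1 m
#' @export
angularAcceleration <- function(rec) {
  stopifnot(is(rec, "WristRecording"))
  L <- rec@sensorSeparation
  if (L <= 0) stop("sensor separation must be positive")
  ch <- rec@channels
  low <- ch[, c("ax_low", "ay_low", "az_low"), drop = FALSE]
  high <- ch[, c("ax_high", "ay_high", "az_high"), drop = FALSE]
  alpha <- (low - high) * STANDARD_GRAVITY / L
  colnames(alpha) <- c("x", "y", "z")
  attr(alpha, "sample_rate_hz") <- rec@sampleRate
  alpha
}

#' Euclidean magnitude of a triaxial series
#'
#' Samplewise Euclidean norm across the three axes; invariant to axis
#' permutation, and reduces to the absolute value for a single-axis signal.
#'
#' @param series numeric matrix with 3 columns (x, y, z).
#' @return numeric vector of samplewise magnitudes.
#' @export
accelMagnitude <- function(series) {
  series <- as.matrix(series)
  stopifnot(is.numeric(series), ncol(series) == 3L)
  sqrt(rowSums(series^2))
}

#' Root mean square of a signal
#'
#' @param x non-empty numeric vector.
#' @return \code{sqrt(mean(x^2))}.
#' @export
rmsAmplitude <- function(x) {
  if (length(x) == 0L) stop("cannot take the RMS of an empty signal")
  stopifnot(is.numeric(x), all(is.finite(x)))
  sqrt(mean(x^2))
}

#' Arm swing asymmetry (ASA) index
#'
#' Maps the ratio of the two arms' RMS angular-acceleration magnitudes to a
#' percentage:
#' \deqn{ASA = \frac{45^\circ - \arctan(RMS_{min}/RMS_{max})}{45^\circ}
#'   \times 100}
#' with the minimum and maximum assigned internally, so the index is symmetric
#' in its arguments and scale-invariant. 0 means perfectly symmetric swing
#' (equal RMS); 100 means one arm does not swing at all.
#'
#' @param rms_a,rms_b non-negative RMS values of the two arms (vectorised;
#'   recycled to common length).
#' @return ASA percentage(s) in [0, 100].
#' @examples
#' armSwingAsymmetry(5, 5)            # 0
#' armSwingAsymmetry(0, 5)            # 100
#' armSwingAsymmetry(tan(pi / 8) * 5, 5)  # 50
#' @export
armSwingAsymmetry <- function(rms_a, rms_b) {
  stopifnot(is.numeric(rms_a), is.numeric(rms_b),
            all(rms_a >= 0), all(rms_b >= 0))
  lo <- pmin(rms_a, rms_b)
  hi <- pmax(rms_a, rms_b)
  if (any(hi == 0))
    stop("ASA is undefined when both RMS values are zero")
  (45 - atan(lo / hi) * 180 / pi) / 45 * 100
}
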