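#' Combined one-sided FFT magnitude of the wrist sensor
#'
#' Computes the one-sided amplitude spectrum of each axis of the
#' wrist-proximal ("low") accelerometer after offset removal, and combines the
#' three per-axis magnitudes at each frequency by their Euclidean norm, so the
#' spectrum does not depend on how the movement is oriented across the axes.
#'
#' The per-axis amplitude at bin k is \code{2 |X_k| / N} (1x for the DC and
#' Nyquist bins), i.e. a sinusoid of amplitude A yields a spectral line of
#' height A. No window is applied by default; a Hann window is available for
#' leakage-sensitive uses.
#'
#' @param rec a [WristRecording-class], at least 2 s long (shorter trials
#'   cannot resolve the 2.5 Hz band edges).
#' @param window \code{"rect"} (default) or \code{"hann"}.
#' @param measure \code{"amplitude"} (default) combines per-axis magnitudes;
#'   \code{"power"} combines their squares (sum across axes).
#' @return data.frame with columns \code{frequency_hz} and \code{value}
#'   (combined magnitude, or power), plus attribute \code{resolution_hz}.
#' @export
combinedSpectrum <- function(rec, window = c("rect", "hann"),
                             measure = c("amplitude", "power")) {
  stopifnot(is(rec, "WristRecording"))
  window <- match.arg(window)
  measure <- match.arg(measure)
  if (duration(rec) < 2)
    stop("recording shorter than 2 s: spectral resolution too coarse for the energy bands")
  x <- removeOffset(rec@channels[, c("ax_low", "ay_low", "az_low"),
                                 drop = FALSE])
  n <- nrow(x)
  if (window == "hann")
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
  n_half <- n %/% 2L
  keep <- seq_len(n_half + 1L)                  # bins 0 .. floor(n/2)
  scale <- rep(2 / n, n_half + 1L)
  scale[1L] <- 1 / n                            # DC
  if (n %% 2L == 0L) scale[n_half + 1L] <- 1 / n  # Nyquist
  amp <- vapply(seq_len(3L),
                function(j) Mod(fft(x[, j]))[keep] * scale,
                numeric(n_half + 1L))
  value <- if (measure == "amplitude") sqrt(rowSums(amp^2)) else rowSums(amp^2)
  res <- rec@sampleRate / n
  out <- data.frame(frequency_hz = (keep - 1L) * res, value = value)
  attr(out, "resolution_hz") <- res
  attr(out, "measure") <- measure
  out
}

#' Sum spectral components over a frequency band
#'
#' Sums the combined spectral values at frequencies \code{band[1] <= f <
#' band[2]} (half-open, so adjacent bands partition the axis without double
#' counting); set \code{include_upper = TRUE} for the topmost band so the
#' partition closes at its upper edge.
#'
#' @param spectrum data.frame from [combinedSpectrum()].
#' @param band numeric length-2 interval in Hz, \code{band[1] < band[2]}.
#' @param include_upper include components at exactly \code{band[2]}.
#' @return the band energy (non-negative scalar).
#' @export
bandEnergy <- function(spectrum, band, include_upper = FALSE) {
  stopifnot(is.data.frame(spectrum),
            all(c("frequency_hz", "value") %in% colnames(spectrum)),
            length(band) == 2L)
  if (band[1] >= band[2]) stop("inverted band: lower edge must be below upper")
  f <- spectrum$frequency_hz
  sel <- f >= band[1] & (if (include_upper) f <= band[2] else f < band[2])
  sum(spectrum$value[sel])
}

#' Per-trial energy-band features
#'
#' Splits the combined spectrum of one recording into low / mid / high bands
#' (defaults 0-2.5, 2.5-5 and 5-10 Hz) plus the total over the full 0-10 Hz
#' span. Normal arm swing concentrates in the low band (cycle ~1 Hz and its
#' harmonics); parkinsonian tremor appears in the 5-10 Hz high band. The
#' bands are half-open with the top edge closed, so low + mid + high = total
#' exactly.
#'
#' @param rec a [WristRecording-class].
#' @param band_edges_hz increasing edges of the bands (default
#'   \code{c(0, 2.5, 5, 10)}).
#' @param window,measure passed to [combinedSpectrum()].
#' @return named numeric vector \code{low}, \code{mid}, \code{high},
#'   \code{total} (band names generalise to \code{band1..k} for non-default
#'   edge counts).
#' @export
trialBandEnergies <- function(rec, band_edges_hz = c(0, 2.5, 5, 10),
                              window = "rect", measure = "amplitude") {
  stopifnot(length(band_edges_hz) >= 2L, !is.unsorted(band_edges_hz, strictly = TRUE))
  spec <- combinedSpectrum(rec, window = window, measure = measure)
  k <- length(band_edges_hz) - 1L
  vals <- vapply(seq_len(k), function(i)
    bandEnergy(spec, band_edges_hz[c(i, i + 1L)], include_upper = (i == k)),
    numeric(1))
  names(vals) <- if (k == 3L) c("low", "mid", "high") else paste0("band", seq_len(k))
  total <- bandEnergy(spec, range(band_edges_hz), include_upper = TRUE)
  c(vals, total = total)
}
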