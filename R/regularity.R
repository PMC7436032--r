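#' Normalized unbiased autocorrelation
#'
#' Estimates the autocorrelation of a (quasi-periodic, offset-removed) signal
#' with the unbiased lag-dependent normalisation
#' \deqn{r(k) = \frac{1}{N-k} \sum_{t=1}^{N-k} y_t\, y_{t+k}}
#' and then divides by \eqn{r(0)} so the zero-lag value is exactly 1. The
#' division by \eqn{N-k} keeps long-lag peaks comparable to short-lag peaks at
#' the cost of inflated variance near \eqn{k = N}; peak searches therefore
#' stay below \eqn{N/2} (see [regularityPeaks()]).
#'
#' Computed via FFT (circular correlation on a zero-padded grid), which is
#' algebraically identical to the direct sum.
#'
#' @param y numeric vector, length >= 4, with its constant offset already
#'   removed (see [removeOffset()]).
#' @return numeric vector \code{r} over lags \code{0 .. N-1};
#'   \code{r[1] == 1}.
#' @export
unbiasedAutocorrelation <- function(y) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  n <- length(y)
  if (n < 4L) stop("need at least 4 samples for an autocorrelation estimate")
  if (var(y) == 0)
    stop("zero-variance signal: autocorrelation normalisation is undefined")
  m <- stats::nextn(2L * n, 2)
  fy <- fft(c(y, numeric(m - n)))
  s <- Re(fft(fy * Conj(fy), inverse = TRUE)) / m
  raw <- s[seq_len(n)] / (n - 0:(n - 1L))
  raw / raw[1L]
}

#' Locate the half-cycle and full-cycle regularity peaks
#'
#' In the autocorrelation of the wrist Y-axis signal, the highest local
#' maximum whose lag falls inside the expected arm-swing cycle duration
#' (default 0.6-2 s) marks the full swing cycle ("peak B": arm swing cycle
#' regularity), and the highest local maximum near half that lag (default
#' 0.25-0.75 of it) marks the posterior-anterior half-phase ("peak A"). In
#' normal gait the anterior swing exceeds the posterior one, so the
#' half-cycle correlation is clearly below the full-cycle one; when the two
#' half-phases become alike - the parkinsonian tendency - peak A approaches
#' peak B.
#'
#' A local maximum is strictly greater than its left neighbour and at least
#' its right neighbour (plateau ties resolve to the smaller lag). Lags above
#' half the signal length are never searched because the unbiased estimator's
#' variance grows without bound there.
#'
#' @param r autocorrelation from [unbiasedAutocorrelation()].
#' @param sample_rate_hz sampling frequency in Hz.
#' @param cycle_bounds_s lag window (s) searched for the full-cycle peak.
#' @param a_window_fraction fractions of the cycle-peak lag bounding the
#'   half-cycle search.
#' @return list with \code{peak_a_amplitude}, \code{peak_a_lag_s},
#'   \code{peak_b_amplitude}, \code{peak_b_lag_s} (all \code{NA} if no local
#'   maximum exists in the respective window, with \code{found = FALSE}),
#'   \code{found}, and the input \code{autocorrelation}.
#' @export
regularityPeaks <- function(r, sample_rate_hz,
                            cycle_bounds_s = c(0.6, 2.0),
                            a_window_fraction = c(0.25, 0.75)) {
  stopifnot(is.numeric(r), length(r) >= 8L, sample_rate_hz > 0,
            length(cycle_bounds_s) == 2L, cycle_bounds_s[1] < cycle_bounds_s[2],
            length(a_window_fraction) == 2L,
            a_window_fraction[1] < a_window_fraction[2])
  if (abs(r[1L] - 1) > 1e-8)
    stop("'r' must be normalised (r[lag 0] == 1)")
  n <- length(r)
  max_lag <- (n - 1L) %/% 2L
  lags <- seq_len(max_lag)          # in samples; r index = lag + 1
  vals <- r[lags + 1L]
  is_max <- c(FALSE, vals[-c(1L, length(vals))] > vals[-c(length(vals) - 1L, length(vals))] &
                vals[-c(1L, length(vals))] >= vals[-(1:2)], FALSE)
  pick <- function(window_lags) {
    cand <- which(is_max & lags >= window_lags[1] & lags <= window_lags[2])
    if (!length(cand)) return(NULL)
    cand[which.max(vals[cand])]
  }
  out <- list(peak_a_amplitude = NA_real_, peak_a_lag_s = NA_real_,
              peak_b_amplitude = NA_real_, peak_b_lag_s = NA_real_,
              found = FALSE, autocorrelation = r)
  b_idx <- pick(round(cycle_bounds_s * sample_rate_hz))
  if (is.null(b_idx)) return(out)
  b_lag <- lags[b_idx]
  a_idx <- pick(c(ceiling(a_window_fraction[1] * b_lag),
                  floor(a_window_fraction[2] * b_lag)))
  if (is.null(a_idx)) return(out)
  out$peak_b_amplitude <- vals[b_idx]
  out$peak_b_lag_s <- b_lag / sample_rate_hz
  out$peak_a_amplitude <- vals[a_idx]
  out$peak_a_lag_s <- lags[a_idx] / sample_rate_hz
  out$found <- TRUE
  out
}
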