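# Daubechies 4 (db4, 8-tap, 4 vanishing moments) orthonormal filter bank,
# decomposition and reconstruction, ascending index
DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                 0.7148465705529157, 0.2303778133088965)
DB4_DEC_HI <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.027983769416859854,
                 0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)
DB4_REC_LO <- rev(DB4_DEC_LO)
DB4_REC_HI <- c(-0.010597401785069032, -0.0328830116668852,
                 0.030841381835560764, 0.18703481171909309,
                -0.027983769416859854, -0.6308807679298589,
                 0.7148465705529157, -0.2303778133088965)

# one analysis step: symmetric (half-sample) boundary extension, filter,
# dyadic downsample; output length floor((n + L - 1) / 2)
dwtStep <- function(x) {
  L <- 8L
  n <- length(x)
  ext <- c(rev(x[seq_len(L - 1L)]), x, rev(x)[seq_len(L - 1L)])
  nout <- (n + L - 1L) %/% 2L
  idx <- (L + 1L) + 2L * (seq_len(nout) - 1L)
  list(a = convolve(ext, rev(DB4_DEC_LO), type = "open")[idx],
       d = convolve(ext, rev(DB4_DEC_HI), type = "open")[idx])
}

# one synthesis step: upsample, filter, sum branches, crop the L-2 boundary
# samples on each side
idwtStep <- function(a, d) {
  L <- 8L
  nc <- length(a)
  up <- function(cf) {
    u <- numeric(2L * nc)
    u[seq(1L, 2L * nc, 2L)] <- cf
    u
  }
  y <- convolve(up(a), rev(DB4_REC_LO), type = "open") +
       convolve(up(d), rev(DB4_REC_HI), type = "open")
  y[(L - 1L):(L - 2L + 2L * nc - L + 2L)]
}

# multilevel analysis: list of detail coefficient vectors (level 1..levels)
# plus the final approximation
db4Decompose <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwtStep(a)
    details[[j]] <- s$d
    a <- s$a
  }
  list(details = details, approximation = a)
}

# reconstruct the level-j detail signal alone (all other branches zeroed)
db4DetailSignal <- function(decomp, j, n_target) {
  a <- numeric(length(decomp$details[[j]]))
  y <- idwtStep(a, decomp$details[[j]])
  if (j > 1L) {
    for (k in (j - 1L):1L) {
      y <- y[seq_len(length(decomp$details[[k]]))]
      y <- idwtStep(y, numeric(length(y)))
    }
  }
  y[seq_len(n_target)]
}

#' Wavelet detail variances of a signal
#'
#' Decomposes one accelerometer axis with the Daubechies-4 (db4) discrete
#' wavelet transform (symmetric boundary extension) and returns the variance
#' of the detail coefficients at each level 1..\code{levels}. Level j spans
#' the dyadic frequency band \eqn{f_s/2^{j+1} < f < f_s/2^j}, so for a
#' 1/f^beta process the per-level log2 variance grows linearly in j with
#' slope beta - the basis of the spectral-exponent estimate in
#' [spectralSlope()].
#'
#' @param x numeric vector, offset-removed; length must be at least
#'   \code{2^levels * 8} samples so the deepest level retains more
#'   coefficients than the filter support.
#' @param levels number of detail levels (default 5).
#' @param variance_target \code{"coefficients"} (default; the standard
#'   wavelet-variance estimator) or \code{"reconstructed"} (variance of the
#'   reconstructed per-level detail signals).
#' @return list with \code{level} (1..levels), \code{variance},
#'   \code{wavelet} (\code{"db4"}), \code{n}; class
#'   \code{"wavelet_variance_profile"}.
#' @export
waveletDetailVariances <- function(x, levels = 5L,
                                   variance_target = c("coefficients",
                                                       "reconstructed")) {
  variance_target <- match.arg(variance_target)
  stopifnot(is.numeric(x), all(is.finite(x)), levels >= 1L)
  min_len <- 2L^levels * 8L
  if (length(x) < min_len)
    stop(sprintf("signal too short for %d wavelet levels: need >= %d samples, got %d",
                 levels, min_len, length(x)))
  decomp <- db4Decompose(x, levels)
  v <- if (variance_target == "coefficients") {
    vapply(decomp$details, var, numeric(1))
  } else {
    vapply(seq_len(levels),
           function(j) var(db4DetailSignal(decomp, j, length(x))),
           numeric(1))
  }
  if (any(v <= 0))
    stop("degenerate decomposition: zero variance at level(s) ",
         paste(which(v <= 0), collapse = ", "))
  structure(list(level = seq_len(levels), variance = v, wavelet = "db4",
                 n = length(x)),
            class = "wavelet_variance_profile")
}

#' Spectral exponent from a wavelet variance profile
#'
#' Fits \code{log2(variance)} against decomposition level by ordinary least
#' squares; the slope is the spectral exponent beta of the 1/f^beta
#' power-spectrum model. White noise has equal per-level coefficient
#' variances and hence beta ~ 0; smoother (more strongly low-frequency)
#' signals have variance rising with level and hence larger beta.
#'
#' @param profile a \code{wavelet_variance_profile} from
#'   [waveletDetailVariances()].
#' @return list with \code{beta} (slope), \code{r2} (fit quality) and
#'   \code{intercept}.
#' @export
spectralSlope <- function(profile) {
  stopifnot(inherits(profile, "wavelet_variance_profile"))
  if (any(profile$variance <= 0))
    stop("spectral slope requires strictly positive level variances")
  fit <- lm(log2(profile$variance) ~ profile$level)
  ss_tot <- sum((log2(profile$variance) - mean(log2(profile$variance)))^2)
  r2 <- if (ss_tot < .Machine$double.eps) 1
        else 1 - sum(residuals(fit)^2) / ss_tot
  list(beta = unname(coef(fit)[2L]), r2 = r2,
       intercept = unname(coef(fit)[1L]))
}

#' Fractal dimension from the spectral exponent
#'
#' Converts the spectral exponent beta of the 1/f^beta model to the Hurst
#' exponent \eqn{H = (\beta - 1)/2} and the fractal dimension
#' \eqn{D = 2 - H}. A fractal profile has 1 < D < 2: D near 1 (beta near 3)
#' is a smooth signal, D near 2 (beta near 1) a complex one. Estimates
#' outside that range are reported as-is with \code{in_range = FALSE} rather
#' than clipped - the range is a property of the model, not a projection
#' rule.
#'
#' @param beta spectral exponent (slope from [spectralSlope()]).
#' @param r2 optional fit quality carried through.
#' @return list with \code{beta}, \code{hurst}, \code{dimension},
#'   \code{in_range}, \code{r2}; the identities \code{dimension + hurst == 2}
#'   and \code{beta == 2 * hurst + 1} hold exactly.
#' @examples
#' fractalDimension(2.01)$dimension  # 1.495
#' fractalDimension(3)$dimension     # 1 (smooth limit)
#' fractalDimension(1)$dimension     # 2 (complex limit)
#' @export
fractalDimension <- function(beta, r2 = NA_real_) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  hurst <- (beta - 1) / 2
  dimension <- 2 - hurst
  list(beta = beta, hurst = hurst, dimension = dimension,
       in_range = (dimension > 1 && dimension < 2), r2 = r2)
}

#' Per-axis fractal dimension of one recording
#'
#' Convenience wrapper: offset removal, db4 variance profile, spectral slope
#' and dimension for each axis of the wrist-proximal sensor.
#'
#' @param rec a [WristRecording-class].
#' @param levels,variance_target passed to [waveletDetailVariances()].
#' @return named list with elements \code{x}, \code{y}, \code{z}, each a
#'   [fractalDimension()] result.
#' @export
trialFractalDimensions <- function(rec, levels = 5L,
                                   variance_target = "coefficients") {
  stopifnot(is(rec, "WristRecording"))
  low <- rec@channels[, c("ax_low", "ay_low", "az_low"), drop = FALSE]
  out <- lapply(seq_len(3L), function(j) {
    prof <- waveletDetailVariances(removeOffset(low[, j]), levels = levels,
                                   variance_target = variance_target)
    sl <- spectralSlope(prof)
    fractalDimension(sl$beta, sl$r2)
  })
  names(out) <- c("x", "y", "z")
  out
}
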