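#' Parameters of the stochastic tone envelopes
#'
#' Each tone of the scene is amplitude-modulated by an independent (or, for
#' the coherent figure, shared) random envelope: half-wave rectified and
#' smoothed band-limited noise. The default 4-24 Hz band overlaps typical
#' speech envelope rates.
#'
#' @param band_lo,band_hi edges of the noise band in Hz.
#' @param smoothing_cutoff half-power cutoff in Hz of the Gaussian smoother
#'   applied after rectification.
#' @param sample_rate sample rate in Hz.
#' @param normalization_target RMS to which each envelope realization is
#'   normalized (dimensionless).
#' @return list of class `envelope_params`.
#' @export
envelope_params <- function(band_lo = 4, band_hi = 24, smoothing_cutoff = 24,
                            sample_rate = 48000, normalization_target = 1) {
  if (!(band_lo > 0 && band_hi > band_lo && band_hi < sample_rate / 2)) {
    stop("need 0 < band_lo < band_hi < sample_rate/2")
  }
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 smoothing_cutoff = smoothing_cutoff,
                 sample_rate = sample_rate,
                 normalization_target = normalization_target),
            class = "envelope_params")
}

# FFT frequency axis (Hz) of an n-point transform at rate fs; negative
# frequencies are represented by their absolute value.
fft_freqs <- function(n, fs) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n == 1) k <- 0
  abs(k[seq_len(n)]) * fs / n
}

#' Band-limited Gaussian noise (pre-rectification envelope stage)
#'
#' Spectrally flat Gaussian noise restricted to `[band_lo, band_hi]` Hz by a
#' zero-phase brick-wall FFT mask, normalized to unit RMS. This is the
#' stage of envelope synthesis before half-wave rectification; it is
#' exported so the band limitation can be verified directly.
#'
#' @param params an [envelope_params()] object.
#' @param duration duration in s (> 0).
#' @param seed optional integer seed (reproducible realizations).
#' @return numeric vector of `round(duration * sample_rate)` samples.
#' @export
band_limited_noise <- function(params, duration, seed = NULL) {
  if (duration <= 0) stop("`duration` must be positive")
  n <- round(duration * params$sample_rate)
  x <- with_seed(seed, stats::rnorm(n))
  f <- fft_freqs(n, params$sample_rate)
  keep <- f >= params$band_lo & f <= params$band_hi
  if (!any(keep)) stop("noise band contains no FFT bins at this duration")
  X <- stats::fft(x)
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / rms(y)
}

# Zero-phase Gaussian low-pass smoother (half-power point at `cutoff` Hz),
# applied in the frequency domain; accepts a vector or a column matrix.
# The impulse response is a positive Gaussian kernel, so nonnegative inputs
# stay nonnegative (up to rounding).
gaussian_lowpass <- function(x, fs, cutoff) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  H <- 2^(-(fft_freqs(n, fs) / cutoff)^2 / 2)
  y <- Re(stats::mvfft(stats::mvfft(x) * H, inverse = TRUE)) / n
  if (vec) drop(y) else y
}

# Exact trigonometric (FFT zero-padding) resampling of the columns of `x`
# to `n_out` rows.
fft_resample <- function(x, n_out) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  m <- nrow(x)
  if (n_out == m) return(if (vec) drop(x) else x)
  if (n_out < m) stop("fft_resample only upsamples")
  C <- stats::mvfft(x)
  Y <- matrix(0 + 0i, n_out, ncol(x))
  h <- floor(m / 2)
  Y[1:(h + 1), ] <- C[1:(h + 1), ]
  if (h > 0) Y[(n_out - h + 1):n_out, ] <- C[(m - h + 1):m, ]
  if (m %% 2 == 0) {   # split the Nyquist bin
    Y[h + 1, ] <- Y[h + 1, ] / 2
    Y[n_out - h + 1, ] <- Y[n_out - h + 1, ] + C[h + 1, ] / 2
  }
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / m
  if (vec) drop(y) else y
}

# Batched envelope synthesis: `cols` independent realizations as columns of
# an n x cols matrix, drawn from the current RNG state (column-major).
# The noise -> rectify -> smooth chain runs at a reduced internal rate
# (the smoothed envelope is band-limited far below it) and is then
# resampled exactly to the audio rate; FFT lengths are kept 2-3-5 smooth.
synth_envelope_mat <- function(params, duration, cols,
                               decimation = 32) {
  if (duration <= 0) stop("`duration` must be positive")
  fs <- params$sample_rate
  n <- round(duration * fs)
  fac <- decimation
  while (fac > 1 && fs / fac < 8 * params$smoothing_cutoff) fac <- fac / 2
  np <- fac * stats::nextn(ceiling(n / fac), c(2, 3, 5))
  m <- np / fac
  rs <- fs * m / np  # internal synthesis rate
  f <- fft_freqs(m, rs)
  keep <- f >= params$band_lo & f <= params$band_hi
  if (!any(keep)) stop("noise band contains no FFT bins at this duration")
  X <- stats::mvfft(matrix(stats::rnorm(m * cols), m, cols))
  X[!keep, ] <- 0
  y <- Re(stats::mvfft(X, inverse = TRUE)) / m
  env <- gaussian_lowpass(pmax(y, 0), rs, params$smoothing_cutoff)
  env <- pmax(if (np > m) fft_resample(env, np) else env, 0)
  env <- env[seq_len(n), , drop = FALSE]
  scale <- params$normalization_target / sqrt(colMeans(env^2))
  env * rep(scale, each = n)
}

#' Synthesize one stochastic envelope realization
#'
#' Gaussian white noise is band-limited to `[band_lo, band_hi]` Hz
#' (zero-phase), half-wave rectified, smoothed with a Gaussian low-pass at
#' `smoothing_cutoff`, and RMS-normalized to `normalization_target`. The
#' result is nonnegative and bit-reproducible under a fixed seed.
#'
#' @inheritParams band_limited_noise
#' @return numeric envelope vector (nonnegative).
#' @export
synth_envelope <- function(params, duration, seed = NULL) {
  with_seed(seed, drop(synth_envelope_mat(params, duration, 1)))
}
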