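#' Constants of the ERB-number (cochlear-tuning) scale
#'
#' The equivalent-rectangular-bandwidth (ERB) number scale maps frequency to
#' units of psychophysically estimated cochlear filter bandwidths. The
#' moderate-level constants used here come from the notched-noise
#' (simultaneous masking) literature: ERB-number
#' \eqn{E(f) = s \log_{10}(c f_{kHz} + 1)} with \eqn{s = 21.4} and
#' \eqn{c = 4.37\,\mathrm{kHz}^{-1}}, and bandwidth
#' \eqn{\mathrm{ERB}(f) = b (c f_{kHz} + 1)} Hz with \eqn{b = 24.7}.
#' Alternative calibrations can be supplied by overriding the constants.
#'
#' @param scale dimensionless scale factor of the ERB-number mapping.
#' @param freq_coef frequency coefficient in 1/kHz.
#' @param bw_scale bandwidth scale in Hz.
#' @return a list of class `erb_scale_params`.
#' @export
erb_scale_params <- function(scale = 21.4, freq_coef = 4.37, bw_scale = 24.7) {
  stopifnot(scale > 0, freq_coef > 0, bw_scale > 0)
  structure(list(scale = scale, freq_coef = freq_coef, bw_scale = bw_scale),
            class = "erb_scale_params")
}

#' ERB-number of a frequency
#'
#' Strictly increasing mapping from frequency (Hz) to ERB-number
#' (dimensionless). `erb_number(1000)` is about 15.62.
#'
#' @param frequency frequency in Hz (> 0), vectorized.
#' @param params an [erb_scale_params()] object.
#' @return ERB-numbers, same length as `frequency`.
#' @seealso [erb_inverse()], [erb_bandwidth()]
#' @export
erb_number <- function(frequency, params = erb_scale_params()) {
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    stop("`frequency` must be positive and finite")
  }
  params$scale * log10(params$freq_coef * frequency / 1000 + 1)
}

#' Frequency at a given ERB-number (inverse mapping)
#'
#' @param e ERB-number (>= 0), vectorized.
#' @param params an [erb_scale_params()] object.
#' @return frequencies in Hz.
#' @export
erb_inverse <- function(e, params = erb_scale_params()) {
  if (any(!is.finite(e)) || any(e < 0)) stop("ERB-number must be nonnegative")
  1000 * (10^(e / params$scale) - 1) / params$freq_coef
}

#' Equivalent rectangular bandwidth at a frequency
#'
#' @param frequency frequency in Hz (> 0), vectorized.
#' @param params an [erb_scale_params()] object.
#' @return bandwidths in Hz.
#' @export
erb_bandwidth <- function(frequency, params = erb_scale_params()) {
  if (any(frequency <= 0)) stop("`frequency` must be positive")
  params$bw_scale * (params$freq_coef * frequency / 1000 + 1)
}

#' Place tones with equal ERB-number spacing
#'
#' Builds the tone bank of the figure-ground scene: `count` carriers with
#' exact endpoints `f_lo` and `f_hi` and constant adjacent spacing on the
#' ERB-number scale. The default 20 tones from 200 Hz to 8 kHz are spaced
#' about 1.445 ERB apart, so adjacent tones excite largely distinct
#' tonotopic channels.
#'
#' @param count number of tones (>= 2).
#' @param f_lo,f_hi lowest/highest carrier frequency in Hz.
#' @param per_tone_level level of each tone in dB SPL.
#' @param params an [erb_scale_params()] object.
#' @return an object of class `tone_bank`: list with `frequencies` (Hz),
#'   `per_tone_level` (dB SPL), `overall_level` (dB SPL), `spacing_erb`
#'   (constant adjacent spacing, ERB units) and the scale constants.
#' @examples
#' bank <- place_tones(20, 200, 8000)
#' bank$spacing_erb  # ~1.445
#' @export
place_tones <- function(count, f_lo, f_hi, per_tone_level = 60,
                        params = erb_scale_params()) {
  if (count < 2) stop("`count` must be at least 2")
  if (!(f_lo > 0 && f_hi > f_lo)) stop("need 0 < f_lo < f_hi")
  e <- seq(erb_number(f_lo, params), erb_number(f_hi, params),
           length.out = count)
  f <- erb_inverse(e, params)
  f[1] <- f_lo          # endpoints exact by construction
  f[count] <- f_hi
  bank <- structure(list(
    frequencies = f,
    per_tone_level = per_tone_level,
    spacing_erb = diff(e)[1],
    erb_params = params
  ), class = "tone_bank")
  bank$overall_level <- overall_level(bank)
  bank
}

#' Overall level of a tone bank
#'
#' Power sum of the per-tone intensities: for `n` equal-level tones the
#' overall level is `per_tone_level + 10*log10(n)` dB SPL (73.0 dB SPL for
#' 20 tones at 60 dB SPL).
#'
#' @param bank a `tone_bank`.
#' @return overall level in dB SPL.
#' @export
overall_level <- function(bank) {
  if (!length(bank$frequencies)) stop("empty tone bank")
  levels <- rep_len(bank$per_tone_level, length(bank$frequencies))
  10 * log10(sum(10^(levels / 10)))
}

#' @export
print.tone_bank <- function(x, ...) {
  cat(sprintf(
    "Tone bank: %d tones, %.0f-%.0f Hz, %.3f ERB spacing, %g dB SPL/tone (overall %.2f dB SPL)\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$spacing_erb, x$per_tone_level[1], x$overall_level))
  invisible(x)
}
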