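#' Spectral source level over a band
#'
#' A spectral (per-root-hertz) source level together with the frequency
#' band it was measured on.
#'
#' @param level Spectral source level (dB re 1 uPa Hz^(-1/2) at 1 m).
#' @param band_low,band_high Band edges (Hz, `band_high > band_low > 0`).
#' @return An object of class `"spectral_source_level"`.
#' @export
spectral_source_level <- function(level, band_low, band_high) {
  stopifnot(is.finite(level), is.finite(band_low), is.finite(band_high))
  if (!(band_high > band_low && band_low > 0))
    stop("require band_high > band_low > 0")
  structure(list(level = level, band_low = band_low, band_high = band_high),
            class = "spectral_source_level")
}

#' Band-integrated RMS source level
#'
#' Integrates a spectral source level over its measurement band assuming a
#' flat spectral density, giving the effective RMS sound pressure level:
#' `SPL = level + 10 log10(band_high - band_low)` (dB re 1 uPa at 1 m).
#' The flat-spectrum assumption is the only one supported; for a sloped
#' spectrum the result is an approximation weighted toward the band's
#' energetic end.
#'
#' @param s A [spectral_source_level()].
#' @return Band-integrated level (dB re 1 uPa).
#' @export
#' @examples
#' # 131 dB re 1 uPa/sqrt(Hz) over 800-1000 Hz -> 154.0 dB re 1 uPa
#' band_integrated_spl(spectral_source_level(131, 800, 1000))
band_integrated_spl <- function(s) {
  stopifnot(inherits(s, "spectral_source_level"))
  s$level + 10 * log10(s$band_high - s$band_low)
}
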