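#' Tremor and total analysis bands
#'
#' The tremor statistic is defined on two nested frequency bands: the tremor
#' band (default 9-16 Hz, where harmaline tremor expresses in mice) and the
#' total motion band (default 0.25-32 Hz). Nesting guarantees MPP <= 100.
#'
#' @param tremor_lo,tremor_hi Tremor band edges in Hz.
#' @param total_lo,total_hi Total band edges in Hz.
#' @return A `band_definition` list with the four edges.
#' @examples
#' band_definition()
#' @export
band_definition <- function(tremor_lo = 9, tremor_hi = 16,
                            total_lo = 0.25, total_hi = 32) {
  if (!(total_lo < tremor_lo && tremor_lo < tremor_hi && tremor_hi <= total_hi))
    stop("invalid band definition: need total_lo < tremor_lo < tremor_hi <= total_hi",
         call. = FALSE)
  structure(list(tremor_lo = tremor_lo, tremor_hi = tremor_hi,
                 total_lo = total_lo, total_hi = total_hi),
            class = "band_definition")
}

#' Chance in-band fraction of a flat spectrum
#'
#' For a signal with a flat power spectrum over `[total_lo, total_hi]`, the
#' expected fraction of power falling in `[band_lo, band_hi]` is simply the
#' bandwidth ratio. This closed form anchors the generator calibration (what
#' MPP a tremor-free flat background would show "by chance") and serves as an
#' analytic oracle for the spectral pipeline.
#'
#' @param band_lo,band_hi Numerator band edges, Hz.
#' @param total_lo,total_hi Denominator band edges, Hz.
#' @return The dimensionless fraction `(band_hi - band_lo) / (total_hi - total_lo)`.
#' @examples
#' flat_spectrum_chance_fraction(9, 16, 0.25, 32) # ~0.2205
#' @export
flat_spectrum_chance_fraction <- function(band_lo, band_hi, total_lo, total_hi) {
  # identity band (band == total) is a legal degenerate case -> 1
  if (!(total_lo <= band_lo && band_lo < band_hi && band_hi <= total_hi))
    stop("invalid band: need total_lo <= band_lo < band_hi <= total_hi",
         call. = FALSE)
  (band_hi - band_lo) / (total_hi - total_lo)
}
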