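#' Doppler geometry convention
#'
#' Backscattering Doppler geometry: the angular frequency shift for
#' intracellular speed `v` is `delta omega = q v` with
#' `q = 4 pi n / lambda0`, i.e. a cyclic frequency `f = 2 n v / lambda0`.
#'
#' @param wavelength free-space wavelength lambda0 in nm (default 840, the
#'   superluminescent-diode center wavelength).
#' @param refractiveIndex medium refractive index (default 1.33, aqueous
#'   tissue).
#' @return list with `wavelength` (m), `refractiveIndex` and the geometry
#'   factor `q` (rad/m).
#' @export
dopplerConvention <- function(wavelength = 840, refractiveIndex = 1.33) {
  stopifnot(wavelength > 0, refractiveIndex >= 1)
  lambda <- wavelength * 1e-9
  list(wavelength = lambda, refractiveIndex = refractiveIndex,
       q = 4 * pi * refractiveIndex / lambda)
}

#' Doppler frequency shift for an intracellular speed
#'
#' @param speed speed in m/s (non-negative).
#' @param conv a [dopplerConvention()].
#' @return cyclic frequency shift in Hz, `f = q v / (2 pi) = 2 n v / lambda0`.
#' @export
#' @examples
#' dopplerShift(1e-6)  # ~3 Hz for 1 micron/s at 840 nm
dopplerShift <- function(speed, conv = dopplerConvention()) {
  if (any(speed < 0)) stop("speed must be non-negative")
  conv$q * speed / (2 * pi)
}

#' Intracellular speed for a Doppler frequency shift
#'
#' Exact inverse of [dopplerShift()].
#'
#' @param frequency cyclic frequency in Hz (non-negative).
#' @param conv a [dopplerConvention()].
#' @return speed in m/s.
#' @export
#' @examples
#' dopplerSpeed(12.5) * 1e6  # ~4 microns/s at the Nyquist frequency
dopplerSpeed <- function(frequency, conv = dopplerConvention()) {
  if (any(frequency < 0)) stop("frequency must be non-negative")
  2 * pi * frequency / conv$q
}
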