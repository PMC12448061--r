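#' Optical pulse description
#'
#' Bundles the laser parameters that determine the photoacoustic source:
#' wavelength, nanosecond pulse duration, per-pulse energy, beam diameter and
#' repetition rate. The fluence delivered at the target surface follows from
#' energy and beam area via [fluence_from_energy()].
#'
#' @param wavelength_nm Optical wavelength in nm (default 1064, Nd:YAG).
#' @param pulse_ns Pulse duration (FWHM) in ns.
#' @param energy_mJ Pulse energy in mJ.
#' @param beam_mm Beam diameter in mm.
#' @param prf_Hz Pulse repetition rate in Hz.
#' @return An object of class `optical_pulse`.
#' @examples
#' p <- optical_pulse(energy_mJ = 80, beam_mm = 6)
#' fluence_from_energy(p$energy_mJ, p$beam_mm)  # ~283 mJ/cm^2
#' @export
optical_pulse <- function(wavelength_nm = 1064, pulse_ns = 3,
                          energy_mJ = 80, beam_mm = 6, prf_Hz = 10) {
  for (nm in c("wavelength_nm", "pulse_ns", "energy_mJ", "beam_mm", "prf_Hz")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("optical_pulse: `", nm, "` must be a single positive number")
  }
  structure(list(wavelength_nm = wavelength_nm, pulse_ns = pulse_ns,
                 energy_mJ = energy_mJ, beam_mm = beam_mm, prf_Hz = prf_Hz),
            class = "optical_pulse")
}

#' Optically absorbing vessel description
#'
#' The blood vessel acts as the photoacoustic source: a cylindrical optical
#' absorber of diameter `diameter_mm` with absorption coefficient
#' `mua_per_cm` and Grueneisen parameter `grueneisen`. Under stress
#' confinement the initial pressure rise is `grueneisen * mua * fluence`
#' ([initial_pressure()]), and the emitted transient has a duration set by
#' the acoustic transit time `diameter / sound_speed`.
#'
#' Defaults are class values for whole blood at 1064 nm and are meant to be
#' overridden from a configuration when measured values are available.
#'
#' @param diameter_mm Vessel diameter in mm.
#' @param mua_per_cm Optical absorption coefficient in 1/cm.
#' @param grueneisen Grueneisen parameter (dimensionless, in (0, 1]).
#' @param sound_speed_mm_us Speed of sound in the surrounding tissue, mm/us.
#' @return An object of class `vessel_absorber`.
#' @export
vessel_absorber <- function(diameter_mm = 0.1, mua_per_cm = 10,
                            grueneisen = 0.20, sound_speed_mm_us = 1.5) {
  if (!is.numeric(diameter_mm) || diameter_mm <= 0)
    stop("vessel_absorber: diameter must be positive")
  if (!is.numeric(mua_per_cm) || mua_per_cm < 0)
    stop("vessel_absorber: absorption coefficient must be non-negative")
  if (!is.numeric(grueneisen) || grueneisen <= 0 || grueneisen > 1)
    stop("vessel_absorber: grueneisen must lie in (0, 1]")
  if (!is.numeric(sound_speed_mm_us) || sound_speed_mm_us <= 0)
    stop("vessel_absorber: sound speed must be positive")
  structure(list(diameter_mm = diameter_mm, mua_per_cm = mua_per_cm,
                 grueneisen = grueneisen,
                 sound_speed_mm_us = sound_speed_mm_us),
            class = "vessel_absorber")
}

#' Fluence from pulse energy and beam diameter
#'
#' `F = E / (pi (d/2)^2)` with the beam area in cm^2. An 80 mJ pulse over a
#' 6 mm beam gives 283 mJ/cm^2.
#'
#' @param energy_mJ Pulse energy in mJ (>= 0).
#' @param beam_mm Beam diameter in mm (> 0).
#' @return Fluence in mJ/cm^2.
#' @examples
#' fluence_from_energy(80, 6)
#' @export
fluence_from_energy <- function(energy_mJ, beam_mm) {
  if (!is.numeric(energy_mJ) || any(energy_mJ < 0))
    stop("fluence_from_energy: energy must be non-negative")
  if (!is.numeric(beam_mm) || any(beam_mm <= 0))
    stop("fluence_from_energy: beam diameter must be positive")
  area_cm2 <- pi * (beam_mm / 2 / 10)^2
  energy_mJ / area_cm2
}

#' Stress-confined initial photoacoustic pressure
#'
#' Under stress confinement (the laser pulse is much shorter than the
#' acoustic transit time across the absorber) the absorbed energy density
#' `mua * F` converts to an initial pressure rise `p0 = Grueneisen * mua * F`.
#' With `mua` in 1/cm and `F` in mJ/cm^2 the product is mJ/cm^3 = 1e3 Pa.
#'
#' @param fluence_mJcm2 Fluence at the absorber in mJ/cm^2 (>= 0).
#' @param absorber A [vessel_absorber()].
#' @return Initial pressure p0 in MPa, linear in fluence.
#' @examples
#' initial_pressure(100, vessel_absorber())
#' @export
initial_pressure <- function(fluence_mJcm2, absorber = vessel_absorber()) {
  stopifnot(inherits(absorber, "vessel_absorber"))
  if (!is.numeric(fluence_mJcm2) || any(fluence_mJcm2 < 0))
    stop("initial_pressure: fluence must be non-negative")
  p0_Pa <- absorber$grueneisen * absorber$mua_per_cm * fluence_mJcm2 * 1e3
  p0_Pa / 1e6
}

#' Photoacoustic pressure transient of an absorbing vessel
#'
#' Builds the bipolar (N-shaped) pressure transient observed near the axis of
#' a cylindrical absorber under stress confinement: a linear ramp from +p0 to
#' -p0 over the acoustic transit time `d/c`, smoothed by convolution with the
#' Gaussian laser envelope (FWHM `pulse$pulse_ns`), then rescaled so the peak
#' equals `initial_pressure(fluence, absorber)`. The waveform is bipolar and
#' integrates to (numerically) zero, as any far-field acoustic transient
#' must.
#'
#' @param absorber A [vessel_absorber()].
#' @param pulse An [optical_pulse()]; only the pulse duration enters here.
#' @param fluence_mJcm2 Fluence at the vessel in mJ/cm^2.
#' @param time_step_ns Sampling step of the returned waveform in ns. Must
#'   resolve the transit time with at least 10 samples.
#' @return An object of class `pa_waveform`: list with `time_ns`,
#'   `pressure_MPa`, `peak_MPa`, `width_ns`.
#' @examples
#' w <- pa_waveform(vessel_absorber(), optical_pulse(), fluence_mJcm2 = 100)
#' w$peak_MPa
#' @export
pa_waveform <- function(absorber = vessel_absorber(), pulse = optical_pulse(),
                        fluence_mJcm2 = 100, time_step_ns = 1) {
  stopifnot(inherits(absorber, "vessel_absorber"),
            inherits(pulse, "optical_pulse"))
  if (fluence_mJcm2 < 0) stop("pa_waveform: fluence must be non-negative")
  transit_ns <- absorber$diameter_mm / absorber$sound_speed_mm_us * 1e3
  if (time_step_ns > transit_ns / 10)
    stop("pa_waveform: time_step_ns too coarse; need >= 10 samples across ",
         "the vessel transit time (", signif(transit_ns, 3), " ns)")
  p0 <- initial_pressure(fluence_mJcm2, absorber)

  # symmetric odd-length grids keep the N-wave antisymmetric after smoothing
  half_span <- transit_ns / 2 + 3 * pulse$pulse_ns
  n_half <- ceiling(half_span / time_step_ns)
  t <- (-n_half:n_half) * time_step_ns
  # ideal N-wave: +1 at leading edge, -1 at trailing edge
  ideal <- ifelse(abs(t) <= transit_ns / 2, -2 * t / transit_ns, 0)
  # Gaussian laser envelope, FWHM = pulse_ns
  s <- pulse$pulse_ns / (2 * sqrt(2 * log(2)))
  m_half <- ceiling(3 * pulse$pulse_ns / time_step_ns)
  tk <- (-m_half:m_half) * time_step_ns
  kern <- exp(-tk^2 / (2 * s^2))
  kern <- kern / sum(kern)
  sm <- stats::convolve(ideal, rev(kern), type = "open")
  # trim convolution tails back onto the t grid (kernel half-width each side)
  sm <- sm[(m_half + 1):(m_half + length(t))]
  pk <- max(abs(sm))
  pressure <- if (pk > 0 && p0 > 0) sm / pk * p0 else sm * 0
  structure(list(time_ns = t, pressure_MPa = pressure,
                 peak_MPa = p0, width_ns = transit_ns,
                 fluence_mJcm2 = fluence_mJcm2),
            class = "pa_waveform")
}

#' @export
print.pa_waveform <- function(x, ...) {
  cat("<pa_waveform> peak", signif(x$peak_MPa, 4), "MPa, width",
      signif(x$width_ns, 4), "ns,", length(x$time_ns), "samples\n")
  invisible(x)
}
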