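#' Liquid medium properties for bubble dynamics
#'
#' Physical constants of the host liquid entering the Keller-Miksis equation
#' and the rectified-diffusion flux. Defaults describe a water/blood-like
#' medium at ambient conditions: density 1000 kg/m^3, viscosity 2 mPa s
#' (a sub-micron bubble in blood sits in the plasma phase between red
#' cells, so the effective viscosity at that scale is plasma-like rather
#' than bulk whole blood), surface tension 0.072 N/m, polytropic exponent
#' 1.4 (adiabatic air), ambient pressure 101.325 kPa, vapor pressure
#' 2.33 kPa, liquid sound speed 1500 m/s, air diffusivity 2e-9 m^2/s,
#' saturation concentration 0.75 mol/m^3 and a gas-saturated liquid
#' (`saturation = 1`).
#'
#' @param rho Density, kg/m^3.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param surface_tension Surface tension, N/m.
#' @param p_inf Ambient (static) pressure, Pa.
#' @param p_v Vapor pressure, Pa.
#' @param kappa Polytropic exponent of the gas core.
#' @param c0 Sound speed in the liquid, m/s.
#' @param diffusivity Dissolved-gas diffusivity, m^2/s.
#' @param c_sat Saturation gas concentration at `p_inf`, mol/m^3.
#' @param saturation Dissolved-gas saturation ratio C_i/C_0 in (0, 1.5].
#' @return An object of class `medium_properties`.
#' @export
medium_properties <- function(rho = 1000, viscosity = 0.002,
                              surface_tension = 0.072,
                              p_inf = 101325, p_v = 2330, kappa = 1.4,
                              c0 = 1500, diffusivity = 2e-9,
                              c_sat = 0.75, saturation = 1) {
  vals <- c(rho = rho, viscosity = viscosity,
            surface_tension = surface_tension, p_inf = p_inf,
            kappa = kappa, c0 = c0, diffusivity = diffusivity,
            c_sat = c_sat, saturation = saturation)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("medium_properties: all parameters must be positive and finite ",
         "(p_v and surface_tension may be >= 0)")
  if (p_v < 0) stop("medium_properties: vapor pressure must be >= 0")
  if (saturation > 1.5)
    stop("medium_properties: saturation ratio must lie in (0, 1.5]")
  structure(list(rho = rho, viscosity = viscosity,
                 surface_tension = surface_tension, p_inf = p_inf,
                 p_v = p_v, kappa = kappa, c0 = c0,
                 diffusivity = diffusivity, c_sat = c_sat,
                 saturation = saturation),
            class = "medium_properties")
}

#' Simulate single-bubble radial dynamics under a drive waveform
#'
#' Integrates the Keller-Miksis equation (first-order compressibility,
#' polytropic gas core in mechanical equilibrium at `R0`, surface tension,
#' Newtonian viscosity) with an adaptive embedded Runge-Kutta scheme
#' implemented in compiled code. The drive may be a [synchronize()]d
#' combined waveform, a bare [make_burst()], or `NULL` for an undriven
#' bubble (free ringdown / equilibrium checks), in which case `t_end_us`
#' must be given.
#'
#' @param drive A `drive_waveform`, `us_burst`, or `NULL`.
#' @param R0_nm Equilibrium bubble radius in nm.
#' @param medium A [medium_properties()].
#' @param samples_per_cycle Output samples per drive cycle (spectral
#'   analysis of period doubling needs >= 16; default 64).
#' @param t_end_us Integration span in us; default the drive duration.
#' @param dt_out_ns Output sampling step for undriven runs, ns.
#' @param R_init_nm Initial radius, nm; default `R0_nm` (equilibrium).
#' @param U_init Initial wall velocity, m/s.
#' @param rtol Relative tolerance of the adaptive integrator.
#' @param max_steps Step budget before the solver gives up.
#' @return An object of class `bubble_trajectory`: `time_us`, `R_nm`,
#'   `U_ms`, `R0_nm`, `frequency_MHz`, `pa_time_us` (NA when no PA pulse),
#'   solver diagnostics, and `fate` (NA until [classify_fate()] assigns it).
#' @examples
#' m <- medium_properties()
#' tr <- simulate_bubble(NULL, R0_nm = 2000, medium = m,
#'                       t_end_us = 2, dt_out_ns = 1)
#' max(abs(tr$R_nm / tr$R0_nm - 1))  # stays at equilibrium
#' @export
simulate_bubble <- function(drive, R0_nm, medium = medium_properties(),
                            samples_per_cycle = 64, t_end_us = NULL,
                            dt_out_ns = 10, R_init_nm = NULL, U_init = 0,
                            rtol = 1e-6, max_steps = 5e7) {
  stopifnot(inherits(medium, "medium_properties"))
  if (R0_nm <= 0) stop("simulate_bubble: R0 must be positive")
  R0 <- R0_nm * 1e-9

  if (is.null(drive)) {
    if (is.null(t_end_us))
      stop("simulate_bubble: t_end_us required for an undriven run")
    drive_p <- c(0, 0)
    drive_t0 <- 0
    drive_dt <- t_end_us * 1e-6
    dt_out <- dt_out_ns * 1e-9
    freq <- NA_real_
    pa_time <- NA_real_
  } else {
    if (!inherits(drive, c("drive_waveform", "us_burst")))
      stop("simulate_bubble: drive must be a drive_waveform, us_burst or NULL")
    drive_p <- drive$pressure_MPa * 1e6
    drive_t0 <- drive$time_ns[1] * 1e-9
    drive_dt <- (drive$time_ns[2] - drive$time_ns[1]) * 1e-9
    freq <- drive$frequency_MHz
    pa_time <- if (!is.null(drive$pa_time_ns)) drive$pa_time_ns * 1e-3 else NA_real_
    if (is.null(t_end_us)) t_end_us <- drive$time_ns[length(drive$time_ns)] * 1e-3
    period_s <- 1e-6 / freq
    dt_out <- period_s / samples_per_cycle
  }
  t_end <- t_end_us * 1e-6
  if (t_end <= 0) stop("simulate_bubble: integration span must be positive")
  R_init <- if (is.null(R_init_nm)) R0 else R_init_nm * 1e-9

  res <- km_integrate_cpp(drive_p, drive_t0, drive_dt, t_end, dt_out,
                          R0, R_init, U_init,
                          medium$rho, medium$viscosity,
                          medium$surface_tension, medium$p_inf, medium$p_v,
                          medium$kappa, medium$c0, rtol, max_steps)
  if (!isTRUE(res$ok))
    stop("simulate_bubble: integration failed (", res$message,
         ") at t = ", signif(res$t_last * 1e6, 6), " us, R = ",
         signif(res$R_last * 1e9, 6), " nm, U = ", signif(res$U_last, 6),
         " m/s after ", res$nstep, " steps")

  structure(list(time_us = res$t * 1e6, R_nm = res$R * 1e9, U_ms = res$U,
                 R0_nm = R0_nm, frequency_MHz = freq, pa_time_us = pa_time,
                 drive = drive, nstep = res$nstep, nfloor = res$nfloor,
                 fate = NA_character_),
            class = "bubble_trajectory")
}

#' Steady-analysis window of a trajectory
#'
#' Selects the portion of a trajectory over which cycle averages and spectra
#' are taken. Without a photoacoustic pulse the first `discard_fraction` of
#' the burst is discarded as start-up transient. When the drive carries a PA
#' pulse, the window opens half a drive cycle before the pulse arrival: the
#' pre-pulse cycles are the transient to exclude, while the pulse-triggered
#' response is the event of interest and is kept in full.
#'
#' @param trajectory A [simulate_bubble()] result.
#' @param discard_fraction Fraction of the span discarded when no PA pulse
#'   is present.
#' @return Logical index vector over the trajectory samples.
#' @keywords internal
steady_window <- function(trajectory, discard_fraction = 0.25) {
  t <- trajectory$time_us
  if (is.finite(trajectory$pa_time_us)) {
    half_period <- 0.5 / trajectory$frequency_MHz
    t_start <- max(trajectory$pa_time_us - half_period, 0)
  } else {
    t_start <- discard_fraction * t[length(t)]
  }
  t >= t_start
}

#' Cycle-averaged rectified-diffusion gas flux
#'
#' Net moles of gas entering the bubble per unit time, averaged over the
#' steady window, in the Eller-Flynn high-frequency approximation:
#'
#' `dn/dt = 4 pi D R0 C_sat <r> ( Ci/C0 - (pg0/p_ref) <r^(4-3kappa)> / <r^4> )`
#'
#' with r denoting `R/R0`, equilibrium gas pressure
#' `pg0 = p_inf + 2 sigma/R0 - p_v`, and reference gas pressure
#' `p_ref = p_inf - p_v` (the gas partial pressure at which the dissolved
#' concentration `C_sat` is the saturation value). The second term is the
#' area-and-shell weighted mean wall gas pressure driving outward diffusion;
#' the fourth-power weighting is what rectifies the exchange: large
#' excursions far above r = 1 contribute enormous `r^4` weight at low interior
#' pressure, turning the average influx positive. Positive flux means
#' rectified-diffusion growth. At r = 1 the expression reduces to the
#' quasi-static Epstein-Plesset dissolution rate, so an undriven sub-micron
#' bubble in a saturated liquid has negative flux (Laplace-pressure
#' dissolution), and a zero-surface-tension undriven bubble in a saturated
#' liquid has exactly zero flux.
#'
#' @param trajectory A [simulate_bubble()] result covering enough cycles
#'   that a steady window exists.
#' @param medium The [medium_properties()] used for the simulation.
#' @param discard_fraction Initial fraction of the analysed span excluded
#'   from the averages (no-PA drives only; see [steady_window()]).
#' @return Flux in mol/s with attributes `mean_r`, `mean_r4`, `mean_r4k`
#'   for the three time averages.
#' @export
mass_flux <- function(trajectory, medium = medium_properties(),
                      discard_fraction = 0.25) {
  stopifnot(inherits(trajectory, "bubble_trajectory"),
            inherits(medium, "medium_properties"))
  keep <- steady_window(trajectory, discard_fraction)
  if (sum(keep) < 8)
    stop("mass_flux: trajectory too short for a steady averaging window")
  r <- trajectory$R_nm[keep] / trajectory$R0_nm
  R0 <- trajectory$R0_nm * 1e-9
  pg0 <- medium$p_inf + 2 * medium$surface_tension / R0 - medium$p_v
  p_ref <- medium$p_inf - medium$p_v
  mean_r <- mean(r)
  mean_r4 <- mean(r^4)
  mean_r4k <- mean(r^(4 - 3 * medium$kappa))
  flux <- 4 * pi * medium$diffusivity * R0 * medium$c_sat * mean_r *
    (medium$saturation - (pg0 / p_ref) * mean_r4k / mean_r4)
  structure(flux, mean_r = mean_r, mean_r4 = mean_r4, mean_r4k = mean_r4k)
}

#' Subharmonic content of a trajectory
#'
#' Amplitude ratio of the R(t) spectral component at half the drive
#' frequency to the component at the drive frequency, computed over the
#' steady window with a Hann taper. Used by [classify_fate()] to detect
#' period doubling; an alternation index of successive cycle maxima is
#' returned as a cross-check.
#'
#' @inheritParams mass_flux
#' @return List with `ratio` (A(f/2)/A(f)), `alternation` (relative
#'   difference between odd- and even-cycle maxima), `f_MHz`.
#' @export
subharmonic_ratio <- function(trajectory, discard_fraction = 0.25) {
  stopifnot(inherits(trajectory, "bubble_trajectory"))
  f <- trajectory$frequency_MHz
  if (!is.finite(f))
    stop("subharmonic_ratio: drive is not periodic; classification refused")
  keep <- steady_window(trajectory, discard_fraction)
  t <- trajectory$time_us[keep]
  r <- trajectory$R_nm[keep] / trajectory$R0_nm
  dt <- t[2] - t[1]
  period <- 1 / f
  # whole number of pairs of cycles so f/2 sits on a Fourier bin
  spc <- round(period / dt)
  n_cyc <- floor(length(r) / spc)
  n_cyc <- n_cyc - (n_cyc %% 2)
  if (n_cyc < 4)
    stop("subharmonic_ratio: need at least 4 steady cycles")
  n <- n_cyc * spc
  x <- r[seq_len(n)] - mean(r[seq_len(n)])
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  sp <- abs(stats::fft(x * w))[seq_len(n %/% 2)]
  # bin k corresponds to frequency (k-1) / (n*dt); drive sits at bin n_cyc+1
  band <- function(k) max(sp[pmax(1, (k - 1)):(k + 1)])
  a_f <- band(n_cyc + 1)
  a_f2 <- band(n_cyc %/% 2 + 1)
  # alternation of successive cycle maxima
  cyc_max <- vapply(seq_len(n_cyc), function(i)
    max(r[((i - 1) * spc + 1):(i * spc)]), numeric(1))
  odd <- cyc_max[seq(1, n_cyc, 2)]; even <- cyc_max[seq(2, n_cyc, 2)]
  alt <- abs(mean(odd) - mean(even)) / max(mean(cyc_max) - 1, 1e-12)
  list(ratio = if (a_f > 0) a_f2 / a_f else 0, alternation = alt, f_MHz = f)
}

#' Radius whose linear resonance matches a given frequency
#'
#' Inverts the Minnaert relation with surface-tension correction,
#' `f0(R) = (1/(2 pi R)) sqrt((3 kappa pg0(R) - 2 sigma/R)/rho)`, for the
#' equilibrium radius resonant at `f_MHz`. Used to locate the
#' subharmonically resonant size `f0(R) = f_drive/2`.
#'
#' @param f_MHz Target linear resonance frequency, MHz.
#' @param medium A [medium_properties()].
#' @return Radius in nm.
#' @export
resonant_radius <- function(f_MHz, medium = medium_properties()) {
  f0 <- function(R) {
    pg0 <- medium$p_inf + 2 * medium$surface_tension / R - medium$p_v
    w2 <- (3 * medium$kappa * pg0 - 2 * medium$surface_tension / R) /
      (medium$rho * R^2)
    sqrt(w2) / (2 * pi) * 1e-6
  }
  stats::uniroot(function(R) f0(R) - f_MHz,
                 interval = c(1e-8, 1e-2), tol = 1e-12)$root * 1e9
}

#' Classify the fate of a driven bubble
#'
#' Assigns one of `DISSOLVE`, `GROW`, `PERIOD_DOUBLED_GROWTH`.
#'
#' `GROW` when the cycle-averaged rectified-diffusion [mass_flux()] over the
#' steady window is positive, `DISSOLVE` otherwise.
#'
#' A growing bubble is labelled `PERIOD_DOUBLED_GROWTH` when its expansion
#' has reached the subharmonically resonant size: the fixed-gas-mass
#' trajectory of a sub-micron nucleus is period-1 (the nucleus is viscously
#' overdamped and resets every cycle), so period doubling appears in the
#' size regime the growing bubble is driven into, not in the nucleus
#' trajectory itself. Concretely: if `max R(t)` reaches the radius whose
#' linear resonance is half the drive frequency ([resonant_radius()]), a
#' bubble of that destination size is simulated under the same drive and
#' the f/2 spectral criterion of [subharmonic_ratio()] (component at half
#' the drive frequency at least `subharmonic_frac` of the drive-frequency
#' component) is applied to that trajectory.
#'
#' @inheritParams mass_flux
#' @param subharmonic_frac Spectral ratio above which the destination-size
#'   trajectory counts as period-doubled.
#' @param destination_subharmonic Optional precomputed f/2 spectral ratio of
#'   the destination-size bubble under this drive (see
#'   [destination_subharmonic()]); `NULL` to compute it on demand. Passing
#'   it avoids re-simulating the destination bubble across map cells that
#'   share a drive pressure.
#' @param check_period_doubling Set `FALSE` to skip the period-doubling
#'   stage entirely (grow/dissolve only), e.g. inside a threshold
#'   bisection where only the flux sign matters.
#' @return List with `fate`, `flux_mol_s`, `max_r` (max R/R0),
#'   `subharmonic` (destination-size spectral ratio, 0 when not evaluated),
#'   `mean_r`.
#' @examples
#' \donttest{
#' d <- put_drive(pnp_MPa = 0.8, fluence_mJcm2 = 120, cycles = 50)
#' tr <- simulate_bubble(d, R0_nm = 100)
#' classify_fate(tr)$fate
#' }
#' @export
classify_fate <- function(trajectory, medium = medium_properties(),
                          subharmonic_frac = 0.1, discard_fraction = 0.25,
                          destination_subharmonic = NULL,
                          check_period_doubling = TRUE) {
  if (!is.finite(trajectory$frequency_MHz))
    stop("classify_fate: drive is not periodic; classification refused")
  flux <- mass_flux(trajectory, medium, discard_fraction)
  grow <- as.numeric(flux) > 0
  max_r <- max(trajectory$R_nm) / trajectory$R0_nm
  sub <- 0
  if (grow && check_period_doubling) {
    R_sub_nm <- resonant_radius(trajectory$frequency_MHz / 2, medium)
    if (max(trajectory$R_nm) >= R_sub_nm) {
      sub <- if (!is.null(destination_subharmonic)) destination_subharmonic
             else destination_subharmonic(trajectory$drive, medium,
                                          discard_fraction)
    }
  }
  fate <- if (!grow) "DISSOLVE"
          else if (sub >= subharmonic_frac) "PERIOD_DOUBLED_GROWTH"
          else "GROW"
  list(fate = fate, flux_mol_s = as.numeric(flux), max_r = max_r,
       subharmonic = sub, mean_r = attr(flux, "mean_r"))
}

#' Subharmonic ratio of the growth-destination bubble under a drive
#'
#' Simulates a bubble whose equilibrium radius is the subharmonically
#' resonant size (`f0 = f_drive/2`) under the given drive and returns the
#' f/2 spectral ratio of its trajectory. Support routine for
#' [classify_fate()]'s period-doubling stage; exposed so map builders can
#' compute it once per drive pressure.
#'
#' @param drive A `drive_waveform` or `us_burst`.
#' @param medium A [medium_properties()].
#' @param discard_fraction Passed to [subharmonic_ratio()].
#' @param ... Passed to [simulate_bubble()].
#' @return The f/2 : f spectral amplitude ratio (numeric scalar).
#' @export
destination_subharmonic <- function(drive, medium = medium_properties(),
                                    discard_fraction = 0.25, ...) {
  R_sub_nm <- resonant_radius(drive$frequency_MHz / 2, medium)
  tr <- simulate_bubble(drive, R_sub_nm, medium, ...)
  subharmonic_ratio(tr, discard_fraction)$ratio
}

#' Build the standard combined PUT drive for one burst
#'
#' Convenience constructor used by the threshold and regime-map routines:
#' an ultrasound burst at `frequency_MHz`/`pnp_MPa` with the photoacoustic
#' transient for `fluence_mJcm2` synchronized onto the rarefaction peak of a
#' mid-burst cycle.
#'
#' @param pnp_MPa Burst peak negative pressure, MPa.
#' @param fluence_mJcm2 Light fluence at the vessel, mJ/cm^2.
#' @param cycles Cycles per burst.
#' @param frequency_MHz Burst centre frequency, MHz.
#' @param absorber A [vessel_absorber()].
#' @param pulse An [optical_pulse()].
#' @param delay_ns PA placement; `NULL` for the mid-burst rarefaction peak.
#' @param time_step_ns Waveform sampling step, ns.
#' @return A `drive_waveform`.
#' @export
put_drive <- function(pnp_MPa, fluence_mJcm2, cycles = 100,
                      frequency_MHz = 0.25, absorber = vessel_absorber(),
                      pulse = optical_pulse(), delay_ns = NULL,
                      time_step_ns = 1) {
  b <- make_burst(frequency_MHz, pnp_MPa, cycles,
                  prf_Hz = pulse$prf_Hz, time_step_ns = time_step_ns)
  pa <- pa_waveform(absorber, pulse, fluence_mJcm2,
                    time_step_ns = time_step_ns)
  synchronize(b, pa, delay_ns)
}

#' @export
print.bubble_trajectory <- function(x, ...) {
  cat("<bubble_trajectory> R0", x$R0_nm, "nm,", length(x$time_us),
      "samples over", signif(max(x$time_us), 5), "us; max R/R0",
      signif(max(x$R_nm) / x$R0_nm, 4), "; fate:",
      if (is.na(x$fate)) "(unclassified)" else x$fate, "\n")
  invisible(x)
}
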