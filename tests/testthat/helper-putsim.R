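# Shared helpers for the test suite.

# Water-like medium used for the classic physics oracles.
water <- function(...) {
  medium_properties(viscosity = 0.001, ...)
}

# Undamped Minnaert frequency with surface-tension correction, MHz.
minnaert_MHz <- function(R0_m, m) {
  pg0 <- m$p_inf + 2 * m$surface_tension / R0_m - m$p_v
  w2 <- (3 * m$kappa * pg0 - 2 * m$surface_tension / R0_m) /
    (m$rho * R0_m^2)
  sqrt(w2) / (2 * pi) * 1e-6
}

# Dominant oscillation frequency of a ringdown, MHz, from zero crossings.
ringdown_MHz <- function(tr) {
  x <- tr$R_nm - mean(tr$R_nm)
  idx <- which(diff(sign(x)) != 0)
  stopifnot(length(idx) >= 5)
  1 / (2 * mean(diff(tr$time_us[idx])))
}

# Hand-built trajectory object for classifier unit tests.
fake_trajectory <- function(time_us, r, R0_nm = 100, frequency_MHz = 0.25,
                            pa_time_us = NA_real_) {
  structure(list(time_us = time_us, R_nm = r * R0_nm,
                 U_ms = rep(0, length(r)), R0_nm = R0_nm,
                 frequency_MHz = frequency_MHz, pa_time_us = pa_time_us,
                 drive = NULL, nstep = 0, nfloor = 0,
                 fate = NA_character_),
            class = "bubble_trajectory")
}

# Quasi-static Epstein-Plesset molar dissolution rate (mol/s) for a bubble
# resting at R0: independent closed form for the static flux oracle.
epstein_plesset_rate <- function(R0_m, m) {
  pg0 <- m$p_inf + 2 * m$surface_tension / R0_m - m$p_v
  p_ref <- m$p_inf - m$p_v
  4 * pi * m$diffusivity * R0_m * m$c_sat * (m$saturation - pg0 / p_ref)
}
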