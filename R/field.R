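#' Synthesize an ultrasound burst
#'
#' Generates the sinusoidal tone burst used to drive cavitation: `cycles`
#' cycles of a sine at `frequency_MHz`, scaled so the rarefaction (most
#' negative) amplitude equals the peak negative pressure `pnp_MPa`. The burst
#' starts on the rarefaction half-cycle. A 500-cycle burst at 0.25 MHz lasts
#' 2 ms; repeated at 10 Hz that is a 2% duty cycle.
#'
#' @param frequency_MHz Centre frequency in MHz.
#' @param pnp_MPa Peak negative pressure in MPa.
#' @param cycles Number of cycles per burst.
#' @param prf_Hz Burst repetition rate in Hz.
#' @param time_step_ns Sampling step in ns.
#' @return An object of class `us_burst` with fields `time_ns`,
#'   `pressure_MPa`, `frequency_MHz`, `pnp_MPa`, `cycles`, `prf_Hz`,
#'   `burst_duration_ms`, `duty_cycle`.
#' @examples
#' b <- make_burst(0.25, 1, cycles = 500, prf_Hz = 10)
#' b$burst_duration_ms  # 2 ms
#' b$duty_cycle         # 0.02
#' @export
make_burst <- function(frequency_MHz = 0.25, pnp_MPa = 1, cycles = 100,
                       prf_Hz = 10, time_step_ns = 1) {
  if (frequency_MHz <= 0 || pnp_MPa < 0 || cycles <= 0 || prf_Hz <= 0)
    stop("make_burst: frequency, cycles and prf must be positive, pnp >= 0")
  period_ns <- 1e3 / frequency_MHz
  duration_ns <- cycles * period_ns
  duty <- duration_ns * 1e-9 * prf_Hz
  if (duty > 1)
    stop("make_burst: duty cycle exceeds 100% (burst longer than the ",
         "repetition period)")
  t <- seq(0, duration_ns, by = time_step_ns)
  p <- -pnp_MPa * sin(2 * pi * t / period_ns)
  structure(list(time_ns = t, pressure_MPa = p,
                 frequency_MHz = frequency_MHz, pnp_MPa = pnp_MPa,
                 cycles = cycles, prf_Hz = prf_Hz,
                 burst_duration_ms = duration_ns * 1e-6,
                 duty_cycle = duty, time_step_ns = time_step_ns),
            class = "us_burst")
}

#' Time of a rarefaction peak within a burst
#'
#' With the [make_burst()] convention (burst opens on the rarefaction
#' half-cycle) the rarefaction peak of 0-based cycle `cycle` falls at
#' `(cycle + 1/4)` periods.
#'
#' @param burst A [make_burst()] object.
#' @param cycle 0-based cycle index; default mid-burst.
#' @return Time in ns.
#' @export
rarefaction_peak_time <- function(burst, cycle = floor(burst$cycles / 2)) {
  stopifnot(inherits(burst, "us_burst"))
  if (cycle < 0 || cycle >= burst$cycles)
    stop("rarefaction_peak_time: cycle outside the burst")
  (cycle + 0.25) * 1e3 / burst$frequency_MHz
}

#' Superimpose a photoacoustic pulse onto an ultrasound burst
#'
#' Adds the photoacoustic transient sample-wise to the burst, placing the
#' negative lobe of the transient at `delay_ns` after burst onset. The
#' default delay centres it on the rarefaction peak of a mid-burst cycle, so
#' the combined peak rarefaction is (approximately) the burst PNP plus the
#' PA negative amplitude. Synchronizing onto a compression phase instead
#' yields a strictly smaller combined rarefaction.
#'
#' @param burst A [make_burst()] object.
#' @param pa A [pa_waveform()] object (may have zero amplitude).
#' @param delay_ns Placement of the PA negative lobe, ns after burst onset;
#'   `NULL` for the mid-burst rarefaction peak.
#' @return An object of class `drive_waveform`: `time_ns`, `pressure_MPa`,
#'   `pa_time_ns` (annotation of the insertion instant), `combined_pnp_MPa`,
#'   plus the burst descriptors.
#' @examples
#' b <- make_burst(0.25, 0.6, cycles = 10)
#' w <- pa_waveform(fluence_mJcm2 = 100)
#' d <- synchronize(b, w)
#' d$combined_pnp_MPa
#' @export
synchronize <- function(burst, pa, delay_ns = NULL) {
  stopifnot(inherits(burst, "us_burst"), inherits(pa, "pa_waveform"))
  if (is.null(delay_ns)) delay_ns <- rarefaction_peak_time(burst)
  dur <- burst$cycles * 1e3 / burst$frequency_MHz
  if (delay_ns < 0 || delay_ns > dur)
    stop("synchronize: delay falls outside the burst")
  # PA negative lobe lands at delay_ns
  t_neg <- pa$time_ns[which.min(pa$pressure_MPa)]
  shifted <- pa$time_ns - t_neg + delay_ns
  add <- stats::approx(shifted, pa$pressure_MPa, xout = burst$time_ns,
                       yleft = 0, yright = 0)$y
  p <- burst$pressure_MPa + add
  structure(list(time_ns = burst$time_ns, pressure_MPa = p,
                 pa_time_ns = delay_ns,
                 combined_pnp_MPa = -min(p),
                 frequency_MHz = burst$frequency_MHz,
                 pnp_MPa = burst$pnp_MPa, cycles = burst$cycles,
                 pa_peak_MPa = pa$peak_MPa,
                 time_step_ns = burst$time_step_ns),
            class = "drive_waveform")
}

#' Convert a trigger delay to a synchronization depth
#'
#' The laser-to-ultrasound trigger delay selects the tissue depth at which
#' the photoacoustic pulse meets a rarefaction peak: `depth = delay * c`.
#' A 500 ns delay at 1.5 mm/us corresponds to 0.75 mm.
#'
#' @param delay_ns Trigger delay in ns (>= 0); vectorized.
#' @param sound_speed_mm_us Speed of sound in mm/us.
#' @return Depth in mm.
#' @examples
#' delay_to_depth(500)   # 0.75 mm
#' delay_to_depth(1500)  # 2.25 mm
#' @export
delay_to_depth <- function(delay_ns, sound_speed_mm_us = 1.5) {
  if (any(delay_ns < 0)) stop("delay_to_depth: delay must be non-negative")
  if (sound_speed_mm_us <= 0)
    stop("delay_to_depth: sound speed must be positive")
  delay_ns * 1e-3 * sound_speed_mm_us
}

#' Expand a delay-sweep synchronization schedule
#'
#' During treatment the laser/ultrasound trigger delay is stepped at fixed
#' intervals so that the synchronized depth sweeps through the tissue: e.g.
#' stepping 500 ns every 60 s over a 240 s session visits depths 0, 0.75,
#' 1.5 and 2.25 mm.
#'
#' @param base_delay_ns Delay during the first interval, ns.
#' @param step_ns Delay increment per interval, ns (>= 0).
#' @param interval_s Length of each constant-delay window, s (> 0).
#' @param total_s Total schedule duration, s (>= interval).
#' @param sound_speed_mm_us Speed of sound for the depth mapping.
#' @return A tibble with one row per window: `t_start_s`, `t_end_s`,
#'   `delay_ns`, `depth_mm`. Windows tile `[0, total_s)` without overlap.
#' @examples
#' sweep_schedule(0, 500, 60, 240)
#' @export
sweep_schedule <- function(base_delay_ns = 0, step_ns = 500, interval_s = 60,
                           total_s = 240, sound_speed_mm_us = 1.5) {
  if (interval_s <= 0) stop("sweep_schedule: interval must be positive")
  if (total_s < interval_s)
    stop("sweep_schedule: total duration shorter than one interval")
  if (base_delay_ns < 0 || step_ns < 0)
    stop("sweep_schedule: delays must be non-negative")
  n <- ceiling(total_s / interval_s - 1e-12)
  t0 <- (seq_len(n) - 1) * interval_s
  delays <- base_delay_ns + (seq_len(n) - 1) * step_ns
  tibble::tibble(window = seq_len(n), t_start_s = t0,
                 t_end_s = pmin(t0 + interval_s, total_s),
                 delay_ns = delays,
                 depth_mm = delay_to_depth(delays, sound_speed_mm_us))
}

#' @export
print.us_burst <- function(x, ...) {
  cat("<us_burst>", x$cycles, "cycles @", x$frequency_MHz, "MHz, PNP",
      x$pnp_MPa, "MPa, duration", signif(x$burst_duration_ms, 4),
      "ms, duty", signif(100 * x$duty_cycle, 3), "%\n")
  invisible(x)
}

#' @export
print.drive_waveform <- function(x, ...) {
  cat("<drive_waveform>", x$cycles, "cycles @", x$frequency_MHz,
      "MHz, burst PNP", x$pnp_MPa, "MPa + PA", signif(x$pa_peak_MPa, 4),
      "MPa at", signif(x$pa_time_ns, 6), "ns; combined PNP",
      signif(x$combined_pnp_MPa, 4), "MPa\n")
  invisible(x)
}
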