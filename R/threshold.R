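#' Rectified-diffusion threshold pressure by bisection
#'
#' Finds the burst peak negative pressure at which the fate of a pre-existing
#' bubble flips from `DISSOLVE` to `GROW` at a given light fluence, by
#' bisection over [simulate_bubble()] + [classify_fate()]. The search
#' brackets `[0, p_max]`; if both ends share a fate the result is flagged
#' out-of-range (`NA` threshold) rather than raising an error.
#'
#' @param fluence_mJcm2 Light fluence at the vessel, mJ/cm^2.
#' @param R0_nm Pre-existing bubble radius, nm.
#' @param medium A [medium_properties()].
#' @param absorber A [vessel_absorber()].
#' @param pulse An [optical_pulse()].
#' @param cycles Burst length (cycles) used for each fate evaluation.
#' @param frequency_MHz Drive frequency, MHz.
#' @param tol_MPa Bisection tolerance on the bracket width, MPa.
#' @param p_max Upper end of the search bracket, MPa.
#' @param ... Passed on to [simulate_bubble()] (e.g. `rtol`).
#' @return List of class `threshold_result`: `threshold_MPa` (bracket
#'   midpoint, `NA` if out of range), `bracket_MPa`, `fate_low`,
#'   `fate_high`, `n_evaluations`.
#' @examples
#' \donttest{
#' threshold_pressure(100, 100, cycles = 50)$threshold_MPa
#' }
#' @export
threshold_pressure <- function(fluence_mJcm2, R0_nm = 100,
                               medium = medium_properties(),
                               absorber = vessel_absorber(),
                               pulse = optical_pulse(),
                               cycles = 100, frequency_MHz = 0.25,
                               tol_MPa = 0.01, p_max = 2, ...) {
  if (tol_MPa <= 0) stop("threshold_pressure: tolerance must be positive")
  fate_at <- function(p) {
    if (p == 0 && fluence_mJcm2 == 0) return("DISSOLVE")  # undriven bubble
    d <- put_drive(p, fluence_mJcm2, cycles = cycles,
                   frequency_MHz = frequency_MHz, absorber = absorber,
                   pulse = pulse)
    tr <- simulate_bubble(d, R0_nm, medium, ...)
    classify_fate(tr, medium, check_period_doubling = FALSE)$fate
  }
  grows <- function(f) f != "DISSOLVE"
  lo <- 0; hi <- p_max
  f_lo <- fate_at(lo); f_hi <- fate_at(hi)
  n_eval <- 2L
  if (grows(f_lo) == grows(f_hi)) {
    return(structure(list(threshold_MPa = NA_real_,
                          bracket_MPa = c(lo, hi),
                          fate_low = f_lo, fate_high = f_hi,
                          out_of_range = TRUE, n_evaluations = n_eval),
                     class = "threshold_result"))
  }
  while (hi - lo > tol_MPa) {
    mid <- (lo + hi) / 2
    f_mid <- fate_at(mid)
    n_eval <- n_eval + 1L
    if (grows(f_mid) == grows(f_hi)) {
      hi <- mid; f_hi <- f_mid
    } else {
      lo <- mid; f_lo <- f_mid
    }
  }
  structure(list(threshold_MPa = (lo + hi) / 2, bracket_MPa = c(lo, hi),
                 fate_low = f_lo, fate_high = f_hi, out_of_range = FALSE,
                 n_evaluations = n_eval),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (isTRUE(x$out_of_range))
    cat("<threshold_result> out of range: fate", x$fate_low, "at both ends\n")
  else
    cat("<threshold_result>", signif(x$threshold_MPa, 4), "MPa (bracket [",
        signif(x$bracket_MPa[1], 4), ",", signif(x$bracket_MPa[2], 4),
        "],", x$n_evaluations, "fate evaluations)\n")
  invisible(x)
}

#' Threshold pressure over an initial-radius grid at several fluences
#'
#' Element-wise [threshold_pressure()] over `R0_nm_grid` x
#' `fluence_levels`. Out-of-range cells propagate as `NA`. Curves at higher
#' fluence lie at or below curves at lower fluence: added light lowers the
#' ultrasound pressure needed for cavitation.
#'
#' @param R0_nm_grid Initial radii, nm.
#' @param fluence_levels Fluences, mJ/cm^2.
#' @param ... Passed on to [threshold_pressure()].
#' @return A tibble with columns `R0_nm`, `fluence_mJcm2`, `threshold_MPa`.
#' @export
threshold_curve <- function(R0_nm_grid, fluence_levels, ...) {
  if (length(R0_nm_grid) == 0 || length(fluence_levels) == 0)
    stop("threshold_curve: grids must be non-empty")
  grid <- expand.grid(R0_nm = R0_nm_grid, fluence_mJcm2 = fluence_levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid$threshold_MPa <- mapply(function(r0, f)
    threshold_pressure(f, r0, ...)$threshold_MPa,
    grid$R0_nm, grid$fluence_mJcm2)
  tibble::as_tibble(grid)
}

#' Grow/dissolve regime map over pressure and fluence
#'
#' Fate of a pre-existing bubble of radius `R0_nm` at every cell of a
#' (peak negative pressure) x (fluence) grid, via [simulate_bubble()] +
#' [classify_fate()]. Each pressure column has at most one
#' DISSOLVE-to-GROW transition, whose location agrees with
#' [threshold_pressure()] to within one grid cell.
#'
#' @param pnp_MPa_grid Peak negative pressures, MPa (paper range 0-1).
#' @param fluence_grid Fluences, mJ/cm^2 (paper range 0-200).
#' @param R0_nm Bubble radius, nm.
#' @param medium,absorber,pulse Model configuration.
#' @param cycles Burst length per cell.
#' @param frequency_MHz Drive frequency, MHz.
#' @param ... Passed on to [simulate_bubble()].
#' @return A tibble with columns `pnp_MPa`, `fluence_mJcm2`, `fate`,
#'   `flux_mol_s`, `subharmonic`.
#' @export
regime_map <- function(pnp_MPa_grid = seq(0, 1, length.out = 21),
                       fluence_grid = seq(0, 200, length.out = 21),
                       R0_nm = 100, medium = medium_properties(),
                       absorber = vessel_absorber(), pulse = optical_pulse(),
                       cycles = 100, frequency_MHz = 0.25, ...) {
  grid <- expand.grid(pnp_MPa = pnp_MPa_grid, fluence_mJcm2 = fluence_grid,
                      KEEP.OUT.ATTRS = FALSE)
  # destination-size subharmonic depends on the drive pressure only;
  # compute lazily once per pressure
  sub_cache <- new.env(parent = emptyenv())
  sub_at <- function(p, d) {
    key <- format(p, digits = 15)
    if (is.null(sub_cache[[key]]))
      sub_cache[[key]] <- destination_subharmonic(d, medium, ...)
    sub_cache[[key]]
  }
  res <- mapply(function(p, f) {
    if (p == 0 && f == 0)
      return(list(fate = "DISSOLVE", flux = NA_real_, sub = 0))
    d <- put_drive(p, f, cycles = cycles, frequency_MHz = frequency_MHz,
                   absorber = absorber, pulse = pulse)
    tr <- simulate_bubble(d, R0_nm, medium, ...)
    cl <- classify_fate(tr, medium, check_period_doubling = FALSE)
    sub <- 0
    if (cl$fate != "DISSOLVE" &&
        max(tr$R_nm) >= resonant_radius(frequency_MHz / 2, medium)) {
      sub <- sub_at(p, d)
      cl <- classify_fate(tr, medium, destination_subharmonic = sub)
    }
    list(fate = cl$fate, flux = cl$flux_mol_s, sub = sub)
  }, grid$pnp_MPa, grid$fluence_mJcm2, SIMPLIFY = FALSE)
  grid$fate <- vapply(res, `[[`, character(1), "fate")
  grid$flux_mol_s <- vapply(res, `[[`, numeric(1), "flux")
  grid$subharmonic <- vapply(res, `[[`, numeric(1), "sub")
  tibble::as_tibble(grid)
}
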