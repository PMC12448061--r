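#' Run the bubble-dynamics mechanism study
#'
#' End-to-end reproduction of the simulation figure set: fate labels for
#' the three reference parameter combinations (0.6 MPa / 100 mJ/cm^2,
#' 0.8 / 120, 1.0 / 120), the threshold-versus-fluence curve, and the
#' grow/dissolve regime map over the (pressure, fluence) grid for a
#' pre-existing bubble of radius `R0_nm`.
#'
#' All stages are deterministic; identical configurations produce
#' identical outputs. When `out_dir` is given, the configuration snapshot
#' (JSON), the regime map, threshold curve and case table (CSV) are
#' written there.
#'
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param pnp_MPa_grid,fluence_grid Regime-map grids (defaults 21 x 21
#'   over 0-1 MPa x 0-200 mJ/cm^2).
#' @param threshold_fluences Fluences at which the threshold pressure is
#'   bisected for the threshold curve.
#' @param R0_nm Bubble radius, nm.
#' @param cycles Burst length per fate evaluation.
#' @param medium,absorber,pulse Model configuration.
#' @param cases Reference cases as a two-column matrix
#'   (PNP MPa, fluence mJ/cm^2).
#' @param ... Passed to [simulate_bubble()].
#' @return List with `cases` (tibble of fates), `thresholds` (tibble),
#'   `map` (tibble from [regime_map()]).
#' @export
run_mechanism_study <- function(out_dir = NULL,
                                pnp_MPa_grid = seq(0, 1, length.out = 21),
                                fluence_grid = seq(0, 200, length.out = 21),
                                threshold_fluences = c(0, 50, 100, 120,
                                                       150, 200),
                                R0_nm = 100, cycles = 100,
                                medium = medium_properties(),
                                absorber = vessel_absorber(),
                                pulse = optical_pulse(),
                                cases = rbind(c(0.6, 100), c(0.8, 120),
                                              c(1.0, 120)), ...) {
  case_rows <- lapply(seq_len(nrow(cases)), function(i) {
    d <- put_drive(cases[i, 1], cases[i, 2], cycles = cycles,
                   absorber = absorber, pulse = pulse)
    tr <- simulate_bubble(d, R0_nm, medium, ...)
    cl <- classify_fate(tr, medium)
    tibble::tibble(pnp_MPa = cases[i, 1], fluence_mJcm2 = cases[i, 2],
                   fate = cl$fate, flux_mol_s = cl$flux_mol_s,
                   max_r = cl$max_r, subharmonic = cl$subharmonic)
  })
  case_tbl <- do.call(rbind, case_rows)

  thr <- threshold_curve(R0_nm, threshold_fluences, medium = medium,
                         absorber = absorber, pulse = pulse,
                         cycles = cycles, ...)
  map <- regime_map(pnp_MPa_grid, fluence_grid, R0_nm = R0_nm,
                    medium = medium, absorber = absorber, pulse = pulse,
                    cycles = cycles, ...)
  res <- list(cases = case_tbl, thresholds = thr, map = map)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    snapshot_config(file.path(out_dir, "config.json"),
                    list(study = "mechanism",
                         pnp_MPa_grid = pnp_MPa_grid,
                         fluence_grid = fluence_grid,
                         threshold_fluences = threshold_fluences,
                         R0_nm = R0_nm, cycles = cycles,
                         medium = unclass(medium),
                         absorber = unclass(absorber),
                         pulse = unclass(pulse)))
    utils::write.csv(case_tbl, file.path(out_dir, "cases.csv"),
                     row.names = FALSE)
    utils::write.csv(thr, file.path(out_dir, "threshold_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(map, file.path(out_dir, "regime_map.csv"),
                     row.names = FALSE)
  }
  res
}

#' Run the synthetic phantom cavitation-detection study
#'
#' Generates a grid of synthetic B-mode stacks whose programmed per-frame
#' event probability rises smoothly with both ultrasound pressure and light
#' fluence, runs baseline fitting and cavitation detection on them, and
#' reports the estimated cavitation-probability map next to the programmed
#' truth.
#'
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param pressures_MPa,fluences Grid of acquisition labels.
#' @param n_frames Frames per stack (study records 100).
#' @param cp_truth Function `(pressure, fluence) -> p_event` programming
#'   the event probability surface; the default is a logistic surface
#'   increasing in both arguments.
#' @param seed Mandatory integer seed.
#' @param ... Passed to [gen_bmode_stack()].
#' @return Tibble with columns `pressure_MPa`, `fluence_mJcm2`,
#'   `cp_true` (programmed), `cp_frames` (realized frame fraction), `cp`
#'   (detected), `n_frames`.
#' @export
run_phantom_study <- function(out_dir = NULL,
                              pressures_MPa = seq(0.2, 1.4, by = 0.3),
                              fluences = seq(0, 200, by = 50),
                              n_frames = 100,
                              cp_truth = function(p, f)
                                stats::plogis(5 * (p / 1.4 + f / 200 - 1)),
                              seed, ...) {
  if (missing(seed)) stop("run_phantom_study: an explicit seed is required")
  base_gen <- gen_bmode_stack(n_frames = n_frames, p_event = 0,
                              fluence_mJcm2 = 0, seed = seed, ...)
  baseline <- fit_baseline(base_gen$stack)
  grid <- expand.grid(pressure_MPa = pressures_MPa,
                      fluence_mJcm2 = fluences, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$pressure_MPa[i]; f <- grid$fluence_mJcm2[i]
    pe <- cp_truth(p, f)
    g <- gen_bmode_stack(n_frames = n_frames, p_event = pe,
                         pressure_MPa = p, fluence_mJcm2 = f,
                         seed = seed + i, ...)
    cp <- cavitation_probability(g$stack, baseline)
    tibble::tibble(pressure_MPa = p, fluence_mJcm2 = f, cp_true = pe,
                   cp_frames = mean(g$truth), cp = as.numeric(cp),
                   n_frames = n_frames)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    snapshot_config(file.path(out_dir, "config.json"),
                    list(study = "phantom", pressures_MPa = pressures_MPa,
                         fluences = fluences, n_frames = n_frames,
                         seed = seed))
    utils::write.csv(res, file.path(out_dir, "cp_map.csv"),
                     row.names = FALSE)
  }
  res
}

#' Run the synthetic OCT-A treatment-outcome analysis
#'
#' Generates paired treated/untreated OCT scan series for each (side,
#' timepoint) condition with a programmed vessel-density reduction, runs
#' the speckle-variance pipeline ([speckle_variance()], [vessel_density()]
#' with the 150-300 um gate, [percent_reduction()]), and reports per-region
#' densities, normalized densities, group summaries and the paired t-test
#' between untreated and treated measurements.
#'
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param conditions Tibble/data.frame with columns `side`, `timepoint`,
#'   `reduction_pct` (programmed truth per condition). The default encodes
#'   the day-7 top/bottom reductions used as programmed ground truth.
#' @param n_regions Treated regions per condition.
#' @param gate_um Analysis depth gate, um.
#' @param seed Mandatory integer seed.
#' @param ... Passed to [gen_oct_series()].
#' @return List with `regions` (per-region tidy tibble), `summary`
#'   (per-condition mean/SD and recovered reduction), `test` (paired
#'   t-test over all regions).
#' @export
run_treatment_analysis <- function(out_dir = NULL,
                                   conditions = tibble::tibble(
                                     side = c("top", "bottom"),
                                     timepoint = "day7",
                                     reduction_pct = c(45.20, 36.06)),
                                   n_regions = 4, gate_um = c(150, 300),
                                   seed, ...) {
  if (missing(seed))
    stop("run_treatment_analysis: an explicit seed is required")
  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(conditions))) {
    retain <- 1 - conditions$reduction_pct[i] / 100
    for (rgn in seq_len(n_regions)) {
      idx <- idx + 1L
      g <- gen_oct_series(treated_fraction_retained = retain,
                          seed = seed + idx, ...)
      du <- vessel_density(speckle_variance(g$untreated), gate_um)
      dt <- vessel_density(speckle_variance(g$treated), gate_um)
      rows[[idx]] <- tibble::tibble(
        side = conditions$side[i], timepoint = conditions$timepoint[i],
        region = rgn, reduction_true_pct = conditions$reduction_pct[i],
        density_untreated = du, density_treated = dt,
        normalized_density = dt / du,
        reduction_pct = percent_reduction(dt, du))
    }
  }
  regions <- do.call(rbind, rows)
  agg <- split(regions, interaction(regions$side, regions$timepoint,
                                    drop = TRUE))
  summary_tbl <- do.call(rbind, lapply(agg, function(g)
    tibble::tibble(side = g$side[1], timepoint = g$timepoint[1],
                   reduction_true_pct = g$reduction_true_pct[1],
                   mean_reduction_pct = mean(g$reduction_pct),
                   sd_reduction_pct = stats::sd(g$reduction_pct),
                   mean_normalized_density = mean(g$normalized_density),
                   n = nrow(g))))
  rownames(summary_tbl) <- NULL
  test <- paired_compare(regions$density_untreated,
                         regions$density_treated)
  res <- list(regions = regions, summary = summary_tbl, test = test)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    snapshot_config(file.path(out_dir, "config.json"),
                    list(study = "treatment",
                         conditions = as.data.frame(conditions),
                         n_regions = n_regions, gate_um = gate_um,
                         seed = seed))
    utils::write.csv(regions, file.path(out_dir, "densities.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tbl, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(test, file.path(out_dir, "paired_test.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

snapshot_config <- function(path, cfg) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}
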