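#' Generate a synthetic B-mode stack of a tube phantom
#'
#' Emulates the active-cavitation-detection recordings of a blood-vessel
#' phantom: a bright static tube wall (annulus) over background speckle,
#' with stochastic hyperechoic cavitation events injected inside the tube
#' lumen in a Bernoulli(`p_event`) subset of frames. The ground-truth event
#' indicator is returned alongside the stack so downstream detectors can be
#' scored without re-deriving truth.
#'
#' Speckle is drawn from a clipped noise distribution (values limited to
#' `clip_sd` standard deviations about the mean): B-mode display data are
#' log-compressed and quantized into a finite dynamic range, so the
#' extreme tails of an unbounded noise model never survive into the
#' recorded image. An unclipped background would make the any-pixel
#' threshold rule of [detect_frame()] fire on noise alone for any usefully
#' sized region of interest, and the margin between the clip boundary and
#' the `k = 3` detection threshold also absorbs the sampling error of the
#' per-pixel baseline statistics estimated from a finite baseline
#' recording.
#'
#' @param shape Frame shape `c(rows, cols)`.
#' @param n_frames Number of frames (the phantom study records 100).
#' @param tube_center,tube_radius_px,wall_px Tube geometry in pixels: lumen
#'   centre, lumen radius, wall thickness.
#' @param speckle_mean,speckle_sd Background speckle mean and SD.
#' @param p_event Per-frame probability of a cavitation event in `[0, 1]`.
#' @param event_contrast Event brightness above the local mean, in
#'   multiples of `speckle_sd` (default 6).
#' @param event_px Event radius in pixels.
#' @param wall_contrast Wall brightness above background, in SDs.
#' @param clip_sd Noise truncation, in SDs about the mean.
#' @param noise Noise family: `"gaussian"` (default) or `"rayleigh"` (with
#'   matched mean and SD, same truncation).
#' @param pressure_MPa,fluence_mJcm2 Labels forwarded to the stack.
#' @param seed Mandatory integer seed; the generator is a pure function of
#'   its arguments.
#' @return List with `stack` (a [frame_stack()]), `truth` (logical
#'   `n_frames` event indicator), `mask_true` (logical matrix of the wall
#'   annulus), `lumen` (logical matrix).
#' @examples
#' g <- gen_bmode_stack(p_event = 0.3, seed = 1)
#' mean(g$truth)
#' @export
gen_bmode_stack <- function(shape = c(64, 64), n_frames = 100,
                            tube_center = NULL, tube_radius_px = 10,
                            wall_px = 3, speckle_mean = 50, speckle_sd = 5,
                            p_event = 0.3, event_contrast = 6, event_px = 2,
                            wall_contrast = 12, clip_sd = 2.0,
                            noise = c("gaussian", "rayleigh"),
                            pressure_MPa = NA_real_,
                            fluence_mJcm2 = NA_real_, seed) {
  if (missing(seed)) stop("gen_bmode_stack: an explicit seed is required")
  noise <- match.arg(noise)
  if (p_event < 0 || p_event > 1)
    stop("gen_bmode_stack: p_event must lie in [0, 1]")
  if (event_contrast <= 0)
    stop("gen_bmode_stack: event contrast must be positive")
  if (is.null(tube_center)) tube_center <- (shape + 1) / 2
  rows <- shape[1]; cols <- shape[2]
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  d2 <- (rr - tube_center[1])^2 + (cc - tube_center[2])^2
  lumen <- d2 <= tube_radius_px^2
  wall <- d2 > tube_radius_px^2 & d2 <= (tube_radius_px + wall_px)^2
  if (tube_radius_px - event_px < 1)
    stop("gen_bmode_stack: event region falls outside the lumen; ",
         "enlarge the tube or shrink event_px")
  inner <- d2 <= (tube_radius_px - event_px)^2

  rng <- function(n) {
    if (noise == "gaussian") {
      x <- stats::rnorm(n, 0, speckle_sd)
    } else {
      scale <- speckle_sd / sqrt((4 - pi) / 2)
      x <- scale * sqrt(-2 * log(stats::runif(n)))
      x <- x - scale * sqrt(pi / 2)  # centre at zero
    }
    pmin(pmax(x, -clip_sd * speckle_sd), clip_sd * speckle_sd)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  truth <- stats::runif(n_frames) < p_event
  frames <- array(speckle_mean + rng(rows * cols * n_frames),
                  c(rows, cols, n_frames))
  wall_val <- speckle_mean + wall_contrast * speckle_sd
  ev_centers <- which(inner)
  for (i in seq_len(n_frames)) {
    frames[, , i][wall] <- wall_val + rng(sum(wall))
    if (truth[i]) {
      ctr <- ev_centers[sample.int(length(ev_centers), 1)]
      er <- (ctr - 1) %% rows + 1
      ec <- (ctr - 1) %/% rows + 1
      ev <- (rr - er)^2 + (cc - ec)^2 <= event_px^2
      frames[, , i][ev] <- frames[, , i][ev] + event_contrast * speckle_sd
    }
  }
  frames[frames < 0] <- 0
  list(stack = frame_stack(frames, pressure_MPa, fluence_mJcm2),
       truth = truth, mask_true = wall, lumen = lumen)
}

#' Generate a synthetic pair of repeated OCT B-scan series
#'
#' Emulates the OCT-angiography acquisitions: at each lateral position a
#' B-scan (depth x lateral) is recorded `n_rep` times. Static tissue pixels
#' repeat across the repeats up to small noise; vessel (flow) pixels are
#' redrawn independently per repeat, so speckle-variance contrast arises
#' from flow decorrelation. Vessels are placed as depth segments within a
#' configurable depth band. The treated series retains a programmed
#' fraction of the vessel pixels (`treated_fraction_retained`), converting
#' the rest to static tissue, which programs the treated/untreated vessel
#' density ratio and hence the ground-truth percent reduction
#' `100 * (1 - treated_fraction_retained)`.
#'
#' @param n_lateral,n_positions Lateral A-lines per B-scan and number of
#'   B-scan positions (the scans cover `extent_mm` x `extent_mm`).
#' @param n_depth Depth pixels per A-line.
#' @param pitch_um Axial pixel pitch, um/px (default 3).
#' @param extent_mm Lateral extent of the scan, mm (default 8).
#' @param n_rep Repeats per position (>= 2; the study uses 3).
#' @param vessel_fraction Areal fraction of (lateral, position) columns
#'   containing a vessel segment.
#' @param vessel_band_um Depth band holding the vessels, um (defaults to
#'   the analysis gate 150-300 um).
#' @param segment_um Vessel segment length range in depth, um.
#' @param mean_intensity Mean backscatter intensity (arbitrary units).
#' @param flow_sd Per-repeat SD of flow pixels (decorrelated speckle).
#' @param static_sd Per-repeat SD of static-tissue pixels.
#' @param treated_fraction_retained Fraction of vessel columns retained in
#'   the treated series, in `[0, 1]`.
#' @param seed Mandatory integer seed.
#' @return List with `untreated` and `treated` (objects of class
#'   `oct_scan_series`), and `truth`: vessel column table, retained column
#'   indicator, programmed `reduction_pct`.
#' @examples
#' g <- gen_oct_series(treated_fraction_retained = 0.6, seed = 1)
#' g$truth$reduction_pct
#' @export
gen_oct_series <- function(n_lateral = 96, n_positions = 24, n_depth = 110,
                           pitch_um = 3, extent_mm = 8, n_rep = 3,
                           vessel_fraction = 0.12,
                           vessel_band_um = c(150, 300),
                           segment_um = c(30, 90), mean_intensity = 1,
                           flow_sd = 0.5, static_sd = 0.015,
                           treated_fraction_retained = 1, seed) {
  if (missing(seed)) stop("gen_oct_series: an explicit seed is required")
  if (n_rep < 2) stop("gen_oct_series: need at least 2 repeats")
  if (treated_fraction_retained < 0 || treated_fraction_retained > 1)
    stop("gen_oct_series: treated_fraction_retained must lie in [0, 1]")
  if (vessel_fraction < 0 || vessel_fraction > 1)
    stop("gen_oct_series: vessel_fraction must lie in [0, 1]")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  depth_um <- (seq_len(n_depth) - 0.5) * pitch_um
  band <- which(depth_um >= vessel_band_um[1] & depth_um <= vessel_band_um[2])
  if (!length(band))
    stop("gen_oct_series: vessel band lies outside the scanned depth")

  n_cols <- n_lateral * n_positions
  n_ves <- round(vessel_fraction * n_cols)
  ves_cols <- sample.int(n_cols, n_ves)
  seg_px <- pmax(1, round(stats::runif(n_ves, segment_um[1], segment_um[2]) /
                            pitch_um))
  seg_top <- band[1] + floor(stats::runif(n_ves) *
                               pmax(1, length(band) - seg_px + 1)) - 1L
  n_keep <- round(treated_fraction_retained * n_ves)
  retained <- logical(n_ves)
  if (n_keep > 0) retained[sample.int(n_ves, n_keep)] <- TRUE

  build <- function(keep) {
    # static volume, shared across repeats up to static_sd noise
    base <- mean_intensity +
      stats::rnorm(n_depth * n_cols, 0, static_sd * 3)  # frozen tissue texture
    vol <- array(NA_real_, c(n_depth, n_lateral, n_rep, n_positions))
    flow_vox <- matrix(FALSE, n_depth, n_cols)
    act <- which(keep)
    for (j in seq_along(act)) {
      k <- act[j]
      rows_k <- seg_top[k]:min(seg_top[k] + seg_px[k] - 1L, band[length(band)])
      flow_vox[rows_k, ves_cols[k]] <- TRUE
    }
    base_m <- matrix(base, n_depth, n_cols)
    for (r in seq_len(n_rep)) {
      snap <- base_m + stats::rnorm(n_depth * n_cols, 0, static_sd)
      nf <- sum(flow_vox)
      if (nf > 0)
        snap[flow_vox] <- mean_intensity +
          stats::rnorm(nf, 0, flow_sd)  # redrawn independently per repeat
      snap[snap < 0] <- 0
      vol[, , r, ] <- array(snap, c(n_depth, n_lateral, n_positions))
    }
    structure(list(volume = vol, pitch_um = pitch_um, extent_mm = extent_mm,
                   n_rep = n_rep),
              class = "oct_scan_series")
  }

  untreated <- build(rep(TRUE, n_ves))
  treated <- build(retained)
  list(untreated = untreated, treated = treated,
       truth = list(vessel_cols = ves_cols, seg_top = seg_top,
                    seg_px = seg_px, retained = retained,
                    reduction_pct = 100 * (1 - treated_fraction_retained)))
}

#' @export
print.oct_scan_series <- function(x, ...) {
  d <- dim(x$volume)
  cat("<oct_scan_series>", d[4], "positions x", d[3], "repeats,",
      d[1], "depth x", d[2], "lateral px (", x$pitch_um, "um axial pitch,",
      x$extent_mm, "mm extent )\n")
  invisible(x)
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
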