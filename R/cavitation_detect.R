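#' B-mode frame stack
#'
#' Container for a stack of B-mode frames acquired over one sonication,
#' stored as a `rows x cols x n_frames` array with the acquisition labels
#' (ultrasound peak negative pressure, light fluence) used to place the
#' stack on the cavitation-probability map. Pixels are indexed `[row, col]`
#' from the top-left corner.
#'
#' @param frames Numeric array `rows x cols x n_frames` (a matrix is
#'   promoted to a single-frame stack). Intensities must be finite and
#'   non-negative.
#' @param pressure_MPa,fluence_mJcm2 Acquisition labels.
#' @param pixel_mm Pixel size metadata, mm.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pressure_MPa = NA_real_,
                        fluence_mJcm2 = NA_real_, pixel_mm = NA_real_) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frame_stack: frames must be a rows x cols x n_frames array")
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("frame_stack: intensities must be finite and non-negative")
  structure(list(frames = frames, n_frames = dim(frames)[3],
                 pressure_MPa = pressure_MPa,
                 fluence_mJcm2 = fluence_mJcm2, pixel_mm = pixel_mm),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("<frame_stack>", d[3], "frames of", d[1], "x", d[2],
      "px; pressure", x$pressure_MPa, "MPa, fluence", x$fluence_mJcm2,
      "mJ/cm^2\n")
  invisible(x)
}

#' Derive a structure mask from a baseline stack
#'
#' The hyperechoic tube walls must be excluded before cavitation detection.
#' When no mask image is supplied, one is derived from the temporal-mean
#' baseline image: pixel intensities are split into two clusters (k-means),
#' the bright cluster is taken as structure, and the mask is dilated by
#' `dilate_px` pixels to cover partial-volume edges.
#'
#' @param stack A baseline [frame_stack()].
#' @param dilate_px Dilation radius in pixels.
#' @return Logical matrix, `TRUE` where pixels are masked (excluded).
#' @export
auto_mask <- function(stack, dilate_px = 2) {
  stopifnot(inherits(stack, "frame_stack"))
  mu <- apply(stack$frames, c(1, 2), mean)
  if (diff(range(mu)) < sqrt(.Machine$double.eps))
    return(matrix(FALSE, nrow(mu), ncol(mu)))  # featureless image
  km <- stats::kmeans(as.vector(mu), centers = range(mu), iter.max = 50)
  bright <- which.max(km$centers)
  mask <- matrix(km$cluster == bright, nrow(mu), ncol(mu))
  if (dilate_px > 0 && any(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    out <- mask
    for (dr in -dilate_px:dilate_px) for (dc in -dilate_px:dilate_px) {
      if (dr * dr + dc * dc > dilate_px^2) next
      rr <- pmin(pmax(idx[, 1] + dr, 1L), nrow(mu))
      cc <- pmin(pmax(idx[, 2] + dc, 1L), ncol(mu))
      out[cbind(rr, cc)] <- TRUE
    }
    mask <- out
  }
  mask
}

#' Fit per-pixel baseline statistics from a zero-fluence stack
#'
#' Estimates the per-pixel temporal mean and standard deviation of the
#' baseline recording (acquired at 0 mJ/cm^2, i.e. ultrasound only, no
#' cavitation events), restricted to unmasked pixels. Detection then flags
#' any unmasked pixel exceeding `mu + k * sd` ([detect_frame()]).
#'
#' Per-pixel statistics are the default because B-mode speckle is spatially
#' inhomogeneous; `global = TRUE` instead pools all unmasked pixels into a
#' single mean/SD pair (the alternative reading of a "baseline" threshold).
#'
#' @param stack A baseline [frame_stack()] with at least 2 frames.
#' @param mask Logical matrix (`TRUE` = excluded), or `NULL` to derive one
#'   with [auto_mask()].
#' @param k Threshold multiplier in baseline SDs (default 3).
#' @param global Use one pooled mean/SD instead of per-pixel statistics.
#' @return An object of class `acd_baseline` with fields `mu`, `sd`
#'   (matrices), `mask`, `k`, `global`.
#' @export
fit_baseline <- function(stack, mask = NULL, k = 3, global = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  if (stack$n_frames < 2)
    stop("fit_baseline: need at least 2 baseline frames to estimate an SD")
  if (k <= 0) stop("fit_baseline: k must be positive")
  if (is.null(mask)) mask <- auto_mask(stack)
  if (!is.logical(mask) || !identical(dim(mask), dim(stack$frames)[1:2]))
    stop("fit_baseline: mask shape must match the frames")
  mu <- apply(stack$frames, c(1, 2), mean)
  sd_ <- apply(stack$frames, c(1, 2), stats::sd)
  if (global) {
    mu_g <- mean(mu[!mask])
    sd_g <- stats::sd(as.vector(
      aperm(stack$frames, c(3, 1, 2))[, !mask, drop = FALSE]))
    mu[] <- mu_g
    sd_[] <- sd_g
  }
  structure(list(mu = mu, sd = sd_, mask = mask, k = k, global = global),
            class = "acd_baseline")
}

#' Detect cavitation in a single frame
#'
#' A frame is flagged when any unmasked pixel exceeds the baseline mean by
#' more than `k` baseline standard deviations.
#'
#' @param frame Numeric matrix matching the baseline geometry.
#' @param baseline An [fit_baseline()] model.
#' @return List with `flagged` (logical) and `n_suprathreshold_pixels`.
#' @export
detect_frame <- function(frame, baseline) {
  stopifnot(inherits(baseline, "acd_baseline"))
  if (!identical(dim(frame), dim(baseline$mu)))
    stop("detect_frame: frame shape does not match the baseline")
  over <- frame > baseline$mu + baseline$k * baseline$sd
  over[baseline$mask] <- FALSE
  n <- sum(over)
  list(flagged = n > 0, n_suprathreshold_pixels = n)
}

#' Cavitation probability of a frame stack
#'
#' Fraction of frames in which cavitation is detected ([detect_frame()]):
#' `CP = n_flagged / n_frames`, exactly.
#'
#' @param stack A [frame_stack()].
#' @param baseline An [fit_baseline()] model fit on the matching
#'   zero-fluence recording.
#' @return CP in `[0, 1]`, with attributes `flagged` (frame indices) and
#'   `n_frames`.
#' @export
cavitation_probability <- function(stack, baseline) {
  stopifnot(inherits(stack, "frame_stack"))
  if (stack$n_frames < 1) stop("cavitation_probability: empty stack")
  flagged <- which(vapply(seq_len(stack$n_frames), function(i)
    detect_frame(stack$frames[, , i], baseline)$flagged, logical(1)))
  structure(length(flagged) / stack$n_frames,
            flagged = flagged, n_frames = stack$n_frames)
}

#' Cavitation-probability map over pressure and fluence
#'
#' Applies [cavitation_probability()] to each labelled stack and assembles
#' the long-format (pressure, fluence) -> CP table of the phantom study.
#'
#' @param stacks List of [frame_stack()]s with `pressure_MPa` and
#'   `fluence_mJcm2` labels.
#' @param baseline A single [fit_baseline()] model, or a list of models
#'   parallel to `stacks` (one per acquisition series).
#' @return A tibble with columns `pressure_MPa`, `fluence_mJcm2`, `cp`,
#'   `n_frames`.
#' @export
cp_map <- function(stacks, baseline) {
  if (!length(stacks)) stop("cp_map: no stacks supplied")
  baselines <- if (inherits(baseline, "acd_baseline"))
    rep(list(baseline), length(stacks)) else baseline
  if (length(baselines) != length(stacks))
    stop("cp_map: need one baseline, or one per stack")
  rows <- lapply(seq_along(stacks), function(i) {
    s <- stacks[[i]]
    if (is.null(baselines[[i]]))
      stop("cp_map: missing baseline for stack ", i)
    cp <- cavitation_probability(s, baselines[[i]])
    tibble::tibble(pressure_MPa = s$pressure_MPa,
                   fluence_mJcm2 = s$fluence_mJcm2,
                   cp = as.numeric(cp), n_frames = s$n_frames)
  })
  do.call(rbind, rows)
}
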