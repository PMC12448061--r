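#' Speckle-variance OCT angiography image
#'
#' Computes, at every (depth, lateral, position) voxel, the temporal
#' variance of intensity across the repeated B-scans:
#' `(1/N) * sum_i (I_i - mean(I))^2` (population convention, divisor
#' `N = n_rep`; recorded in the output metadata). Flow decorrelates the
#' speckle between repeats and lights up; static tissue cancels.
#'
#' @param series An `oct_scan_series` (see [gen_oct_series()]) with
#'   `n_rep >= 2` repeats.
#' @return An object of class `octa_image`: `values`
#'   (depth x lateral x position array), `pitch_um`, `n_rep`,
#'   `variance_divisor`.
#' @export
speckle_variance <- function(series) {
  stopifnot(inherits(series, "oct_scan_series"))
  v <- series$volume
  d <- dim(v)
  if (length(d) != 4L)
    stop("speckle_variance: volume must be depth x lateral x repeat x position")
  n_rep <- d[3]
  if (n_rep < 2) stop("speckle_variance: need at least 2 repeats")
  mu <- apply(v, c(1, 2, 4), mean)
  ss <- array(0, d[c(1, 2, 4)])
  for (r in seq_len(n_rep)) {
    vr <- array(v[, , r, , drop = FALSE], d[c(1, 2, 4)])
    ss <- ss + (vr - mu)^2
  }
  structure(list(values = ss / n_rep, pitch_um = series$pitch_um,
                 n_rep = n_rep, variance_divisor = n_rep),
            class = "octa_image")
}

#' @export
print.octa_image <- function(x, ...) {
  d <- dim(x$values)
  cat("<octa_image>", d[1], "depth x", d[2], "lateral x", d[3],
      "positions; population variance over", x$n_rep, "repeats\n")
  invisible(x)
}

#' Depth-gated vessel density from an OCT-A image
#'
#' Vessel density is the total OCT-A (speckle-variance) signal within the
#' analysis depth band, normalized by the number of gated voxels - i.e. the
#' area-normalized mean angiography intensity over the whole scan. The
#' depth of voxel i is `(i - 0.5) * pitch_um`.
#'
#' @param octa An [speckle_variance()] image.
#' @param gate_um Depth gate `c(min, max)` in um (study band 150-300 um).
#' @return Density scalar (mean gated OCT-A intensity).
#' @export
vessel_density <- function(octa, gate_um = c(150, 300)) {
  stopifnot(inherits(octa, "octa_image"))
  depth_um <- (seq_len(dim(octa$values)[1]) - 0.5) * octa$pitch_um
  keep <- depth_um >= gate_um[1] & depth_um <= gate_um[2]
  if (!any(keep))
    stop("vessel_density: depth gate [", gate_um[1], ", ", gate_um[2],
         "] um contains no voxels (scan depth ",
         round(max(depth_um)), " um)")
  mean(octa$values[keep, , ])
}

#' Percent reduction of treated relative to untreated density
#'
#' `100 * (1 - treated / untreated)`.
#'
#' @param treated,untreated Density scalars; `untreated` must be positive.
#' @return Percent reduction (0 when equal, 100 when treated is zero;
#'   negative if the treated density exceeds the untreated one).
#' @examples
#' percent_reduction(0.55, 1)  # 45
#' @export
percent_reduction <- function(treated, untreated) {
  if (!is.numeric(untreated) || any(untreated <= 0))
    stop("percent_reduction: untreated density must be positive")
  if (any(treated < 0)) stop("percent_reduction: densities must be >= 0")
  100 * (1 - treated / untreated)
}

#' Paired comparison of two density groups
#'
#' Paired t-test between matched density measurements (e.g. treated vs
#' untreated regions of the same animal). Zero-variance differences are a
#' degenerate case: identical groups return `t = 0, p = 1`; constant
#' non-zero differences are reported with `degenerate = TRUE` and an `NA`
#' p-value rather than a spuriously infinite statistic.
#'
#' @param a,b Equal-length numeric vectors of paired measurements,
#'   `n >= 2`.
#' @return List with `t`, `df`, `p_value`, `mean_difference`, `n`,
#'   `degenerate`.
#' @examples
#' paired_compare(c(1.0, 0.8, 0.9), c(0.5, 0.4, 0.6))
#' @export
paired_compare <- function(a, b) {
  if (length(a) != length(b))
    stop("paired_compare: groups must be paired (equal length)")
  n <- length(a)
  if (n < 2) stop("paired_compare: need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p_value = 1, mean_difference = 0,
                  n = n, degenerate = FALSE))
    return(list(t = NA_real_, df = n - 1, p_value = NA_real_,
                mean_difference = mean(d), n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate),
       n = n, degenerate = FALSE)
}
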