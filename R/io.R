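#' Export a waveform as CSV with a JSON metadata sidecar
#'
#' Writes a two-column CSV (`time_ns`, `pressure_MPa`) plus a `.json`
#' sidecar carrying the waveform descriptors (peak amplitude, width,
#' frequency, duty cycle - whichever the object defines).
#'
#' @param waveform A `pa_waveform`, `us_burst` or `drive_waveform`.
#' @param path Output CSV path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
export_waveform <- function(waveform, path) {
  if (!inherits(waveform, c("pa_waveform", "us_burst", "drive_waveform")))
    stop("export_waveform: not a waveform object")
  utils::write.csv(data.frame(time_ns = waveform$time_ns,
                              pressure_MPa = waveform$pressure_MPa),
                   path, row.names = FALSE)
  meta <- waveform[setdiff(names(waveform), c("time_ns", "pressure_MPa"))]
  meta$class <- class(waveform)[1]
  jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a B-mode frame stack from TIFF
#'
#' Loads a multi-page TIFF (or every single-page TIFF in a directory, in
#' lexical order) into a [frame_stack()]. Intensities are returned on the
#' scale stored in the file.
#'
#' @param path A `.tif`/`.tiff` file or a directory of them.
#' @param pressure_MPa,fluence_mJcm2 Acquisition labels to attach.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, pressure_MPa = NA_real_,
                             fluence_mJcm2 = NA_real_) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("read_frame_stack: the 'tiff' package is required")
  files <- if (dir.exists(path))
    sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
  else path
  pages <- unlist(lapply(files, function(f)
    tiff::readTIFF(f, all = TRUE, as.is = TRUE)), recursive = FALSE)
  if (!length(pages)) stop("read_frame_stack: no TIFF pages found")
  frames <- array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages)))
  frame_stack(frames, pressure_MPa, fluence_mJcm2)
}

#' Write a frame stack to a multi-page TIFF
#'
#' Intensities are rescaled to `[0, 1]` by `scale_max` (default: the stack
#' maximum) as required by the TIFF writer; the scale is returned so reads
#' can be undone.
#'
#' @param stack A [frame_stack()].
#' @param path Output `.tif` path.
#' @param scale_max Intensity mapped to full scale.
#' @return `scale_max`, invisibly.
#' @export
write_frame_stack <- function(stack, path, scale_max = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("write_frame_stack: the 'tiff' package is required")
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(scale_max)) scale_max <- max(stack$frames)
  if (scale_max <= 0) scale_max <- 1
  pages <- lapply(seq_len(stack$n_frames), function(i)
    pmin(stack$frames[, , i] / scale_max, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(scale_max)
}
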