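#' Acquisition calibration metadata
#'
#' Bundles the physical calibration of a 4-D (xyz-t) confocal acquisition so
#' that all downstream computation happens in micrometres and seconds.
#'
#' @param pixel_size_xy Lateral pixel size, um/pixel. Must be > 0.
#' @param z_step Axial slice spacing, um/slice. Must be > 0.
#' @param frame_interval Time between consecutive frames (volumes), seconds.
#' @param anterograde_axis Length-2 numeric xy vector giving the image
#'   direction of anterograde transport (away from the cell body). Normalised
#'   to unit length; default `c(1, 0)`, i.e. +x. In microgroove chambers axons
#'   run parallel, so a single axis suffices.
#' @param n_frames,n_z,height,width Grid dimensions (counts).
#'
#' @return An object of class `acquisition_metadata`.
#' @export
acquisition_metadata <- function(pixel_size_xy, z_step, frame_interval,
                                 anterograde_axis = c(1, 0),
                                 n_frames = NA_integer_, n_z = NA_integer_,
                                 height = NA_integer_, width = NA_integer_) {
  stopifnot(is.numeric(pixel_size_xy), length(pixel_size_xy) == 1L, pixel_size_xy > 0)
  stopifnot(is.numeric(z_step), length(z_step) == 1L, z_step > 0)
  stopifnot(is.numeric(frame_interval), length(frame_interval) == 1L, frame_interval > 0)
  stopifnot(is.numeric(anterograde_axis), length(anterograde_axis) == 2L)
  nrm <- sqrt(sum(anterograde_axis^2))
  if (!is.finite(nrm) || nrm <= 0) stop("anterograde_axis must be a nonzero xy vector")
  structure(list(
    pixel_size_xy = as.numeric(pixel_size_xy),
    z_step = as.numeric(z_step),
    frame_interval = as.numeric(frame_interval),
    anterograde_axis = anterograde_axis / nrm,
    n_frames = as.integer(n_frames), n_z = as.integer(n_z),
    height = as.integer(height), width = as.integer(width)
  ), class = "acquisition_metadata")
}

#' @export
print.acquisition_metadata <- function(x, ...) {
  cat(sprintf(
    "acquisition_metadata: %d frame(s) x %d z x %d y x %d x | %.4g um/px, %.4g um/z, dt = %.4g s\n",
    x$n_frames, x$n_z, x$height, x$width,
    x$pixel_size_xy, x$z_step, x$frame_interval))
  invisible(x)
}

#' Calibrated 4-D image sequence
#'
#' A non-negative intensity array indexed `(t, z, y, x)` (0-based physical
#' convention: voxel `(iz, iy, ix)` sits at `(x, y, z) = (ix * pixel_size_xy,
#' iy * pixel_size_xy, iz * z_step)` um) together with its
#' [acquisition_metadata()].
#'
#' @param intensities 4-D numeric array, dimensions `(t, z, y, x)`, finite and
#'   non-negative.
#' @param metadata An [acquisition_metadata()]; its counts must match
#'   `dim(intensities)` (missing counts are filled in from the array).
#'
#' @return An object of class `image_sequence_4d` with elements `intensities`
#'   and `metadata`.
#' @export
image_sequence_4d <- function(intensities, metadata) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 4L)
  if (!inherits(metadata, "acquisition_metadata"))
    stop("metadata must be an acquisition_metadata object")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("intensities must be finite")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  d <- dim(intensities)
  declared <- c(metadata$n_frames, metadata$n_z, metadata$height, metadata$width)
  for (k in seq_len(4L)) {
    if (is.na(declared[k])) declared[k] <- d[k]
    else if (declared[k] != d[k])
      stop(sprintf("array dimension %d (%d) does not match metadata (%d)",
                   k, d[k], declared[k]))
  }
  metadata$n_frames <- declared[1L]; metadata$n_z <- declared[2L]
  metadata$height <- declared[3L]; metadata$width <- declared[4L]
  structure(list(intensities = intensities, metadata = metadata),
            class = "image_sequence_4d")
}

#' @export
print.image_sequence_4d <- function(x, ...) {
  cat("image_sequence_4d\n  ")
  print(x$metadata)
  invisible(x)
}

#' Extract one 3-D volume (z, y, x) from an image sequence
#'
#' @param seq An [image_sequence_4d()].
#' @param t Frame index (1-based).
#' @return 3-D array `(z, y, x)`.
#' @export
get_volume <- function(seq, t) {
  stopifnot(inherits(seq, "image_sequence_4d"))
  d <- dim(seq$intensities)
  if (t < 1L || t > d[1L]) stop("frame index out of range")
  array(seq$intensities[t, , , ], dim = d[2:4])
}
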