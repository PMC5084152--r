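# Particle segmentation: coarse PP-map thresholding plus marker-controlled
# watershed, so the number of segmented mitochondria equals the number of
# markers exactly (no artificial splits or merges).

#' Coarse particle mask from a PP map
#'
#' Thresholds the particle-probability map and removes connected components
#' smaller than a minimum volume derived from the particle diameter.
#'
#' @param pp_map 3-D PP map in `[0, 1]`.
#' @param threshold Threshold in `(0, 1)`.
#' @param diameter_px Particle diameter, pixels.
#' @param min_volume_factor Minimum component volume as a fraction of
#'   `(diameter_px / 2)^3` voxels (default 0.15).
#' @return Logical 3-D array.
#' @export
coarse_particle_mask <- function(pp_map, threshold = 0.5, diameter_px = 7L,
                                 min_volume_factor = 0.15) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  mask <- pp_map >= threshold
  if (!any(mask)) return(array(FALSE, dim = dim(pp_map)))
  min_vol <- max(1, min_volume_factor * (diameter_px / 2)^3)
  labs <- .cc_label_3d(as.logical(mask), dim(pp_map))
  sizes <- tabulate(labs[labs > 0L])
  small <- which(sizes < min_vol)
  if (length(small)) mask[labs %in% small] <- FALSE
  array(mask, dim = dim(pp_map))
}

#' Foreground markers from a PP map
#'
#' Local maxima inside the mask, with anisotropic minimum separation
#' `diameter_px / 2` voxels in xy (scaled by `z_ratio` axially) and PP value
#' at least `threshold`. Peaks are located on the unclamped Haar response
#' (attribute `"response"` of [haar_response_map()] output) when available:
#' the clamped map saturates at 1 over blob cores, and flat plateaus cannot
#' be peak-picked.
#'
#' @param pp_map 3-D PP map.
#' @param mask Logical mask from [coarse_particle_mask()].
#' @param diameter_px Particle diameter, pixels.
#' @param threshold Minimum PP value of a marker.
#' @param z_ratio `pixel_size_xy / z_step` (shrinks the z exclusion radius).
#' @return Integer 3-D array: marker voxels labelled 1..K (0 elsewhere),
#'   labels ordered by (x, y, z) voxel position.
#' @export
find_markers <- function(pp_map, mask, diameter_px = 7L, threshold = 0.5,
                         z_ratio = 1) {
  rxy <- max(1L, floor(diameter_px / 2))
  rz <- max(1L, round(rxy * z_ratio))
  resp <- attr(pp_map, "response")
  if (is.null(resp)) resp <- pp_map
  mx <- .local_maxima_3d(as.numeric(resp), dim(pp_map),
                         as.integer(rxy), as.integer(rz), -Inf)
  markers <- array(0L, dim = dim(pp_map))
  if (nrow(mx)) {
    keep <- mask[mx] & pp_map[mx] >= threshold
    mx <- mx[keep, , drop = FALSE]
    if (nrow(mx)) markers[mx] <- seq_len(nrow(mx))
  }
  markers
}

#' Marker-controlled watershed segmentation
#'
#' Priority-flood watershed on the inverted intensity (brightest voxels
#' flood first), restricted to the mask and seeded by the foreground
#' markers; every marker grows exactly one connected region, so the label
#' count equals the marker count.
#'
#' @param volume 3-D (denoised) intensity array: the relief is `-volume`.
#' @param mask Logical 3-D array restricting the flood.
#' @param markers Integer 3-D marker array from [find_markers()] (positive
#'   labels at seed voxels). Markers outside the mask are an error.
#' @return Integer 3-D label map (`0` = background, labels `1..K`).
#' @export
watershed_segment <- function(volume, mask, markers) {
  stopifnot(identical(dim(volume), dim(mask)),
            identical(dim(volume), dim(markers)))
  if (!any(markers > 0L)) return(array(0L, dim = dim(volume)))
  .watershed_3d(as.numeric(-volume), as.logical(mask),
                as.integer(markers), dim(volume))
}

#' Extract detections from a label map
#'
#' Intensity-weighted centroid (um: voxel index times pixel size / z step),
#' voxel volume and intensity summaries for every label, ordered by label.
#'
#' @param label_map Integer 3-D label map `(z, y, x)`.
#' @param volume Matching intensity volume.
#' @param metadata An [acquisition_metadata()].
#' @param frame Frame index stored on the rows (default 1).
#' @return Data frame with columns `frame, label_id, x_um, y_um, z_um,
#'   volume_vox, total_intensity, peak_intensity`.
#' @export
extract_detections <- function(label_map, volume, metadata, frame = 1L) {
  stopifnot(identical(dim(label_map), dim(volume)))
  empty <- data.frame(frame = integer(0), label_id = integer(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      volume_vox = integer(0), total_intensity = numeric(0),
                      peak_intensity = numeric(0))
  idx <- which(label_map > 0L)
  if (!length(idx)) return(empty)
  d <- dim(label_map)
  nz <- d[1L]; ny <- d[2L]
  iz <- (idx - 1L) %% nz
  iy <- ((idx - 1L) %/% nz) %% ny
  ix <- (idx - 1L) %/% (nz * ny)
  lab <- label_map[idx]
  w <- volume[idx]
  wsum <- as.numeric(rowsum(w, lab))
  labels <- sort(unique(lab))
  cx <- as.numeric(rowsum(w * ix, lab)) / wsum
  cy <- as.numeric(rowsum(w * iy, lab)) / wsum
  cz <- as.numeric(rowsum(w * iz, lab)) / wsum
  vol_vox <- as.integer(tabulate(lab)[labels])
  peak <- as.numeric(tapply(w, lab, max))
  data.frame(frame = as.integer(frame), label_id = labels,
             x_um = cx * metadata$pixel_size_xy,
             y_um = cy * metadata$pixel_size_xy,
             z_um = cz * metadata$z_step,
             volume_vox = vol_vox, total_intensity = wsum,
             peak_intensity = peak)
}

#' Segment one frame end to end
#'
#' Coarse mask, markers, watershed and detection extraction with the
#' config's (possibly per-frame) segmentation threshold.
#'
#' @param volume Denoised 3-D intensity volume.
#' @param pp_map Matching PP map.
#' @param metadata An [acquisition_metadata()].
#' @param config A [pipeline_config()].
#' @param frame Frame index (selects a per-frame threshold override).
#' @return Detections data frame (see [extract_detections()]).
#' @export
segment_frame <- function(volume, pp_map, metadata, config = pipeline_config(),
                          frame = 1L) {
  thr <- frame_threshold(config, frame)
  z_ratio <- metadata$pixel_size_xy / metadata$z_step
  mask <- coarse_particle_mask(pp_map, thr, config$mito_diameter_px,
                               config$min_volume_factor)
  markers <- find_markers(pp_map, mask, config$mito_diameter_px, thr, z_ratio)
  labels <- watershed_segment(volume, mask, markers)
  extract_detections(labels, volume, metadata, frame = frame)
}
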