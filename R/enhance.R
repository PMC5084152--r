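# Particle enhancement: multi-scale Haar-like centre-surround filtering into
# a particle-probability (PP) map, then feature-preserving non-local-means
# denoising.

# Box-filter sums along one dimension (window i-r .. i+r, clipped at the
# borders), via cumulative sums. `a` is a 3-D array.
box_sum_dim <- function(a, r, d) {
  if (r < 1L) return(a)
  perm <- switch(d, `1` = 1:3, `2` = c(2L, 1L, 3L), `3` = c(3L, 2L, 1L))
  b <- aperm(a, perm)
  dm <- dim(b); n <- dm[1L]
  m <- matrix(b, nrow = n)
  cs <- m
  if (n > 1L) for (i in 2:n) cs[i, ] <- cs[i, ] + cs[i - 1L, ]
  hi <- pmin(seq_len(n) + r, n)
  lo <- seq_len(n) - r - 1L
  out <- cs[hi, , drop = FALSE]
  pos <- lo >= 1L
  if (any(pos))
    out[pos, ] <- out[pos, ] - cs[lo[pos], , drop = FALSE]
  aperm(array(out, dm), perm)
}

box_mean_3d <- function(vol, rz, rxy) {
  s <- box_sum_dim(box_sum_dim(box_sum_dim(vol, rz, 1L), rxy, 2L), rxy, 3L)
  ones <- array(1, dim = dim(vol))
  cnt <- box_sum_dim(box_sum_dim(box_sum_dim(ones, rz, 1L), rxy, 2L), rxy, 3L)
  s / cnt
}

#' Raw centre-surround Haar response at one scale
#'
#' Inner-box mean minus surround-shell mean, with the inner box matched to a
#' particle of diameter `size_xy` pixels (z extent `size_z` voxels) and the
#' surround twice that size. Positive where the volume is locally blob-like
#' at that scale; exactly invariant to adding a constant.
#'
#' @param volume 3-D array `(z, y, x)`.
#' @param size_xy Inner window diameter in pixels (odd).
#' @param size_z Inner window diameter in z voxels (odd; default 1 + scaled).
#' @return 3-D response array, same shape.
#' @export
haar_center_surround <- function(volume, size_xy, size_z = 1L) {
  stopifnot(length(dim(volume)) == 3L)
  r_in_xy <- max(1L, floor(size_xy / 2))
  r_in_z <- max(0L, floor(size_z / 2))
  r_out_xy <- 2L * r_in_xy + 1L
  r_out_z <- min(dim(volume)[1L], 2L * r_in_z + 1L)
  if (2L * r_out_xy + 1L > min(dim(volume)[2:3]))
    stop("volume smaller than largest Haar window")
  inner_sum <- box_sum_dim(box_sum_dim(box_sum_dim(volume, r_in_z, 1L),
                                       r_in_xy, 2L), r_in_xy, 3L)
  outer_sum <- box_sum_dim(box_sum_dim(box_sum_dim(volume, r_out_z, 1L),
                                       r_out_xy, 2L), r_out_xy, 3L)
  ones <- array(1, dim = dim(volume))
  inner_cnt <- box_sum_dim(box_sum_dim(box_sum_dim(ones, r_in_z, 1L),
                                       r_in_xy, 2L), r_in_xy, 3L)
  outer_cnt <- box_sum_dim(box_sum_dim(box_sum_dim(ones, r_out_z, 1L),
                                       r_out_xy, 2L), r_out_xy, 3L)
  surround_cnt <- outer_cnt - inner_cnt
  inner_sum / inner_cnt - (outer_sum - inner_sum) / pmax(surround_cnt, 1)
}

#' Multi-scale particle-probability map
#'
#' Haar centre-surround responses at several window scales bracketing the
#' particle diameter, combined by per-voxel maximum, then rescaled to `[0, 1]`
#' by a robust (1st/99th percentile) min-max. A response range below machine
#' epsilon (e.g. a constant volume) yields an all-zero map.
#'
#' @param volume 3-D array `(z, y, x)`.
#' @param diameter_px Expected particle diameter, pixels (5-13).
#' @param scales Integer vector of window diameters; default
#'   `diameter_px + c(-2, 0, 2)` clipped to `[3, 15]`.
#' @param z_ratio Ratio `pixel_size_xy / z_step` used to shrink windows in z
#'   (z sampling is coarser than xy).
#' @return PP map: 3-D array in `[0, 1]`, same shape as `volume`. The
#'   unclamped combined response is attached as attribute `"response"`
#'   (the percentile clamp flattens blob cores into plateaus of 1, so peak
#'   finding must use the raw response; see [find_markers()]).
#' @export
haar_response_map <- function(volume, diameter_px = 7L, scales = NULL,
                              z_ratio = 1) {
  if (diameter_px < 5L || diameter_px > 13L)
    stop("diameter_px must lie in [5, 13]")
  if (is.null(scales))
    scales <- unique(pmax(3L, pmin(15L, diameter_px + c(-2L, 0L, 2L))))
  resp <- NULL
  for (s in scales) {
    sz <- max(1L, round(s * z_ratio))
    if (sz %% 2L == 0L) sz <- sz + 1L
    r <- haar_center_surround(volume, s, sz)
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  qs <- stats::quantile(resp, c(0.01, 0.99), names = FALSE)
  if ((qs[2L] - qs[1L]) < .Machine$double.eps)
    return(array(0, dim = dim(volume)))
  out <- (resp - qs[1L]) / (qs[2L] - qs[1L])
  out[out < 0] <- 0; out[out > 1] <- 1
  attr(out, "response") <- resp
  out
}

#' Robust noise-sd estimate of a volume
#'
#' Median absolute deviation of the in-plane discrete Laplacian, scaled so
#' the estimate is unbiased for iid Gaussian noise on a smooth background.
#'
#' @param volume 3-D array `(z, y, x)`.
#' @return Estimated noise standard deviation (intensity units).
#' @export
estimate_noise_sd <- function(volume) {
  d <- dim(volume)
  ny <- d[2L]; nx <- d[3L]
  if (ny < 3L || nx < 3L) return(stats::sd(volume))
  c0 <- volume[, 2:(ny - 1L), 2:(nx - 1L), drop = FALSE]
  lap <- 4 * c0 -
    volume[, 1:(ny - 2L), 2:(nx - 1L), drop = FALSE] -
    volume[, 3:ny,        2:(nx - 1L), drop = FALSE] -
    volume[, 2:(ny - 1L), 1:(nx - 2L), drop = FALSE] -
    volume[, 2:(ny - 1L), 3:nx,        drop = FALSE]
  # var(lap) = 20 sigma^2 for iid noise
  stats::mad(lap, center = 0) / sqrt(20)
}

#' Feature-preserving non-local-means denoising
#'
#' Non-local means in 3-D where patch similarity is computed on the intensity
#' patch augmented with the PP-map patch (weighted by `beta`), so particle
#' voxels preferentially average with other particle voxels and blob peaks
#' are preserved while the background is smoothed. Output values never leave
#' the input range (weights are convex).
#'
#' @param volume 3-D array `(z, y, x)`.
#' @param pp_map Optional PP map from [haar_response_map()]; `NULL` gives
#'   plain NLM.
#' @param patch_radius,search_radius In-plane patch / search radii, voxels
#'   (defaults 1 and 3).
#' @param patch_radius_z,search_radius_z Axial radii (defaults 1).
#' @param h Filtering strength on the normalised intensity scale; default
#'   ties it to the [estimate_noise_sd()] of the volume.
#' @param beta Weight of the PP channel in the patch distance (default 1).
#' @return Denoised 3-D array.
#' @export
fp_nlm_denoise <- function(volume, pp_map = NULL, patch_radius = 1L,
                           search_radius = 3L, patch_radius_z = 1L,
                           search_radius_z = 1L, h = NULL, beta = 1) {
  stopifnot(patch_radius >= 1L, search_radius >= 1L)
  rng <- diff(range(volume))
  if (is.null(h)) {
    sigma <- estimate_noise_sd(volume)
    h <- if (rng > 0) max(1e-6, 1.5 * sigma / rng) else 1e-6
  }
  if (h <= 0) stop("h must be > 0")
  if (is.null(pp_map)) { pp_map <- numeric(0); beta <- 0 }
  .fp_nlm_3d(as.numeric(volume), as.numeric(pp_map), dim(volume),
             as.integer(patch_radius), as.integer(patch_radius_z),
             as.integer(search_radius), as.integer(search_radius_z),
             h, beta)
}

#' Enhance every frame of an image sequence
#'
#' Per-frame particle enhancement: PP map via [haar_response_map()], then
#' [fp_nlm_denoise()] guided by that map. Frames are processed independently,
#' so the result does not depend on evaluation order.
#'
#' @param seq An [image_sequence_4d()].
#' @param config A [pipeline_config()].
#' @param recompute_pp Recompute the PP maps from the denoised volumes before
#'   returning them (default `FALSE`: maps reflect the raw data).
#' @return List with `denoised` (an [image_sequence_4d()]) and `pp_maps`
#'   (list of 3-D arrays, one per frame).
#' @export
enhance_sequence <- function(seq, config = pipeline_config(),
                             recompute_pp = FALSE) {
  stopifnot(inherits(seq, "image_sequence_4d"))
  md <- seq$metadata
  z_ratio <- md$pixel_size_xy / md$z_step
  out <- seq$intensities
  pp_maps <- vector("list", md$n_frames)
  for (f in seq_len(md$n_frames)) {
    vol <- get_volume(seq, f)
    pp <- haar_response_map(vol, config$mito_diameter_px, z_ratio = z_ratio)
    den <- fp_nlm_denoise(vol, pp)
    if (recompute_pp)
      pp <- haar_response_map(den, config$mito_diameter_px, z_ratio = z_ratio)
    out[f, , , ] <- den
    pp_maps[[f]] <- pp
  }
  list(denoised = image_sequence_4d(out, md), pp_maps = pp_maps)
}
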