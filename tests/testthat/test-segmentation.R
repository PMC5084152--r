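test_that("coarse mask thresholds, validates and filters small components", {
  pp <- array(0, c(3, 16, 16))
  expect_true(all(!coarse_particle_mask(pp, 0.5)))
  expect_error(coarse_particle_mask(pp, 0), "in \\(0, 1\\)")
  expect_error(coarse_particle_mask(pp, 1), "in \\(0, 1\\)")

  # a large and a tiny component; the tiny one is removed
  pp[2, 3:9, 3:9] <- 0.9           # 49 voxels
  pp[1, 14, 14] <- 0.9             # 1 voxel
  m <- coarse_particle_mask(pp, 0.5, diameter_px = 7L)
  expect_true(m[2, 5, 5])
  expect_false(m[1, 14, 14])
})

test_that("two separated blobs give exactly two components and markers", {
  md <- default_md(n_z = 5L, height = 48L, width = 48L)
  pos <- rbind(c(2.4, 2.4, 2), c(7.0, 7.0, 2))
  vol <- render_frame(pos, quiet_imaging(), md)
  pp <- haar_response_map(vol, 7L, z_ratio = 0.2)
  mask <- coarse_particle_mask(pp, 0.5)
  labs <- mitotrack:::.cc_label_3d(as.logical(mask), dim(mask))
  expect_identical(max(labs), 2L)
  markers <- find_markers(pp, mask, 7L, 0.5, z_ratio = 0.2)
  expect_identical(max(markers), 2L)
})

test_that("watershed conserves marker count and handles edge cases", {
  md <- default_md(n_z = 5L, height = 48L, width = 48L)
  # two blobs overlapping at roughly half-max along x
  sigma <- quiet_imaging()$psf_sigma_xy
  sep <- 2.355 * sigma                       # one FWHM apart
  pos <- rbind(c(4.0, 4.8, 2), c(4.0 + sep, 4.8, 2))
  vol <- render_frame(pos, quiet_imaging(), md)
  pp <- haar_response_map(vol, 7L, z_ratio = 0.2)
  mask <- coarse_particle_mask(pp, 0.5)
  markers <- array(0L, dim(vol))
  vx <- round(pos[, 1] / 0.2) + 1L; vy <- round(pos[, 2] / 0.2) + 1L
  markers[cbind(c(3L, 3L), vy, vx)] <- 1:2
  labs <- watershed_segment(vol, mask | markers > 0L, markers)
  expect_identical(sort(unique(as.integer(labs[labs > 0]))), 1:2)
  dets <- extract_detections(labs, vol, md)
  expect_identical(nrow(dets), 2L)
  # centroid separation within 1 voxel (0.2 um) of truth
  expect_lt(abs((dets$x_um[2] - dets$x_um[1]) - sep), 0.2)

  # zero markers: empty label map, zero detections
  empty <- watershed_segment(vol, mask, array(0L, dim(vol)))
  expect_true(all(empty == 0L))
  expect_identical(nrow(extract_detections(empty, vol, md)), 0L)

  # marker outside mask is an error
  bad <- array(0L, dim(vol)); bad[1, 1, 1] <- 1L
  expect_error(watershed_segment(vol, array(FALSE, dim(vol)), bad),
               "marker outside mask")

  # one marker, one blob: a single label covering the blob's mask
  vol1 <- blob_volume(c(4.8, 4.8, 2), md)
  pp1 <- haar_response_map(vol1, 7L, z_ratio = 0.2)
  mask1 <- coarse_particle_mask(pp1, 0.5)
  mk1 <- find_markers(pp1, mask1, 7L, 0.5, z_ratio = 0.2)
  labs1 <- watershed_segment(vol1, mask1, mk1)
  expect_identical(max(labs1), 1L)
  # the single blob's mask is one connected region: fully flooded
  expect_true(all(labs1[mask1] == 1L))
})

test_that("centroid arithmetic converts voxels to um exactly", {
  labs <- array(0L, c(3, 5, 6))
  labs[2, 3, 4] <- 1L                       # 0-based (z, y, x) = (1, 2, 3)
  vol <- array(1, c(3, 5, 6))
  md <- acquisition_metadata(0.2, 1.0, 1.5, n_frames = 1L, n_z = 3L,
                             height = 5L, width = 6L)
  det <- extract_detections(labs, vol, md)
  expect_equal(unlist(det[, c("x_um", "y_um", "z_um")]),
               c(x_um = 0.6, y_um = 0.4, z_um = 1.0))
  expect_identical(det$volume_vox, 1L)

  # symmetric noiseless blob: centroid within 0.25 voxel of the true centre
  md2 <- default_md(n_z = 5L, height = 48L, width = 48L)
  truth <- c(4.8, 4.8, 2)
  vol2 <- blob_volume(truth, md2)
  pp2 <- haar_response_map(vol2, 7L, z_ratio = 0.2)
  det2 <- segment_frame(vol2, pp2, md2, pipeline_config())
  expect_identical(nrow(det2), 1L)
  expect_lt(abs(det2$x_um - truth[1]), 0.25 * 0.2)
  expect_lt(abs(det2$y_um - truth[2]), 0.25 * 0.2)
})

test_that("detection count equals marker count on simulated frames", {
  md <- default_md(n_frames = 3L, n_z = 5L, height = 96L, width = 96L)
  ds <- generate_dataset(n_particles = 8L, n_frames = 3L, seed = 13,
                         metadata = md,
                         imaging = imaging_params(groove_spacing = 6))
  cfg <- pipeline_config()
  enh <- enhance_sequence(ds$sequence, cfg)
  for (f in 1:3) {
    vol <- get_volume(enh$denoised, f)
    pp <- enh$pp_maps[[f]]
    mask <- coarse_particle_mask(pp, 0.5, cfg$mito_diameter_px)
    markers <- find_markers(pp, mask, cfg$mito_diameter_px, 0.5, 0.2)
    labs <- watershed_segment(vol, mask, markers)
    dets <- extract_detections(labs, vol, md, frame = f)
    expect_identical(nrow(dets), max(markers))
  }
  # noiseless render with enforced spacing: detections = simulated particles
  ds0 <- generate_dataset(n_particles = 8L, n_frames = 2L, seed = 13,
                          metadata = default_md(2L, 5L, 96L, 96L),
                          imaging = quiet_imaging(groove_spacing = 6))
  enh0 <- enhance_sequence(ds0$sequence, cfg)
  for (f in 1:2) {
    dets <- segment_frame(get_volume(enh0$denoised, f), enh0$pp_maps[[f]],
                          ds0$sequence$metadata, cfg, frame = f)
    expect_identical(nrow(dets), 8L)
  }
})

test_that("raising the coarse threshold never increases detection count", {
  md <- default_md(n_z = 5L, height = 64L, width = 64L)
  ds <- generate_dataset(n_particles = 5L, n_frames = 1L, seed = 21,
                         metadata = default_md(1L, 5L, 64L, 64L),
                         imaging = imaging_params(groove_spacing = 5))
  cfg <- pipeline_config()
  enh <- enhance_sequence(ds$sequence, cfg)
  vol <- get_volume(enh$denoised, 1L)
  pp <- enh$pp_maps[[1L]]
  counts <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8, 0.95), function(th) {
    nrow(segment_frame(vol, pp, ds$sequence$metadata,
                       pipeline_config(segmentation_threshold = th)))
  }, 0L)
  expect_true(all(diff(counts) <= 0L))
})
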