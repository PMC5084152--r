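#' Pipeline configuration
#'
#' Collects the handful of user-set parameters the tracking and motion
#' analysis stages need. Defaults follow typical axonal mitochondria imaged
#' at ~0.2 um/px and 1.5 s/frame.
#'
#' @param mito_diameter_px Average mitochondrion diameter in pixels; integer
#'   in `[5, 13]` (default 7). Drives the Haar window scales and marker
#'   separation.
#' @param segmentation_threshold Threshold on the particle-probability map in
#'   `(0, 1)` (default 0.5).
#' @param threshold_overrides Optional named list / vector of per-frame
#'   threshold overrides (names are 1-based frame indices), replacing
#'   interactive per-frame tuning.
#' @param clustering_threshold_speed Speed threshold separating motion states,
#'   um/s (default 0.05).
#' @param window_size Sliding-window length for the transient-velocity
#'   decomposition; must be a power of two `2^k`, `k >= 2` (default 16).
#' @param gating_distance Maximum track-to-detection match distance, um
#'   (default 4: a bit over twice the largest per-frame run displacement at
#'   ~1 um/s and 1.5 s/frame, since a newborn track predicts with zero
#'   velocity).
#' @param max_gap Maximum consecutive missed frames before a track is
#'   terminated (default 3).
#' @param min_track_length Minimum track length in frames kept after
#'   trimming (default 8).
#' @param feature_weight Weight of the intensity/volume mismatch term in the
#'   assignment cost (default 1).
#' @param min_volume_factor Minimum accepted component volume, as a fraction
#'   of `(diameter/2)^3` voxels (default 0.15).
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mito_diameter_px = 7L,
                            segmentation_threshold = 0.5,
                            threshold_overrides = NULL,
                            clustering_threshold_speed = 0.05,
                            window_size = 16L,
                            gating_distance = 4.0,
                            max_gap = 3L,
                            min_track_length = 8L,
                            feature_weight = 1.0,
                            min_volume_factor = 0.15) {
  mito_diameter_px <- as.integer(mito_diameter_px)
  if (is.na(mito_diameter_px) || mito_diameter_px < 5L || mito_diameter_px > 13L)
    stop("mito_diameter_px must be an integer between 5 and 13")
  if (!is.numeric(segmentation_threshold) || segmentation_threshold <= 0 ||
      segmentation_threshold >= 1)
    stop("segmentation_threshold must lie in (0, 1)")
  window_size <- as.integer(window_size)
  k <- log2(window_size)
  if (is.na(window_size) || window_size < 4L || abs(k - round(k)) > 1e-12)
    stop("window_size must be a power of two (2^k, k >= 2)")
  if (!is.numeric(clustering_threshold_speed) || clustering_threshold_speed <= 0)
    stop("clustering_threshold_speed must be > 0")
  if (gating_distance <= 0) stop("gating_distance must be > 0")
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (min_track_length < 1) stop("min_track_length must be >= 1")
  if (!is.null(threshold_overrides)) {
    ov <- unlist(threshold_overrides)
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("threshold_overrides must be named by frame index")
    if (any(ov <= 0 | ov >= 1)) stop("threshold overrides must lie in (0, 1)")
    threshold_overrides <- stats::setNames(as.numeric(ov), names(ov))
  }
  structure(list(
    mito_diameter_px = mito_diameter_px,
    segmentation_threshold = segmentation_threshold,
    threshold_overrides = threshold_overrides,
    clustering_threshold_speed = clustering_threshold_speed,
    window_size = window_size,
    gating_distance = gating_distance,
    max_gap = as.integer(max_gap),
    min_track_length = as.integer(min_track_length),
    feature_weight = feature_weight,
    min_volume_factor = min_volume_factor
  ), class = "pipeline_config")
}

#' Per-frame segmentation threshold
#'
#' @param config A [pipeline_config()].
#' @param frame 1-based frame index.
#' @return The override for `frame` if present, else the global threshold.
#' @export
frame_threshold <- function(config, frame) {
  ov <- config$threshold_overrides
  key <- as.character(frame)
  if (!is.null(ov) && key %in% names(ov)) unname(ov[key])
  else config$segmentation_threshold
}

#' Load a pipeline configuration from JSON (or YAML)
#'
#' Absent fields take their defaults; present fields are validated by
#' [pipeline_config()]. YAML is supported when the optional `yaml` package is
#' installed; JSON always works.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw[intersect(names(raw), known)])
}
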