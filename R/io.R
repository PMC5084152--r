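#' Construct a trajectory
#'
#' A trajectory is a data.frame of time-ordered 3-D positions (um) and
#' per-timepoint features for one tracked mitochondrion, with the track id
#' kept as an attribute. Frames must be strictly increasing; gaps are allowed
#' (and interpolated samples are flagged).
#'
#' @param track_id Integer id.
#' @param frame Integer frame indices (1-based), strictly increasing.
#' @param t_s Time stamps in seconds (defaults to `(frame - 1) * dt` if `dt`
#'   given).
#' @param x_um,y_um,z_um Positions, um.
#' @param intensity,volume_vox Optional per-point summed intensity and voxel
#'   volume.
#' @param interpolated Logical flag per point (gap-filled samples).
#' @param dt Frame interval used to fill `t_s` when absent.
#' @return A `mito_trajectory` data.frame.
#' @export
trajectory <- function(track_id, frame, x_um, y_um = 0, z_um = 0,
                       t_s = NULL, intensity = NA_real_,
                       volume_vox = NA_real_, interpolated = FALSE,
                       dt = NULL) {
  frame <- as.integer(frame)
  n <- length(frame)
  if (n == 0L) stop("trajectory must have at least one point")
  if (is.unsorted(frame, strictly = TRUE)) stop("frames must be strictly increasing")
  if (is.null(t_s)) {
    if (is.null(dt)) dt <- 1.0
    t_s <- (frame - 1L) * dt
  }
  df <- data.frame(
    frame = frame, t_s = as.numeric(t_s),
    x_um = as.numeric(rep_len(x_um, n)), y_um = as.numeric(rep_len(y_um, n)),
    z_um = as.numeric(rep_len(z_um, n)),
    intensity = as.numeric(rep_len(intensity, n)),
    volume_vox = as.numeric(rep_len(volume_vox, n)),
    interpolated = rep_len(as.logical(interpolated), n)
  )
  if (any(!is.finite(as.matrix(df[, c("x_um", "y_um", "z_um")]))))
    stop("positions must be finite")
  attr(df, "track_id") <- as.integer(track_id)
  class(df) <- c("mito_trajectory", "data.frame")
  df
}

#' @export
print.mito_trajectory <- function(x, ...) {
  cat(sprintf("trajectory %d: %d points, frames %d-%d\n",
              attr(x, "track_id"), nrow(x), min(x$frame), max(x$frame)))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

traj_positions <- function(traj) as.matrix(traj[, c("x_um", "y_um", "z_um")])

#' Write trajectories to CSV
#'
#' Schema: `track_id, frame, t_s, x_um, y_um, z_um, intensity, volume_vox,
#' interpolated`, ordered by `(track_id, frame)`. An empty list writes the
#' header only.
#'
#' @param trajectories List of [trajectory()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  cols <- c("track_id", "frame", "t_s", "x_um", "y_um", "z_um",
            "intensity", "volume_vox", "interpolated")
  if (length(trajectories) == 0L) {
    dt <- data.table::as.data.table(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    data.table::fwrite(dt, path)
    return(invisible(path))
  }
  rows <- lapply(trajectories, function(tr) {
    df <- as.data.frame(tr)
    df$track_id <- attr(tr, "track_id")
    df[, cols]
  })
  dt <- data.table::rbindlist(rows)
  data.table::setorder(dt, track_id, frame)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Inverse of [write_trajectories()]: rows are grouped by `track_id` and
#' sorted by `frame`. Duplicate `(track_id, frame)` pairs are an error.
#'
#' @param path CSV path in the [write_trajectories()] schema.
#' @return List of [trajectory()] objects.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  dt <- data.table::fread(path)
  required <- c("track_id", "frame", "t_s", "x_um", "y_um", "z_um",
                "intensity", "volume_vox")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(dt) == 0L) return(list())
  for (cc in c("frame", "t_s", "x_um", "y_um", "z_um"))
    if (!is.numeric(dt[[cc]]))
      stop("non-numeric values in column ", cc)
  if (!"interpolated" %in% names(dt)) dt$interpolated <- FALSE
  if (anyDuplicated(dt[, c("track_id", "frame")]))
    stop("duplicate timepoint: repeated (track_id, frame) rows")
  data.table::setorder(dt, track_id, frame)
  lapply(split(as.data.frame(dt), dt$track_id), function(g) {
    trajectory(track_id = g$track_id[1L], frame = g$frame, t_s = g$t_s,
               x_um = g$x_um, y_um = g$y_um, z_um = g$z_um,
               intensity = g$intensity, volume_vox = g$volume_vox,
               interpolated = as.logical(g$interpolated))
  })
}

# -- image sequence IO --------------------------------------------------------

build_metadata_json <- function(md) {
  jsonlite::toJSON(list(
    mitotrack = as.character(utils::packageVersion("mitotrack")),
    pixel_size_xy = md$pixel_size_xy, z_step = md$z_step,
    frame_interval = md$frame_interval,
    anterograde_axis = md$anterograde_axis,
    n_frames = md$n_frames, n_z = md$n_z
  ), auto_unbox = TRUE, digits = NA)
}

build_ome_xml <- function(md) {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYZTC" Type="float"',
    sprintf(' SizeX="%d" SizeY="%d" SizeZ="%d" SizeT="%d" SizeC="1"',
            md$width, md$height, md$n_z, md$n_frames),
    sprintf(' PhysicalSizeX="%.10g" PhysicalSizeY="%.10g" PhysicalSizeZ="%.10g"',
            md$pixel_size_xy, md$pixel_size_xy, md$z_step),
    sprintf(' TimeIncrement="%.10g" TimeIncrementUnit="s"', md$frame_interval),
    '></Pixels></Image></OME>')
}

parse_description_metadata <- function(description) {
  out <- list()
  if (is.null(description) || !nzchar(description)) return(out)
  if (grepl("<OME", description, fixed = TRUE)) {
    doc <- tryCatch(xml2::read_xml(description), error = function(e) NULL)
    if (is.null(doc)) return(out)
    px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
    if (inherits(px, "xml_missing")) return(out)
    grab <- function(a) {
      v <- xml2::xml_attr(px, a)
      if (is.na(v)) NULL else as.numeric(v)
    }
    out$pixel_size_xy <- grab("PhysicalSizeX")
    out$z_step <- grab("PhysicalSizeZ")
    out$frame_interval <- grab("TimeIncrement")
    out$n_frames <- grab("SizeT"); out$n_z <- grab("SizeZ")
    ord <- xml2::xml_attr(px, "DimensionOrder")
    if (!is.na(ord))
      out$z_fastest <- regexpr("Z", ord) < regexpr("T", ord)
  } else if (grepl("^\\s*\\{", description)) {
    parsed <- tryCatch(jsonlite::fromJSON(description), error = function(e) NULL)
    if (!is.null(parsed))
      out <- parsed[intersect(names(parsed),
                              c("pixel_size_xy", "z_step", "frame_interval",
                                "anterograde_axis", "n_frames", "n_z"))]
  }
  out[!vapply(out, is.null, logical(1L))]
}

#' Write an image sequence as a multi-page TIFF
#'
#' Pages are ordered frame-major with z varying fastest within each frame
#' (the `XYZT` dialect). Acquisition metadata is embedded in the first page's
#' ImageDescription, as compact JSON (default) or minimal OME-XML.
#'
#' @param seq An [image_sequence_4d()].
#' @param path Output path.
#' @param description_format `"json"` or `"ome"`.
#' @return `path`, invisibly.
#' @export
write_image_sequence <- function(seq, path, description_format = c("json", "ome")) {
  stopifnot(inherits(seq, "image_sequence_4d"))
  description_format <- match.arg(description_format)
  md <- seq$metadata
  pages <- vector("list", md$n_frames * md$n_z)
  k <- 1L
  for (t in seq_len(md$n_frames)) for (z in seq_len(md$n_z)) {
    pages[[k]] <- matrix(seq$intensities[t, z, , ], nrow = md$height,
                         ncol = md$width)
    k <- k + 1L
  }
  desc <- if (description_format == "json") build_metadata_json(md)
          else build_ome_xml(md)
  write_tiff(path, pages, description = as.character(desc))
}

#' Read a 4-D image sequence from a multi-page TIFF / OME-TIFF
#'
#' Calibration is taken from embedded metadata (this package's JSON dialect or
#' OME-XML) and may be overridden or completed by the `...` arguments; any
#' calibration field available from neither source is an error.
#'
#' @param path TIFF path.
#' @param pixel_size_xy,z_step,frame_interval,n_frames,n_z,anterograde_axis
#'   Metadata overrides (see [acquisition_metadata()]).
#' @param z_fastest Page-order dialect: `TRUE` (default) means z varies
#'   fastest within each frame; `FALSE` the transpose. An OME
#'   `DimensionOrder` in the file takes effect unless this is supplied.
#' @return An [image_sequence_4d()].
#' @export
read_image_sequence <- function(path, pixel_size_xy = NULL, z_step = NULL,
                                frame_interval = NULL, n_frames = NULL,
                                n_z = NULL, anterograde_axis = NULL,
                                z_fastest = NULL) {
  tf <- read_tiff(path)
  emb <- parse_description_metadata(tf$description)
  pick <- function(override, field, default = NULL) {
    if (!is.null(override)) override
    else if (!is.null(emb[[field]])) emb[[field]]
    else default
  }
  n_z_v <- pick(n_z, "n_z")
  n_frames_v <- pick(n_frames, "n_frames")
  n_pages <- length(tf$pages)
  if (is.null(n_z_v) && is.null(n_frames_v))
    stop("missing calibration: neither n_z nor n_frames known")
  if (is.null(n_z_v)) n_z_v <- n_pages / as.integer(n_frames_v)
  if (is.null(n_frames_v)) n_frames_v <- n_pages / as.integer(n_z_v)
  n_z_v <- as.integer(n_z_v); n_frames_v <- as.integer(n_frames_v)
  if (n_frames_v * n_z_v != n_pages)
    stop(sprintf("page count mismatch: %d pages != t(%d) x z(%d)",
                 n_pages, n_frames_v, n_z_v))
  px <- pick(pixel_size_xy, "pixel_size_xy")
  zs <- pick(z_step, "z_step")
  dtv <- pick(frame_interval, "frame_interval")
  missing_cal <- c("pixel_size_xy", "z_step", "frame_interval")[
    vapply(list(px, zs, dtv), is.null, logical(1L))]
  if (length(missing_cal))
    stop("missing calibration: ", paste(missing_cal, collapse = ", "),
         " (supply as override)")
  ax <- pick(anterograde_axis, "anterograde_axis", c(1, 0))
  zf <- if (!is.null(z_fastest)) z_fastest
        else if (!is.null(emb$z_fastest)) emb$z_fastest else TRUE
  height <- nrow(tf$pages[[1L]]); width <- ncol(tf$pages[[1L]])
  arr <- array(0, dim = c(n_frames_v, n_z_v, height, width))
  k <- 1L
  if (isTRUE(zf)) {
    for (t in seq_len(n_frames_v)) for (z in seq_len(n_z_v)) {
      arr[t, z, , ] <- tf$pages[[k]]; k <- k + 1L
    }
  } else {
    for (z in seq_len(n_z_v)) for (t in seq_len(n_frames_v)) {
      arr[t, z, , ] <- tf$pages[[k]]; k <- k + 1L
    }
  }
  md <- acquisition_metadata(pixel_size_xy = px, z_step = zs,
                             frame_interval = dtv, anterograde_axis = ax,
                             n_frames = n_frames_v, n_z = n_z_v,
                             height = height, width = width)
  image_sequence_4d(arr, md)
}
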