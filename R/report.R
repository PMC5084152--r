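# Reporting surface: z projections, kymographs, speed-distribution fits,
# intersection-based threshold estimation and grouped summaries.

#' Maximum-intensity projection along z
#'
#' `out[t, y, x] = max_z in[t, z, y, x]`, exactly.
#'
#' @param seq An [image_sequence_4d()].
#' @return 3-D array `(t, y, x)`.
#' @export
max_project_z <- function(seq) {
  stopifnot(inherits(seq, "image_sequence_4d"))
  d <- dim(seq$intensities)
  if (d[2L] == 1L) return(array(seq$intensities[, 1L, , ], dim = d[c(1L, 3L, 4L)]))
  apply(seq$intensities, c(1L, 3L, 4L), max)
}

#' Kymograph (position-along-axis vs time)
#'
#' Image mode: each row is the 1-D intensity profile along the anterograde
#' axis at one frame, taking the maximum over z and over the direction
#' orthogonal to the axis (within an optional band). Trajectory mode: each
#' track's projected position is rasterised into its row. A moving particle
#' traces a sloped line; slope = speed.
#'
#' @param x An [image_sequence_4d()] or a list of [trajectory()] objects.
#' @param axis Length-2 unit xy vector (default +x).
#' @param bin_um Spatial bin width, um (default the pixel size in image mode,
#'   0.2 in trajectory mode).
#' @param band Optional `c(min, max)` um range of the orthogonal coordinate
#'   to include (image mode).
#' @param n_frames,axis_length_um Trajectory mode grid (defaults inferred).
#' @return Object of class `kymograph_2d`: list with `intensity`
#'   (`n_frames x n_bins` matrix), `bin_um`, `dt`.
#' @export
kymograph <- function(x, axis = c(1, 0), bin_um = NULL, band = NULL,
                      n_frames = NULL, axis_length_um = NULL) {
  axis <- axis / sqrt(sum(axis^2))
  if (inherits(x, "image_sequence_4d")) {
    md <- x$metadata
    if (is.null(bin_um)) bin_um <- md$pixel_size_xy
    proj <- max_project_z(x)                      # (t, y, x)
    px <- md$pixel_size_xy
    xs <- (seq_len(md$width) - 1L) * px
    ys <- (seq_len(md$height) - 1L) * px
    # coordinates of each (y, x) pixel along / orthogonal to the axis
    along <- outer(ys * axis[2L], xs * axis[1L], `+`)
    ortho <- outer(ys * axis[1L], xs * -axis[2L], `+`)
    sel <- if (is.null(band)) rep(TRUE, length(ortho))
           else ortho >= band[1L] & ortho <= band[2L]
    if (!any(sel)) stop("band outside field")
    bins <- floor(along / bin_um)
    bins_sel <- bins[sel]
    bin_ids <- sort(unique(as.integer(bins_sel)))
    n_bins <- length(bin_ids)
    out <- matrix(0, md$n_frames, n_bins)
    fb <- match(as.integer(bins_sel), bin_ids)
    for (t in seq_len(md$n_frames)) {
      frame <- proj[t, , ][sel]
      out[t, ] <- as.numeric(tapply(frame, fb, max))
    }
    res <- list(intensity = out, bin_um = bin_um, dt = md$frame_interval,
                bin_start_um = bin_ids[1L] * bin_um)
  } else {
    trajs <- x
    if (!length(trajs)) stop("no trajectories")
    if (is.null(bin_um)) bin_um <- 0.2
    pos_along <- lapply(trajs, function(tr) {
      p <- traj_positions(tr)
      p[, 1L] * axis[1L] + p[, 2L] * axis[2L]
    })
    if (is.null(n_frames))
      n_frames <- max(vapply(trajs, function(tr) max(tr$frame), 0L))
    if (is.null(axis_length_um))
      axis_length_um <- max(unlist(pos_along)) + bin_um
    n_bins <- max(1L, ceiling(axis_length_um / bin_um))
    out <- matrix(0, n_frames, n_bins)
    for (k in seq_along(trajs)) {
      tr <- trajs[[k]]
      cols <- pmin(pmax(floor(pos_along[[k]] / bin_um) + 1L, 1L), n_bins)
      out[cbind(tr$frame, cols)] <- out[cbind(tr$frame, cols)] + 1
    }
    res <- list(intensity = out, bin_um = bin_um, dt = NA_real_,
                bin_start_um = 0)
  }
  class(res) <- "kymograph_2d"
  res
}

#' Fit a speed distribution
#'
#' Histogram with Freedman-Diaconis bins normalised to a density, plus a
#' smooth fitted curve: a log-normal by maximum likelihood on the positive
#' speeds (default; speeds are positive and right-skewed) or a Gaussian
#' kernel density estimate. The Kolmogorov-Smirnov statistic against the
#' fitted curve is reported as a goodness-of-fit summary.
#'
#' @param values Speeds, um/s (>= 50 values required).
#' @param component Label: `"sustained"` or `"transient"` (metadata only).
#' @param family `"lognormal"` (default) or `"kde"`.
#' @return Object of class `speed_distribution`: list with `breaks`,
#'   `density` (histogram), `family`, `parameters`, `pdf` (vectorised
#'   evaluator), `ks_statistic`, `component`, `n`.
#' @export
fit_speed_distribution <- function(values, component = c("transient", "sustained"),
                                   family = c("lognormal", "kde")) {
  component <- match.arg(component)
  family <- match.arg(family)
  values <- values[is.finite(values)]
  if (length(values) < 50L) stop("need at least 50 speed values")
  if (stats::sd(values) < .Machine$double.eps)
    stop("degenerate speed values (zero spread)")
  pos <- values[values > 0]
  h <- graphics::hist(values, breaks = "FD", plot = FALSE)
  if (family == "lognormal") {
    if (length(pos) < 50L) stop("too few positive speeds for a log-normal fit")
    lv <- log(pos)
    meanlog <- mean(lv)
    sdlog <- stats::sd(lv)
    if (sdlog < .Machine$double.eps) stop("degenerate speed values (zero spread)")
    pdf <- function(x) stats::dlnorm(x, meanlog, sdlog)
    cdf <- function(x) stats::plnorm(x, meanlog, sdlog)
    pars <- c(meanlog = meanlog, sdlog = sdlog)
    ks <- suppressWarnings(stats::ks.test(pos, cdf)$statistic)
  } else {
    bw <- tryCatch(stats::bw.SJ(values), error = function(e) stats::bw.nrd0(values))
    de <- stats::density(values, bw = bw)
    pdf <- stats::approxfun(de$x, de$y, yleft = 0, yright = 0)
    pars <- c(bw = bw)
    ecdf_v <- stats::ecdf(values)
    xs <- sort(values)
    cdf_num <- cumsum(pdf(xs)) / sum(pdf(xs))
    ks <- max(abs(ecdf_v(xs) - cdf_num))
  }
  structure(list(breaks = h$breaks, density = h$density, family = family,
                 parameters = pars, pdf = pdf,
                 ks_statistic = unname(ks), component = component,
                 n = length(values)),
            class = "speed_distribution")
}

#' @export
print.speed_distribution <- function(x, ...) {
  cat(sprintf("speed_distribution (%s, %s fit, n = %d): %s; KS = %.3f\n",
              x$component, x$family, x$n,
              paste(sprintf("%s = %.4g", names(x$parameters), x$parameters),
                    collapse = ", "),
              x$ks_statistic))
  invisible(x)
}

#' Intersection point of two fitted speed distributions
#'
#' The smallest positive speed at which the two fitted density curves cross
#' (sign change of their difference, refined by bisection to `tol`). When
#' distributions of experimental groups with different motility all cross
#' near one speed, that crossing is the natural threshold separating
#' non-motile from motile behaviour.
#'
#' @param dist_a,dist_b [fit_speed_distribution()] objects.
#' @param lower,upper Search interval, um/s.
#' @param tol Bisection tolerance (default 1e-4 um/s).
#' @return The crossing speed, um/s.
#' @export
find_intersection_threshold <- function(dist_a, dist_b, lower = 1e-4,
                                        upper = 5, tol = 1e-4) {
  f <- function(x) dist_a$pdf(x) - dist_b$pdf(x)
  xs <- seq(lower, upper, length.out = 2048L)
  fx <- f(xs)
  sgn <- sign(fx)
  nz <- which(sgn != 0)
  flip_at <- if (length(nz) >= 2L) nz[which(diff(sgn[nz]) != 0)] else integer(0)
  if (!length(flip_at))
    stop("no intersection: density difference never changes sign in [",
         lower, ", ", upper, "]")
  k <- flip_at[1L]
  a <- xs[k]
  b <- xs[nz[match(k, nz) + 1L]]
  fa <- f(a)
  while (b - a > tol) {
    m <- (a + b) / 2
    fm <- f(m)
    if (fm == 0) return(m)
    if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
  }
  (a + b) / 2
}

#' Median pairwise intersection threshold across groups
#'
#' @param dists List of >= 2 [fit_speed_distribution()] objects.
#' @param ... Passed to [find_intersection_threshold()].
#' @return Median of all pairwise crossing speeds, um/s.
#' @export
intersection_threshold_multi <- function(dists, ...) {
  stopifnot(length(dists) >= 2L)
  pairs <- utils::combn(length(dists), 2L)
  crossings <- apply(pairs, 2L, function(p)
    find_intersection_threshold(dists[[p[1L]]], dists[[p[2L]]], ...))
  stats::median(crossings)
}

#' Summarise state proportions and running speeds by group
#'
#' The unit of replication is the image sequence: per-sequence pooled state
#' proportions and mean running sustained speed are averaged within each
#' group (mean and sd across sequences). No hypothesis testing is performed.
#'
#' @param groups Named list; each element is one group: a list of sequences,
#'   each sequence a list of [analyze_trajectory()] results.
#' @return Data frame with one row per group: `group, n_sequences,
#'   ST_mean, ST_sd, DP_mean, DP_sd, AR_mean, AR_sd, RR_mean, RR_sd,
#'   run_speed_mean, run_speed_sd`.
#' @export
summarize_groups <- function(groups) {
  if (!length(groups)) stop("no groups supplied")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  rows <- lapply(names(groups), function(g) {
    seqs <- groups[[g]]
    if (!length(seqs)) stop("empty group: ", g)
    props <- t(vapply(seqs, state_proportions, numeric(4L)))
    run_speed <- vapply(seqs, function(series_list) {
      pooled <- data.table::rbindlist(lapply(series_list, as.data.frame))
      run <- pooled[pooled$valid & pooled$state %in% c("AR", "RR"), ]
      if (nrow(run)) mean(run$sustained_speed) else NA_real_
    }, 0)
    row <- data.frame(group = g, n_sequences = length(seqs))
    for (s in MOTION_STATES) {
      row[[paste0(s, "_mean")]] <- mean(props[, s])
      row[[paste0(s, "_sd")]] <- if (nrow(props) > 1L) stats::sd(props[, s]) else 0
    }
    row$run_speed_mean <- mean(run_speed, na.rm = TRUE)
    row$run_speed_sd <- if (sum(!is.na(run_speed)) > 1L)
      stats::sd(run_speed, na.rm = TRUE) else 0
    row
  })
  do.call(rbind, rows)
}
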