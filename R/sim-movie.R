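# Minimum distance (px) from each pixel centre to a polyline (x, y in px).
distanceToPolyline <- function(height, width, axis) {
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  dmin <- matrix(Inf, height, width)
  for (i in seq_len(nrow(axis) - 1L)) {
    p0 <- axis[i, ]; p1 <- axis[i + 1L, ]
    v <- p1 - p0
    len2 <- sum(v^2)
    if (len2 == 0) {
      d <- sqrt((xs - p0[1])^2 + (ys - p0[2])^2)
    } else {
      tt <- ((xs - p0[1]) * v[1] + (ys - p0[2]) * v[2]) / len2
      tt <- pmin(pmax(tt, 0), 1)
      d <- sqrt((xs - (p0[1] + tt * v[1]))^2 + (ys - (p0[2] + tt * v[2]))^2)
    }
    dmin <- pmin(dmin, d)
  }
  dmin
}

#' Simulate a vessel movie with analytically known diameter
#'
#' Renders a single-channel movie of one vessel along a given axis polyline.
#' The intensity perpendicular to the axis follows the configured profile
#' shape with the frame's ground-truth full width at half maximum: for the
#' Gaussian profile, sigma is set so that `2*sqrt(2*log(2))*sigma` equals
#' the requested diameter; the plateau profile is flat at peak intensity
#' with a one-pixel linear edge whose half-maximum crossings are exactly one
#' diameter apart. Identical parameters and seed give bit-identical stacks.
#'
#' @param p a [movieSimParams()] object. The axis must keep a margin of at
#'   least the maximum diameter from the frame border.
#' @param vesselMeta [VesselRecord-class] attached to the movie.
#' @return A list with `movie` (a [VesselMovie-class]) and `truth` (the
#'   per-frame ground-truth diameter series, um).
#' @examples
#' p <- movieSimParams(n_frames = 2, height_px = 48, width_px = 48,
#'   pixel_size_um = 1, vessel_axis = cbind(c(10, 38), c(24, 24)),
#'   diameter_series_um = 8)
#' sim <- makeVesselMovie(p)
#' @export
makeVesselMovie <- function(p, vesselMeta = VesselRecord()) {
  stopifnot(inherits(p, "MovieSimParams"))
  ax <- p$vessel_axis
  dmax_px <- max(p$diameter_series_um) / p$pixel_size_um
  margin <- min(ax[, 1] - 1, p$width_px - ax[, 1],
                ax[, 2] - 1, p$height_px - ax[, 2])
  if (margin < dmax_px)
    stop("vessel axis too close to the frame border: margin ",
         round(margin, 1), " px < max diameter ", round(dmax_px, 1), " px")
  dist_px <- distanceToPolyline(p$height_px, p$width_px, ax)
  frames <- array(0, dim = c(p$height_px, p$width_px, p$n_frames))
  bg <- p$background_intensity
  amp <- p$peak_intensity - bg
  for (f in seq_len(p$n_frames)) {
    d_px <- p$diameter_series_um[f] / p$pixel_size_um
    if (p$profile_shape == "gaussian") {
      sigma <- d_px / (2 * sqrt(2 * log(2)))
      frames[, , f] <- bg + amp * exp(-dist_px^2 / (2 * sigma^2))
    } else {
      r <- d_px / 2
      edge <- pmin(pmax(r + 0.5 - dist_px, 0), 1)
      frames[, , f] <- bg + amp * edge
    }
  }
  if (p$noise_sd > 0) {
    frames <- withSeed(p$rng_seed,
      frames + array(stats::rnorm(length(frames), sd = p$noise_sd),
                     dim = dim(frames)))
  }
  list(
    movie = VesselMovie(frames, pixelSizeUm = p$pixel_size_um,
                        axis = ax, vesselMeta = vesselMeta),
    truth = p$diameter_series_um
  )
}
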