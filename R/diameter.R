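# Integer-pixel rigid shift estimate of `frame` relative to `reference`
# by phase correlation. Returns c(dx, dy): the displacement that moves
# `reference` onto `frame`.
phaseCorrelationShift <- function(frame, reference) {
  F1 <- stats::fft(frame)
  F2 <- stats::fft(reference)
  cross <- F1 * Conj(F2)
  denom <- Mod(cross)
  denom[denom == 0] <- 1
  r <- Re(stats::fft(cross / denom, inverse = TRUE))
  peak <- which(r == max(r), arr.ind = TRUE)[1, ]
  h <- nrow(frame); w <- ncol(frame)
  dy <- peak[1] - 1; dx <- peak[2] - 1
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(dx = unname(dx), dy = unname(dy))
}

# Shift a frame by integer (dx, dy), filling uncovered pixels with the
# frame median.
shiftFrame <- function(frame, dx, dy) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(stats::median(frame), h, w)
  ys <- seq_len(h) - dy; xs <- seq_len(w) - dx
  oky <- ys >= 1 & ys <= h; okx <- xs >= 1 & xs <= w
  out[oky, okx] <- frame[ys[oky], xs[okx]]
  out
}

#' Estimate per-frame rigid translations against the stack mean
#'
#' Phase-correlation estimate of the integer-pixel (dx, dy) displacement of
#' each frame relative to the stack mean frame. Subtracting the returned
#' shift from a frame registers it onto the mean.
#'
#' @param movie a [VesselMovie-class].
#' @return A two-column matrix (`dx`, `dy`), one row per frame.
#' @export
estimateFrameShifts <- function(movie) {
  fr <- movieFrames(movie)
  ref <- apply(fr, c(1, 2), mean)
  t(apply(fr, 3, phaseCorrelationShift, reference = ref))
}

#' Preprocess a vessel movie
#'
#' Standard cleanup ahead of diameter extraction: (1) rescale the stack to
#' the 8-bit range using the stack-global minimum and maximum; (2) despeckle
#' each frame with a 3x3 median filter; (3) equalize each frame's contrast
#' (linear match of mean and SD) to the stack mean frame, countering
#' stimulus light artifacts; (4) register each frame to the stack mean by
#' rigid translation estimated with phase correlation.
#'
#' @param movie a [VesselMovie-class] with at least one frame.
#' @param rescale,despeckle,equalize,register logical switches for the four
#'   steps (all on by default).
#' @return The preprocessed [VesselMovie-class].
#' @export
preprocessMovie <- function(movie, rescale = TRUE, despeckle = TRUE,
                            equalize = TRUE, register = TRUE) {
  fr <- movieFrames(movie)
  if (length(fr) == 0 || dim(fr)[3] < 1) stop("empty movie stack")
  if (rescale) {
    lo <- min(fr); hi <- max(fr)
    fr <- if (hi > lo) (fr - lo) / (hi - lo) * 255 else fr * 0
  }
  if (despeckle) {
    lo <- min(fr); hi <- max(fr)
    if (hi > lo) {
      for (f in seq_len(dim(fr)[3])) {
        norm <- (fr[, , f] - lo) / (hi - lo)
        fr[, , f] <- EBImage::medianFilter(norm, size = 1) * (hi - lo) + lo
      }
    }
  }
  if (equalize && dim(fr)[3] > 1) {
    ref <- apply(fr, c(1, 2), mean)
    m0 <- mean(ref); s0 <- stats::sd(as.vector(ref))
    for (f in seq_len(dim(fr)[3])) {
      m <- mean(fr[, , f]); s <- stats::sd(as.vector(fr[, , f]))
      if (s > 0) fr[, , f] <- (fr[, , f] - m) * (s0 / s) + m0
    }
  }
  if (register && dim(fr)[3] > 1) {
    ref <- apply(fr, c(1, 2), mean)
    for (f in seq_len(dim(fr)[3])) {
      sh <- phaseCorrelationShift(fr[, , f], ref)
      if (any(sh != 0)) fr[, , f] <- shiftFrame(fr[, , f], -sh[1], -sh[2])
    }
  }
  VesselMovie(fr, pixelSizeUm = pixelSize(movie), frameRateHz = frameRate(movie),
              axis = vesselAxis(movie), vesselMeta = vesselMeta(movie))
}

#' Full width at half maximum of a 1-D intensity profile
#'
#' The background is the profile minimum (or a low percentile, for
#' robustness to noise); the half level is halfway between background and
#' the global peak. Walking outward from the peak on each side, the first
#' sub-half-level crossing is located with linear sub-sample interpolation;
#' the width is the distance between the two crossings. Returns `NA` (no
#' measurement) for flat profiles or when the profile never falls below the
#' half level on either side.
#'
#' @param profile numeric intensity samples (>= 3).
#' @param spacing_um distance between consecutive samples, micrometres.
#' @param background `"min"` (default) or `"percentile"`.
#' @param bg_percentile percentile (0-100) used when
#'   `background = "percentile"`.
#' @return Width in micrometres, or `NA_real_` if no measurement.
#' @examples
#' fwhmProfile(c(0, 0, rep(100, 11), 0, 0), spacing_um = 1)  # 11
#' @export
fwhmProfile <- function(profile, spacing_um = 1,
                        background = c("min", "percentile"),
                        bg_percentile = 5) {
  background <- match.arg(background)
  if (length(profile) < 3 || anyNA(profile)) return(NA_real_)
  bg <- if (background == "min") min(profile)
        else stats::quantile(profile, bg_percentile / 100, names = FALSE)
  peak_i <- which.max(profile)
  peak <- profile[peak_i]
  if (peak <= bg) return(NA_real_)
  half <- bg + 0.5 * (peak - bg)
  left <- firstCrossing(profile, half, peak_i:1)
  right <- firstCrossing(profile, half, peak_i:length(profile))
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * spacing_um
}

#' Intensity profiles perpendicular to the vessel axis
#'
#' At every `step_px`-th axis point, samples intensities by bilinear
#' interpolation along the local normal at one-pixel spacing, centred on the
#' axis, out to `sample_halfwidth_um` on each side. Positions whose normal
#' extends outside the frame are skipped and reported as invalid.
#'
#' @param movie a [VesselMovie-class].
#' @param frame frame index.
#' @param sample_halfwidth_um half-length of the sampled normal, um; should
#'   exceed the expected vessel radius.
#' @param step_px spacing between sampled axis points, pixels.
#' @return A list: `profiles` (list of numeric profiles for the valid
#'   positions), `valid` (logical per sampled axis position) and
#'   `spacing_um` (= pixel size).
#' @export
perpendicularProfiles <- function(movie, frame, sample_halfwidth_um,
                                  step_px = 1) {
  fr <- movieFrames(movie)[, , frame]
  ax <- vesselAxis(movie)
  px <- pixelSize(movie)
  hw_px <- max(2L, ceiling(sample_halfwidth_um / px))
  offsets <- seq(-hw_px, hw_px, by = 1)
  idx <- seq(1, nrow(ax), by = max(1L, as.integer(step_px)))
  profiles <- vector("list", length(idx))
  valid <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    i0 <- max(1L, i - 1L); i1 <- min(nrow(ax), i + 1L)
    tang <- ax[i1, ] - ax[i0, ]
    nt <- sqrt(sum(tang^2))
    if (nt == 0) next
    nrm <- c(-tang[2], tang[1]) / nt
    xs <- ax[i, 1] + offsets * nrm[1]
    ys <- ax[i, 2] + offsets * nrm[2]
    vals <- bilinearSample(fr, xs, ys)
    if (anyNA(vals)) next
    profiles[[j]] <- vals
    valid[j] <- TRUE
  }
  list(profiles = profiles[valid], valid = valid, spacing_um = px)
}

#' Extract a per-frame diameter trace from a vessel movie
#'
#' For each frame, measures the full width at half maximum of the intensity
#' profile perpendicular to the vessel axis at every `step_px`-th axis
#' position and averages the valid widths along the vessel; the fraction of
#' axis positions yielding a valid measurement is recorded per frame as the
#' QC fraction. Frames whose QC fraction falls below `qc_threshold` are
#' retained but their values should be interpreted with care (whole noisy
#' trials, not frames, are excluded downstream).
#'
#' @param movie a (preprocessed) [VesselMovie-class].
#' @param sample_halfwidth_um half-length of the sampled normals, um;
#'   defaults to the largest value that keeps all normals inside the frame.
#' @param step_px axis sampling stride, pixels.
#' @param qc_threshold QC fraction below which a frame is flagged.
#' @param background,bg_percentile background convention passed to
#'   [fwhmProfile()].
#' @return A [DiameterTrace-class].
#' @export
extractDiameter <- function(movie, sample_halfwidth_um = NULL, step_px = 1,
                            qc_threshold = 0.5,
                            background = c("min", "percentile"),
                            bg_percentile = 5) {
  background <- match.arg(background)
  fr <- movieFrames(movie)
  ax <- vesselAxis(movie)
  px <- pixelSize(movie)
  if (is.null(sample_halfwidth_um)) {
    margin <- min(ax[, 1] - 1, dim(fr)[2] - ax[, 1],
                  ax[, 2] - 1, dim(fr)[1] - ax[, 2])
    sample_halfwidth_um <- max(2 * px, (margin - 1) * px)
  }
  nT <- dim(fr)[3]
  values <- rep(NA_real_, nT)
  qc <- numeric(nT)
  for (f in seq_len(nT)) {
    pp <- perpendicularProfiles(movie, f, sample_halfwidth_um, step_px)
    widths <- vapply(pp$profiles, fwhmProfile, numeric(1),
                     spacing_um = pp$spacing_um, background = background,
                     bg_percentile = bg_percentile)
    ok <- !is.na(widths)
    qc[f] <- sum(ok) / length(pp$valid)
    if (any(ok)) values[f] <- mean(widths[ok])
  }
  if (all(is.na(values)))
    stop("no valid FWHM measurement in any frame: check axis placement, ",
         "sample_halfwidth_um and image contrast")
  DiameterTrace(values, frameRateHz = frameRate(movie), qcFraction = qc,
                vesselMeta = vesselMeta(movie))
}
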