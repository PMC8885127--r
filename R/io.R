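#' Read and write vasomorph objects in plain formats
#'
#' Traces, schedules and locomotion go to/from headered CSV; movies to/from
#' multi-page grayscale TIFF; vascular trees to/from JSON.
#'
#' @name vasomorph-io
NULL

#' @describeIn vasomorph-io Write a diameter trace as CSV with columns
#'   `frame`, `time_s`, `diameter_um`, `qc_fraction`.
#' @param trace a [DiameterTrace-class].
#' @param path file path.
#' @export
writeDiameterTrace <- function(trace, path) {
  v <- diameterValues(trace)
  utils::write.csv(data.frame(
    frame = seq_along(v),
    time_s = (seq_along(v) - 1) / frameRate(trace),
    diameter_um = v,
    qc_fraction = qcFraction(trace)), path, row.names = FALSE)
  invisible(path)
}

#' @describeIn vasomorph-io Read a diameter trace CSV; the frame rate is
#'   inferred from the `time_s` column unless given.
#' @param frame_rate_hz sampling rate override, Hz.
#' @param vesselMeta [VesselRecord-class] to attach.
#' @export
readDiameterTrace <- function(path, frame_rate_hz = NULL,
                              vesselMeta = VesselRecord()) {
  d <- utils::read.csv(path)
  if (is.null(frame_rate_hz)) {
    if (nrow(d) < 2) stop("cannot infer frame rate from a single row")
    frame_rate_hz <- 1 / stats::median(diff(d$time_s))
  }
  qc <- if ("qc_fraction" %in% names(d)) d$qc_fraction else rep(1, nrow(d))
  DiameterTrace(d$diameter_um, frameRateHz = frame_rate_hz,
                qcFraction = qc, vesselMeta = vesselMeta)
}

#' @describeIn vasomorph-io Write a stimulus schedule as CSV
#'   (`onset_s`, `offset_s`, `condition`).
#' @param schedule a [StimulusSchedule-class].
#' @export
writeStimulusSchedule <- function(schedule, path) {
  utils::write.csv(stimulusEvents(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @describeIn vasomorph-io Read a stimulus schedule CSV.
#' @export
readStimulusSchedule <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("StimulusSchedule", events = d[, c("onset_s", "offset_s", "condition")])
}

#' @describeIn vasomorph-io Write a locomotion trace as CSV
#'   (`time_s`, `displacement`).
#' @param loco a [LocomotionTrace-class].
#' @export
writeLocomotion <- function(loco, path) {
  utils::write.csv(data.frame(time_s = loco@timeS,
                              displacement = loco@displacement),
                   path, row.names = FALSE)
  invisible(path)
}

#' @describeIn vasomorph-io Read a locomotion CSV.
#' @export
readLocomotion <- function(path) {
  d <- utils::read.csv(path)
  LocomotionTrace(d$time_s, d$displacement)
}

#' @describeIn vasomorph-io Write a movie as a multi-page grayscale TIFF.
#'   Intensities are scaled by `2^bits - 1` into the TIFF's unit range, so
#'   a round trip through [readVesselMovie()] with the same `bits`
#'   preserves values up to quantization.
#' @param movie a [VesselMovie-class].
#' @param bits 8 or 16.
#' @export
writeVesselMovie <- function(movie, path, bits = 16) {
  stopifnot(bits %in% c(8, 16))
  fr <- movieFrames(movie)
  maxval <- 2^bits - 1
  fr <- pmin(pmax(fr, 0), maxval)
  pages <- lapply(seq_len(dim(fr)[3]),
                  function(f) round(fr[, , f]) / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' @describeIn vasomorph-io Read a multi-page TIFF as a movie; calibration
#'   and the axis polyline are supplied by the caller (axes are drawn or
#'   generated, not auto-traced).
#' @param axis two-column (x, y) matrix in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @export
readVesselMovie <- function(path, axis, pixel_size_um = 0.1958,
                            frame_rate_hz = 7.6, bits = 16,
                            vesselMeta = VesselRecord()) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  maxval <- 2^bits - 1
  fr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    fr[, , f] <- pg * maxval
  }
  VesselMovie(fr, pixelSizeUm = pixel_size_um, frameRateHz = frame_rate_hz,
              axis = axis, vesselMeta = vesselMeta)
}

#' @describeIn vasomorph-io Write a vascular tree as JSON (segments,
#'   somata, branch points, marker annotations, background intensity).
#' @param tree a [VesselTree-class].
#' @export
writeVesselTree <- function(tree, path) {
  jsonlite::write_json(list(
    segments = treeSegments(tree),
    somata = treeSomata(tree),
    branch_points = treeBranchPoints(tree),
    markers = markerAnnotations(tree),
    background = as.list(tree@backgroundIntensity)
  ), path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @describeIn vasomorph-io Read a vascular tree JSON.
#' @export
readVesselTree <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bg <- unlist(x$background)
  new("VesselTree", segments = as.data.frame(x$segments),
      somata = as.data.frame(x$somata),
      branchPoints = as.data.frame(x$branch_points),
      markers = as.data.frame(x$markers),
      backgroundIntensity = c(mean = unname(bg["mean"]),
                              sd = unname(bg["sd"])))
}

#' @describeIn vasomorph-io Write a power spectrum as CSV
#'   (`freq_hz`, `power`, `power_corrected`).
#' @param ps a [PowerSpectrum-class].
#' @export
writeSpectrum <- function(ps, path) {
  utils::write.csv(data.frame(freq_hz = freqs(ps),
                              power = spectralPower(ps),
                              power_corrected = correctedPower(ps)),
                   path, row.names = FALSE)
  invisible(path)
}
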