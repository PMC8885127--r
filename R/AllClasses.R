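#' @import methods
NULL

#' Metadata describing a single imaged vessel
#'
#' Carries the identity and classification of one vessel: its category
#' (penetrating arteriole or capillary), branch order, cortical depth and the
#' pixel size of the recording it came from. Under the in vivo convention a
#' capillary's branch order is at least 1 (the first offshoot protruding off
#' the penetrating arteriole is order 1).
#'
#' @slot vesselId character label.
#' @slot category `"penetrating_arteriole"` or `"capillary"`.
#' @slot branchOrder integer branch order (>= 0).
#' @slot depthUm cortical depth in micrometres.
#' @slot pixelSizeUm pixel size of the source recording, micrometres/pixel.
#'
#' @export
setClass("VesselRecord",
  representation(
    vesselId = "character",
    category = "character",
    branchOrder = "integer",
    depthUm = "numeric",
    pixelSizeUm = "numeric"
  ),
  prototype(
    vesselId = "vessel", category = "capillary", branchOrder = 1L,
    depthUm = 0, pixelSizeUm = 0.1958
  )
)

setValidity("VesselRecord", function(object) {
  msg <- character()
  if (!object@category %in% c("penetrating_arteriole", "capillary"))
    msg <- c(msg, "category must be 'penetrating_arteriole' or 'capillary'")
  if (length(object@branchOrder) != 1L || object@branchOrder < 0L)
    msg <- c(msg, "branchOrder must be a single non-negative integer")
  if (object@category == "capillary" && object@branchOrder < 1L)
    msg <- c(msg, "capillaries have branch order >= 1 (in vivo convention)")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a VesselRecord
#'
#' @param vesselId character label identifying the vessel.
#' @param category `"penetrating_arteriole"` or `"capillary"`.
#' @param branchOrder branch order; capillaries start at 1.
#' @param depthUm cortical depth below the pial surface, micrometres.
#' @param pixelSizeUm micrometres per pixel of the recording.
#' @return A [VesselRecord-class] object.
#' @examples
#' VesselRecord("v1", "penetrating_arteriole", branchOrder = 0)
#' @export
VesselRecord <- function(vesselId = "vessel", category = "capillary",
                         branchOrder = if (category == "capillary") 1L else 0L,
                         depthUm = 0, pixelSizeUm = 0.1958) {
  new("VesselRecord", vesselId = as.character(vesselId), category = category,
      branchOrder = as.integer(branchOrder), depthUm = as.numeric(depthUm),
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' Time-lapse vessel movie
#'
#' A single-channel intensity stack together with the spatial calibration,
#' frame rate and the vessel-axis polyline along which diameters are
#' measured. Frames are stored as a `height x width x nframes` array; axis
#' coordinates are `(x, y)` pixel positions (x = column, y = row, 1-based).
#'
#' @slot frames numeric array, `height x width x nframes`.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot frameRateHz acquisition rate, Hz.
#' @slot axis two-column matrix of (x, y) pixel coordinates along the vessel
#'   midline, at least two points, all inside the frame.
#' @slot vesselMeta a [VesselRecord-class].
#'
#' @export
setClass("VesselMovie",
  representation(
    frames = "array",
    pixelSizeUm = "numeric",
    frameRateHz = "numeric",
    axis = "matrix",
    vesselMeta = "VesselRecord"
  )
)

setValidity("VesselMovie", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be a 3-D array (h x w x t)")
  else {
    if (d[3] < 1L) msg <- c(msg, "movie must contain at least one frame")
    ax <- object@axis
    if (ncol(ax) != 2L || nrow(ax) < 2L)
      msg <- c(msg, "axis needs >= 2 (x, y) points")
    else if (any(ax[, 1] < 1 | ax[, 1] > d[2] | ax[, 2] < 1 | ax[, 2] > d[1]))
      msg <- c(msg, "axis points must lie inside the frame")
  }
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be positive")
  if (object@frameRateHz <= 0) msg <- c(msg, "frameRateHz must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a VesselMovie
#'
#' @param frames `height x width x nframes` numeric array.
#' @param pixelSizeUm micrometres per pixel.
#' @param frameRateHz frames per second.
#' @param axis two-column matrix of (x, y) axis coordinates in pixels.
#' @param vesselMeta a [VesselRecord-class] (defaulted if omitted).
#' @return A [VesselMovie-class].
#' @export
VesselMovie <- function(frames, pixelSizeUm = 0.1958, frameRateHz = 7.6,
                        axis, vesselMeta = VesselRecord()) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  new("VesselMovie", frames = frames, pixelSizeUm = pixelSizeUm,
      frameRateHz = frameRateHz, axis = as.matrix(axis),
      vesselMeta = vesselMeta)
}

#' Per-frame vessel diameter trace
#'
#' Continuous diameter of one vessel over time, in micrometres, with a
#' per-frame QC fraction giving the proportion of axis positions that
#' yielded a valid FWHM measurement in that frame.
#'
#' @slot valuesUm numeric, one diameter per frame (um).
#' @slot frameRateHz sampling rate, Hz.
#' @slot qcFraction numeric in \[0, 1\], same length as `valuesUm`.
#' @slot vesselMeta a [VesselRecord-class].
#'
#' @export
setClass("DiameterTrace",
  representation(
    valuesUm = "numeric",
    frameRateHz = "numeric",
    qcFraction = "numeric",
    vesselMeta = "VesselRecord"
  )
)

setValidity("DiameterTrace", function(object) {
  msg <- character()
  n <- length(object@valuesUm)
  if (length(object@qcFraction) != n)
    msg <- c(msg, "qcFraction must have one value per frame")
  if (any(object@qcFraction < 0 | object@qcFraction > 1, na.rm = TRUE))
    msg <- c(msg, "qcFraction must lie in [0, 1]")
  ok <- object@qcFraction > 0 & !is.na(object@valuesUm)
  if (any(object@valuesUm[ok] <= 0))
    msg <- c(msg, "diameters must be positive where qcFraction > 0")
  if (object@frameRateHz <= 0) msg <- c(msg, "frameRateHz must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a DiameterTrace
#'
#' @param valuesUm per-frame diameter, micrometres.
#' @param frameRateHz sampling rate, Hz.
#' @param qcFraction per-frame fraction of valid axis positions (default 1).
#' @param vesselMeta a [VesselRecord-class].
#' @return A [DiameterTrace-class].
#' @export
DiameterTrace <- function(valuesUm, frameRateHz = 7.6,
                          qcFraction = rep(1, length(valuesUm)),
                          vesselMeta = VesselRecord()) {
  new("DiameterTrace", valuesUm = as.numeric(valuesUm),
      frameRateHz = frameRateHz, qcFraction = as.numeric(qcFraction),
      vesselMeta = vesselMeta)
}

#' Stimulus presentation schedule
#'
#' Ordered, non-overlapping stimulus events with onset, offset and a
#' condition label (contrast, size or spatial-frequency conditions are
#' carried as labels only).
#'
#' @slot events data.frame with columns `onset_s`, `offset_s`, `condition`.
#'
#' @export
setClass("StimulusSchedule", representation(events = "data.frame"))

setValidity("StimulusSchedule", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("onset_s", "offset_s", "condition")
  if (!all(need %in% names(ev)))
    return("events must have columns onset_s, offset_s, condition")
  if (nrow(ev) > 1L) {
    if (is.unsorted(ev$onset_s, strictly = TRUE))
      msg <- c(msg, "events must be time-ordered")
    if (any(ev$onset_s[-1L] < ev$offset_s[-nrow(ev)]))
      msg <- c(msg, "events must not overlap")
  }
  if (any(ev$offset_s <= ev$onset_s)) msg <- c(msg, "offset must exceed onset")
  if (length(msg)) msg else TRUE
})

#' Locomotion encoder trace
#'
#' Sampled rotary-encoder signal from the running cylinder: sample times and
#' displacement per sample. Times must be strictly increasing.
#'
#' @slot timeS sample times, seconds.
#' @slot displacement encoder displacement per sample (arbitrary units).
#'
#' @export
setClass("LocomotionTrace",
  representation(timeS = "numeric", displacement = "numeric"))

setValidity("LocomotionTrace", function(object) {
  msg <- character()
  if (length(object@timeS) != length(object@displacement))
    msg <- c(msg, "timeS and displacement must have equal length")
  if (length(object@timeS) > 1L && is.unsorted(object@timeS, strictly = TRUE))
    msg <- c(msg, "timeS must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a LocomotionTrace
#' @param timeS sample times, seconds (strictly increasing).
#' @param displacement encoder displacement per sample.
#' @return A [LocomotionTrace-class].
#' @export
LocomotionTrace <- function(timeS, displacement) {
  new("LocomotionTrace", timeS = as.numeric(timeS),
      displacement = as.numeric(displacement))
}

#' A set of stimulus-locked trials from one vessel
#'
#' Thirty-second normalized diameter segments cut around stimulus
#' presentations, together with per-trial metadata and metrics: rest status,
#' baseline SD, responsiveness, stimulus-window peak, value at stimulus
#' cessation (10 s), onset time and the noisy-trial exclusion flag.
#'
#' @slot trials data.frame, one row per trial (columns documented in
#'   [segmentTrials()] and downstream steps).
#' @slot traces numeric matrix, trials x samples; raw diameters (um) after
#'   [segmentTrials()], normalized traces after [normalizeTrials()].
#' @slot timeS within-trial sample times, seconds (0 at window start).
#' @slot frameRateHz sampling rate, Hz.
#' @slot normMode `"none"`, `"range"` or `"mean"`.
#' @slot stimWindow numeric length-2, stimulus onset/offset within the trial
#'   (seconds, default `c(5, 10)`).
#' @slot vesselMeta a [VesselRecord-class].
#'
#' @export
setClass("TrialSet",
  representation(
    trials = "data.frame",
    traces = "matrix",
    timeS = "numeric",
    frameRateHz = "numeric",
    normMode = "character",
    stimWindow = "numeric",
    vesselMeta = "VesselRecord"
  )
)

setValidity("TrialSet", function(object) {
  msg <- character()
  if (nrow(object@traces) != nrow(object@trials))
    msg <- c(msg, "one trace row per trial required")
  if (ncol(object@traces) != length(object@timeS))
    msg <- c(msg, "timeS must match trace columns")
  if (!object@normMode %in% c("none", "range", "mean"))
    msg <- c(msg, "normMode must be 'none', 'range' or 'mean'")
  if (length(object@stimWindow) != 2L ||
      object@stimWindow[1] >= object@stimWindow[2])
    msg <- c(msg, "stimWindow must be increasing length-2")
  if (length(msg)) msg else TRUE
})

#' One-sided Welch power spectrum of a diameter trace
#'
#' Frequencies, spectral density and the 1/f-corrected density
#' (power x frequency) for one vessel. Frequencies start at 0 and are spaced
#' by `frame rate / window length`; the corrected DC value is 0 by
#' construction.
#'
#' @slot freqsHz one-sided frequency grid, Hz.
#' @slot power Welch spectral density estimate (um^2/Hz).
#' @slot powerCorrected `power * freqsHz` (1/f-corrected).
#' @slot frameRateHz sampling rate of the source trace, Hz.
#' @slot vesselMeta a [VesselRecord-class].
#'
#' @export
setClass("PowerSpectrum",
  representation(
    freqsHz = "numeric",
    power = "numeric",
    powerCorrected = "numeric",
    frameRateHz = "numeric",
    vesselMeta = "VesselRecord"
  )
)

setValidity("PowerSpectrum", function(object) {
  msg <- character()
  n <- length(object@freqsHz)
  if (length(object@power) != n || length(object@powerCorrected) != n)
    msg <- c(msg, "freqsHz, power and powerCorrected must align")
  if (n && object@freqsHz[1] != 0) msg <- c(msg, "frequency grid must start at 0")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (n && object@powerCorrected[1] != 0)
    msg <- c(msg, "corrected power at DC must be 0")
  if (length(msg)) msg else TRUE
})

#' Vascular tree with mural-cell somata and marker annotations
#'
#' A rooted tree of straight vessel segments (the root is the penetrating
#' arteriole, possibly split into sections between capillary offshoots),
#' mural-cell soma positions along the segments, branch-point records with
#' locally measured diameter and inter-soma distance (ISD), and per-segment
#' molecular-marker annotations.
#'
#' @slot segments data.frame: `id`, `parent_id` (NA for the root section),
#'   `is_pa` (penetrating-arteriole section?), `pa_index` (section index
#'   down the arteriole, NA for capillaries), `x0,y0,x1,y1` (um),
#'   `length_um`, `diameter_um`.
#' @slot somata data.frame: `id`, `segment_id`, `pos_um` (distance along the
#'   segment from its proximal end), `x_um`, `y_um`.
#' @slot branchPoints data.frame: `id`, `x_um`, `y_um`, `parent_segment`,
#'   `child_segments` (comma-separated ids), `local_diameter_um`,
#'   `local_isd_um` (the soma pair spanning the bifurcation).
#' @slot markers data.frame: `marker`, `segment_id`, `intensity` (signal on
#'   that segment; absent segments carry background-level intensity).
#' @slot backgroundIntensity numeric mean and SD of marker background, used
#'   by the presence threshold (mean + 2 SD).
#'
#' @export
setClass("VesselTree",
  representation(
    segments = "data.frame",
    somata = "data.frame",
    branchPoints = "data.frame",
    markers = "data.frame",
    backgroundIntensity = "numeric"
  )
)

setValidity("VesselTree", function(object) {
  seg <- object@segments
  msg <- character()
  need <- c("id", "parent_id", "is_pa", "x0", "y0", "x1", "y1",
            "length_um", "diameter_um")
  if (!all(need %in% names(seg)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  roots <- seg$id[is.na(seg$parent_id)]
  if (length(roots) != 1L)
    msg <- c(msg, "tree must have exactly one root segment")
  # acyclicity: walking parents from every segment must reach the root
  par <- seg$parent_id; names(par) <- seg$id
  for (s in seg$id) {
    seen <- character(); cur <- s
    while (!is.na(par[[cur]])) {
      if (cur %in% seen) { msg <- c(msg, "segment graph contains a cycle"); break }
      seen <- c(seen, cur); cur <- par[[cur]]
      if (!cur %in% seg$id) { msg <- c(msg, "dangling parent_id"); break }
    }
    if (length(msg)) break
  }
  if (length(msg)) msg else TRUE
})
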