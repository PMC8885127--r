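#' @name accessors
#' @title Accessors for vasomorph data classes
#'
#' @description Small accessor layer over the S4 containers: frame rate,
#' pixel size, diameter values, QC fractions, spectrum components, trial
#' tables and tree components.
#'
#' @param object a vasomorph S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("vesselMeta", function(object) standardGeneric("vesselMeta"))
#' @rdname accessors
#' @export
setGeneric("diameterValues", function(object) standardGeneric("diameterValues"))
#' @rdname accessors
#' @export
setGeneric("qcFraction", function(object) standardGeneric("qcFraction"))
#' @rdname accessors
#' @export
setGeneric("movieFrames", function(object) standardGeneric("movieFrames"))
#' @rdname accessors
#' @export
setGeneric("vesselAxis", function(object) standardGeneric("vesselAxis"))
#' @rdname accessors
#' @export
setGeneric("stimulusEvents", function(object) standardGeneric("stimulusEvents"))
#' @rdname accessors
#' @export
setGeneric("trialTable", function(object) standardGeneric("trialTable"))
#' @rdname accessors
#' @export
setGeneric("trialTraces", function(object) standardGeneric("trialTraces"))
#' @rdname accessors
#' @export
setGeneric("trialTimes", function(object) standardGeneric("trialTimes"))
#' @rdname accessors
#' @export
setGeneric("freqs", function(object) standardGeneric("freqs"))
#' @rdname accessors
#' @export
setGeneric("spectralPower", function(object) standardGeneric("spectralPower"))
#' @rdname accessors
#' @export
setGeneric("correctedPower", function(object) standardGeneric("correctedPower"))
#' @rdname accessors
#' @export
setGeneric("treeSegments", function(object) standardGeneric("treeSegments"))
#' @rdname accessors
#' @export
setGeneric("treeSomata", function(object) standardGeneric("treeSomata"))
#' @rdname accessors
#' @export
setGeneric("treeBranchPoints", function(object) standardGeneric("treeBranchPoints"))
#' @rdname accessors
#' @export
setGeneric("markerAnnotations", function(object) standardGeneric("markerAnnotations"))

#' @rdname accessors
setMethod("frameRate", "VesselMovie", function(object) object@frameRateHz)
#' @rdname accessors
setMethod("frameRate", "DiameterTrace", function(object) object@frameRateHz)
#' @rdname accessors
setMethod("frameRate", "TrialSet", function(object) object@frameRateHz)
#' @rdname accessors
setMethod("frameRate", "PowerSpectrum", function(object) object@frameRateHz)

#' @rdname accessors
setMethod("pixelSize", "VesselMovie", function(object) object@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSize", "VesselRecord", function(object) object@pixelSizeUm)

#' @rdname accessors
setMethod("vesselMeta", "VesselMovie", function(object) object@vesselMeta)
#' @rdname accessors
setMethod("vesselMeta", "DiameterTrace", function(object) object@vesselMeta)
#' @rdname accessors
setMethod("vesselMeta", "TrialSet", function(object) object@vesselMeta)
#' @rdname accessors
setMethod("vesselMeta", "PowerSpectrum", function(object) object@vesselMeta)

#' @rdname accessors
setMethod("diameterValues", "DiameterTrace", function(object) object@valuesUm)
#' @rdname accessors
setMethod("qcFraction", "DiameterTrace", function(object) object@qcFraction)
#' @rdname accessors
setMethod("movieFrames", "VesselMovie", function(object) object@frames)
#' @rdname accessors
setMethod("vesselAxis", "VesselMovie", function(object) object@axis)
#' @rdname accessors
setMethod("stimulusEvents", "StimulusSchedule", function(object) object@events)
#' @rdname accessors
setMethod("trialTable", "TrialSet", function(object) object@trials)
#' @rdname accessors
setMethod("trialTraces", "TrialSet", function(object) object@traces)
#' @rdname accessors
setMethod("trialTimes", "TrialSet", function(object) object@timeS)
#' @rdname accessors
setMethod("freqs", "PowerSpectrum", function(object) object@freqsHz)
#' @rdname accessors
setMethod("spectralPower", "PowerSpectrum", function(object) object@power)
#' @rdname accessors
setMethod("correctedPower", "PowerSpectrum", function(object) object@powerCorrected)
#' @rdname accessors
setMethod("treeSegments", "VesselTree", function(object) object@segments)
#' @rdname accessors
setMethod("treeSomata", "VesselTree", function(object) object@somata)
#' @rdname accessors
setMethod("treeBranchPoints", "VesselTree", function(object) object@branchPoints)
#' @rdname accessors
setMethod("markerAnnotations", "VesselTree", function(object) object@markers)

#' Number of frames in a movie or samples in a trace
#' @param object a [VesselMovie-class] or [DiameterTrace-class].
#' @return integer count.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname nFrames
setMethod("nFrames", "VesselMovie", function(object) dim(object@frames)[3])
#' @rdname nFrames
setMethod("nFrames", "DiameterTrace", function(object) length(object@valuesUm))

setMethod("show", "VesselRecord", function(object) {
  cat(sprintf("VesselRecord '%s': %s, branch order %d, depth %.1f um\n",
              object@vesselId, object@category, object@branchOrder,
              object@depthUm))
})

setMethod("show", "VesselMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "VesselMovie: %d frames of %dx%d px (%.4f um/px) at %.2f Hz, axis of %d points\n",
    d[3], d[1], d[2], object@pixelSizeUm, object@frameRateHz,
    nrow(object@axis)))
})

setMethod("show", "DiameterTrace", function(object) {
  v <- object@valuesUm
  cat(sprintf(
    "DiameterTrace '%s': %d frames at %.2f Hz (%.1f s), mean %.2f um, mean QC %.2f\n",
    object@vesselMeta@vesselId, length(v), object@frameRateHz,
    length(v) / object@frameRateHz, mean(v, na.rm = TRUE),
    mean(object@qcFraction)))
})

setMethod("show", "StimulusSchedule", function(object) {
  ev <- object@events
  cat(sprintf("StimulusSchedule: %d events, conditions: %s\n", nrow(ev),
              paste(unique(ev$condition), collapse = ", ")))
})

setMethod("show", "LocomotionTrace", function(object) {
  cat(sprintf("LocomotionTrace: %d samples over %.1f s, %.1f%% moving\n",
              length(object@timeS), diff(range(object@timeS)),
              100 * mean(object@displacement != 0)))
})

setMethod("show", "TrialSet", function(object) {
  tr <- object@trials
  cat(sprintf("TrialSet '%s': %d trials (%s-normalized)\n",
              object@vesselMeta@vesselId, nrow(tr), object@normMode))
  if ("is_rest" %in% names(tr))
    cat(sprintf("  rest: %d; responsive: %d\n", sum(tr$is_rest),
                sum(tr$is_responsive %in% TRUE)))
})

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf(
    "PowerSpectrum '%s': %d bins, df %.4f Hz, Nyquist %.2f Hz\n",
    object@vesselMeta@vesselId, length(object@freqsHz),
    if (length(object@freqsHz) > 1) diff(object@freqsHz[1:2]) else NA_real_,
    max(object@freqsHz)))
})

setMethod("show", "VesselTree", function(object) {
  cat(sprintf(
    "VesselTree: %d segments (%d PA sections), %d somata, %d branch points, markers: %s\n",
    nrow(object@segments), sum(object@segments$is_pa), nrow(object@somata),
    nrow(object@branchPoints),
    paste(unique(object@markers$marker), collapse = ", ")))
})
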