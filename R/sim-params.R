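#' Parameters for simulated diameter traces
#'
#' Defines the generative model for a synthetic vessel-diameter time series:
#' a constant baseline, a stimulus-locked dilation kernel added on trials
#' that truly respond, a vasomotion sinusoid, pink (1/f) background noise
#' and white measurement noise.
#'
#' Defaults reflect typical awake two-photon recordings of cortical
#' microvessels: 7.6 Hz acquisition, ~8 um vessels, dilations of a few
#' percent of baseline, and vasomotion centered at 0.1 Hz.
#'
#' @param duration_s recording length, seconds.
#' @param frame_rate_hz sampling rate, Hz.
#' @param baseline_diameter_um resting diameter, micrometres.
#' @param dilation_amplitude_frac response peak as a fraction of baseline.
#' @param dilation_onset_s rise time constant of the response kernel, s.
#' @param dilation_decay_s decay time constant of the response kernel, s.
#' @param vasomotion_freq_hz vasomotion frequency, Hz.
#' @param vasomotion_amplitude_um vasomotion sinusoid amplitude, um.
#' @param vasomotion_phase_rad initial phase of the vasomotion sinusoid,
#'   radians; the default `NULL` draws a uniform random phase per trace
#'   (vasomotion is not locked to the stimulus in vivo).
#' @param pink_noise_sd_um SD of the 1/f background component, um.
#' @param white_noise_sd_um SD of the white measurement noise, um.
#' @param response_probability probability that a trial truly responds.
#' @param rng_seed integer seed, or NULL to use the current RNG state.
#' @return A validated list of class `TraceSimParams`.
#' @examples
#' p <- traceSimParams(duration_s = 90, vasomotion_amplitude_um = 0.3)
#' @export
traceSimParams <- function(duration_s = 600, frame_rate_hz = 7.6,
                           baseline_diameter_um = 8,
                           dilation_amplitude_frac = 0.05,
                           dilation_onset_s = 1, dilation_decay_s = 3,
                           vasomotion_freq_hz = 0.1,
                           vasomotion_amplitude_um = 0.25,
                           vasomotion_phase_rad = NULL,
                           pink_noise_sd_um = 0.05,
                           white_noise_sd_um = 0.05,
                           response_probability = 0.6,
                           rng_seed = NULL) {
  stopifnot(duration_s > 0, frame_rate_hz > 0, baseline_diameter_um > 0,
            dilation_amplitude_frac >= 0, dilation_onset_s > 0,
            dilation_decay_s > dilation_onset_s,
            vasomotion_freq_hz >= 0, vasomotion_amplitude_um >= 0,
            pink_noise_sd_um >= 0, white_noise_sd_um >= 0,
            response_probability >= 0, response_probability <= 1)
  structure(list(
    duration_s = duration_s, frame_rate_hz = frame_rate_hz,
    baseline_diameter_um = baseline_diameter_um,
    dilation_amplitude_frac = dilation_amplitude_frac,
    dilation_onset_s = dilation_onset_s, dilation_decay_s = dilation_decay_s,
    vasomotion_freq_hz = vasomotion_freq_hz,
    vasomotion_amplitude_um = vasomotion_amplitude_um,
    vasomotion_phase_rad = vasomotion_phase_rad,
    pink_noise_sd_um = pink_noise_sd_um,
    white_noise_sd_um = white_noise_sd_um,
    response_probability = response_probability, rng_seed = rng_seed
  ), class = "TraceSimParams")
}

#' Parameters for simulated vessel movies
#'
#' Defines a synthetic single-channel movie of one vessel whose
#' cross-sectional intensity profile perpendicular to a given axis polyline
#' has an analytically known full width at half maximum per frame, so the
#' diameter-extraction stage can be validated against ground truth.
#'
#' For the `"gaussian"` profile the Gaussian sigma is chosen so that
#' `2*sqrt(2*log(2))*sigma` equals the requested diameter. The `"plateau"`
#' profile is flat at peak intensity with a one-pixel linear edge whose
#' half-maximum crossings are exactly one diameter apart.
#'
#' @param n_frames number of frames.
#' @param height_px,width_px frame size, pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param vessel_axis two-column matrix of (x, y) axis coordinates, pixels.
#' @param profile_shape `"gaussian"` or `"plateau"`.
#' @param diameter_series_um per-frame ground-truth diameter, um
#'   (length `n_frames`).
#' @param peak_intensity,background_intensity intensity levels (arbitrary
#'   units); peak must exceed background.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param rng_seed integer seed, or NULL.
#' @return A validated list of class `MovieSimParams`.
#' @export
movieSimParams <- function(n_frames, height_px, width_px,
                           pixel_size_um = 0.1958, vessel_axis,
                           profile_shape = c("gaussian", "plateau"),
                           diameter_series_um,
                           peak_intensity = 200, background_intensity = 20,
                           noise_sd = 0, rng_seed = NULL) {
  profile_shape <- match.arg(profile_shape)
  stopifnot(n_frames >= 1, height_px >= 4, width_px >= 4, pixel_size_um > 0,
            noise_sd >= 0)
  if (length(diameter_series_um) == 1L)
    diameter_series_um <- rep(diameter_series_um, n_frames)
  if (length(diameter_series_um) != n_frames)
    stop("diameter_series_um must have one value per frame")
  if (peak_intensity <= background_intensity)
    stop("peak_intensity must exceed background_intensity")
  structure(list(
    n_frames = as.integer(n_frames), height_px = as.integer(height_px),
    width_px = as.integer(width_px), pixel_size_um = pixel_size_um,
    vessel_axis = as.matrix(vessel_axis), profile_shape = profile_shape,
    diameter_series_um = as.numeric(diameter_series_um),
    peak_intensity = peak_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd, rng_seed = rng_seed
  ), class = "MovieSimParams")
}

#' Parameters for simulated vascular trees
#'
#' Defines a rooted synthetic vascular tree: a penetrating arteriole split
#' into sections by capillary offshoots, with per-branch-order diameters
#' (non-increasing) and inter-soma distances (non-decreasing), branch-point
#' specialization ratios, and molecular markers that terminate at configured
#' branch orders. Index 1 of the order-indexed sequences is the penetrating
#' arteriole (order 0), index k+1 is capillary order k.
#'
#' @param max_branch_order deepest capillary branch order generated.
#' @param diameter_by_order_um non-increasing numeric, orders 0..max.
#' @param isd_by_order_um non-decreasing numeric, orders 0..max.
#' @param branch_diameter_ratio branch-point diameter over the mean of the
#'   adjacent up/downstream diameters (> 1 in real vessels).
#' @param branch_isd_ratio branch-point ISD over the mean of the adjacent
#'   up/downstream ISDs (in (0, 1) in real vessels).
#' @param marker_termination_orders named numeric; most distal branch order
#'   (immunohistochemistry convention: arteriole = 0) at which each marker
#'   is still present.
#' @param n_offshoots number of capillary offshoots leaving the arteriole.
#' @param somata_per_segment mural-cell somata placed on each segment.
#' @param soma_jitter_frac uniform jitter on soma spacing, as a fraction of
#'   the local ISD (0 gives the deterministic skeleton).
#' @param rng_seed integer seed, or NULL.
#' @return A validated list of class `TreeSimParams`.
#' @export
treeSimParams <- function(max_branch_order = 4,
                          diameter_by_order_um = c(15, 9, 7, 6, 5),
                          isd_by_order_um = c(12, 18, 25, 35, 50),
                          branch_diameter_ratio = 1.2,
                          branch_isd_ratio = 0.6,
                          marker_termination_orders =
                            c(elastin = 0, nestin = 2, aSMA = 3),
                          n_offshoots = 3, somata_per_segment = 3,
                          soma_jitter_frac = 0, rng_seed = NULL) {
  stopifnot(max_branch_order >= 1,
            length(diameter_by_order_um) == max_branch_order + 1,
            length(isd_by_order_um) == max_branch_order + 1,
            n_offshoots >= 1, somata_per_segment >= 2,
            soma_jitter_frac >= 0, soma_jitter_frac < 0.5)
  if (branch_diameter_ratio <= 0 || branch_isd_ratio <= 0)
    stop("branch ratios must be positive")
  if (any(diff(diameter_by_order_um) > 0))
    stop("diameter_by_order_um must be non-increasing")
  if (any(diff(isd_by_order_um) < 0))
    stop("isd_by_order_um must be non-decreasing")
  if (is.null(names(marker_termination_orders)) ||
      any(!nzchar(names(marker_termination_orders))))
    stop("marker_termination_orders must be a named vector")
  structure(list(
    max_branch_order = as.integer(max_branch_order),
    diameter_by_order_um = as.numeric(diameter_by_order_um),
    isd_by_order_um = as.numeric(isd_by_order_um),
    branch_diameter_ratio = branch_diameter_ratio,
    branch_isd_ratio = branch_isd_ratio,
    marker_termination_orders = marker_termination_orders,
    n_offshoots = as.integer(n_offshoots),
    somata_per_segment = as.integer(somata_per_segment),
    soma_jitter_frac = soma_jitter_frac, rng_seed = rng_seed
  ), class = "TreeSimParams")
}
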