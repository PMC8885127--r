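# Shared fixture builders (all fixtures are generated in code).

# PowerSpectrum with given one-sided frequency grid and power values.
makePS <- function(freqs, power, fs = 7.6) {
  new("PowerSpectrum", freqsHz = freqs, power = power,
      powerCorrected = power * freqs, frameRateHz = fs,
      vesselMeta = VesselRecord())
}

# TrialSet built directly from a trials-x-samples matrix of already
# normalized traces, with baseline statistics computed from the matrix.
trialSetFromMatrix <- function(X, fs = 7.6, stim = c(5, 10),
                               norm_mode = "range") {
  n <- ncol(X)
  tt <- (seq_len(n) - 1) / fs
  base_idx <- which(tt < stim[1])
  tr <- data.frame(
    trial = seq_len(nrow(X)),
    condition = "stim",
    onset_s = stim[1], offset_s = stim[2],
    norm_valid = TRUE,
    baseline_mean_pct = apply(X[, base_idx, drop = FALSE], 1, mean),
    baseline_sd_pct = apply(X[, base_idx, drop = FALSE], 1, stats::sd))
  new("TrialSet", trials = tr, traces = X, timeS = tt, frameRateHz = fs,
      normMode = norm_mode, stimWindow = as.numeric(stim),
      vesselMeta = VesselRecord())
}

# Minimal hand-built VesselTree from a segments data.frame (+ optional
# somata / branch points), filling required empty tables.
manualTree <- function(segments, somata = NULL, branch_points = NULL,
                       markers = NULL) {
  if (is.null(somata))
    somata <- data.frame(id = character(), segment_id = character(),
                         pos_um = numeric(), x_um = numeric(),
                         y_um = numeric())
  if (is.null(branch_points))
    branch_points <- data.frame(id = character(), x_um = numeric(),
                                y_um = numeric(),
                                parent_segment = character(),
                                child_segments = character(),
                                local_diameter_um = numeric(),
                                local_isd_um = numeric())
  if (is.null(markers))
    markers <- data.frame(marker = character(), segment_id = character(),
                          intensity = numeric())
  new("VesselTree", segments = segments, somata = somata,
      branchPoints = branch_points, markers = markers,
      backgroundIntensity = c(mean = 10, sd = 2))
}

# straight horizontal-axis movie params helper
horizMovieParams <- function(diam_um, n_frames = 2, px = 1,
                             shape = "gaussian", size = 64, noise = 0,
                             seed = NULL) {
  movieSimParams(n_frames = n_frames, height_px = size, width_px = size,
                 pixel_size_um = px,
                 vessel_axis = cbind(c(size * 0.35, size * 0.65),
                                     c(size / 2, size / 2)),
                 profile_shape = shape, diameter_series_um = diam_um,
                 noise_sd = noise, rng_seed = seed)
}
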