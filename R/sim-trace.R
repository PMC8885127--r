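#' Build a periodic stimulus schedule
#'
#' Creates `n_trials` stimulus events on a regular trial grid: event `k`
#' (0-based) has onset `k * trial_length_s + stim_onset_s` and offset
#' `k * trial_length_s + stim_offset_s`. Condition labels are cycled
#' deterministically through `conditions` (so condition counts are balanced
#' by construction) or drawn uniformly when `condition_mode = "random"`.
#'
#' @param n_trials number of stimulus presentations (> 0).
#' @param trial_length_s trial cycle length, seconds (default 30).
#' @param stim_onset_s,stim_offset_s stimulus window within each trial,
#'   seconds (default 5 and 10).
#' @param conditions character vector of condition labels.
#' @param condition_mode `"cycle"` (default) or `"random"`.
#' @param rng_seed seed used when `condition_mode = "random"`.
#' @return A [StimulusSchedule-class].
#' @examples
#' stimulusEvents(makeStimulusSchedule(3))$onset_s   # 5 35 65
#' @export
makeStimulusSchedule <- function(n_trials, trial_length_s = 30,
                                 stim_onset_s = 5, stim_offset_s = 10,
                                 conditions = "stim",
                                 condition_mode = c("cycle", "random"),
                                 rng_seed = NULL) {
  condition_mode <- match.arg(condition_mode)
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 1)
    stop("n_trials must be a positive count")
  if (!(stim_onset_s >= 0 && stim_onset_s < stim_offset_s &&
        stim_offset_s <= trial_length_s))
    stop("need 0 <= stim_onset_s < stim_offset_s <= trial_length_s")
  k <- seq_len(n_trials) - 1
  cond <- if (condition_mode == "cycle") {
    rep_len(conditions, n_trials)
  } else {
    withSeed(rng_seed, sample(conditions, n_trials, replace = TRUE))
  }
  new("StimulusSchedule", events = data.frame(
    onset_s = k * trial_length_s + stim_onset_s,
    offset_s = k * trial_length_s + stim_offset_s,
    condition = cond, stringsAsFactors = FALSE))
}

# Difference-of-exponentials dilation kernel, unit peak, causal.
responseKernel <- function(t, rise_s, decay_s) {
  h <- ifelse(t < 0, 0, exp(-t / decay_s) - exp(-t / rise_s))
  tpeak <- rise_s * decay_s * log(decay_s / rise_s) / (decay_s - rise_s)
  h / (exp(-tpeak / decay_s) - exp(-tpeak / rise_s))
}

#' Simulate a vessel diameter trace with known ground truth
#'
#' Generates a diameter time series as the sum of a constant baseline, a
#' stimulus-locked dilation kernel (difference of exponentials, peak scaled
#' to `dilation_amplitude_frac * baseline`) on trials drawn as true
#' responders, a vasomotion sinusoid, pink (1/f) noise and white noise.
#' The same parameters and seed always produce the identical trace.
#'
#' @param p a [traceSimParams()] object.
#' @param schedule a [StimulusSchedule-class]; must fit within `duration_s`.
#' @param vesselMeta [VesselRecord-class] attached to the trace.
#' @return A list with elements `trace` (a [DiameterTrace-class]), and
#'   `truth`: a list with `true_response` (logical per trial), `vasomotion`
#'   (the sinusoid component, um), `response_component`, `noise` and
#'   `time_s`.
#' @examples
#' sch <- makeStimulusSchedule(3)
#' p <- traceSimParams(duration_s = 90, rng_seed = 1)
#' sim <- makeDiameterTrace(p, sch)
#' @export
makeDiameterTrace <- function(p, schedule, vesselMeta = VesselRecord()) {
  stopifnot(inherits(p, "TraceSimParams"), is(schedule, "StimulusSchedule"))
  ev <- stimulusEvents(schedule)
  if (nrow(ev) && max(ev$offset_s) > p$duration_s)
    stop("stimulus schedule exceeds trace duration")
  n <- round(p$duration_s * p$frame_rate_hz)
  t <- (seq_len(n) - 1) / p$frame_rate_hz
  withSeed(p$rng_seed, {
    true_resp <- if (nrow(ev))
      stats::runif(nrow(ev)) < p$response_probability else logical(0)
    response <- numeric(n)
    amp <- p$dilation_amplitude_frac * p$baseline_diameter_um
    if (amp > 0 && any(true_resp)) {
      for (i in which(true_resp)) {
        response <- response +
          amp * responseKernel(t - ev$onset_s[i],
                               p$dilation_onset_s, p$dilation_decay_s)
      }
    }
    phase <- if (is.null(p$vasomotion_phase_rad))
      stats::runif(1, 0, 2 * pi) else p$vasomotion_phase_rad
    vaso <- p$vasomotion_amplitude_um *
      sin(2 * pi * p$vasomotion_freq_hz * t + phase)
    noise <- pinkNoise(n, p$pink_noise_sd_um)
    if (p$white_noise_sd_um > 0)
      noise <- noise + stats::rnorm(n, sd = p$white_noise_sd_um)
    values <- p$baseline_diameter_um + response + vaso + noise
    list(
      trace = DiameterTrace(values, frameRateHz = p$frame_rate_hz,
                            vesselMeta = vesselMeta),
      truth = list(true_response = true_resp, vasomotion = vaso,
                   vasomotion_phase_rad = phase,
                   response_component = response, noise = noise, time_s = t)
    )
  })
}

#' Simulate a locomotion encoder trace
#'
#' Produces a sampled displacement trace that is nonzero exactly inside the
#' requested locomotion bouts (half-open intervals `[start, start + dur)`)
#' and zero elsewhere.
#'
#' @param duration_s trace length, seconds.
#' @param sample_rate_hz encoder sampling rate, Hz.
#' @param bout_starts_s,bout_durations_s equal-length numeric vectors of
#'   bout onsets and durations, seconds; bouts must not overlap and must lie
#'   within the trace.
#' @param bout_displacement displacement value inside bouts (default 1).
#' @return A [LocomotionTrace-class].
#' @examples
#' loco <- makeLocomotion(10, 100, bout_starts_s = 2, bout_durations_s = 0.5)
#' @export
makeLocomotion <- function(duration_s, sample_rate_hz,
                           bout_starts_s = numeric(),
                           bout_durations_s = numeric(),
                           bout_displacement = 1) {
  stopifnot(duration_s > 0, sample_rate_hz > 0,
            length(bout_starts_s) == length(bout_durations_s))
  if (length(bout_starts_s)) {
    o <- order(bout_starts_s)
    bs <- bout_starts_s[o]; bd <- bout_durations_s[o]
    if (any(bd <= 0)) stop("bout durations must be positive")
    if (any(bs < 0) || any(bs + bd > duration_s))
      stop("bouts must lie within the trace")
    if (length(bs) > 1L && any(bs[-1L] < (bs + bd)[-length(bs)]))
      stop("locomotion bouts must not overlap")
    bout_starts_s <- bs; bout_durations_s <- bd
  }
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  disp <- numeric(n)
  for (i in seq_along(bout_starts_s)) {
    inside <- t >= bout_starts_s[i] & t < bout_starts_s[i] + bout_durations_s[i]
    disp[inside] <- bout_displacement
  }
  LocomotionTrace(t, disp)
}
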