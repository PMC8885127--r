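#' Detrend a diameter trace with a rolling low-percentile baseline
#'
#' Subtracts the 8th percentile computed over a centred 15-s rolling window
#' (truncated at the trace edges) from the trace, removing slow drift while
#' preserving oscillations faster than the window. The percentile is the
#' linear-interpolated empirical percentile.
#'
#' @param trace a [DiameterTrace-class] at least `window_s` long.
#' @param window_s rolling window length, seconds (default 15).
#' @param percentile percentile subtracted, 0-100 (default 8).
#' @return A [DiameterTrace-class] of the same length holding the detrended
#'   values (which may be near zero; validity of positivity is waived by
#'   flagging qc as-is). Returned values are plain numeric in a
#'   [DiameterTrace-class]-like list: see Details.
#' @details The detrended signal is returned as a numeric vector with
#'   attributes `frame_rate_hz` preserved via the `frameRateHz` argument of
#'   downstream functions; spectral functions in this package accept either
#'   a numeric vector plus `frame_rate_hz`, or a [DiameterTrace-class].
#' @export
detrendTrace <- function(trace, window_s = 15, percentile = 8) {
  v <- diameterValues(trace)
  fs <- frameRate(trace)
  width <- round(window_s * fs)
  if (width > length(v))
    stop("trace shorter than the detrending window (", window_s, " s)")
  baseline <- rollingPercentile(v, width, percentile / 100)
  out <- v - baseline
  attr(out, "frame_rate_hz") <- fs
  out
}

#' Welch power spectral density of a (detrended) diameter trace
#'
#' One-sided Welch estimate: the trace is split into Hamming-windowed
#' segments of `window_s` seconds with `overlap_frac` overlap; modified
#' periodograms are averaged and density-scaled so that the integral of the
#' spectrum over frequency approximates the signal variance. The frequency
#' spacing is `1 / window_s` Hz (1/60 Hz at the default), so 0.1 Hz falls
#' exactly on a bin.
#'
#' @param x numeric trace (e.g. from [detrendTrace()]) or a
#'   [DiameterTrace-class].
#' @param frame_rate_hz sampling rate; taken from `x` when it is a trace or
#'   carries a `frame_rate_hz` attribute.
#' @param window_s Welch segment length, seconds (default 60).
#' @param overlap_frac segment overlap fraction (default 0.5).
#' @param demean remove each segment's mean before windowing (default
#'   TRUE), preventing the DC line of offset signals from leaking into the
#'   lowest bins.
#' @param vesselMeta [VesselRecord-class] attached to the spectrum.
#' @return A [PowerSpectrum-class] with the raw and 1/f-corrected power.
#' @export
welchPSD <- function(x, frame_rate_hz = NULL, window_s = 60,
                     overlap_frac = 0.5, demean = TRUE, vesselMeta = NULL) {
  if (is(x, "DiameterTrace")) {
    if (is.null(vesselMeta)) vesselMeta <- vesselMeta(x)
    frame_rate_hz <- frameRate(x)
    x <- diameterValues(x)
  }
  if (is.null(frame_rate_hz)) frame_rate_hz <- attr(x, "frame_rate_hz")
  if (is.null(frame_rate_hz)) stop("frame_rate_hz required")
  if (is.null(vesselMeta)) vesselMeta <- VesselRecord()
  x <- as.numeric(x)
  fs <- frame_rate_hz
  nper <- round(window_s * fs)
  if (nper > length(x)) stop("trace shorter than one Welch window")
  step <- max(1L, round(nper * (1 - overlap_frac)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- hammingWindow(nper)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- floor(nper / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    if (demean) seg <- seg - mean(seg)
    seg <- seg * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + Mod(X)^2 * scale
  }
  pxx <- acc / length(starts)
  # one-sided: double everything except DC and (for even nper) Nyquist
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  pxx <- pxx * dbl
  freqs <- (seq_len(nfreq) - 1) * fs / nper
  ps <- new("PowerSpectrum", freqsHz = freqs, power = pxx,
            powerCorrected = pxx * freqs, frameRateHz = fs,
            vesselMeta = vesselMeta)
  ps
}

#' 1/f (pink-noise) correction of a power spectrum
#'
#' Multiplies the spectral density by its frequency
#' (`corrected = power * frequency`), flattening 1/f background noise; the
#' corrected DC value is 0. [welchPSD()] already fills this slot; use this
#' function to (re)apply the correction explicitly.
#'
#' @param ps a [PowerSpectrum-class].
#' @return The [PowerSpectrum-class] with `powerCorrected` recomputed.
#' @export
oneOverFCorrect <- function(ps) {
  methods::initialize(ps, powerCorrected = spectralPower(ps) * freqs(ps))
}

#' Vasomotion summary of one corrected spectrum
#'
#' Extracts the 1/f-corrected power at the bin nearest `target_hz`
#' (exactly the 0.1 Hz bin with 60-s Welch windows) and the trapezoidal
#' integral of corrected power over the vasomotion band.
#'
#' @param ps a [PowerSpectrum-class].
#' @param target_hz frequency of interest, Hz (default 0.1).
#' @param band lower/upper band limits for the AUC, Hz (default 0.05-0.15).
#' @return A list: `power_at_target` (corrected power at the nearest bin),
#'   `band_auc`, `target_hz`, `band`.
#' @export
summarizeVasomotion <- function(ps, target_hz = 0.1, band = c(0.05, 0.15)) {
  f <- freqs(ps)
  pc <- correctedPower(ps)
  nyq <- max(f)
  if (band[2] > nyq || target_hz > nyq)
    stop("requested band exceeds the Nyquist frequency")
  i <- which.min(abs(f - target_hz))
  inb <- f >= band[1] & f <= band[2]
  fb <- f[inb]; pb <- pc[inb]
  auc <- if (sum(inb) > 1)
    sum(diff(fb) * (pb[-1] + pb[-length(pb)]) / 2) else 0
  list(power_at_target = pc[i], band_auc = auc,
       target_hz = f[i], band = band)
}

#' Remove outlier spectra from a cohort
#'
#' For each spectrum the maximum corrected power in `[0, f_max]` Hz is
#' taken; spectra whose maximum exceeds `k` times the standard deviation of
#' all the maxima are removed. If the SD is zero (all maxima equal) nothing
#' is removed.
#'
#' @param cohort list of [PowerSpectrum-class] objects (>= 2 for the rule to
#'   apply; a single spectrum is returned unchanged).
#' @param f_max upper frequency bound for the peak search, Hz (default 1).
#' @param k SD multiplier (default 3).
#' @param use_corrected use corrected (default) or raw power for the maxima.
#' @return A list: `kept` (the retained spectra), `removed` (integer indices
#'   of removed spectra), `maxima` (per-spectrum peak values),
#'   `threshold`.
#' @export
removeOutlierSpectra <- function(cohort, f_max = 1.0, k = 3,
                                 use_corrected = TRUE) {
  maxima <- vapply(cohort, function(ps) {
    f <- freqs(ps)
    p <- if (use_corrected) correctedPower(ps) else spectralPower(ps)
    max(p[f <= f_max])
  }, numeric(1))
  if (length(cohort) < 2) {
    return(list(kept = cohort, removed = integer(), maxima = maxima,
                threshold = NA_real_))
  }
  s <- stats::sd(maxima)
  if (is.na(s) || s == 0) {
    return(list(kept = cohort, removed = integer(), maxima = maxima,
                threshold = NA_real_))
  }
  thr <- k * s
  removed <- which(maxima > thr)
  list(kept = cohort[setdiff(seq_along(cohort), removed)], removed = removed,
       maxima = maxima, threshold = thr)
}

#' Flag vessels with high vasomotion power
#'
#' A vessel is high-power when its corrected power at the target frequency
#' exceeds `k` times the standard deviation of that power across the
#' cohort. With zero SD all flags are FALSE.
#'
#' @param powers numeric vector of per-vessel corrected power at the target
#'   frequency (e.g. `power_at_target` from [summarizeVasomotion()]).
#' @param k SD multiplier (default 0.5).
#' @return logical vector of flags, same length as `powers`, with the
#'   threshold as attribute `"threshold"`.
#' @export
classifyHighPower <- function(powers, k = 0.5) {
  if (length(powers) < 2) {
    out <- rep(FALSE, length(powers))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  s <- stats::sd(powers)
  if (is.na(s) || s == 0) {
    out <- rep(FALSE, length(powers))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  out <- powers > k * s
  attr(out, "threshold") <- k * s
  out
}
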