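---
title: "Methods: microvascular diameter dynamics, vasomotion and morphometry"
author: "vasomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microvascular diameter dynamics, vasomotion and morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasomorph)
```

# Scope and data model

vasomorph quantifies cerebral microvascular function along the
arteriole–capillary axis from awake two-photon imaging and fixed-tissue
morphometry. Its containers mirror the experiment: a `VesselMovie` (an
intensity stack with pixel size, frame rate and a user-supplied vessel-axis
polyline), a `DiameterTrace` (per-frame diameter in µm with a per-frame QC
fraction), a `TrialSet` (stimulus-locked 30-s segments with flags and
metrics), a `PowerSpectrum` (one-sided Welch estimate plus its 1/f-corrected
form) and a `VesselTree` (segments, mural-cell somata, branch points and
molecular-marker annotations). Axes and soma positions are *inputs*: the
package does not segment vessels or detect cells.

# Diameter extraction

Preprocessing follows standard practice for vessel recordings: stack-global
rescaling to the 8-bit range, a 3×3 median filter against shot noise
("despeckling"), per-frame linear contrast matching to the stack mean frame
(countering stimulus light artifacts), and rigid-translation registration by
phase correlation against the mean frame. Translation-only registration is
adequate for the rigid, small-displacement motion this package's synthetic
fixtures (and typically head-fixed recordings) exhibit; non-rigid
registration is out of scope.

The diameter at one axis position is the full width at half maximum (FWHM)
of the intensity profile sampled by bilinear interpolation along the local
normal at 1-px spacing. Numerical choices, both exposed as arguments:

- **Background** defaults to the profile minimum; a low-percentile
  alternative is available for noisy profiles. With the minimum convention
  the sampled normal must be long enough for the profile to reach
  background — for a Gaussian cross-section a half-width of ≳ 2× the
  expected diameter keeps the truncation bias of the half level well below
  1%.
- **Crossing rule**: walking outward from the global peak, the *first*
  sub-half-level crossing on each side is located with linear sub-sample
  interpolation. First-crossing-from-peak (rather than outermost crossing)
  avoids capturing neighboring vessels on short normals centred on the
  axis.
- Flat profiles, or profiles that never fall below the half level on a
  side, yield "no measurement"; the per-frame fraction of valid positions
  is recorded as the QC fraction. Frames with QC below 0.5 are flagged but
  retained — exclusion happens at the trial level, not the frame level.

The per-frame diameter is the arithmetic mean of valid widths along the
axis. On noise-free synthetic vessels (Gaussian and plateau profiles,
5–20 px wide) the extracted diameter matches the analytic FWHM within 2%,
which is the package's oracle-equivalence contract.

# Trial analysis

Traces are cut into 30-s trials starting 5 s before each stimulus onset;
within a trial the stimulus occupies 5–10 s. Conventions that the data do
not themselves dictate, fixed as follows:

- The stimulus window is half-open, `5 ≤ t < 10` s, for window maxima; the
  "value at cessation" is read at the sample nearest t = 10 s. This avoids
  double-counting the boundary frame.
- Locomotion epochs: encoder samples with |displacement| above threshold
  (default: any nonzero displacement) form runs; runs closer than 1 s are
  merged *first*, then merged runs lasting ≤ 1/3 s are discarded. Merging
  first treats the 1-s separation as part of the definition of an epoch.
- A trial is at rest when no epoch intersects the *closed* interval from
  2 s before onset to stimulus offset — a conservative reading of "prior
  to or during".
- Normalization: the default `"range"` mode is
  100·(D − Dmin)/(Dmax − Dmin) with Dmin/Dmax over the 5-s baseline, which
  maps the baseline extremes to 0 and 100 exactly. A `"mean"` mode
  (100·(D − mean)/mean, i.e. percent change from baseline) is provided
  because reported peak magnitudes of a few percent are natural in that
  scale; every output records the mode. The baseline SD used by the
  classifier is computed on the normalized baseline, consistent with how
  the threshold is applied.
- Responsiveness: stimulus-window maximum minus baseline mean, strictly
  greater than 0.5 × baseline SD. The comparison is affine-invariant, so
  the choice of normalization mode does not affect classification.
- Onset time: the first time at or after stimulus onset at which the trace
  reaches baseline mean + 10% of (peak − baseline mean), linearly
  interpolated between frames.
- Noisy trials: responsive trials whose peak exceeds 10× the mean peak of
  *all* responsive trials in the dataset are excluded from summaries.

A caveat that matters for interpreting response rates: the 0.5 × SD maximum
criterion compares the maximum of ~38 stimulus-window samples against a
threshold only half an SD above the mean, so under any stationary noise it
has a substantial positive rate by construction (for i.i.d. Gaussian noise,
near 1; lower when slow vasomotion dominates the baseline SD). Classified
response rates are therefore calibrated quantities, not estimates of the
underlying response probability; the acceptance tests check them against a
brute-force Monte-Carlo of the same rule rather than against the raw
response probability.

# Vasomotion

Traces are detrended by subtracting a rolling 8th percentile over a
centred 15-s window (linear-interpolated empirical percentile; edge windows
truncated rather than padded), which removes drift while preserving
oscillations faster than the window. The Welch estimate uses Hamming
windows of 60 s with 50% overlap and one-sided density scaling, giving a
1/60 Hz bin spacing so that 0.1 Hz is exactly bin 6; the value "at 0.1 Hz"
is the nearest bin, with no interpolation. Each segment's mean is removed
before windowing: the percentile detrend deliberately leaves a positive
offset, and its DC line would otherwise leak through the Hamming mainlobe
into the two lowest bins. The 1/f correction multiplies power by frequency,
flattening pink noise; the corrected DC value is 0 by construction.

Cohort rules are implemented literally as stated thresholds — outlier
spectra with a 0–1 Hz corrected-power maximum above 3 × SD of all maxima
are removed, and vessels with corrected 0.1 Hz power above 0.5 × SD of the
cohort's values are flagged high-power — with two guards: a zero SD removes
or flags nothing (the literal rule degenerates), and the SD is the sample
(n−1) standard deviation throughout. Mean + k·SD variants and raw-power
maxima are available as options.

Because stimulation recurs every 30 s, its spectral signature falls at
1/30 Hz ≈ 0.03 Hz and harmonics, leaving the 0.05–0.15 Hz vasomotion band
interpretable; this is verified as an acceptance property.

# Morphometry

Branch orders are assigned under both field conventions. Ex vivo
(immunohistochemistry): the penetrating arteriole is order 0 throughout and
the first vessel branching off it is order 1, incrementing at each
subsequent bifurcation in the capillary bed. In vivo: the arteriole carries
its own counter (sections PA0, PA1, … between successive offshoots) while
capillary orders are unchanged. The two conventions therefore differ only
in how the arteriole itself is subdivided.

ISD is the Euclidean distance from each soma to its nearest more-proximal
soma on the same segment, measured in one plane (path-length ISD is a
configuration option). Branch-point ratios divide the locally measured
branch value by the mean of the adjacent upstream and downstream values,
with downstream values averaged over daughters; the ISD "at" a branch point
is the soma pair spanning the bifurcation, and that convention is recorded
in the output. Marker termination points are found by walking distally from
the root along the main path toward the capillary bed (preferring
marker-positive daughters) and taking the most distal above-threshold
position; presence means intensity above background mean + 2 × background
SD (configurable — visual identification in the original workflow). The ISD
at the termination is likewise the pair spanning the termination point, and
the surrounding profile reports ISDs at soma offsets −2…+2 normalized to
offset 0 (exactly 1 there by construction). A marker present to the edge of
the field yields a distinct "no termination in field" status rather than a
fabricated point.

# Statistics

The group-comparison layer wraps the standard tests: a generalized
Cochran–Mantel–Haenszel test across stimulus-condition strata (the single
candidate stratification variable given the condition-balance checks), with
pairwise Fisher exact tests on collapsed 2×2 tables, Holm-adjusted by
default; for one stratum the statistic reduces to (N−1)/N × Pearson
chi-square, computed in closed form. Kruskal–Wallis uses mid-ranks with tie
correction; pairwise rank-sum post hocs are exact when both groups have ≤ 8
observations and no ties (where they equal full-permutation enumeration)
and use the continuity-corrected normal approximation otherwise, unadjusted
by default to match common reporting, with Holm available. One-way ANOVA
reports Tukey HSD pairs; degenerate inputs (all values identical, or zero
residual variance with unequal means) return the 0/1 or 0-limit results
with an explicit flag rather than failing. The linear mixed model for
perivascular nNOS intensity is intentionally not re-implemented — the
package emits the long-format table such a model consumes.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

- **Traces**: baseline diameter (default 8 µm) + a causal
  difference-of-exponentials dilation kernel (rise 1 s, decay 3 s, peak
  scaled to 5% of baseline) on trials drawn as true responders + a
  vasomotion sinusoid (default 0.1 Hz, 0.25 µm) + pink noise (power ∝ 1/f,
  generated by spectral shaping with amplitude ∝ f^(−1/2), DC zeroed,
  scaled to a target SD) + white noise, sampled at 7.6 Hz. The kernel shape
  is a modelling choice — smooth, causal, with an analytic peak — not a
  measured waveform. The sinusoid's initial phase is random (seeded) by
  default: vasomotion is not stimulus-locked in vivo, and a fixed phase at
  exactly 0.1 Hz would repeat identically in every 30-s trial.
- **Movies**: Gaussian cross-sections with σ = FWHM/(2√(2 ln 2)), or
  plateau cross-sections with a one-pixel linear edge whose half-maximum
  crossings are exactly one diameter apart, rendered around an axis that
  must keep a margin of at least the maximum diameter from the border.
- **Trees**: an arteriole chain with capillary offshoots bifurcating to a
  configurable maximum order; per-order diameters non-increasing and ISDs
  non-decreasing (defaults 15→5 µm and 12→50 µm over orders 0–4, spanning
  the arteriole-to-capillary range); branch-point diameter and ISD set to
  the configured ratios times the mean of adjacent values; markers present
  up to configured termination orders at a fixed signal level well above
  background. With zero soma jitter the tree is deterministic, so
  configured ratios are recovered exactly.

Everything is reproducible: identical parameters and seed give bit-identical
rasters and exact floats, and with all stochastic amplitudes zero each
generator returns its deterministic skeleton.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: non-rigid tissue motion, depth-dependent SNR and
scattering, broadband (rather than sinusoidal) vasomotion, heartbeat and
respiration artifacts, vessel curvature in 3-D, condition-dependent
response amplitudes (condition is a label only), and correlated activity
between vessels.

# Acceptance-check design

The end-to-end session check uses 8 vessel categories (PA0–PA3, C1–C4),
each one 600-s vessel per run over 100 seeded runs (20 trials per vessel),
with graded true response probabilities and vasomotion amplitudes separated
geometrically (factor ≈ 1.4) above the white-noise spectral floor so that
the per-category ranking of corrected 0.1 Hz power is identifiable from a
600-s recording. The session's vasomotion frequency is 0.1033 Hz — near
0.1 Hz but incommensurate with the 30-s trial grid (3.1 cycles per trial),
so the phase rotates uniformly across a session's trials instead of
repeating; it still falls in the 0.1 Hz bin's capture range. Pooled
classified response rates are compared, per category, against the expected
classification rate (true responders plus the rule's positive rate)
computed by an independent per-trial Monte-Carlo of the stated criterion,
within exact binomial 95% confidence intervals; the power ranking must
match the amplitude ranking in ≥ 95% of runs. Other checks run at the
sizes stated in their tests: 10,000 null trials for classifier calibration,
1800-s pink-noise traces for the 1/f-flattening identity, 600-s traces for
Parseval and amplitude-squared scaling, trees with 24 branch points for the
morphometry identities, and 2000-replicate null simulations for test
calibration.

# Known limitations

- FWHM diameters assume a roughly unimodal cross-section; overlapping
  vessels within the sampled normal bias the width (mitigated, not
  eliminated, by the first-crossing rule).
- Registration is integer-pixel and translation-only.
- The 0.5 × SD responsiveness criterion is threshold-calibrated, not a
  hypothesis test; rates depend on the noise spectrum (see above).
- Branch-point ISD conventions ("the pair spanning the bifurcation";
  "nearest non-branch neighbor" one soma away) are one reasonable reading
  of measurement practice; outputs record them so they can be audited.
- The generator's vasomotion is a single sinusoid; real vasomotion is
  narrowband noise, so spectral peak widths in real data will be broader
  than in simulation.
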