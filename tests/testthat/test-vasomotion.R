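test_that("rolling-percentile detrending removes drift and offsets", {
  fs <- 7.6
  # constant trace -> all zeros
  z <- detrendTrace(DiameterTrace(rep(8, 1000), fs))
  expect_equal(as.numeric(z), rep(0, 1000))

  # slow drift + 0.1 Hz sinusoid: drift removed, amplitude preserved to 10%
  t <- (0:(300 * fs - 1)) / fs
  x <- 8 + 0.005 * t + sin(2 * pi * 0.1 * t)
  d <- detrendTrace(DiameterTrace(x, fs))
  fit <- lm(d ~ sin(2 * pi * 0.1 * t) + cos(2 * pi * 0.1 * t))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(amp, 1, tolerance = 0.1)
  expect_lt(abs(coef(lm(d ~ t))[2]), 0.001)  # drift gone

  # step offset: output returns near 0 within one window after the step
  xs <- c(rep(8, 800), rep(10, 800))
  ds <- detrendTrace(DiameterTrace(xs, fs))
  after <- ds[(800 + round(15 * fs) + 1):1600]
  expect_lt(max(abs(after)), 0.01)

  expect_error(detrendTrace(DiameterTrace(rep(8, 50), fs)), "shorter")
})

test_that("Welch estimates conserve variance and concentrate sinusoid power", {
  fs <- 7.6
  set.seed(12)
  x <- rnorm(round(600 * fs))
  ps <- welchPSD(x, fs)
  df <- freqs(ps)[2] - freqs(ps)[1]
  expect_equal(df, 1 / 60, tolerance = 1e-9)
  expect_equal(sum(spectralPower(ps)) * df, var(x), tolerance = 0.1)
  # 0.1 Hz falls exactly on bin 6
  expect_equal(freqs(ps)[7], 0.1, tolerance = 1e-12)

  t <- (seq_along(x) - 1) / fs
  s <- sin(2 * pi * 0.1 * t)
  pss <- welchPSD(s, fs)
  i <- which.min(abs(freqs(pss) - 0.1))
  frac <- sum(spectralPower(pss)[(i - 1):(i + 1)]) / sum(spectralPower(pss))
  expect_gt(frac, 0.9)

  expect_error(welchPSD(rnorm(100), fs), "shorter")
})

test_that("1/f correction flattens c/f spectra and zeroes DC", {
  f <- seq(0, 3.8, by = 1 / 60)
  p <- c(0, 5 / f[-1])
  ps <- oneOverFCorrect(makePS(f, p))
  expect_equal(correctedPower(ps)[1], 0)
  expect_equal(correctedPower(ps)[-1], rep(5, length(f) - 1))
})

test_that("corrected spectra of generated pink noise are flat in log-log", {
  set.seed(4)
  fs <- 7.6
  x <- vasomorph:::pinkNoise(round(1800 * fs), 1)
  ps <- welchPSD(x, fs)
  f <- freqs(ps); pc <- correctedPower(ps)
  sel <- f >= 0.03 & f <= 1
  slope <- coef(lm(log(pc[sel]) ~ log(f[sel])))[2]
  expect_lt(abs(slope), 0.2)
})

test_that("vasomotion summaries scale as amplitude squared", {
  fs <- 7.6
  t <- (0:(600 * fs - 1)) / fs
  pow_at <- function(A) {
    x <- A * sin(2 * pi * 0.1 * t)
    summarizeVasomotion(welchPSD(x, fs))$power_at_target
  }
  expect_equal(pow_at(2) / pow_at(1), 4, tolerance = 0.01)
  z <- summarizeVasomotion(welchPSD(rep(0, length(t)), fs))
  expect_equal(z$power_at_target, 0)
  expect_equal(z$band_auc, 0)
  expect_error(summarizeVasomotion(welchPSD(rnorm(length(t)), fs),
                                   band = c(3, 5)), "Nyquist")
})

test_that("band AUC grows monotonically with vasomotion amplitude", {
  aucs <- vapply(c(0.1, 0.2, 0.4, 0.8), function(A) {
    p <- traceSimParams(duration_s = 600, dilation_amplitude_frac = 0,
                        vasomotion_amplitude_um = A, pink_noise_sd_um = 0.02,
                        white_noise_sd_um = 0.05, rng_seed = 8)
    sim <- makeDiameterTrace(p, makeStimulusSchedule(20))
    summarizeVasomotion(welchPSD(detrendTrace(sim$trace)))$band_auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("outlier spectra are removed by the 3-SD-of-maxima rule", {
  f <- seq(0, 3.8, by = 1 / 60)
  # spectrum whose corrected maximum over [0, 1] Hz is exactly m:
  # a single line at 1 Hz of density m
  line <- function(m) {
    p <- numeric(length(f)); p[which.min(abs(f - 1))] <- m
    makePS(f, p)
  }
  cohort <- c(lapply(rep(0.1, 19), line), list(line(5)))
  # corrected maxima: 19 x 0.1 and one 5 -> SD 1.0956
  out <- removeOutlierSpectra(cohort, f_max = 1, k = 3)
  expect_equal(sd(out$maxima), 1.0956, tolerance = 1e-3)
  expect_equal(out$removed, 20L)
  expect_equal(length(out$kept), 19)

  same <- removeOutlierSpectra(lapply(rep(1, 5), line), f_max = 1)
  expect_equal(length(same$removed), 0)
  one <- removeOutlierSpectra(list(line(1)))
  expect_equal(length(one$removed), 0)
})

test_that("high-power flags follow the 0.5-SD cohort threshold", {
  fl <- classifyHighPower(c(0, 0, 0, 10))
  expect_equal(which(fl), 4L)
  expect_false(any(classifyHighPower(rep(0, 5))))
  # linearity: flags invariant to common scaling of the cohort
  set.seed(9)
  p <- rexp(30)
  expect_identical(as.logical(classifyHighPower(p)),
                   as.logical(classifyHighPower(p * 123.4)))
})

test_that("power scales quadratically under trace scaling", {
  fs <- 7.6
  set.seed(10)
  x <- rnorm(round(300 * fs))
  p1 <- spectralPower(welchPSD(x, fs))
  p3 <- spectralPower(welchPSD(3 * x, fs))
  expect_equal(p3, 9 * p1, tolerance = 1e-9)
})

test_that("the corrected-power argmax identifies the vasomotion frequency", {
  for (f0 in c(0.07, 0.1, 0.13)) {
    p <- traceSimParams(duration_s = 600, dilation_amplitude_frac = 0,
                        vasomotion_freq_hz = f0,
                        vasomotion_amplitude_um = 0.4,
                        pink_noise_sd_um = 0.02, white_noise_sd_um = 0.05,
                        rng_seed = 21)
    sim <- makeDiameterTrace(p, makeStimulusSchedule(20))
    ps <- welchPSD(detrendTrace(sim$trace))
    f <- freqs(ps)
    band <- f > 0.05 & f < 0.15
    fmax <- f[band][which.max(correctedPower(ps)[band])]
    expect_lt(abs(fmax - f0), 1 / 60 + 1e-9)
  }
})
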