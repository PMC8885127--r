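locoFromRuns <- function(duration, rate, runs) {
  makeLocomotion(duration, rate,
                 bout_starts_s = vapply(runs, `[`, numeric(1), 1),
                 bout_durations_s = vapply(runs, function(r) r[2] - r[1],
                                           numeric(1)))
}

test_that("locomotion epochs merge close runs, then drop short ones", {
  expect_equal(nrow(detectLocomotionEpochs(
    makeLocomotion(5, 100))), 0)

  # runs [0, 0.2] and [0.5, 1.2]: gap 0.3 s < 1 s -> merged, kept
  ep <- detectLocomotionEpochs(locoFromRuns(3, 100,
                                            list(c(0, 0.2), c(0.5, 1.2))))
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_s, 0)
  expect_equal(ep$end_s, 1.2, tolerance = 0.011)

  # isolated 0.30-s run: 0.30 <= 1/3 -> discarded
  expect_equal(nrow(detectLocomotionEpochs(
    locoFromRuns(3, 100, list(c(1, 1.3))))), 0)
  # 0.35-s run: kept (> 1/3)
  expect_equal(nrow(detectLocomotionEpochs(
    locoFromRuns(3, 100, list(c(1, 1.35))))), 1)
})

test_that("trials are cut on the 30-s grid with nearest-frame mapping", {
  tr <- DiameterTrace(rep(8, round(90 * 7.6)), 7.6)
  ts <- segmentTrials(tr, makeStimulusSchedule(3))
  expect_equal(nrow(trialTable(ts)), 3)
  expect_equal(ncol(trialTraces(ts)), 228)  # round(30 * 7.6)

  # an event whose window would start before the trace is skipped
  sch_bad <- new("StimulusSchedule",
                 events = data.frame(onset_s = 3, offset_s = 8,
                                     condition = "stim"))
  expect_warning(ts2 <- segmentTrials(tr, sch_bad), "skipped")
  expect_equal(nrow(trialTable(ts2)), 0)

  # stimulus window is half-open [5, 10)
  tt <- trialTimes(ts)
  stim_idx <- which(tt >= 5 & tt < 10)
  expect_true(max(tt[stim_idx]) < 10)
  expect_equal(min(tt[stim_idx]), 5)
})

test_that("rest marking uses the closed [onset - 2, offset] exclusion window", {
  tr <- DiameterTrace(rep(8, round(40 * 7.6)), 7.6)
  ts <- segmentTrials(tr, makeStimulusSchedule(1))  # onset 5, offset 10
  rest <- function(epochs)
    trialTable(markRest(ts, epochs))$is_rest
  expect_true(rest(data.frame(start_s = 0, end_s = 0.5)))    # ends 2.5 s before
  expect_false(rest(data.frame(start_s = 4, end_s = 4.5)))   # inside [3, 10]
  expect_false(rest(data.frame(start_s = 2.5, end_s = 3)))   # touches endpoint
  expect_false(rest(data.frame(start_s = 10, end_s = 11)))   # touches offset
  expect_true(rest(data.frame(start_s = 10.5, end_s = 11)))  # after offset
})

test_that("range normalization maps the baseline extremes to 0 and 100", {
  n <- 228
  fs <- 7.6
  base_idx <- seq_len(sum((0:(n - 1)) / fs < 5))
  # one trial whose baseline contains the extremes 4 and 5
  v <- rep(4.5, n)
  v[base_idx[1]] <- 4; v[base_idx[2]] <- 5
  ts <- segmentTrials(DiameterTrace(rep(v, 2)[1:456], fs),
                      makeStimulusSchedule(1))
  nx <- normalizeTrials(ts, "range")
  X <- trialTraces(nx)
  expect_equal(X[1, base_idx[1]], 0)
  expect_equal(X[1, base_idx[2]], 100)
  expect_equal(X[1, base_idx[3]], 50)  # D = 4.5 between 4 and 5

  # mean mode: baseline mean 5, D = 5.25 -> 5.0
  v2 <- rep(5, n); v2[150] <- 5.25  # sample 150 is outside the baseline
  ts2 <- segmentTrials(DiameterTrace(rep(v2, 2)[1:456], fs),
                       makeStimulusSchedule(1))
  X2 <- trialTraces(normalizeTrials(ts2, "mean"))
  expect_equal(X2[1, 150], 5)

  # degenerate baseline flagged invalid
  flat <- segmentTrials(DiameterTrace(rep(8, 456), fs),
                        makeStimulusSchedule(1))
  expect_false(trialTable(normalizeTrials(flat, "range"))$norm_valid)
})

test_that("responsiveness uses a strict threshold on the baseline SD", {
  fs <- 7.6
  n <- 228
  tt <- (0:(n - 1)) / fs
  base <- rep(c(0, 20), length.out = sum(tt < 5))
  m <- mean(base); s <- sd(base)
  mk <- function(stim_value) {
    X <- matrix(rep(base, length.out = n), nrow = 1)
    X[1, tt >= 5 & tt < 10] <- stim_value
    trialSetFromMatrix(X, fs)
  }
  eps <- 1e-9
  below <- classifyResponsive(mk(m + 0.5 * s - eps))
  above <- classifyResponsive(mk(m + 0.5 * s + eps))
  expect_false(trialTable(below)$is_responsive)
  expect_true(trialTable(above)$is_responsive)
  # example ratio: SD ~10, excess 6 -> responsive (6 > 5)
  six <- classifyResponsive(mk(m + 6 * (s / 10)))
  expect_equal(trialTable(six)$is_responsive, 6 * (s / 10) > 0.5 * s)
})

test_that("adding stimulus-window signal never flips responsive to non-responsive", {
  fs <- 7.6; n <- 228
  tt <- (0:(n - 1)) / fs
  stim_idx <- tt >= 5 & tt < 10
  set.seed(31)
  for (i in 1:25) {
    X <- matrix(rnorm(n), nrow = 1)
    ts0 <- classifyResponsive(trialSetFromMatrix(X, fs))
    X2 <- X; X2[1, stim_idx] <- X2[1, stim_idx] + runif(1, 0, 5)
    ts1 <- classifyResponsive(trialSetFromMatrix(X2, fs))
    if (trialTable(ts0)$is_responsive)
      expect_true(trialTable(ts1)$is_responsive)
  }
})

test_that("response metrics: onset interpolation and the 10-s value", {
  fs <- 7.6; n <- 228
  tt <- (0:(n - 1)) / fs
  # linear ramp 0 -> 100 over [5, 10]
  X <- matrix(0, nrow = 1, ncol = n)
  ramp <- tt >= 5 & tt <= 10
  X[1, ramp] <- 20 * (tt[ramp] - 5)
  X[1, tt > 10] <- 0
  ts <- responseMetrics(classifyResponsive(trialSetFromMatrix(X, fs)))
  tab <- trialTable(ts)
  expect_equal(tab$onset_time_s, 5.5, tolerance = 0.05)
  expect_equal(tab$value_at_10s_pct, 100, tolerance = 1e-9)

  # flat 0 then step to 80 at t = 7
  Xs <- matrix(0, nrow = 1, ncol = n)
  Xs[1, tt >= 7] <- 80
  tabs <- trialTable(responseMetrics(classifyResponsive(
    trialSetFromMatrix(Xs, fs))))
  expect_equal(tabs$onset_time_s, 7, tolerance = 1 / fs)
  expect_equal(tabs$peak_stim_pct, 80)

  # peak 60 at t = 8, value 30 at t = 10
  Xp <- matrix(0, nrow = 1, ncol = n)
  Xp[1, tt >= 7.5 & tt < 8.5] <- 60
  Xp[1, tt >= 8.5] <- 30
  tabp <- trialTable(responseMetrics(classifyResponsive(
    trialSetFromMatrix(Xp, fs))))
  expect_equal(tabp$peak_stim_pct, 60)
  expect_equal(tabp$value_at_10s_pct, 30)
})

test_that("noisy-trial exclusion applies the 10x-mean-peak rule", {
  mk <- function(peaks) data.frame(peak_stim_pct = peaks,
                                   is_responsive = TRUE)
  # {5,6,7,100}: mean 29.5, threshold 295 -> none removed
  expect_false(any(removeNoisyTrials(mk(c(5, 6, 7, 100)))$excluded_noisy))
  # {5 x 9, 600}: mean 64.5 -> none
  expect_false(any(removeNoisyTrials(mk(c(rep(5, 9), 600)))$excluded_noisy))
  # {5 x 19, 2000}: mean 104.75, threshold 1047.5 -> the 2000 removed
  out <- removeNoisyTrials(mk(c(rep(5, 19), 2000)))
  expect_equal(which(out$excluded_noisy), 20L)
  # all equal -> none
  expect_false(any(removeNoisyTrials(mk(rep(7, 5)))$excluded_noisy))
  # no responsive trials -> no-op
  t0 <- data.frame(peak_stim_pct = c(1, 2), is_responsive = FALSE)
  expect_false(any(removeNoisyTrials(t0)$excluded_noisy))
})

test_that("vessel summaries count rest trials and average peaks", {
  tab <- data.frame(
    vessel_id = "v1", is_rest = TRUE, norm_valid = TRUE,
    is_responsive = c(TRUE, FALSE, FALSE, FALSE),
    peak_stim_pct = c(10, 2, 3, 1))
  s <- vesselSummary(tab)
  expect_equal(s$response_rate_pct, 25)
  expect_equal(s$peak_all_pct, 4)
  expect_equal(s$peak_responsive_pct, 10)

  tab2 <- tab; tab2$is_responsive <- TRUE
  s2 <- vesselSummary(tab2)
  expect_equal(s2$response_rate_pct, 100)
  expect_equal(s2$peak_all_pct, s2$peak_responsive_pct)

  # vessel without rest trials omitted with a warning
  tab3 <- rbind(tab, within(tab, { vessel_id <- "v2"; is_rest <- FALSE }))
  expect_warning(s3 <- vesselSummary(tab3), "v2")
  expect_equal(s3$vessel_id, "v1")
})

test_that("rest and responsive flags conserve counts end-to-end", {
  sch <- makeStimulusSchedule(10)
  p <- traceSimParams(duration_s = 300, rng_seed = 3)
  sim <- makeDiameterTrace(p, sch)
  loco <- makeLocomotion(300, 100, bout_starts_s = c(33, 100, 250),
                         bout_durations_s = c(2, 1, 5))
  tab <- runTrialPipeline(sim$trace, sch, loco)
  expect_equal(sum(tab$is_rest) + sum(!tab$is_rest), nrow(tab))
  # trial 2 (onset 35 s) overlaps the 33-35 s bout
  expect_false(tab$is_rest[2])
  expect_true(all(tab$norm_valid))
})
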