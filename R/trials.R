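#' Detect locomotion epochs from an encoder trace
#'
#' Samples whose absolute displacement exceeds `move_threshold` form
#' candidate runs; runs separated by less than `min_gap_s` are merged into
#' one epoch (epochs are by definition at least `min_gap_s` apart), and
#' merged runs lasting `min_duration_s` or less are discarded.
#'
#' @param loco a [LocomotionTrace-class].
#' @param move_threshold displacement magnitude that counts as movement;
#'   the default 0 treats any nonzero displacement as movement.
#' @param min_duration_s minimum epoch duration, seconds (strict; default
#'   1/3 s).
#' @param min_gap_s runs closer than this are merged, seconds (default 1).
#' @return data.frame with columns `start_s`, `end_s` (one row per epoch).
#' @export
detectLocomotionEpochs <- function(loco, move_threshold = 0,
                                   min_duration_s = 1 / 3, min_gap_s = 1) {
  t <- loco@timeS
  if (length(t) == 0) return(data.frame(start_s = numeric(), end_s = numeric()))
  dt <- if (length(t) > 1) stats::median(diff(t)) else 0
  moving <- abs(loco@displacement) > move_threshold
  if (!any(moving)) return(data.frame(start_s = numeric(), end_s = numeric()))
  r <- rle(moving)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- data.frame(start_s = t[starts_i[r$values]],
                     end_s = t[ends_i[r$values]] + dt)
  # merge runs separated by < min_gap_s, then apply the duration filter
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start_s[i] - merged$end_s[nrow(merged)] < min_gap_s) {
      merged$end_s[nrow(merged)] <- runs$end_s[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  keep <- (merged$end_s - merged$start_s) > min_duration_s
  out <- merged[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cut a diameter trace into stimulus-locked trials
#'
#' One trial per stimulus event: the window starts `stim_window[1]` seconds
#' before stimulus onset and lasts `trial_length_s`; sample times are mapped
#' to the nearest frames. Events whose window falls outside the trace are
#' skipped with a warning. Within a trial the stimulus occupies
#' `stim_window[1] <= t < stim_window[2]` (half-open convention).
#'
#' @param trace a [DiameterTrace-class].
#' @param schedule a [StimulusSchedule-class] in the trace's time base.
#' @param trial_length_s trial window length, seconds (default 30).
#' @param stim_window stimulus onset/offset within the trial, seconds
#'   (default `c(5, 10)`).
#' @return A [TrialSet-class] with raw (un-normalized) traces and a trial
#'   table holding `trial`, `condition`, `onset_s`, `offset_s`.
#' @export
segmentTrials <- function(trace, schedule, trial_length_s = 30,
                          stim_window = c(5, 10)) {
  fs <- frameRate(trace)
  v <- diameterValues(trace)
  ev <- stimulusEvents(schedule)
  n_samp <- round(trial_length_s * fs)
  rows <- list(); mats <- list()
  for (i in seq_len(nrow(ev))) {
    start_t <- ev$onset_s[i] - stim_window[1]
    start_idx <- round(start_t * fs) + 1L
    if (start_idx < 1L || start_idx + n_samp - 1L > length(v)) {
      warning("trial ", i, " window [", start_t, ", ",
              start_t + trial_length_s, "] s outside trace; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      trial = i, condition = ev$condition[i],
      onset_s = ev$onset_s[i], offset_s = ev$offset_s[i],
      stringsAsFactors = FALSE)
    mats[[length(mats) + 1L]] <- v[start_idx:(start_idx + n_samp - 1L)]
  }
  trials <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial = integer(), condition = character(),
               onset_s = numeric(), offset_s = numeric())
  traces <- if (length(mats)) do.call(rbind, mats) else
    matrix(numeric(), nrow = 0, ncol = n_samp)
  new("TrialSet", trials = trials, traces = traces,
      timeS = (seq_len(n_samp) - 1) / fs, frameRateHz = fs,
      normMode = "none", stimWindow = as.numeric(stim_window),
      vesselMeta = vesselMeta(trace))
}

#' Flag rest trials using locomotion epochs
#'
#' A trial is a rest trial if no locomotion epoch intersects the closed
#' interval from 2 s before stimulus onset to stimulus offset (no
#' significant locomotion in the 2 s prior to or during the stimulus). An
#' epoch exactly touching either endpoint disqualifies the trial.
#'
#' @param trialset a [TrialSet-class].
#' @param epochs data.frame from [detectLocomotionEpochs()] in the same
#'   absolute time base as the stimulus schedule.
#' @param pre_s seconds before stimulus onset that must be locomotion-free.
#' @return The [TrialSet-class] with an `is_rest` column.
#' @export
markRest <- function(trialset, epochs, pre_s = 2) {
  tr <- trialTable(trialset)
  a <- tr$onset_s - pre_s
  b <- tr$offset_s
  tr$is_rest <- vapply(seq_len(nrow(tr)), function(i) {
    if (nrow(epochs) == 0) return(TRUE)
    !any(epochs$start_s <= b[i] & epochs$end_s >= a[i])
  }, logical(1))
  methods::initialize(trialset, trials = tr)
}

#' Normalize trials to their pre-stimulus baseline
#'
#' Default `"range"` mode applies
#' `100 * (D - Dmin) / (Dmax - Dmin)` with `Dmin`/`Dmax` taken over the 5-s
#' baseline (samples before stimulus onset), so the baseline minimum maps
#' to 0 and the baseline maximum to 100. `"mean"` mode applies the
#' fractional change `100 * (D - mean_baseline) / mean_baseline`. The SD of
#' the normalized baseline is stored per trial as `baseline_sd_pct`; trials
#' whose baseline has zero range (or zero mean) are flagged invalid.
#'
#' @param trialset a [TrialSet-class] from [segmentTrials()].
#' @param mode `"range"` (the printed formula) or `"mean"`.
#' @return The [TrialSet-class] with normalized traces and columns
#'   `norm_valid`, `baseline_mean_pct`, `baseline_sd_pct`.
#' @export
normalizeTrials <- function(trialset, mode = c("range", "mean")) {
  mode <- match.arg(mode)
  tr <- trialTable(trialset)
  X <- trialTraces(trialset)
  base_idx <- which(trialset@timeS < trialset@stimWindow[1])
  if (!length(base_idx)) stop("empty baseline segment")
  norm_valid <- logical(nrow(tr))
  base_mean <- base_sd <- rep(NA_real_, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    b <- X[i, base_idx]
    if (mode == "range") {
      dmin <- min(b); dmax <- max(b)
      if (dmax > dmin) {
        X[i, ] <- 100 * (X[i, ] - dmin) / (dmax - dmin)
        norm_valid[i] <- TRUE
      }
    } else {
      mb <- mean(b)
      if (mb != 0) {
        X[i, ] <- 100 * (X[i, ] - mb) / mb
        norm_valid[i] <- TRUE
      }
    }
    if (norm_valid[i]) {
      base_mean[i] <- mean(X[i, base_idx])
      base_sd[i] <- stats::sd(X[i, base_idx])
    }
  }
  tr$norm_valid <- norm_valid
  tr$baseline_mean_pct <- base_mean
  tr$baseline_sd_pct <- base_sd
  methods::initialize(trialset, trials = tr, traces = X, normMode = mode)
}

#' Classify trials as responsive to the stimulus
#'
#' A trial is responsive when the maximum dilation during the stimulus
#' window, measured as the excess of the stimulus-window maximum over the
#' baseline mean of the normalized trace, strictly exceeds
#' `k` times the SD of the 5-s normalized baseline.
#'
#' @param trialset a normalized [TrialSet-class].
#' @param k threshold multiplier on the baseline SD (default 0.5).
#' @return The [TrialSet-class] with columns `peak_stim_pct` (the
#'   stimulus-window maximum of the normalized trace), `peak_excess_pct`
#'   (that maximum minus the baseline mean) and `is_responsive`.
#' @export
classifyResponsive <- function(trialset, k = 0.5) {
  if (trialset@normMode == "none")
    stop("normalize trials before classifying responsiveness")
  tr <- trialTable(trialset)
  X <- trialTraces(trialset)
  w <- trialset@stimWindow
  stim_idx <- which(trialset@timeS >= w[1] & trialset@timeS < w[2])
  peak <- excess <- rep(NA_real_, nrow(tr))
  resp <- rep(NA, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    if (!tr$norm_valid[i]) next
    peak[i] <- max(X[i, stim_idx])
    excess[i] <- peak[i] - tr$baseline_mean_pct[i]
    resp[i] <- excess[i] > k * tr$baseline_sd_pct[i]
  }
  tr$peak_stim_pct <- peak
  tr$peak_excess_pct <- excess
  tr$is_responsive <- resp
  methods::initialize(trialset, trials = tr)
}

#' Compute response timing and magnitude metrics per trial
#'
#' For every valid trial: the stimulus-window peak (already stored by
#' [classifyResponsive()]), the value of the normalized trace at the
#' stimulus cessation (the sample nearest t = 10 s), and the onset time of
#' the dilation: the first time at or after stimulus onset at which the
#' trace reaches 10\% of the peak (measured above the baseline mean), with
#' linear interpolation between frames. Metrics are computed for
#' non-responsive trials too; `is_responsive` flags which to trust.
#'
#' @param trialset a classified [TrialSet-class].
#' @return The [TrialSet-class] with columns `value_at_10s_pct` and
#'   `onset_time_s`.
#' @export
responseMetrics <- function(trialset) {
  tr <- trialTable(trialset)
  if (is.null(tr$peak_stim_pct))
    stop("run classifyResponsive() before responseMetrics()")
  X <- trialTraces(trialset)
  tt <- trialset@timeS
  w <- trialset@stimWindow
  stim_idx <- which(tt >= w[1] & tt <= w[2])
  cess_idx <- which.min(abs(tt - w[2]))
  v10 <- onset <- rep(NA_real_, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    if (!tr$norm_valid[i]) next
    v10[i] <- X[i, cess_idx]
    level <- tr$baseline_mean_pct[i] +
      0.1 * (tr$peak_stim_pct[i] - tr$baseline_mean_pct[i])
    y <- X[i, ]
    if (y[stim_idx[1]] >= level) {
      onset[i] <- tt[stim_idx[1]]
    } else {
      cross <- firstCrossing(y, level, stim_idx)
      if (!is.na(cross)) {
        j0 <- floor(cross); frac <- cross - j0
        onset[i] <- tt[j0] + frac * (tt[min(j0 + 1, length(tt))] - tt[j0])
      }
    }
  }
  tr$value_at_10s_pct <- v10
  tr$onset_time_s <- onset
  methods::initialize(trialset, trials = tr)
}

#' Exclude noisy trials by the 10x-mean-peak rule
#'
#' Computes the mean stimulus-window peak across all responsive trials in
#' the table (the whole dataset, not per vessel) and flags responsive trials
#' whose peak exceeds `factor` times that mean as `excluded_noisy`. With no
#' responsive trials the table is returned unchanged (all flags FALSE).
#'
#' @param trial_table data.frame of trials (rows from one or more vessels)
#'   with columns `peak_stim_pct` and `is_responsive`.
#' @param factor exclusion multiplier (default 10).
#' @return The table with an `excluded_noisy` column.
#' @export
removeNoisyTrials <- function(trial_table, factor = 10) {
  resp <- trial_table$is_responsive %in% TRUE
  trial_table$excluded_noisy <- FALSE
  if (!any(resp)) return(trial_table)
  m <- mean(trial_table$peak_stim_pct[resp])
  trial_table$excluded_noisy <- resp & trial_table$peak_stim_pct > factor * m
  trial_table
}

#' Per-vessel response summary
#'
#' Summarizes rest trials per vessel: the response rate (percentage of rest
#' trials classified responsive) and mean stimulus-window peaks over all
#' rest trials ("All") and over responsive rest trials only ("R"), after
#' dropping noisy-flagged trials. Vessels without rest trials are omitted
#' with a warning.
#'
#' @param trial_table data.frame of trials with columns `vessel_id`,
#'   `is_rest`, `is_responsive`, `peak_stim_pct` and (optionally)
#'   `excluded_noisy`, `category`, `branch_order`.
#' @return data.frame, one row per vessel: `vessel_id`, `n_rest`,
#'   `n_responsive`, `response_rate_pct`, `peak_all_pct`,
#'   `peak_responsive_pct` (plus carried category/branch order).
#' @export
vesselSummary <- function(trial_table) {
  if (is.null(trial_table$excluded_noisy)) trial_table$excluded_noisy <- FALSE
  keep <- trial_table$is_rest & !trial_table$excluded_noisy &
    trial_table$norm_valid %in% c(TRUE, NA)
  out <- lapply(split(trial_table[keep, , drop = FALSE],
                      trial_table$vessel_id[keep]), function(d) {
    n_rest <- nrow(d)
    n_resp <- sum(d$is_responsive %in% TRUE)
    data.frame(
      vessel_id = d$vessel_id[1],
      category = if ("category" %in% names(d)) d$category[1] else NA,
      branch_order = if ("branch_order" %in% names(d)) d$branch_order[1] else NA,
      n_rest = n_rest, n_responsive = n_resp,
      response_rate_pct = 100 * n_resp / n_rest,
      peak_all_pct = mean(d$peak_stim_pct, na.rm = TRUE),
      peak_responsive_pct = if (n_resp)
        mean(d$peak_stim_pct[d$is_responsive %in% TRUE]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  omitted <- setdiff(unique(trial_table$vessel_id), names(out))
  if (length(omitted))
    warning("vessels without rest trials omitted: ",
            paste(omitted, collapse = ", "))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full trial pipeline for one vessel
#'
#' Convenience wrapper: segment, mark rest (using locomotion epochs if a
#' trace is given), normalize, classify and compute metrics, returning the
#' annotated trial table with vessel metadata columns attached.
#'
#' @param trace a [DiameterTrace-class].
#' @param schedule a [StimulusSchedule-class].
#' @param loco optional [LocomotionTrace-class].
#' @param norm_mode `"range"` or `"mean"`.
#' @param k responsiveness threshold multiplier.
#' @param move_threshold passed to [detectLocomotionEpochs()].
#' @return data.frame: one row per trial with all flags and metrics.
#' @export
runTrialPipeline <- function(trace, schedule, loco = NULL,
                             norm_mode = c("range", "mean"), k = 0.5,
                             move_threshold = 0) {
  norm_mode <- match.arg(norm_mode)
  ts <- segmentTrials(trace, schedule)
  epochs <- if (is.null(loco))
    data.frame(start_s = numeric(), end_s = numeric())
  else detectLocomotionEpochs(loco, move_threshold = move_threshold)
  ts <- markRest(ts, epochs)
  ts <- normalizeTrials(ts, mode = norm_mode)
  ts <- classifyResponsive(ts, k = k)
  ts <- responseMetrics(ts)
  tab <- trialTable(ts)
  vm <- vesselMeta(trace)
  tab$vessel_id <- vm@vesselId
  tab$category <- vm@category
  tab$branch_order <- vm@branchOrder
  tab$norm_mode <- norm_mode
  tab
}
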