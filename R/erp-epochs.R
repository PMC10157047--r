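# Epoch-level operations: segmentation, baseline correction, artifact
# rejection, averaging. An `epoch_set` holds the trials of one
# (participant, condition, channel) cell as a trials x samples matrix in uV,
# with a ms time axis relative to stimulus onset and per-trial kept flags.

new_epoch_set <- function(participant_id, condition, channel, data, time_ms,
                          fs, kept = rep(TRUE, nrow(data)),
                          dropped = integer(0)) {
  structure(list(participant_id = participant_id, condition = condition,
                 channel = channel, data = data, time_ms = time_ms, fs = fs,
                 kept = kept, dropped = dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s %s/%s: %d trials (%d kept) x %d samples, [%g, %g) ms\n",
              x$participant_id, x$condition, x$channel, nrow(x$data),
              sum(x$kept), ncol(x$data), x$time_ms[1],
              x$time_ms[length(x$time_ms)] + 1000 / x$fs))
  invisible(x)
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Extracts, for every requested channel and condition, the window
#' `[window[1], window[2])` ms around each event onset (onset sample = t = 0,
#' belonging to the post-stimulus side). Trials whose window would run off
#' either end of the record are dropped and logged.
#'
#' @param recording a `raw_recording`.
#' @param window length-2 numeric, epoch window in ms (half-open).
#' @param channels channels to epoch (default: all channels in the recording).
#' @param conditions conditions to keep (default: all present).
#' @return nested list `epochs[[channel]][[condition]]` of `epoch_set`s.
#' @export
segment_epochs <- function(recording, window = c(-200, 600), channels = NULL,
                           conditions = NULL) {
  stopifnot(inherits(recording, "raw_recording"))
  channels <- channels %||% recording$channels
  assert_that_(all(channels %in% recording$channels), "unknown channel requested")
  conditions <- conditions %||% unique(recording$events$condition)
  fs <- recording$fs
  time_ms <- epoch_time_ms(fs, window)
  offsets <- round(time_ms / (1000 / fs))        # sample offsets from onset
  n_samples <- ncol(recording$signal)
  out <- list()
  for (ch in channels) {
    out[[ch]] <- list()
    for (cond in conditions) {
      onsets <- recording$events$onset_sample[recording$events$condition == cond]
      ok <- onsets + offsets[1] >= 1 & onsets + offsets[length(offsets)] <= n_samples
      dropped <- which(!ok)
      if (length(dropped))
        message(sprintf("%s %s/%s: dropped %d boundary trial(s)",
                        recording$participant_id, cond, ch, length(dropped)))
      onsets <- onsets[ok]
      idx <- rep(onsets, each = length(offsets)) + rep(offsets, length(onsets))
      data <- matrix(recording$signal[ch, idx], nrow = length(onsets),
                     ncol = length(offsets), byrow = TRUE)
      out[[ch]][[cond]] <- new_epoch_set(recording$participant_id, cond, ch,
                                         data, time_ms, fs, dropped = dropped)
    }
  }
  out
}

#' Subtract the pre-stimulus baseline from every epoch
#'
#' The mean over `baseline_window` (default the full 200 ms pre-stimulus
#' interval) is removed from each trial, so the baseline mean of every
#' corrected epoch is zero to float precision. Idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param baseline_window length-2 numeric, ms, half-open, inside the epoch.
#' @return corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline_window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$time_ms >= baseline_window[1] & epochs$time_ms < baseline_window[2]
  assert_that_(any(sel), "baseline window contains no samples")
  bl <- rowMeans(epochs$data[, sel, drop = FALSE])
  epochs$data <- epochs$data - bl
  epochs
}

#' Flag blink/movement trials by peak-to-peak threshold
#'
#' A trial is rejected when its peak-to-peak amplitude on the scalp channel or
#' on any supplied EOG channel exceeds `threshold`. A deterministic stand-in
#' for visual inspection/ICA cleaning; trials are flagged, not removed, so the
#' ledger of scheduled trials stays intact.
#'
#' @param epochs scalp-channel `epoch_set`.
#' @param eog list of `epoch_set`s for the EOG channels, trial-aligned with
#'   `epochs` (may be empty).
#' @param threshold rejection threshold in µV (default 100).
#' @return `epochs` with updated `kept` flags.
#' @export
reject_artifact_epochs <- function(epochs, eog = list(), threshold = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- nrow(epochs$data)
  for (e in eog) {
    stopifnot(inherits(e, "epoch_set"))
    assert_that_(nrow(e$data) == n,
                 "EOG epochs not trial-aligned with scalp epochs")
  }
  p2p <- apply(epochs$data, 1, peak_to_peak)
  bad <- p2p > threshold
  for (e in eog) bad <- bad | apply(e$data, 1, peak_to_peak) > threshold
  epochs$kept <- epochs$kept & !bad
  epochs
}

new_erp_waveform <- function(condition, channel, mean, se, n, time_ms, fs,
                             participant_id = NULL) {
  structure(list(participant_id = participant_id, condition = condition,
                 channel = channel, mean = mean, se = se, n_trials = n,
                 time_ms = time_ms, fs = fs),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %s/%s over %d trial(s)/participant(s)\n",
              x$condition, x$channel, x$n_trials))
  invisible(x)
}

#' Average the kept epochs of one condition
#'
#' @param epochs a baseline-corrected `epoch_set`.
#' @param min_trials minimum number of kept trials required (default 20).
#' @return an `erp_waveform` with pointwise mean and standard error
#'   (sd / sqrt(n); `NA` when only one trial is kept).
#' @export
average_condition <- function(epochs, min_trials = 20) {
  stopifnot(inherits(epochs, "epoch_set"))
  kept <- epochs$data[epochs$kept, , drop = FALSE]
  n <- nrow(kept)
  if (n < min_trials)
    stop(errorCondition(
      sprintf("insufficient trials for %s %s/%s: %d kept < %d required",
              epochs$participant_id, epochs$condition, epochs$channel, n,
              min_trials),
      class = c("erpselect_insufficient_trials", "error")))
  m <- colMeans(kept)
  se <- if (n > 1) apply(kept, 2, stats::sd) / sqrt(n) else rep(NA_real_, ncol(kept))
  new_erp_waveform(epochs$condition, epochs$channel, m, se, n,
                   epochs$time_ms, epochs$fs,
                   participant_id = epochs$participant_id)
}

#' Grand average across participants
#'
#' @param waveforms list of `erp_waveform`s sharing condition, channel and
#'   time axis (one per participant).
#' @return an `erp_waveform` whose mean and SE are taken across participants.
#' @export
grand_average <- function(waveforms) {
  assert_that_(length(waveforms) >= 1, "no waveforms supplied")
  w1 <- waveforms[[1]]
  for (w in waveforms) {
    stopifnot(inherits(w, "erp_waveform"))
    assert_that_(identical(w$condition, w1$condition) &&
                   identical(w$channel, w1$channel) &&
                   isTRUE(all.equal(w$time_ms, w1$time_ms)),
                 "waveforms differ in condition, channel or time axis")
  }
  mat <- do.call(rbind, lapply(waveforms, `[[`, "mean"))
  n <- nrow(mat)
  se <- if (n > 1) apply(mat, 2, stats::sd) / sqrt(n) else rep(NA_real_, ncol(mat))
  new_erp_waveform(w1$condition, w1$channel, colMeans(mat), se, n,
                   w1$time_ms, w1$fs)
}
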