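#' ERP pipeline parameters
#'
#' Tunables of the measurement chain with their defaults: the 1–20 Hz
#' band-pass (order 4), the −200..600 ms epoch and −200..0 ms baseline
#' windows, the N170/P200 peak-search windows ([120, 220) and [150, 300) ms),
#' a 1 µV identifiability floor, the 100 µV peak-to-peak rejection threshold
#' and a 20 kept-trial minimum per average.
#'
#' @param filter_band,filter_order band edges (Hz) and magnitude order.
#' @param epoch_window,baseline_window half-open ms windows.
#' @param peak_windows named list of half-open ms search windows per component.
#' @param prominence_min minimum |extremum| in µV for a peak to count as
#'   identified.
#' @param reject_threshold peak-to-peak rejection threshold, µV.
#' @param min_trials minimum kept trials per condition average.
#' @param electrodes scalp channels entering the statistics.
#' @return a list of class `erp_params`.
#' @export
erp_params <- function(filter_band = c(1, 20), filter_order = 4,
                       epoch_window = c(-200, 600),
                       baseline_window = c(-200, 0),
                       peak_windows = list(N170 = c(120, 220),
                                           P200 = c(150, 300)),
                       prominence_min = 1, reject_threshold = 100,
                       min_trials = 20, electrodes = c("T5", "T6")) {
  structure(list(filter_band = filter_band, filter_order = filter_order,
                 epoch_window = epoch_window,
                 baseline_window = baseline_window,
                 peak_windows = peak_windows,
                 prominence_min = prominence_min,
                 reject_threshold = reject_threshold,
                 min_trials = min_trials, electrodes = electrodes),
            class = "erp_params")
}

#' Locate one ERP component in an averaged waveform
#'
#' The N170 is the sample of minimum value inside its search window; the P200
#' is the sample of maximum value inside its window, restricted to times
#' strictly after an already-identified N170 (pass its latency as `after_ms`).
#' A component is `identified` only when the extremum has the component's
#' polarity with `|value| >= prominence_min` and sits strictly inside the
#' window (an edge extremum means the true peak may lie outside).
#'
#' @param waveform an `erp_waveform`.
#' @param component `"N170"` or `"P200"`.
#' @param window half-open ms search window (defaults to [erp_params()]'s).
#' @param prominence_min identifiability floor, µV.
#' @param after_ms if non-`NULL`, restrict the search to `time > after_ms`.
#' @return a `peak_measure`: list with `component`, `channel`, `condition`,
#'   `latency_ms`, `amplitude`, `identified`.
#' @export
detect_component_peak <- function(waveform, component = c("N170", "P200"),
                                  window = NULL, prominence_min = 1,
                                  after_ms = NULL) {
  stopifnot(inherits(waveform, "erp_waveform"))
  component <- match.arg(component)
  window <- window %||% erp_params()$peak_windows[[component]]
  t <- waveform$time_ms
  assert_that_(window[1] >= t[1] && window[2] <= t[length(t)] + 1000 / waveform$fs,
               "search window outside the epoch time axis")
  sel <- t >= window[1] & t < window[2]
  if (!is.null(after_ms)) sel <- sel & t > after_ms
  idx <- which(sel)
  negative <- component == "N170"
  vals <- waveform$mean[idx]
  pos <- if (negative) which.min(vals) else which.max(vals)
  amp <- vals[pos]
  lat <- t[idx[pos]]
  interior <- pos > 1 && pos < length(vals)
  right_sign <- if (negative) amp < 0 else amp > 0
  identified <- interior && right_sign && abs(amp) >= prominence_min
  structure(list(component = component, channel = waveform$channel,
                 condition = waveform$condition, latency_ms = lat,
                 amplitude = amp, identified = identified),
            class = "peak_measure")
}

#' @export
print.peak_measure <- function(x, ...) {
  cat(sprintf("<peak_measure> %s %s/%s: %s (%.0f ms, %.2f uV)\n",
              x$component, x$condition, x$channel,
              if (x$identified) "identified" else "NOT identified",
              x$latency_ms, x$amplitude))
  invisible(x)
}

# Measure both components of one waveform, honouring the post-N170 constraint
# on the P200.
measure_components <- function(waveform, params = erp_params()) {
  n170 <- detect_component_peak(waveform, "N170",
                                window = params$peak_windows$N170,
                                prominence_min = params$prominence_min)
  p200 <- detect_component_peak(waveform, "P200",
                                window = params$peak_windows$P200,
                                prominence_min = params$prominence_min,
                                after_ms = if (n170$identified) n170$latency_ms)
  list(N170 = n170, P200 = p200)
}

#' Run the measurement chain for one participant
#'
#' Band-pass filters the scalp channels, epochs all requested channels,
#' baseline-corrects, flags artifact trials from the (unfiltered) EOG and the
#' scalp channel itself, and averages the kept trials per condition.
#'
#' @param recording a `raw_recording`.
#' @param params an [erp_params()].
#' @param conditions conditions to average.
#' @return list with `waveforms[[electrode]][[condition]]` (`erp_waveform`),
#'   `kept_counts` (per electrode × condition) and `errors` (conditions whose
#'   average failed, with messages).
#' @export
process_participant <- function(recording, params = erp_params(),
                                conditions = c("AW", "RW", "ST")) {
  stopifnot(inherits(recording, "raw_recording"))
  filt <- recording
  # Only channels that are epoched downstream need filtering.
  scalp <- intersect(intersect(scalp_channels(), params$electrodes),
                     recording$channels)
  assert_that_(length(scalp) > 0, "no analyzed electrode present in recording")
  filt$signal[scalp, ] <- bandpass_filter(recording$signal[scalp, , drop = FALSE],
                                          recording$fs,
                                          params$filter_band[1],
                                          params$filter_band[2],
                                          params$filter_order)
  eog_present <- intersect(eog_channels(), recording$channels)
  eps <- segment_epochs(filt, params$epoch_window,
                        channels = params$electrodes, conditions = conditions)
  eog_eps <- if (length(eog_present))
    segment_epochs(recording, params$epoch_window, channels = eog_present,
                   conditions = conditions) else list()
  waveforms <- list(); kept <- list(); errors <- list()
  for (el in params$electrodes) {
    waveforms[[el]] <- list()
    for (cond in conditions) {
      ep <- baseline_correct(eps[[el]][[cond]], params$baseline_window)
      eog_list <- lapply(eog_present, function(ch) eog_eps[[ch]][[cond]])
      ep <- reject_artifact_epochs(ep, eog_list, params$reject_threshold)
      kept[[el]][[cond]] <- sum(ep$kept)
      wf <- tryCatch(average_condition(ep, params$min_trials),
                     erpselect_insufficient_trials = function(e) e)
      if (inherits(wf, "error")) {
        errors[[paste(el, cond, sep = "_")]] <- conditionMessage(wf)
      } else {
        waveforms[[el]][[cond]] <- wf
      }
    }
  }
  list(waveforms = waveforms, kept_counts = kept, errors = errors)
}

#' Assemble the per-electrode feature tables
#'
#' For each electrode a participant is retained only when all four component
#' peaks (N170 and P200, in AW and RW) are identified there; retained rows
#' carry the eight indicators `<electrode>_<component>_<condition>_<latency|
#' amplitude>`. Retention is decided per electrode independently; exclusions
#' are logged with reasons.
#'
#' @param participants data frame with `id` and `satq`.
#' @param waveforms named list: `waveforms[[id]][[electrode]][[condition]]`,
#'   as produced by [process_participant()].
#' @param electrodes electrodes to score.
#' @param params an [erp_params()].
#' @return list with `tables` (one complete data frame per electrode) and
#'   `exclusions` (data frame `id`, `electrode`, `reason`).
#' @export
extract_feature_table <- function(participants, waveforms,
                                  electrodes = c("T5", "T6"),
                                  params = erp_params()) {
  stopifnot(all(c("id", "satq") %in% names(participants)))
  tables <- list(); excl <- list()
  for (el in electrodes) {
    rows <- list()
    for (i in seq_len(nrow(participants))) {
      id <- participants$id[i]
      wfs <- waveforms[[id]][[el]]
      missing_conds <- setdiff(c("AW", "RW"), names(wfs))
      if (length(missing_conds)) {
        excl[[length(excl) + 1L]] <- data.frame(
          id = id, electrode = el,
          reason = paste("no average for", paste(missing_conds, collapse = ", ")),
          stringsAsFactors = FALSE)
        next
      }
      meas <- lapply(wfs[c("AW", "RW")], measure_components, params = params)
      flags <- unlist(lapply(meas, function(m)
        c(m$N170$identified, m$P200$identified)))
      if (!all(flags)) {
        bad <- c(outer(c("N170", "P200"), c("AW", "RW"), paste))[!flags]
        excl[[length(excl) + 1L]] <- data.frame(
          id = id, electrode = el,
          reason = paste("unidentified:", paste(bad, collapse = ", ")),
          stringsAsFactors = FALSE)
        next
      }
      vals <- list(id = id, satq = participants$satq[i])
      for (cond in c("AW", "RW")) {
        for (comp in c("N170", "P200")) {
          m <- meas[[cond]][[comp]]
          vals[[paste(el, comp, cond, "latency", sep = "_")]] <- m$latency_ms
          vals[[paste(el, comp, cond, "amplitude", sep = "_")]] <- m$amplitude
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(vals, stringsAsFactors = FALSE)
    }
    tables[[el]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = character(0), satq = numeric(0))
  }
  if (all(vapply(tables, nrow, 0L) == 0L))
    stop("no participant retained at any electrode")
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(0), electrode = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(tables = tables, exclusions = exclusions)
}
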