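#' Draw integer trait scores from a truncated, rounded normal
#'
#' Scores are drawn from `N(mean, sd)`, rounded to the nearest integer and
#' redrawn while outside `[lo, hi]` (truncation by rejection), mirroring a
#' questionnaire total that is a bounded sum of Likert items.
#'
#' @param n number of participants.
#' @param mean,sd distribution parameters on the score scale.
#' @param lo,hi inclusive score bounds, `lo < hi`.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return integer vector of length `n`, each element in `[lo, hi]`.
#' @examples
#' generate_trait_scores(5, 27.77, 8.02, 0, 72, seed = 1)
#' @export
generate_trait_scores <- function(n, mean, sd, lo, hi, seed = NULL) {
  assert_that_(is_count(n), "n must be a positive integer")
  assert_that_(lo < hi, "trait bounds must satisfy lo < hi")
  assert_that_(sd >= 0, "sd must be >= 0")
  with_seed_(seed, {
    out <- integer(0)
    while (length(out) < n) {
      draw <- round(rnorm(n - length(out), mean, sd))
      out <- c(out, draw[draw >= lo & draw <= hi])
      if (sd == 0 && length(out) == 0)
        abort_input("degenerate sampler: round(mean) outside bounds")
    }
    as.integer(out[seq_len(n)])
  })
}

#' Build a randomized trial schedule
#'
#' Lays out `n_sets` sets of `set_size` trials. Within each set the condition
#' labels follow `condition_ratio` exactly and are shuffled uniformly. Trial k
#' occupies `still_ms + motion_ms + fixation_k` ms, with `fixation_k` drawn
#' uniformly (on the sampling grid) from `fixation_range_ms`; the ERP onset of
#' a trial is the first sample of its motion video.
#'
#' @param config a [generative_config()].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A `trial_schedule`: data frame with columns `trial`, `set`,
#'   `condition`, `onset_sample` (1-based), plus attributes `fs` and `counts`.
#' @examples
#' sch <- build_trial_schedule(generative_config(), seed = 1)
#' table(sch$condition)
#' @export
build_trial_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generative_config"))
  ratio <- config$condition_ratio
  per_set <- config$set_size / sum(ratio)
  assert_that_(per_set == round(per_set),
               "set_size must be divisible by the condition-ratio sum")
  step_ms <- 1000 / config$fs
  with_seed_(seed, {
    conditions <- unlist(lapply(seq_len(config$n_sets), function(s) {
      sample(rep(names(ratio), times = ratio * per_set))
    }))
    n_trials <- length(conditions)
    fix_lo <- round(config$fixation_range_ms[1] / step_ms)
    fix_hi <- round(config$fixation_range_ms[2] / step_ms)
    fixation_smp <- if (fix_hi > fix_lo)
      sample(fix_lo:fix_hi, n_trials, replace = TRUE) else rep(fix_lo, n_trials)
    still_smp <- round(config$still_ms / step_ms)
    motion_smp <- round(config$motion_ms / step_ms)
    trial_len <- still_smp + motion_smp + fixation_smp
    trial_start <- cumsum(c(0, trial_len[-n_trials]))
    onset <- trial_start + still_smp + 1L   # 1-based index of first motion sample
    sched <- data.frame(
      trial = seq_len(n_trials),
      set = rep(seq_len(config$n_sets), each = config$set_size),
      condition = conditions,
      onset_sample = as.integer(onset),
      stringsAsFactors = FALSE
    )
    structure(sched,
              fs = config$fs,
              counts = table(factor(conditions, levels = names(ratio))),
              class = c("trial_schedule", "data.frame"))
  })
}

#' Gaussian evoked-component kernel
#'
#' `amplitude * exp(-((t - latency) / width)^2)`: a smooth symmetric unimodal
#' pulse peaking at `latency` with value `amplitude`, where `width` is the 1/e
#' half-width. Beyond `3 * width` from the peak the magnitude is below
#' `exp(-9)` (0.012%) of `|amplitude|`.
#'
#' @param latency peak time, ms.
#' @param amplitude peak value, µV (sign gives polarity).
#' @param width 1/e half-width, ms; must be > 0.
#' @param t_grid numeric vector of times, ms.
#' @return waveform in µV evaluated on `t_grid`.
#' @examples
#' component_kernel(170, -5, 20, t_grid = seq(0, 400, by = 4))
#' @export
component_kernel <- function(latency, amplitude, width, t_grid) {
  assert_that_(is.numeric(width) && width > 0, "width must be > 0")
  amplitude * exp(-((t_grid - latency) / width)^2)
}

# Effective kernel parameters for one (component, condition, electrode) cell
# given a trait score: base + slope * (trait - trait_mean).
effective_params <- function(config, component, condition, electrode, trait) {
  comp <- config$components
  row <- comp[comp$component == component & comp$condition == condition &
                comp$electrode == electrode, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  d <- trait - config$trait_mean
  slope_of <- function(kind) {
    nm <- paste(electrode, component, condition, kind, sep = "_")
    unname(config$effect_slopes[nm]) %||% 0
  }
  lat_slope <- slope_of("latency"); lat_slope[is.na(lat_slope)] <- 0
  amp_slope <- slope_of("amplitude"); amp_slope[is.na(amp_slope)] <- 0
  list(latency = row$base_latency + lat_slope * d,
       amplitude = row$base_amplitude + amp_slope * d,
       width = row$width)
}

#' Synthesize a continuous recording for one participant
#'
#' Builds an 8-channel record (µV) at `config$fs` Hz. Every channel carries
#' 1/f-shaped noise of SD `noise_sd`; AW and RW trials additionally carry the
#' configured N170/P200 kernels on T5 and T6 with trait-dependent latency and
#' amplitude; ST trials carry no evoked components. A Bernoulli
#' (`artifact_rate`) subset of trials receives a slow blink transient of
#' `artifact_amplitude` µV on both EOG channels (opposite polarity below the
#' eye) with `artifact_leakage`-scaled leakage on all scalp channels.
#'
#' @param trait the participant's trait score.
#' @param schedule a [build_trial_schedule()] result consistent with `config`.
#' @param config a [generative_config()].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param participant_id identifier stored in the recording.
#' @param channels channels to synthesize (default: the full 8-channel
#'   montage). Restricting to the channels a study actually reads (e.g.
#'   T5/T6 plus EOG) is a pure compute saving: channels carry independent
#'   noise, so omitting unread ones changes no downstream result.
#' @return A `raw_recording`: list with `participant_id`, `trait`, `channels`,
#'   `fs`, `signal` (channels × samples matrix, µV), `events` (data frame
#'   `onset_sample`, `condition`), and `artifact_trials` (ground-truth indices
#'   of blink-carrying trials).
#' @export
synthesize_recording <- function(trait, schedule, config, seed = NULL,
                                 participant_id = "P01",
                                 channels = all_channels()) {
  stopifnot(inherits(config, "generative_config"),
            inherits(schedule, "trial_schedule"))
  assert_that_(all(channels %in% all_channels()) && !anyDuplicated(channels),
               "channels must be a subset of the montage, without duplicates")
  fs <- config$fs
  step_ms <- 1000 / fs
  post_smp <- round(0.6 * fs)
  n_samples <- max(schedule$onset_sample) + post_smp + round(fs)
  chans <- channels
  with_seed_(seed, {
    # Each channel's noise lives in its own substream, so synthesizing a
    # channel subset reproduces exactly the realization the full montage
    # would carry on those channels.
    noise_base <- sample.int(2147483646L, 1)
    sig <- matrix(0, nrow = length(chans), ncol = n_samples,
                  dimnames = list(chans, NULL))
    for (ci in seq_along(all_channels())) {
      ch <- all_channels()[ci]
      if (ch %in% chans)
        sig[ch, ] <- with_seed_(derive_seed(noise_base, ci),
                                pink_noise(n_samples, config$noise_sd))
    }

    evoked <- intersect(c("T5", "T6"), chans)
    n_trials <- nrow(schedule)
    jitter <- if (config$latency_jitter_sd > 0)
      rnorm(n_trials, 0, config$latency_jitter_sd) else numeric(n_trials)
    for (k in seq_len(n_trials)) {
      cond <- schedule$condition[k]
      if (!cond %in% c("AW", "RW")) next
      onset <- schedule$onset_sample[k]
      for (el in evoked) {
        for (comp in c("N170", "P200")) {
          p <- effective_params(config, comp, cond, el, trait)
          if (is.null(p)) next
          lat <- p$latency + jitter[k]
          span <- ceiling(3 * p$width / step_ms)
          centre <- onset + round(lat / step_ms)
          idx <- max(1L, centre - span):min(n_samples, centre + span)
          t_rel <- (idx - onset) * step_ms
          sig[el, idx] <- sig[el, idx] +
            component_kernel(lat, p$amplitude, p$width, t_rel)
        }
      }
    }

    art <- which(runif(n_trials) < config$artifact_rate)
    blink_width <- 100  # ms, slow ocular transient
    for (k in art) {
      onset <- schedule$onset_sample[k]
      lat <- runif(1, 50, 400)      # blink somewhere inside the epoch window
      span <- ceiling(3 * blink_width / step_ms)
      centre <- onset + round(lat / step_ms)
      idx <- max(1L, centre - span):min(n_samples, centre + span)
      t_rel <- (idx - onset) * step_ms
      blink <- component_kernel(lat, config$artifact_amplitude, blink_width, t_rel)
      if ("EOG_upper" %in% chans)
        sig["EOG_upper", idx] <- sig["EOG_upper", idx] + blink
      if ("EOG_lower" %in% chans)
        sig["EOG_lower", idx] <- sig["EOG_lower", idx] - blink
      for (ch in intersect(scalp_channels(), chans))
        sig[ch, idx] <- sig[ch, idx] + config$artifact_leakage * blink
    }

    structure(list(
      participant_id = participant_id,
      trait = trait,
      channels = chans,
      fs = fs,
      signal = sig,
      events = data.frame(onset_sample = schedule$onset_sample,
                          condition = schedule$condition,
                          stringsAsFactors = FALSE),
      artifact_trials = art
    ), class = "raw_recording")
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s: %d channels x %d samples @ %g Hz, %d events\n",
              x$participant_id, nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Draws trait scores, builds one schedule and one recording per participant
#' (independent schedules), all from substreams of `config$seed`.
#'
#' @param config a [generative_config()].
#' @return list with `participants` (data frame `id`, `satq`) and
#'   `recordings` (list of `raw_recording`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  traits <- generate_trait_scores(config$n_participants, config$trait_mean,
                                  config$trait_sd, config$trait_bounds[1],
                                  config$trait_bounds[2],
                                  seed = derive_seed(config$seed, 0))
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  recordings <- lapply(seq_len(config$n_participants), function(i) {
    sch <- build_trial_schedule(config, seed = derive_seed(config$seed, i))
    synthesize_recording(traits[i], sch, config,
                         seed = derive_seed(config$seed, 10000 + i),
                         participant_id = ids[i])
  })
  list(participants = data.frame(id = ids, satq = traits,
                                 stringsAsFactors = FALSE),
       recordings = recordings)
}
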