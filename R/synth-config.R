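#' Configuration of the synthetic EEG generator
#'
#' Collects every tunable of the generative model in one validated object.
#' Defaults reproduce the study design the package emulates: 30 participants,
#' trait scores (SATQ, 0–72) drawn from a truncated normal with mean 27.77 and
#' SD 8.02, five stimulus sets of 60 trials in an AW:RW:ST = 2:2:1 ratio at a
#' 250 Hz sampling rate, N170 (−5 µV at 170 ms) and P200 (+6 µV at 200 ms)
#' components on the temporal electrodes T5/T6 in the AW and RW conditions,
#' and trait effects confined to the AW condition: P200 latency at T6 grows by
#' 0.5 ms per trait unit and P200 amplitude at T5/T6 shrinks by 0.1 µV per
#' trait unit.
#'
#' @param n_participants number of simulated participants.
#' @param trait_mean,trait_sd mean and SD of the trait-score distribution.
#' @param trait_bounds length-2 numeric, inclusive score range.
#' @param fs sampling frequency in Hz.
#' @param n_sets,set_size number of stimulus sets and trials per set.
#' @param condition_ratio named integer vector, trials per condition within a
#'   ratio unit; `set_size` must be divisible by its sum.
#' @param still_ms,motion_ms,fixation_range_ms trial timing envelope in ms:
#'   still image, motion video, and the uniform range of the fixation period.
#'   The stimulus (ERP) onset is the start of the motion video.
#' @param components data frame with columns `component`, `condition`,
#'   `electrode`, `base_latency`, `base_amplitude`, `width` (all ms / µV)
#'   giving the evoked kernels embedded in each AW/RW trial.
#' @param effect_slopes named numeric vector of linear trait effects; names
#'   follow `<electrode>_<component>_<condition>_<latency|amplitude>` and units
#'   are ms (latency) or µV (amplitude) per trait unit relative to
#'   `trait_mean`.
#' @param noise_sd per-trial 1/f noise SD in µV.
#' @param latency_jitter_sd SD in ms of trial-to-trial latency jitter
#'   (default 0: reproducible noiseless recordings).
#' @param artifact_rate probability that a trial carries a blink artifact.
#' @param artifact_amplitude blink amplitude in µV on the EOG channels.
#' @param artifact_leakage fraction of the blink leaking into scalp channels.
#' @param seed integer seed governing all randomness downstream.
#'
#' @return An object of class `generative_config` (a validated list).
#' @examples
#' cfg <- generative_config(n_participants = 4, noise_sd = 5)
#' cfg$fs
#' @export
generative_config <- function(n_participants = 30,
                              trait_mean = 27.77,
                              trait_sd = 8.02,
                              trait_bounds = c(0, 72),
                              fs = 250,
                              n_sets = 5,
                              set_size = 60,
                              condition_ratio = c(AW = 2, RW = 2, ST = 1),
                              still_ms = 1200,
                              motion_ms = 1220,
                              fixation_range_ms = c(1800, 2200),
                              components = default_components(),
                              effect_slopes = default_effect_slopes(),
                              noise_sd = 10,
                              latency_jitter_sd = 0,
                              artifact_rate = 0.1,
                              artifact_amplitude = 150,
                              artifact_leakage = 0.15,
                              seed = 1L) {
  assert_that_(is_count(n_participants), "n_participants must be a positive integer")
  assert_that_(is.numeric(fs) && fs > 0, "fs must be > 0")
  assert_that_(length(trait_bounds) == 2 && trait_bounds[1] < trait_bounds[2],
               "trait_bounds must satisfy lo < hi")
  assert_that_(is_count(n_sets) && is_count(set_size), "n_sets/set_size must be counts")
  assert_that_(!is.null(names(condition_ratio)) && all(condition_ratio >= 1),
               "condition_ratio must be a named positive vector")
  assert_that_(set_size %% sum(condition_ratio) == 0,
               "set_size (", set_size, ") must be divisible by the ratio sum (",
               sum(condition_ratio), ")")
  assert_that_(all(c("component", "condition", "electrode", "base_latency",
                     "base_amplitude", "width") %in% names(components)),
               "components is missing required columns")
  assert_that_(all(components$width > 0), "component widths must be > 0")
  assert_that_(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  assert_that_(is.numeric(artifact_rate) && artifact_rate >= 0 && artifact_rate <= 1,
               "artifact_rate must lie in [0, 1]")
  assert_that_(length(fixation_range_ms) == 2 &&
                 fixation_range_ms[1] <= fixation_range_ms[2],
               "fixation_range_ms must be an increasing pair")
  if (length(effect_slopes)) {
    assert_that_(!is.null(names(effect_slopes)), "effect_slopes must be named")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    trait_mean = trait_mean, trait_sd = trait_sd,
    trait_bounds = trait_bounds,
    fs = fs, n_sets = as.integer(n_sets), set_size = as.integer(set_size),
    condition_ratio = condition_ratio,
    still_ms = still_ms, motion_ms = motion_ms,
    fixation_range_ms = fixation_range_ms,
    components = components, effect_slopes = effect_slopes,
    noise_sd = noise_sd, latency_jitter_sd = latency_jitter_sd,
    artifact_rate = artifact_rate,
    artifact_amplitude = artifact_amplitude,
    artifact_leakage = artifact_leakage,
    seed = as.integer(seed)
  ), class = "generative_config")
}

#' Default evoked-component table
#'
#' N170: −5 µV at 170 ms, width 20 ms; P200: +6 µV at 200 ms, width 30 ms; both
#' present at T5 and T6 in the AW and RW conditions and absent in ST. `width`
#' is the 1/e half-width of the Gaussian pulse (see [component_kernel()]).
#'
#' @return data.frame with one row per (component, condition, electrode).
#' @export
default_components <- function() {
  grid <- expand.grid(component = c("N170", "P200"),
                      condition = c("AW", "RW"),
                      electrode = c("T5", "T6"),
                      stringsAsFactors = FALSE)
  grid$base_latency <- ifelse(grid$component == "N170", 170, 200)
  grid$base_amplitude <- ifelse(grid$component == "N170", -5, 6)
  grid$width <- ifelse(grid$component == "N170", 20, 30)
  grid
}

#' Default trait-effect slopes
#'
#' Encodes the AW-specific effect directions the analysis is meant to recover:
#' P200 latency at T6 increases with the trait (+0.5 ms per score unit) and
#' P200 amplitude at T5 and T6 decreases (−0.1 µV per score unit); every other
#' indicator is trait-invariant.
#'
#' @return named numeric vector.
#' @export
default_effect_slopes <- function() {
  c(T6_P200_AW_latency = 0.5,
    T5_P200_AW_amplitude = -0.1,
    T6_P200_AW_amplitude = -0.1)
}

#' @export
print.generative_config <- function(x, ...) {
  cat("<generative_config>\n")
  cat(sprintf("  participants: %d, trait ~ N(%.2f, %.2f) in [%g, %g]\n",
              x$n_participants, x$trait_mean, x$trait_sd,
              x$trait_bounds[1], x$trait_bounds[2]))
  cat(sprintf("  schedule: %d sets x %d trials, ratio %s, fs %g Hz\n",
              x$n_sets, x$set_size,
              paste(names(x$condition_ratio), x$condition_ratio,
                    sep = "=", collapse = " "), x$fs))
  cat(sprintf("  noise_sd %g uV, artifact_rate %g, seed %d\n",
              x$noise_sd, x$artifact_rate, x$seed))
  invisible(x)
}

# Channel montage (fixed by the emulated recording setup).
scalp_channels <- function() c("C3", "C4", "T5", "T6", "O1", "O2")
eog_channels <- function() c("EOG_upper", "EOG_lower")
all_channels <- function() c(scalp_channels(), eog_channels())

# Read/write a generative or run configuration as JSON.

#' Serialize a configuration to JSON
#'
#' @param config a `generative_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- unclass(config)
  # named numeric vectors must round-trip with their names
  raw$condition_ratio <- as.list(raw$condition_ratio)
  raw$effect_slopes <- as.list(raw$effect_slopes)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a configuration from JSON
#'
#' @param path JSON file written by [write_config()] (or hand-edited).
#' @return a validated `generative_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$components)) raw$components <- as.data.frame(raw$components)
  if (!is.null(raw$effect_slopes)) raw$effect_slopes <- unlist(raw$effect_slopes)
  if (!is.null(raw$condition_ratio)) raw$condition_ratio <- unlist(raw$condition_ratio)
  do.call(generative_config, raw)
}
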