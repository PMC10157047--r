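#' End-to-end run configuration
#'
#' @param mode `"synthetic"` (generate data) or `"real-data"` (read a dataset
#'   directory written in the package's on-disk format).
#' @param generative a [generative_config()] (synthetic mode).
#' @param data_dir dataset directory (real-data mode).
#' @param erp an [erp_params()].
#' @param K top-K size for the weight diagrams.
#' @param seed global seed, fanned out to per-stage substreams.
#' @param channels channels to synthesize in synthetic mode (see
#'   [synthesize_recording()]).
#' @param out_dir where to write the report bundle; `NULL` keeps the bundle in
#'   memory only.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "real-data"),
                       generative = generative_config(),
                       data_dir = NULL,
                       erp = erp_params(),
                       K = 50,
                       seed = generative$seed,
                       channels = all_channels(),
                       out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "real-data")
    assert_that_(!is.null(data_dir) && dir.exists(data_dir),
                 "real-data mode needs an existing data_dir")
  structure(list(mode = mode, generative = generative, data_dir = data_dir,
                 erp = erp, K = K, seed = as.integer(seed),
                 channels = channels, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline: synth → erp → essearch
#'
#' Deterministic given `config$seed`. Each participant is generated (or read),
#' filtered, epoched, cleaned and averaged; per-electrode feature tables are
#' assembled with exclusion logging; every feature table is pushed through the
#' exhaustive-search engine. When `config$out_dir` is set the bundle is
#' written to disk with a manifest (MD5 checksum per file).
#'
#' @param config a [run_config()].
#' @return a `run_bundle`: list with `features` (per-electrode tables),
#'   `exclusions`, `grand_averages[[electrode]][[condition]]`, `searches`
#'   (per-electrode `es_search`), `counts` (bookkeeping), `config`, and
#'   `files` when written.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  gen <- config$generative
  if (config$mode == "synthetic") {
    gen$seed <- config$seed
    traits <- generate_trait_scores(gen$n_participants, gen$trait_mean,
                                    gen$trait_sd, gen$trait_bounds[1],
                                    gen$trait_bounds[2],
                                    seed = derive_seed(config$seed, 0))
    ids <- sprintf("P%02d", seq_len(gen$n_participants))
    participants <- data.frame(id = ids, satq = traits,
                               stringsAsFactors = FALSE)
    get_recording <- function(i) {
      sch <- build_trial_schedule(gen, seed = derive_seed(config$seed, i))
      synthesize_recording(traits[i], sch, gen,
                           seed = derive_seed(config$seed, 10000 + i),
                           participant_id = ids[i],
                           channels = config$channels %||% all_channels())
    }
    n_part <- gen$n_participants
  } else {
    ds <- read_dataset(config$data_dir)
    participants <- ds$participants
    get_recording <- function(i) ds$recordings[[i]]
    n_part <- nrow(participants)
  }

  waveforms <- list()
  kept_counts <- list()
  for (i in seq_len(n_part)) {
    rec <- get_recording(i)
    pr <- process_participant(rec, config$erp)
    waveforms[[rec$participant_id]] <- pr$waveforms
    kept_counts[[rec$participant_id]] <- pr$kept_counts
  }

  electrodes <- config$erp$electrodes
  feats <- extract_feature_table(participants, waveforms, electrodes,
                                 config$erp)

  grand <- list()
  for (el in electrodes) {
    grand[[el]] <- list()
    for (cond in c("AW", "RW", "ST")) {
      wfs <- Filter(Negate(is.null),
                    lapply(waveforms, function(w) w[[el]][[cond]]))
      if (length(wfs)) grand[[el]][[cond]] <- grand_average(wfs)
    }
  }

  searches <- list()
  for (el in electrodes) {
    if (nrow(feats$tables[[el]]) == 0) {
      warning("no retained participants at ", el, "; skipping search")
      next
    }
    pm <- predictor_matrix(feats$tables[[el]], el)
    searches[[el]] <- es_search(pm, K = config$K)
  }

  counts <- list(
    enrolled = n_part,
    retained = vapply(feats$tables, nrow, 0L),
    models_per_electrode = vapply(searches, function(s) nrow(s$cve_table), 0L),
    top_k = vapply(searches, function(s) nrow(s$topK), 0L)
  )
  bundle <- structure(list(features = feats$tables,
                           exclusions = feats$exclusions,
                           grand_averages = grand,
                           searches = searches,
                           kept_counts = kept_counts,
                           counts = counts,
                           participants = participants,
                           config = config),
                      class = "run_bundle")
  if (!is.null(config$out_dir)) bundle <- write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("<run_bundle>\n")
  cat(sprintf("  participants: %d enrolled; retained: %s\n",
              x$counts$enrolled,
              paste(names(x$counts$retained), x$counts$retained,
                    sep = "=", collapse = " ")))
  cat(sprintf("  models per electrode: %s\n",
              paste(names(x$counts$models_per_electrode),
                    x$counts$models_per_electrode, sep = "=", collapse = " ")))
  invisible(x)
}

# Serialize the bundle: feature/CVE/selection/best-model TSVs per electrode,
# grand averages in long format, exclusion log, config echo, and a manifest
# with an MD5 checksum per file.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
  }
  for (el in names(bundle$features))
    put(bundle$features[[el]], sprintf("features_%s.tsv", el))
  ga_rows <- list()
  for (el in names(bundle$grand_averages))
    for (cond in names(bundle$grand_averages[[el]])) {
      g <- bundle$grand_averages[[el]][[cond]]
      ga_rows[[paste(el, cond)]] <- data.frame(
        electrode = el, condition = cond, time_ms = g$time_ms,
        mean = g$mean, se = g$se, n = g$n_trials, stringsAsFactors = FALSE)
    }
  put(do.call(rbind, ga_rows), "grand_averages.tsv")
  for (el in names(bundle$searches)) {
    s <- bundle$searches[[el]]
    put(s$cve_table, sprintf("cve_%s.tsv", el))
    put(data.frame(variable = names(s$selection_counts),
                   count = as.integer(s$selection_counts),
                   stringsAsFactors = FALSE),
        sprintf("selection_frequency_%s.tsv", el))
    bf <- s$best_fit
    put(data.frame(variable = bf$variables, B = bf$B, SE = bf$se,
                   beta = bf$beta, p = bf$p, stringsAsFactors = FALSE),
        sprintf("best_model_%s.tsv", el))
    wd_files <- write_weight_diagram(s$weight_diagram,
                                     file.path(out_dir,
                                               sprintf("weight_diagram_%s", el)))
    files <- c(files, wd_files)
  }
  excl_path <- file.path(out_dir, "exclusions.json")
  jsonlite::write_json(bundle$exclusions, excl_path, dataframe = "rows")
  files <- c(files, excl_path)
  cfg_path <- file.path(out_dir, "config.json")
  cfg <- bundle$config
  cfg$generative <- unclass(cfg$generative)
  cfg$erp <- unclass(cfg$erp)
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, null = "null")
  files <- c(files, cfg_path)
  manifest <- list(
    seed = bundle$config$seed,
    package_version = as.character(utils::packageVersion("erpselect")),
    r_version = R.version.string,
    counts = bundle$counts,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  bundle$files <- c(files, file.path(out_dir, "manifest.json"))
  bundle
}
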