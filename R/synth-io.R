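#' Write a synthetic dataset to disk
#'
#' One gzip-compressed columnar signal file per participant plus a JSON
#' sidecar describing the 16-bit quantization (physical range, scale, sampling
#' rate, channel order — the same information an EDF header would carry), one
#' events TSV per participant, and a cohort-level participants TSV. Signals
#' are stored as signed 16-bit integers with a per-file physical range, so the
#' round-trip error is bounded by half a quantization step.
#'
#' @param recordings list of `raw_recording` objects.
#' @param participants data frame with columns `id`, `satq`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a data frame listing the written files.
#' @export
write_dataset <- function(recordings, participants, out_dir) {
  stopifnot(is.data.frame(participants),
            all(c("id", "satq") %in% names(participants)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that_(dir.exists(out_dir), "cannot create output directory ", out_dir)
  written <- character(0)
  if (length(recordings) == 0L)
    warning("empty recording list: writing participants table only")
  for (rec in recordings) {
    stopifnot(inherits(rec, "raw_recording"))
    id <- rec$participant_id
    phys_max <- max(abs(rec$signal), 1e-9) * 1.0001
    scale <- (2 * phys_max) / 65535          # uV per digital unit
    digital <- round(rec$signal / scale)
    sig_path <- file.path(out_dir, paste0(id, "_signal.tsv.gz"))
    con <- gzfile(sig_path, "wb")
    write.table(t(digital), con, sep = "\t", row.names = FALSE,
                col.names = rec$channels, quote = FALSE)
    close(con)
    meta_path <- file.path(out_dir, paste0(id, "_signal.json"))
    jsonlite::write_json(list(participant_id = id, fs = rec$fs,
                              channels = rec$channels,
                              phys_max = phys_max, scale = scale,
                              n_samples = ncol(rec$signal)),
                         meta_path, auto_unbox = TRUE, digits = NA)
    ev_path <- file.path(out_dir, paste0(id, "_events.tsv"))
    write.table(rec$events, ev_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
    written <- c(written, sig_path, meta_path, ev_path)
  }
  part_path <- file.path(out_dir, "participants.tsv")
  write.table(participants, part_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  written <- c(written, part_path)
  invisible(data.frame(path = written, stringsAsFactors = FALSE))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `participants` and `recordings` (signals dequantized to
#'   µV).
#' @export
read_dataset <- function(dir) {
  part_path <- file.path(dir, "participants.tsv")
  assert_that_(file.exists(part_path), "no participants.tsv under ", dir)
  participants <- read.delim(part_path, stringsAsFactors = FALSE)
  metas <- sort(list.files(dir, pattern = "_signal\\.json$", full.names = TRUE))
  recordings <- lapply(metas, function(meta_path) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    id <- meta$participant_id
    digital <- as.matrix(read.delim(
      gzfile(file.path(dir, paste0(id, "_signal.tsv.gz"))),
      check.names = FALSE))
    events <- read.delim(file.path(dir, paste0(id, "_events.tsv")),
                         stringsAsFactors = FALSE)
    trait <- participants$satq[match(id, participants$id)]
    structure(list(participant_id = id,
                   trait = trait,
                   channels = meta$channels,
                   fs = meta$fs,
                   signal = t(digital) * meta$scale,
                   events = events,
                   artifact_trials = integer(0)),
              class = "raw_recording")
  })
  list(participants = participants, recordings = recordings)
}
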