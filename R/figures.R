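#' Plot a grand-average waveform set
#'
#' One trace per condition with a shaded ±1 SE band, stimulus onset at 0 ms.
#'
#' @param waveforms named list of `erp_waveform`s (e.g. AW/RW/ST of one
#'   electrode).
#' @param main title.
#' @export
plot_grand_average <- function(waveforms, main = "Grand average") {
  assert_that_(length(waveforms) >= 1, "no waveforms to plot")
  t <- waveforms[[1]]$time_ms
  cols <- setNames(c("#D73027", "#4575B4", "#666666")[seq_along(waveforms)],
                   names(waveforms))
  ylim <- range(unlist(lapply(waveforms, function(w)
    range(w$mean + ifelse(is.na(w$se), 0, w$se),
          w$mean - ifelse(is.na(w$se), 0, w$se)))))
  plot(t, waveforms[[1]]$mean, type = "n", ylim = ylim,
       xlab = "time from stimulus onset (ms)", ylab = "amplitude (uV)",
       main = main)
  abline(v = 0, lty = 3); abline(h = 0, lty = 3)
  for (nm in names(waveforms)) {
    w <- waveforms[[nm]]
    if (!all(is.na(w$se)))
      polygon(c(t, rev(t)), c(w$mean + w$se, rev(w$mean - w$se)),
              col = paste0(substr(cols[nm], 1, 7), "33"), border = NA)
    lines(t, w$mean, col = cols[nm], lwd = 2)
  }
  legend("topright", legend = names(waveforms), col = cols, lwd = 2, bty = "n")
  invisible(waveforms)
}

#' Render the bundle's figures
#'
#' One grand-average PNG per electrode (AW/RW/ST traces with SE shading) and
#' one weight-diagram PNG per electrode (CVE trace over a beta color map).
#'
#' @param bundle a `run_bundle` from [run_full_analysis()].
#' @param out_dir output directory (defaults to the bundle's).
#' @return character vector of the written files.
#' @export
render_figures <- function(bundle, out_dir = bundle$config$out_dir) {
  stopifnot(inherits(bundle, "run_bundle"))
  assert_that_(!is.null(out_dir), "no output directory for figures")
  assert_that_(length(bundle$grand_averages) > 0 && length(bundle$searches) > 0,
               "incomplete bundle: run the full analysis first")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (el in names(bundle$grand_averages)) {
    path <- file.path(out_dir, sprintf("grand_average_%s.png", el))
    png(path, width = 900, height = 600, res = 110)
    plot_grand_average(bundle$grand_averages[[el]],
                       main = sprintf("Grand-average ERP at %s", el))
    dev.off()
    written <- c(written, path)
  }
  for (el in names(bundle$searches)) {
    path <- file.path(out_dir, sprintf("weight_diagram_%s.png", el))
    png(path, width = 900, height = 700, res = 110)
    plot(bundle$searches[[el]]$weight_diagram)
    dev.off()
    written <- c(written, path)
  }
  written
}
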