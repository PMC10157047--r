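#' Build a weight diagram from the top-K models
#'
#' A K × N grid of standardized partial regression coefficients: row k holds
#' the betas of the k-th best model (ascending CVE), with `NA` wherever a
#' variable is not in that model (rendered white when plotted). The paired CVE
#' trace and per-variable selection counts are attached.
#'
#' @param topK ranked models from [rank_models()].
#' @param data the [predictor_matrix()] the models were fit on.
#' @return a `weight_diagram`: list with `betas` (K × N matrix), `cve`,
#'   `masks`, `selection_counts`, `variables`, `electrode`.
#' @export
build_weight_diagram <- function(topK, data) {
  stopifnot(inherits(data, "predictor_matrix"), nrow(topK) >= 1)
  N <- ncol(data$X)
  K <- nrow(topK)
  betas <- matrix(NA_real_, nrow = K, ncol = N,
                  dimnames = list(NULL, data$names))
  for (i in seq_len(K)) {
    fit <- fit_ols(data, topK$mask[i])
    betas[i, fit$variables] <- standardized_betas(fit, data)
  }
  structure(list(betas = betas, cve = topK$cve, masks = topK$mask,
                 selection_counts = selection_frequency(topK, N, data$names),
                 variables = data$names, electrode = data$electrode),
            class = "weight_diagram")
}

#' @export
print.weight_diagram <- function(x, ...) {
  cat(sprintf("<weight_diagram> %s: %d models x %d variables, CVE %.3f..%.3f\n",
              x$electrode, nrow(x$betas), ncol(x$betas), min(x$cve), max(x$cve)))
  invisible(x)
}

#' Plot a weight diagram
#'
#' Upper panel: CVE of the ranked models. Lower panel: beta color map with
#' warm colors for positive coefficients, cool for negative, white where a
#' variable is absent from the model.
#'
#' @param x a `weight_diagram`.
#' @param main plot title.
#' @param ... ignored.
#' @export
plot.weight_diagram <- function(x, main = paste("Weight diagram", x$electrode),
                                ...) {
  K <- nrow(x$betas); N <- ncol(x$betas)
  op <- par(no.readonly = TRUE); on.exit(par(op))
  layout(matrix(1:2, ncol = 1), heights = c(1, 2.2))
  par(mar = c(0.5, 10, 3, 2))
  plot(seq_len(K), x$cve, type = "l", xaxt = "n", xlab = "", ylab = "CVE",
       main = main)
  points(seq_len(K), x$cve, pch = 16, cex = 0.5)
  par(mar = c(4, 10, 0.5, 2))
  lim <- max(abs(x$betas), na.rm = TRUE)
  pal <- colorRampPalette(c("#2166AC", "#92C5DE", "#F7F7F7",
                            "#F4A582", "#B2182B"))(255)
  z <- t(x$betas)[, rev(seq_len(K)), drop = FALSE]   # variables x models
  image(x = seq_len(K), y = seq_len(N), z = t(z), zlim = c(-lim, lim),
        col = pal, xlab = "model rank (ascending CVE)", ylab = "", yaxt = "n")
  axis(2, at = seq_len(N), labels = rev(x$variables), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Serialize a weight diagram
#'
#' Writes `<prefix>.tsv` (models × variables beta grid with rank, mask and
#' CVE columns) and `<prefix>.json` (the full object).
#'
#' @param wd a `weight_diagram`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_weight_diagram <- function(wd, prefix) {
  stopifnot(inherits(wd, "weight_diagram"))
  tsv <- paste0(prefix, ".tsv")
  df <- data.frame(rank = seq_along(wd$cve), mask = wd$masks, cve = wd$cve,
                   wd$betas, check.names = FALSE)
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(list(electrode = wd$electrode, variables = wd$variables,
                            cve = wd$cve, masks = wd$masks,
                            selection_counts = as.list(wd$selection_counts),
                            betas = wd$betas),
                       js, auto_unbox = TRUE, digits = NA, na = "null",
                       matrix = "rowmajor")
  invisible(c(tsv, js))
}
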