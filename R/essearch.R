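# Exhaustive best-subset regression scored by leave-one-out cross-validated
# mean absolute error (CVE). Subsets are encoded as bitmasks over the N
# candidate predictors; bit j (value 2^(j-1)) includes column j.

#' Build the predictor matrix for one electrode
#'
#' @param features per-electrode feature table from [extract_feature_table()]
#'   (columns `id`, `satq`, then the eight indicators).
#' @param electrode label used to pick columns prefixed `<electrode>_`; when
#'   `NULL`, every column other than `id`/`satq` is used.
#' @return a `predictor_matrix`: list with `y`, `X`, `names`, `electrode`.
#' @export
predictor_matrix <- function(features, electrode = NULL) {
  stopifnot(is.data.frame(features), "satq" %in% names(features))
  cols <- setdiff(names(features), c("id", "satq"))
  if (!is.null(electrode))
    cols <- cols[startsWith(cols, paste0(electrode, "_"))]
  assert_that_(length(cols) >= 1, "no indicator columns found")
  X <- as.matrix(features[, cols, drop = FALSE])
  assert_that_(!anyNA(X) && !anyNA(features$satq),
               "missing values in the feature table")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    abort_input("constant indicator column(s): ",
                paste(cols[const], collapse = ", "))
  structure(list(y = as.numeric(features$satq), X = X, names = cols,
                 electrode = electrode %||% ""),
            class = "predictor_matrix")
}

#' Enumerate every nonempty predictor subset
#'
#' @param N number of candidate predictors, `1 <= N <= 20`.
#' @return integer vector of the `2^N - 1` bitmasks in ascending order.
#' @examples
#' length(enumerate_subsets(8))  # 255
#' @export
enumerate_subsets <- function(N) {
  assert_that_(is_count(N) && N <= 20, "N must be an integer in [1, 20]")
  seq_len(2^N - 1L)
}

#' Decode a subset bitmask
#'
#' @param mask integer bitmask.
#' @param N number of candidate predictors.
#' @return integer indices of the included predictors.
#' @export
subset_variables <- function(mask, N) {
  which(bitwAnd(mask, 2^(seq_len(N) - 1L)) > 0L)
}

#' Ordinary least squares fit of one subset model
#'
#' Fits `y ~ X[, vars]` with intercept and reports the usual summary
#' statistics: per-variable unstandardized B, standard error, standardized
#' beta (`B * sd(x) / sd(y)`) and two-sided t-test p-value; R², adjusted R²,
#' and the overall F test on (k, n − k − 1) degrees of freedom.
#'
#' @param data a [predictor_matrix()].
#' @param mask integer bitmask selecting the predictors.
#' @return an `ols_fit` list.
#' @export
fit_ols <- function(data, mask) {
  stopifnot(inherits(data, "predictor_matrix"))
  vars <- subset_variables(mask, ncol(data$X))
  assert_that_(length(vars) >= 1, "empty subset")
  y <- data$y
  n <- length(y); k <- length(vars)
  assert_that_(n > k + 1, "need n > k + 1 observations")
  Xd <- cbind(`(Intercept)` = 1, data$X[, vars, drop = FALSE])
  qr_d <- qr(Xd)
  if (qr_d$rank < ncol(Xd))
    stop(errorCondition(
      paste0("singular fit for subset {",
             paste(data$names[vars], collapse = ", "), "}"),
      class = c("erpselect_singular_fit", "error")))
  coef <- qr.coef(qr_d, y)
  fitted <- drop(Xd %*% coef)
  res <- y - fitted
  df_res <- n - k - 1
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  f_stat <- (r2 / k) / ((1 - r2) / df_res)
  sigma2 <- rss / df_res
  xtx_inv <- chol2inv(chol(crossprod(Xd)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- coef / se
  pval <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)
  sdx <- apply(data$X[, vars, drop = FALSE], 2, stats::sd)
  beta <- coef[-1] * sdx / stats::sd(y)
  structure(list(
    mask = mask, variables = data$names[vars], k = k, n = n,
    intercept = unname(coef[1]),
    B = setNames(unname(coef[-1]), data$names[vars]),
    se = setNames(unname(se[-1]), data$names[vars]),
    beta = setNames(unname(beta), data$names[vars]),
    p = setNames(unname(pval[-1]), data$names[vars]),
    r_squared = r2, adj_r_squared = adj_r2,
    f_statistic = f_stat, df = c(k, df_res),
    model_p = pf(f_stat, k, df_res, lower.tail = FALSE),
    residuals = res
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> k=%d, n=%d: F(%d,%d)=%.3f, p=%.3f, R2=%.3f, adjR2=%.3f\n",
              x$k, x$n, x$df[1], x$df[2], x$f_statistic, x$model_p,
              x$r_squared, x$adj_r_squared))
  tab <- data.frame(B = x$B, SE = x$se, beta = x$beta, p = x$p)
  print(round(tab, 3))
  invisible(x)
}

#' Standardized partial regression coefficients
#'
#' `beta_j = B_j * sd(x_j) / sd(y)` with sample (n−1) standard deviations —
#' identical to refitting after z-scoring the response and every predictor.
#'
#' @param fit an `ols_fit`.
#' @param data the [predictor_matrix()] the fit came from.
#' @return named numeric vector of betas.
#' @export
standardized_betas <- function(fit, data) {
  stopifnot(inherits(fit, "ols_fit"), inherits(data, "predictor_matrix"))
  sdy <- stats::sd(data$y)
  sdx <- apply(data$X[, fit$variables, drop = FALSE], 2, stats::sd)
  assert_that_(sdy > 0 && all(sdx > 0), "zero-variance column")
  setNames(fit$B * sdx / sdy, fit$variables)
}

#' Leave-one-out cross-validated mean absolute error
#'
#' For each of the n observations the subset model is fit on the remaining
#' n − 1 rows (raw, unstandardized scale) and used to predict the held-out
#' trait score; the CVE is the mean of the n absolute prediction errors.
#' Implemented through the exact OLS leave-one-out identity
#' `e_i / (1 - h_ii)`, which is algebraically equal to refitting every fold.
#' A model is invalid when the fit is rank-deficient or any leverage is 1
#' (some fold would be singular).
#'
#' @param data a [predictor_matrix()].
#' @param mask integer bitmask selecting the predictors.
#' @return list with `cve`, `fold_errors` (n absolute errors), `n_folds`,
#'   and `valid`.
#' @export
loocv_mae <- function(data, mask) {
  stopifnot(inherits(data, "predictor_matrix"))
  vars <- subset_variables(mask, ncol(data$X))
  y <- data$y
  n <- length(y); k <- length(vars)
  # every training fold needs at least k + 1 rows for a unique LS solution
  assert_that_(n - 1 >= k + 1, "need n - 1 >= k + 1 for every training fold")
  Xd <- cbind(1, data$X[, vars, drop = FALSE])
  qr_d <- qr(Xd)
  if (qr_d$rank < ncol(Xd))
    return(list(cve = NA_real_, fold_errors = rep(NA_real_, n), n_folds = n,
                valid = FALSE))
  res <- qr.resid(qr_d, y)
  h <- rowSums(qr.Q(qr_d)^2)
  if (any(1 - h < 1e-10))
    return(list(cve = NA_real_, fold_errors = rep(NA_real_, n), n_folds = n,
                valid = FALSE))
  fold_errors <- abs(res / (1 - h))
  list(cve = mean(fold_errors), fold_errors = fold_errors, n_folds = n,
       valid = TRUE)
}

#' Rank models by cross-validation error
#'
#' Ascending CVE; ties are broken by fewer predictors, then ascending bitmask,
#' making the ordering fully deterministic. Invalid models are excluded.
#'
#' @param cve_table data frame with columns `mask`, `k`, `cve`, `valid`.
#' @param K number of models to keep.
#' @return the top-K rows of `cve_table`, ordered.
#' @export
rank_models <- function(cve_table, K) {
  stopifnot(all(c("mask", "k", "cve", "valid") %in% names(cve_table)))
  valid <- cve_table[cve_table$valid & !is.na(cve_table$cve), , drop = FALSE]
  if (K > nrow(valid)) {
    warning(sprintf("K=%d exceeds the %d valid models; truncating", K,
                    nrow(valid)))
    K <- nrow(valid)
  }
  ord <- order(valid$cve, valid$k, valid$mask)
  valid[ord[seq_len(K)], , drop = FALSE]
}

#' How often each variable enters the top-K models
#'
#' @param topK ranked models from [rank_models()].
#' @param N number of candidate predictors.
#' @param names optional variable names for the result.
#' @return integer vector of counts in `[0, K]`.
#' @export
selection_frequency <- function(topK, N, names = NULL) {
  assert_that_(nrow(topK) >= 1, "empty top-K set")
  counts <- vapply(seq_len(N), function(j)
    sum(bitwAnd(topK$mask, 2^(j - 1L)) > 0L), integer(1))
  if (!is.null(names)) names(counts) <- names
  counts
}

#' Standardized coefficient of a single-predictor regression
#'
#' Computed as `B * sd(x) / sd(y)` from the one-variable least-squares slope;
#' equal to the Pearson correlation of `x` and `y`.
#'
#' @param x indicator values.
#' @param y trait scores.
#' @return the standardized coefficient (scalar).
#' @export
single_variable_regression <- function(x, y) {
  assert_that_(length(x) == length(y) && length(x) > 2, "x and y must match")
  sdx <- stats::sd(x); sdy <- stats::sd(y)
  assert_that_(sdx > 0 && sdy > 0, "zero-variance input")
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b * sdx / sdy
}

#' Exhaustive-search regression with LOOCV scoring
#'
#' Fits all `2^N − 1` subset models, cross-validates each one, ranks them by
#' CVE, tallies selection frequencies over the top K and assembles the weight
#' diagram.
#'
#' @param data a [predictor_matrix()].
#' @param K how many top models enter the weight diagram (default 50).
#' @return an `es_search` object: `cve_table` (one row per model: mask,
#'   variables, k, cve, n_folds, r_squared, adj_r_squared, f_statistic,
#'   model_p, valid), `topK`, `selection_counts`, `weight_diagram`,
#'   `best_fit`, `electrode`, `n`, `N`.
#' @export
es_search <- function(data, K = 50) {
  stopifnot(inherits(data, "predictor_matrix"))
  N <- ncol(data$X)
  masks <- enumerate_subsets(N)
  rows <- vector("list", length(masks))
  for (m in masks) {
    cv <- loocv_mae(data, m)
    fit <- tryCatch(fit_ols(data, m), erpselect_singular_fit = function(e) NULL)
    rows[[m]] <- data.frame(
      mask = m,
      variables = paste(data$names[subset_variables(m, N)], collapse = "+"),
      k = length(subset_variables(m, N)),
      cve = cv$cve, n_folds = cv$n_folds,
      r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
      adj_r_squared = if (is.null(fit)) NA_real_ else fit$adj_r_squared,
      f_statistic = if (is.null(fit)) NA_real_ else fit$f_statistic,
      model_p = if (is.null(fit)) NA_real_ else fit$model_p,
      valid = cv$valid && !is.null(fit),
      stringsAsFactors = FALSE)
  }
  cve_table <- do.call(rbind, rows)
  topK <- rank_models(cve_table, K)
  counts <- selection_frequency(topK, N, names = data$names)
  wd <- build_weight_diagram(topK, data)
  best_fit <- fit_ols(data, topK$mask[1])
  structure(list(cve_table = cve_table, topK = topK,
                 selection_counts = counts, weight_diagram = wd,
                 best_fit = best_fit, electrode = data$electrode,
                 n = length(data$y), N = N),
            class = "es_search")
}

#' @export
print.es_search <- function(x, ...) {
  cat(sprintf("<es_search> %s: %d models over %d indicators, n=%d\n",
              x$electrode, nrow(x$cve_table), x$N, x$n))
  cat(sprintf("  best model (CVE %.3f): %s\n", x$topK$cve[1],
              x$topK$variables[1]))
  cat("  selection counts in top-", nrow(x$topK), ":\n", sep = "")
  print(sort(x$selection_counts, decreasing = TRUE))
  invisible(x)
}
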