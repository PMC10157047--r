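# Internal helpers: argument checking, seeded evaluation, small numerics.

abort_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("erpselect_input_error", "error")))
}

assert_that_ <- function(cond, ...) {
  if (!isTRUE(cond)) abort_input(...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 1
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# stream; seed = NULL uses the current stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_that_(is_count(abs(seed) + 1), "seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic substream derivation (Lehmer step), kept inside 32-bit range
# so derived seeds are valid arguments to set.seed().
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(index) * 9973) %% 2147483647)
}

# Time axis of an epoch window [from, to) in ms on the sampling grid.
epoch_time_ms <- function(fs, window = c(-200, 600)) {
  step <- 1000 / fs
  i0 <- round(window[1] / step)
  i1 <- round(window[2] / step) - 1
  (i0:i1) * step
}

# 1/f-shaped ("pink") noise: white Gaussian noise whose spectrum is scaled by
# 1/sqrt(f), renormalized to the requested standard deviation.
pink_noise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  m <- stats::nextn(n)      # highly composite length keeps the FFT O(m log m)
  # Draw the spectrum directly (complex white noise scaled by 1/sqrt(f)); the
  # real part of its inverse transform is a Gaussian series with the target
  # spectral shape, for one FFT instead of two.
  f <- c(1, pmin(1:(m - 1), m - 1:(m - 1)))
  spec <- complex(real = rnorm(m), imaginary = rnorm(m)) / sqrt(f)
  spec[1] <- 0
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)] / m
  x * (sd / stats::sd(x))
}

peak_to_peak <- function(x) max(x) - min(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
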