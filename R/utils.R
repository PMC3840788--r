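#' @importFrom stats fft mvfft rnorm runif var sd quantile
#' @importFrom utils head tail write.table read.table
NULL

# Run code with a private RNG state so generators are pure in (args, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Unnormalized FFT sample frequencies in cycles per unit, matching the
# layout of stats::fft output (DC first, negative frequencies in the
# upper half). `d` is the sample spacing.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_septomo <- function(...) stop(..., call. = FALSE)

# Local maxima of a 1d profile above min_frac * max, with parabolic
# sub-sample refinement.  Returns positions (fractional indices) and values.
find_peaks_1d <- function(p, min_frac = 0.2, min_separation = 1) {
  n <- length(p)
  if (n < 3) return(data.frame(pos = numeric(0), value = numeric(0)))
  thr <- min_frac * max(p)
  idx <- which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n]) + 1L
  idx <- idx[p[idx] >= thr]
  if (length(idx) == 0) return(data.frame(pos = numeric(0), value = numeric(0)))
  # parabolic refinement around each maximum
  refine <- function(i) {
    y1 <- p[i - 1]; y2 <- p[i]; y3 <- p[i + 1]
    denom <- (y1 - 2 * y2 + y3)
    delta <- if (abs(denom) > .Machine$double.eps) 0.5 * (y1 - y3) / denom else 0
    i + max(-0.5, min(0.5, delta))
  }
  pos <- vapply(idx, refine, numeric(1))
  val <- p[idx]
  # enforce minimum separation, keeping the higher peak
  ord <- order(val, decreasing = TRUE)
  keep <- logical(length(idx))
  taken <- numeric(0)
  for (i in ord) {
    if (all(abs(pos[i] - taken) >= min_separation)) {
      keep[i] <- TRUE
      taken <- c(taken, pos[i])
    }
  }
  out <- data.frame(pos = pos[keep], value = val[keep])
  out[order(out$pos), , drop = FALSE]
}
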