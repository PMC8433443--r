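#' @importFrom stats fft rpois dnorm lm coef confint median quantile sd runmed setNames
#' @importFrom utils modifyList head tail read.table write.table
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

# Circular shift of a vector by a possibly fractional number of bins
# (positive = shift right/later). Fractional part is linearly interpolated,
# which keeps the result nonnegative for nonnegative input.
circ_shift <- function(v, bins) {
  n <- length(v)
  k <- floor(bins)
  f <- bins - k
  i0 <- ((seq_len(n) - 1L - k) %% n) + 1L
  if (f == 0) return(v[i0])
  i1 <- ((seq_len(n) - 1L - k - 1L) %% n) + 1L
  (1 - f) * v[i0] + f * v[i1]
}

# Circular (periodic) convolution of two equal-length vectors via FFT.
circ_convolve <- function(a, b) {
  n <- length(a)
  if (length(b) != n) stopf("circular convolution requires equal lengths (%d vs %d)", n, length(b))
  Re(fft(fft(a) * fft(b), inverse = TRUE)) / n
}

#' Measure the full width at half maximum of a sampled curve
#'
#' Locates the global maximum and the two half-maximum crossings by linear
#' interpolation between samples; the width is the distance between the
#' crossings on the time axis.
#'
#' @param values numeric vector of nonnegative samples.
#' @param bin_width spacing of the samples (same unit as the returned width).
#' @return width at half maximum, in units of `bin_width`.
#' @export
measure_fwhm <- function(values, bin_width = 1) {
  n <- length(values)
  if (n < 3L) stopf("need at least 3 samples to measure a FWHM")
  imax <- which.max(values)
  half <- values[imax] / 2
  # left crossing
  il <- imax
  while (il > 1L && values[il - 1L] > half) il <- il - 1L
  if (il == 1L) stopf("left half-maximum crossing lies outside the sampled window")
  xl <- (il - 2) + (half - values[il - 1L]) / (values[il] - values[il - 1L])
  # right crossing
  ir <- imax
  while (ir < n && values[ir + 1L] > half) ir <- ir + 1L
  if (ir == n) stopf("right half-maximum crossing lies outside the sampled window")
  xr <- (ir - 1) + (values[ir] - half) / (values[ir] - values[ir + 1L])
  (xr - xl) * bin_width
}
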