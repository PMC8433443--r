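#' Instrument response kernel
#'
#' A discrete instrument response function (IRF) sampled on the TCSPC time
#' grid. The kernel has unit area so that convolving it with a decay model
#' conserves photons. Use [make_irf()] for the usual Gaussian parameterization
#' or this constructor for a measured kernel.
#'
#' @param values nonnegative kernel samples, one per time bin (renormalized to
#'   unit sum).
#' @param bin_width time bin width in ps.
#' @param center nominal center position of the kernel in ps (defaults to the
#'   first-moment of the samples).
#' @param fwhm nominal width in ps (defaults to the numerically measured FWHM,
#'   `NA` for degenerate kernels such as a delta).
#' @return an object of class `irf_kernel` with fields `values`, `bin_width`,
#'   `center` and `fwhm`.
#' @export
irf_kernel <- function(values, bin_width, center = NULL, fwhm = NULL) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) stopf("IRF samples must be finite and nonnegative")
  s <- sum(values)
  if (s <= 0) stopf("IRF must have positive total area")
  values <- values / s
  if (!is.numeric(bin_width) || bin_width <= 0) stopf("bin_width must be a positive number of ps")
  t <- (seq_along(values) - 0.5) * bin_width
  if (is.null(center)) center <- sum(t * values)
  if (is.null(fwhm)) fwhm <- tryCatch(measure_fwhm(values, bin_width), error = function(e) NA_real_)
  structure(list(values = values, bin_width = bin_width, center = center, fwhm = fwhm),
            class = "irf_kernel")
}

#' Gaussian instrument response kernel
#'
#' Builds a Gaussian IRF of the requested full width at half maximum, sampled
#' at the centers of the TCSPC time bins, truncated to the acquisition window
#' and renormalized to unit area. The measured FWHM of the returned kernel
#' matches the request within one bin width (sampling resolution).
#'
#' @param fwhm full width at half maximum in ps (e.g. 100 ps for a fast hybrid
#'   detector).
#' @param bin_width time bin width in ps.
#' @param n_bins number of time bins in the acquisition window.
#' @param center position of the Gaussian peak in ps, within
#'   `[0, n_bins * bin_width]`.
#' @return an [irf_kernel()] object.
#' @examples
#' irf <- make_irf(fwhm = 100, bin_width = 12500 / 256, n_bins = 256, center = 1000)
#' measure_fwhm(irf$values, irf$bin_width)
#' @export
make_irf <- function(fwhm = 100, bin_width = 12500 / 256, n_bins = 256L, center = 1000) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0) stopf("fwhm must be a positive number of ps")
  if (fwhm < bin_width / 2)
    stopf("IRF fwhm (%g ps) is not resolvable on a %g ps grid (needs fwhm >= bin_width/2)", fwhm, bin_width)
  if (!is_count(n_bins) || n_bins < 16) stopf("n_bins must be an integer >= 16")
  window <- n_bins * bin_width
  if (center < 0 || center > window) stopf("center (%g ps) outside acquisition window [0, %g] ps", center, window)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  t <- (seq_len(n_bins) - 0.5) * bin_width
  v <- dnorm(t, mean = center, sd = sigma)
  if (sum(v) <= 0) stopf("IRF truncated to zero within the window; move center inside the window")
  irf_kernel(v, bin_width, center = center, fwhm = fwhm)
}

# Delta ("ideal") IRF concentrated in one bin; used for tests and for fitting
# data that were already deconvolved.
#' @rdname make_irf
#' @param bin index of the bin carrying the delta impulse.
#' @export
delta_irf <- function(n_bins, bin_width, bin = 1L) {
  v <- numeric(n_bins)
  v[bin] <- 1
  irf_kernel(v, bin_width, center = (bin - 0.5) * bin_width, fwhm = NA_real_)
}

#' @export
print.irf_kernel <- function(x, ...) {
  cat(sprintf("IRF kernel: %d bins x %.3g ps, center %.3g ps, FWHM %.3g ps\n",
              length(x$values), x$bin_width, x$center, x$fwhm))
  invisible(x)
}
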