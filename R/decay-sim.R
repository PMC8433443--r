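#' TCSPC acquisition settings
#'
#' @param n_bins number of time bins (>= 16); default 256.
#' @param period laser repetition window in ns; default 12.5 ns (80 MHz
#'   Ti:Sapphire convention).
#' @param total_photons expected total photon count of the histogram.
#' @param seed integer RNG seed for the Poisson draw.
#' @return an object of class `acquisition`.
#' @export
acquisition <- function(n_bins = 256L, period = 12.5, total_photons = 1e6, seed = 1L) {
  if (!is_count(n_bins) || n_bins < 16) stopf("n_bins must be an integer >= 16")
  if (!is.numeric(period) || period <= 0) stopf("period must be > 0 ns")
  if (!is_count(total_photons)) stopf("total_photons must be a nonnegative integer")
  structure(list(n_bins = as.integer(n_bins), period = period,
                 total_photons = total_photons, seed = as.integer(seed)),
            class = "acquisition")
}

#' TCSPC decay histogram
#'
#' Binned photon arrival counts over one laser period. The time axis is bin
#' left edges in ps, starting at `t0` (0 at the acquisition-window start).
#'
#' @param counts nonnegative integer counts per bin.
#' @param bin_width bin width in ps.
#' @param t0 time of the first bin edge in ps.
#' @param metadata named list of free-form metadata (seed, truth, ...).
#' @return an object of class `decay_histogram`.
#' @export
decay_histogram <- function(counts, bin_width, t0 = 0, metadata = list()) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) stopf("counts must be finite and nonnegative")
  if (!is.numeric(bin_width) || bin_width <= 0) stopf("bin_width must be > 0 ps")
  structure(list(counts = counts, bin_width = bin_width, t0 = t0, metadata = metadata),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("TCSPC histogram: %d bins x %.3g ps, %.0f photons\n",
              length(x$counts), x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Simulate a TCSPC decay histogram
#'
#' Draws per-bin Poisson counts around the expected IRF-convolved decay
#' (see [model_decay()]). With zero baseline the expected total equals
#' `acq$total_photons`; the realized total fluctuates by counting noise.
#' The draw is reproducible: a fixed `acq$seed` fixes every count.
#'
#' @param params a [decay_params()] ground-truth decay.
#' @param irf an [irf_kernel()] with `acq$n_bins` bins.
#' @param acq an [acquisition()] object.
#' @return a [decay_histogram()] whose metadata records the truth, seed and
#'   expected curve.
#' @export
simulate_decay <- function(params, irf, acq) {
  stopifnot(inherits(params, "decay_params"), inherits(irf, "irf_kernel"),
            inherits(acq, "acquisition"))
  if (length(irf$values) != acq$n_bins)
    stopf("IRF has %d bins but acquisition expects %d", length(irf$values), acq$n_bins)
  bin_width <- acq$period * 1000 / acq$n_bins
  if (abs(bin_width - irf$bin_width) > 1e-6 * bin_width)
    stopf("IRF bin width (%g ps) does not match acquisition bin width (%g ps)", irf$bin_width, bin_width)
  expected <- model_decay(params, irf, n_photons = acq$total_photons)
  counts <- with_seed(acq$seed, rpois(acq$n_bins, expected))
  decay_histogram(counts, bin_width = bin_width, t0 = 0,
                  metadata = list(truth = params, seed = acq$seed,
                                  total_photons = acq$total_photons,
                                  expected = expected, irf_fwhm = irf$fwhm))
}
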