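#' Multi-exponential decay model parameters
#'
#' Parameters of a mono- or bi-exponential fluorescence decay: amplitude
#' fractions `a_i` (summing to one), component lifetimes `tau_i` in ns, and a
#' constant baseline in counts per bin. Components are stored in canonical
#' order `tau_1 <= tau_2`.
#'
#' Amplitudes are decay amplitudes at t = 0, not photon (intensity) fractions;
#' the photon fraction of component i is `a_i tau_i / sum(a_j tau_j)` and is
#' reported by [intensity_fractions()].
#'
#' @param amplitudes nonnegative amplitude fractions, length 1 or 2; rescaled
#'   to sum to one.
#' @param lifetimes component lifetimes in ns, same length, all positive.
#' @param baseline constant background level in counts per bin, >= 0.
#' @return an object of class `decay_params`.
#' @export
decay_params <- function(amplitudes, lifetimes, baseline = 0) {
  amplitudes <- as.numeric(amplitudes)
  lifetimes <- as.numeric(lifetimes)
  k <- length(lifetimes)
  if (!k %in% c(1L, 2L)) stopf("only mono- and bi-exponential models are supported (got %d components)", k)
  if (length(amplitudes) != k) stopf("amplitudes and lifetimes must have the same length")
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0)) stopf("lifetimes must be positive (ns)")
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) stopf("amplitudes must be nonnegative")
  s <- sum(amplitudes)
  if (s <= 0) stopf("at least one amplitude must be positive")
  amplitudes <- amplitudes / s
  if (!is.numeric(baseline) || baseline < 0) stopf("baseline must be >= 0 counts/bin")
  o <- order(lifetimes)
  structure(list(amplitudes = amplitudes[o], lifetimes = lifetimes[o], baseline = baseline),
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  k <- length(x$lifetimes)
  cat(sprintf("%s-exponential decay:\n", if (k == 1L) "mono" else "bi"))
  for (i in seq_len(k))
    cat(sprintf("  a_%d = %.4f  tau_%d = %.4g ns\n", i, x$amplitudes[i], i, x$lifetimes[i]))
  cat(sprintf("  baseline = %.4g counts/bin\n", x$baseline))
  invisible(x)
}

#' Fluoro-Gold-like and lipofuscin-like default decays
#'
#' `fg_decay()` returns the two-component decay of the hydroxystilbamidine
#' tracer: a fast component at 0.1 ns and a slow component at 2.3 ns, with the
#' amplitude split chosen so the intensity-weighted mean lifetime is 1.4 ns
#' (see [amplitude_for_mean_lifetime()]). `background_decay()` returns the
#' mono-exponential 1.35 ns lipofuscin-like tissue autofluorescence.
#'
#' @param tau1,tau2 component lifetimes in ns.
#' @param mean_lifetime target intensity-weighted mean lifetime in ns used to
#'   solve for the amplitude split.
#' @param baseline constant background counts per bin.
#' @return a [decay_params()] object.
#' @export
fg_decay <- function(tau1 = 0.1, tau2 = 2.3, mean_lifetime = 1.4, baseline = 0) {
  a1 <- amplitude_for_mean_lifetime(mean_lifetime, tau1, tau2, mode = "intensity")
  decay_params(c(a1, 1 - a1), c(tau1, tau2), baseline = baseline)
}

#' @rdname fg_decay
#' @param tau background lifetime in ns.
#' @export
background_decay <- function(tau = 1.35, baseline = 0) {
  decay_params(1, tau, baseline = baseline)
}

#' Summary lifetime of a multi-exponential decay
#'
#' Amplitude-weighted mean: `sum(a_i tau_i) / sum(a_i)`. Intensity-weighted
#' mean: `sum(a_i tau_i^2) / sum(a_i tau_i)`. Both lie between the extreme
#' component lifetimes. The intensity-weighted form is what a per-pixel
#' "apparent lifetime" map reports by default, since it weights each component
#' by the photons it contributes.
#'
#' @param params a [decay_params()] object.
#' @param mode `"intensity"` (default) or `"amplitude"`.
#' @return mean lifetime in ns.
#' @examples
#' mean_lifetime(decay_params(c(.5, .5), c(1, 3)), "amplitude") # 2.0
#' mean_lifetime(decay_params(c(.5, .5), c(1, 3)), "intensity") # 2.5
#' @export
mean_lifetime <- function(params, mode = c("intensity", "amplitude")) {
  mode <- match.arg(mode)
  a <- params$amplitudes
  tau <- params$lifetimes
  if (mode == "amplitude") sum(a * tau) / sum(a) else sum(a * tau^2) / sum(a * tau)
}

#' Solve the two-component amplitude split for a target mean lifetime
#'
#' Given component lifetimes `tau1 < tau2`, returns the amplitude fraction
#' `a_1` such that the weighted mean lifetime equals `mean`. The
#' intensity-weighted mean is linear in `a_1`, so the solution is closed-form.
#'
#' @param mean target mean lifetime in ns, strictly between `tau1` and `tau2`.
#' @param tau1,tau2 component lifetimes in ns.
#' @param mode weighting convention, as in [mean_lifetime()].
#' @return the amplitude fraction `a_1` of the short component.
#' @export
amplitude_for_mean_lifetime <- function(mean, tau1, tau2, mode = c("intensity", "amplitude")) {
  mode <- match.arg(mode)
  if (!(mean > min(tau1, tau2) && mean < max(tau1, tau2)))
    stopf("target mean %.4g ns must lie strictly between the component lifetimes", mean)
  if (mode == "amplitude") {
    (tau2 - mean) / (tau2 - tau1)
  } else {
    (tau2^2 - mean * tau2) / (mean * (tau1 - tau2) - tau1^2 + tau2^2)
  }
}

#' Photon (intensity) fractions of the decay components
#'
#' @param params a [decay_params()] object.
#' @return numeric vector `a_i tau_i / sum(a_j tau_j)`.
#' @export
intensity_fractions <- function(params) {
  w <- params$amplitudes * params$lifetimes
  w / sum(w)
}

# Periodic multi-exponential decay sampled at bin centers, unit sum.
# Pulsed excitation at an 80 MHz-class repetition rate leaves the tail of a
# long-lifetime component in the next period; the steady-state periodic decay
# of component i is exp(-t/tau_i) / (1 - exp(-T/tau_i)) over one period T.
periodic_decay_curve <- function(params, n_bins, bin_width) {
  t <- (seq_len(n_bins) - 0.5) * bin_width        # ps
  period <- n_bins * bin_width                    # ps
  d <- numeric(n_bins)
  for (i in seq_along(params$lifetimes)) {
    tau_ps <- params$lifetimes[i] * 1000
    d <- d + params$amplitudes[i] * exp(-t / tau_ps) / (1 - exp(-period / tau_ps))
  }
  d / sum(d)
}

#' Expected TCSPC counts under an IRF-convolved decay model
#'
#' Computes the periodic (wrap-around) convolution of the normalized
#' multi-exponential decay with the instrument response, shifted by `shift`
#' ps, scaled to `n_photons` photons, plus the model baseline. The total over
#' one period equals `n_photons + n_bins * baseline` to numerical precision
#' (photon conservation).
#'
#' @param params a [decay_params()] object (canonical order `tau_1 <= tau_2`).
#' @param irf an [irf_kernel()] with as many bins as the histogram.
#' @param n_photons expected total photon count over the period.
#' @param shift temporal shift of the IRF in ps (the TCSPC "color shift"
#'   nuisance); positive shifts move the response later.
#' @return numeric vector of expected counts per bin.
#' @export
model_decay <- function(params, irf, n_photons, shift = 0) {
  stopifnot(inherits(params, "decay_params"), inherits(irf, "irf_kernel"))
  n <- length(irf$values)
  d <- periodic_decay_curve(params, n, irf$bin_width)
  kern <- if (shift != 0) circ_shift(irf$values, shift / irf$bin_width) else irf$values
  conv <- circ_convolve(d, kern)
  conv <- pmax(conv, 0)
  conv <- conv / sum(conv)
  n_photons * conv + params$baseline
}
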