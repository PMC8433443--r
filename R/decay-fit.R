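#' Options for TCSPC decay fitting
#'
#' @param weighting `"pearson"` (weighted least squares with weights
#'   `1/max(expected, 1)`, the default and the convention of commercial TCSPC
#'   software) or `"mle"` (Poisson maximum likelihood via the deviance).
#' @param min_counts minimum total counts required to attempt a fit.
#' @param fit_shift whether the IRF temporal shift ("color shift") is a free
#'   nuisance parameter.
#' @param shift_bounds_bins symmetric bound on the shift, in bins.
#' @param fit_baseline whether a constant baseline is fitted.
#' @param tau_bounds lower/upper bounds on lifetimes in ns.
#' @param chi2_floor bins with expected counts below this floor are excluded
#'   from the reduced chi-squared (avoids divide-by-near-zero).
#' @param tau_equal_tol relative tolerance under which a two-component fit is
#'   declared unidentifiable (`tau_1 ~ tau_2`) and collapsed to a mono fit.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @param init optional named list overriding initial values
#'   (`tau1`, `tau2`, `a1`, `baseline`, `shift`).
#' @return a list of class `fit_opts`.
#' @export
fit_opts <- function(weighting = c("pearson", "mle"), min_counts = 1000,
                     fit_shift = TRUE, shift_bounds_bins = 5,
                     fit_baseline = TRUE, tau_bounds = c(1e-3, 50),
                     chi2_floor = 1, tau_equal_tol = 0.05,
                     maxiter = 200, init = list()) {
  structure(list(weighting = match.arg(weighting), min_counts = min_counts,
                 fit_shift = fit_shift, shift_bounds_bins = shift_bounds_bins,
                 fit_baseline = fit_baseline, tau_bounds = tau_bounds,
                 chi2_floor = chi2_floor, tau_equal_tol = tau_equal_tol,
                 maxiter = maxiter, init = init),
            class = "fit_opts")
}

#' Reduced chi-squared of a fit
#'
#' `sum((obs - exp)^2 / max(exp, eps)) / n_free`, where bins with expected
#' counts below `floor` are excluded and `eps = 1e-12` guards the division.
#' For a correctly specified model with Poisson noise and adequate counts the
#' expectation is close to 1.
#'
#' @param observed,expected count vectors of equal length.
#' @param n_free degrees of freedom (used bins minus free parameters).
#' @param floor expected-count floor below which bins are excluded.
#' @return nonnegative scalar.
#' @export
reduced_chi_squared <- function(observed, expected, n_free, floor = 1) {
  if (length(observed) != length(expected)) stopf("observed and expected lengths differ")
  use <- expected >= floor
  if (!any(use) || n_free <= 0) return(NA_real_)
  sum((observed[use] - expected[use])^2 / pmax(expected[use], 1e-12)) / n_free
}

# --- initialization -------------------------------------------------------

# Tail log-slope estimate of the long lifetime; two-point amplitude solve for
# the short/long split. All heuristic, clamped, and overridable via opts$init.
init_decay_fit <- function(counts, bin_width, model) {
  n <- length(counts)
  sm <- runmed(counts, k = min(2 * (n %/% 20) + 1, 9))
  baseline0 <- max(0, min(sm))
  ipeak <- which.max(sm)
  # tail window: from well past the peak to 95% of the period
  i1 <- min(n - 2L, ipeak + max(3L, n %/% 8))
  i2 <- max(i1 + 3L, floor(0.95 * n))
  idx <- i1:min(i2, n)
  y <- pmax(counts[idx] - baseline0, 0.5)
  t <- (idx - 0.5) * bin_width
  fitl <- lm(log(y) ~ t)
  slope <- coef(fitl)[2]
  tau2 <- if (is.finite(slope) && slope < -1e-9) -1 / slope / 1000 else 20  # ns
  tau2 <- min(max(tau2, 0.2), 20)
  if (model == "mono")
    return(list(tau2 = tau2, baseline = baseline0))
  tau1 <- 0.05
  # extrapolate the tail component back to the peak; the excess is the fast one
  A2_peak <- exp(coef(fitl)[1] + slope * (ipeak - 0.5) * bin_width)
  peak <- max(counts[ipeak] - baseline0, 1)
  short_amp <- max(peak - A2_peak, 0.02 * peak)
  a1 <- min(max(short_amp / (short_amp + max(A2_peak, 1e-9)), 0.01), 0.99)
  list(tau1 = tau1, tau2 = tau2, a1 = unname(a1), baseline = baseline0)
}

# --- engine ---------------------------------------------------------------

fit_decay_engine <- function(hist, irf, model = c("biexp", "mono"), opts = fit_opts()) {
  model <- match.arg(model)
  stopifnot(inherits(hist, "decay_histogram"), inherits(irf, "irf_kernel"))
  counts <- hist$counts
  n <- length(counts)
  if (length(irf$values) != n) stopf("IRF has %d bins, histogram has %d", length(irf$values), n)
  if (sum(counts) < opts$min_counts)
    stopf("histogram has %.0f counts, below the minimum of %g", sum(counts), opts$min_counts)
  bw <- hist$bin_width

  init <- modifyList(init_decay_fit(counts, bw, model), opts$init)
  N0 <- max(sum(counts) - n * init$baseline, 1)
  smax <- opts$shift_bounds_bins * bw

  # parameter vector layout: [a1] tau1? tau2 N [shift] [baseline]
  if (model == "biexp") {
    par <- c(a1 = init$a1, tau1 = init$tau1, tau2 = init$tau2, N = N0)
    lower <- c(0, opts$tau_bounds[1], opts$tau_bounds[1], 1e-3)
    upper <- c(1, opts$tau_bounds[2], opts$tau_bounds[2], Inf)
  } else {
    par <- c(tau = init$tau2, N = N0)
    lower <- c(opts$tau_bounds[1], 1e-3)
    upper <- c(opts$tau_bounds[2], Inf)
  }
  if (opts$fit_shift) { par <- c(par, shift = 0); lower <- c(lower, -smax); upper <- c(upper, smax) }
  if (opts$fit_baseline) { par <- c(par, baseline = init$baseline); lower <- c(lower, 0); upper <- c(upper, Inf) }

  expected_of <- function(p) {
    if (model == "biexp") {
      prm <- list(amplitudes = c(p[["a1"]], 1 - p[["a1"]]),
                  lifetimes = c(p[["tau1"]], p[["tau2"]]),
                  baseline = if (opts$fit_baseline) p[["baseline"]] else 0)
      # keep optimizer coordinates unsorted; sort only inside the curve
      o <- order(prm$lifetimes)
      prm$amplitudes <- prm$amplitudes[o]; prm$lifetimes <- prm$lifetimes[o]
    } else {
      prm <- list(amplitudes = 1, lifetimes = p[["tau"]],
                  baseline = if (opts$fit_baseline) p[["baseline"]] else 0)
    }
    class(prm) <- "decay_params"
    model_decay(prm, irf, n_photons = p[["N"]],
                shift = if (opts$fit_shift) p[["shift"]] else 0)
  }

  resid_fn <- function(p) {
    names(p) <- names(par)
    e <- expected_of(p)
    (counts - e) / sqrt(pmax(e, 1))
  }

  if (opts$weighting == "pearson") {
    fit <- minpack.lm::nls.lm(par = par, lower = lower, upper = upper, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = opts$maxiter, ftol = 1e-13, ptol = 1e-13))
    p <- unlist(fit$par)
    names(p) <- names(par)
    # info 5 (maxfev) with an essentially zero sum of squares is a perfect
    # fit that never triggered the relative-reduction stopping rule
    converged <- fit$info %in% c(1, 2, 3, 4) ||
      fit$deviance < 1e-6 * length(counts)
    hess <- fit$hessian
  } else {
    dev_fn <- function(p) {
      names(p) <- names(par)
      e <- pmax(expected_of(p), 1e-12)
      o <- counts
      2 * sum(e - o + ifelse(o > 0, o * log(o / e), 0))
    }
    of <- stats::optim(par, dev_fn, method = "L-BFGS-B", lower = lower,
                       upper = pmin(upper, 1e12),
                       control = list(maxit = opts$maxiter * 5, factr = 1e4))
    p <- of$par; names(p) <- names(par)
    converged <- of$convergence == 0
    hess <- NULL
  }

  baseline <- if (opts$fit_baseline) unname(p[["baseline"]]) else 0
  shift <- if (opts$fit_shift) unname(p[["shift"]]) else 0
  meta <- list(model = model, weighting = opts$weighting, warnings = character(0))

  if (model == "biexp") {
    a <- c(p[["a1"]], 1 - p[["a1"]]); tau <- c(p[["tau1"]], p[["tau2"]])
    if (tau[1] > tau[2]) { tau <- rev(tau); a <- rev(a) }  # canonicalize
    # unidentifiable two-component fit (coincident lifetimes, or one
    # component with negligible amplitude): collapse to mono, with a warning
    if (abs(tau[2] - tau[1]) / tau[2] < opts$tau_equal_tol || min(a) < 1e-4) {
      mono <- fit_decay_engine(hist, irf, "mono", opts)
      mono$metadata$warnings <- c(mono$metadata$warnings,
        if (min(a) < 1e-4)
          sprintf("biexponential fit unidentifiable (component amplitude %.2g); collapsed to mono", min(a))
        else
          sprintf("biexponential fit unidentifiable (tau1 ~ tau2 ~ %.3g ns); collapsed to mono", tau[2]))
      mono$metadata$collapsed_from_biexp <- TRUE
      return(mono)
    }
    params <- decay_params(a, tau, baseline = baseline)
  } else {
    params <- decay_params(1, p[["tau"]], baseline = baseline)
  }

  at_bound <- any(abs(params$lifetimes - opts$tau_bounds[1]) < 1e-9) ||
              any(abs(params$lifetimes - opts$tau_bounds[2]) < 1e-9)
  if (at_bound) {
    meta$warnings <- c(meta$warnings, "fitted lifetime at a bound; fit unreliable")
    converged <- FALSE
  }
  meta$at_bound <- at_bound

  # lifetimes well beyond the excitation period make the periodic model
  # nearly flat and the lifetime poorly identifiable
  period_ns <- n * bw / 1000
  if (any(params$lifetimes > period_ns))
    meta$warnings <- c(meta$warnings, sprintf(
      "fitted lifetime exceeds the %.3g ns excitation period; poorly identifiable", period_ns))

  expected <- expected_of(p)
  used <- expected >= opts$chi2_floor
  n_par <- length(par)
  n_free <- sum(used) - n_par
  chi2 <- reduced_chi_squared(counts, expected, n_free, floor = opts$chi2_floor)
  residuals <- (counts - expected) / sqrt(pmax(expected, 1))

  covariance <- NULL
  if (!is.null(hess)) {
    s2 <- sum(residuals[used]^2) / max(n_free, 1)
    covariance <- tryCatch(solve(hess) * s2, error = function(e) NULL)
    if (!is.null(covariance)) dimnames(covariance) <- list(names(par), names(par))
  }
  meta$intensity_fractions <- intensity_fractions(params)
  meta$n_photons_fit <- unname(p[["N"]])

  structure(list(params = params, irf_shift = shift, chi2_reduced = chi2,
                 residuals = residuals, n_free = n_free, converged = converged,
                 covariance = covariance, expected = expected, metadata = meta),
            class = "decay_fit")
}

#' Fit a mono-exponential IRF-convolved decay
#'
#' Weighted least-squares (default) or Poisson-MLE fit of a single-lifetime
#' decay convolved with the instrument response, with free photon count,
#' optional free baseline and IRF color shift.
#'
#' @param hist a [decay_histogram()].
#' @param irf an [irf_kernel()] with the same number of bins.
#' @param opts a [fit_opts()] list.
#' @return an object of class `decay_fit` with fields `params`
#'   ([decay_params()]), `irf_shift` (ps), `chi2_reduced`, `residuals`
#'   (Poisson-weighted, one per bin), `n_free`, `converged`, `covariance` and
#'   `metadata` (warnings, intensity fractions, fitted photon count).
#' @export
fit_monoexponential <- function(hist, irf, opts = fit_opts()) {
  fit_decay_engine(hist, irf, "mono", opts)
}

#' Fit a bi-exponential IRF-convolved decay
#'
#' As [fit_monoexponential()], with two lifetime components in canonical order
#' `tau_1 <= tau_2`. If the two fitted lifetimes agree within
#' `opts$tau_equal_tol` the fit is unidentifiable and collapses to the mono
#' model, recorded in `metadata$warnings`.
#'
#' @inheritParams fit_monoexponential
#' @return an object of class `decay_fit`; see [fit_monoexponential()].
#' @export
fit_biexponential <- function(hist, irf, opts = fit_opts()) {
  fit_decay_engine(hist, irf, "biexp", opts)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Decay fit (%s, %s weighting): %s\n", x$metadata$model, x$metadata$weighting,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  cat(sprintf("  mean lifetime (intensity) = %.4g ns\n", mean_lifetime(x$params)))
  cat(sprintf("  IRF shift = %.3g ps, reduced chi^2 = %.3f (df %d)\n",
              x$irf_shift, x$chi2_reduced, x$n_free))
  for (w in x$metadata$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
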