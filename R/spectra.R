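#' Wavelength-indexed fluorescence series
#'
#' A fluorescence measurement series over a strictly increasing wavelength
#' grid, optionally with the per-wavelength average laser power and a
#' background series in the same units.
#'
#' @param wavelengths wavelengths in nm, strictly increasing.
#' @param intensity fluorescence intensity F(lambda), arbitrary units.
#' @param power optional average laser power P(lambda), mW.
#' @param background optional background series B(lambda), same units as F.
#' @param metadata named list.
#' @return an object of class `spectral_series`.
#' @export
spectral_series <- function(wavelengths, intensity, power = NULL,
                            background = NULL, metadata = list()) {
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) stopf("wavelengths must be strictly increasing and unique")
  n <- length(wavelengths)
  if (length(intensity) != n) stopf("intensity length != wavelength length")
  if (!is.null(power) && length(power) != n) stopf("power length != wavelength length")
  if (!is.null(background) && length(background) != n) stopf("background length != wavelength length")
  structure(list(wavelengths = wavelengths, intensity = as.numeric(intensity),
                 power = if (is.null(power)) NULL else as.numeric(power),
                 background = if (is.null(background)) NULL else as.numeric(background),
                 metadata = metadata),
            class = "spectral_series")
}

#' Relative two-photon cross-section curve
#'
#' @param wavelengths wavelengths in nm, strictly increasing.
#' @param sigma relative two-photon cross-sections (arbitrary but
#'   self-consistent scale), >= 0 where defined.
#' @param metadata named list.
#' @return an object of class `cross_section_curve`.
#' @export
cross_section_curve <- function(wavelengths, sigma, metadata = list()) {
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) stopf("wavelengths must be strictly increasing and unique")
  sigma <- as.numeric(sigma)
  if (length(sigma) != length(wavelengths)) stopf("sigma length != wavelength length")
  if (any(sigma[is.finite(sigma)] < 0)) stopf("sigma must be >= 0")
  structure(list(wavelengths = wavelengths, sigma = sigma, metadata = metadata),
            class = "cross_section_curve")
}

check_same_grid <- function(w1, w2) {
  if (length(w1) != length(w2) || any(abs(w1 - w2) > 1e-9))
    stopf("wavelength grids differ; measure both series on one grid (no silent resampling)")
}

#' Normalize fluorescence by laser power
#'
#' Two-photon signal scales with the square of excitation power, so the
#' default removes P(lambda)^2; exponent 1 is available for one-photon-style
#' normalization.
#'
#' @param s a [spectral_series()] with power present and > 0 everywhere.
#' @param exponent power-law exponent (default 2).
#' @return a [spectral_series()] with `intensity = F / P^exponent`; the
#'   exponent is recorded in the metadata and the power set to 1.
#' @export
normalize_by_power <- function(s, exponent = 2) {
  stopifnot(inherits(s, "spectral_series"))
  if (is.null(s$power)) stopf("series has no power record")
  if (any(s$power <= 0)) stopf("power must be > 0 at every wavelength")
  meta <- modifyList(s$metadata, list(power_exponent = exponent))
  spectral_series(s$wavelengths, s$intensity / s$power^exponent,
                  power = rep(1, length(s$power)), background = s$background,
                  metadata = meta)
}

#' Subtract a background series
#'
#' `F'(lambda) = max(F(lambda) - B(lambda), 0)`; wavelengths whose corrected
#' value ends up at zero (difference at or below zero) are flagged in
#' `metadata$floored` so downstream peak calls can exclude them.
#'
#' @param s a [spectral_series()].
#' @param b background as a [spectral_series()] on the same grid.
#' @return a background-subtracted [spectral_series()].
#' @export
background_subtract <- function(s, b) {
  stopifnot(inherits(s, "spectral_series"), inherits(b, "spectral_series"))
  check_same_grid(s$wavelengths, b$wavelengths)
  diffv <- s$intensity - b$intensity
  floored <- diffv <= 0
  meta <- modifyList(s$metadata, list(floored = floored))
  spectral_series(s$wavelengths, pmax(diffv, 0), power = s$power, metadata = meta)
}

#' Instrument correction curve from a reference dye
#'
#' With a reference dye of known relative cross-section sigma_R measured under
#' the same conditions as the sample, the per-wavelength correction is
#' `f_c(lambda) = F_R(lambda) / sigma_R(lambda)`. It absorbs everything shared
#' between the two measurements: instrument spectral response, concentration
#' and the (power-law) excitation term.
#'
#' @param F_R the reference dye's measured [spectral_series()].
#' @param sigma_R the reference dye's known [cross_section_curve()] on the
#'   same grid; wavelengths with `sigma_R = 0` are dropped and reported.
#' @return an object of class `correction_curve` with `wavelengths`, `fc` and
#'   `dropped` (wavelengths removed because `sigma_R` was zero).
#' @export
correction_curve <- function(F_R, sigma_R) {
  stopifnot(inherits(F_R, "spectral_series"), inherits(sigma_R, "cross_section_curve"))
  check_same_grid(F_R$wavelengths, sigma_R$wavelengths)
  keep <- sigma_R$sigma > 0
  structure(list(wavelengths = F_R$wavelengths[keep],
                 fc = F_R$intensity[keep] / sigma_R$sigma[keep],
                 dropped = F_R$wavelengths[!keep]),
            class = "correction_curve")
}

#' Relative two-photon cross-section of a sample dye
#'
#' `sigma_S(lambda) = F_S(lambda) / f_c(lambda) * C_R / C_S`: the sample's
#' fluorescence divided by the reference-derived correction curve, scaled by
#' the molar concentration ratio of reference to sample.
#'
#' @param F_S the sample's measured [spectral_series()] (same imaging
#'   conditions as the reference).
#' @param fc a [correction_curve()] on the same grid.
#' @param C_R,C_S molar concentrations of reference and sample, > 0.
#' @return a [cross_section_curve()].
#' @export
relative_cross_section <- function(F_S, fc, C_R, C_S) {
  stopifnot(inherits(F_S, "spectral_series"), inherits(fc, "correction_curve"))
  if (C_R <= 0 || C_S <= 0) stopf("concentrations must be > 0")
  if (length(fc$dropped) > 0) {
    keep <- !(F_S$wavelengths %in% fc$dropped)
    F_S <- spectral_series(F_S$wavelengths[keep], F_S$intensity[keep])
  }
  check_same_grid(F_S$wavelengths, fc$wavelengths)
  cross_section_curve(F_S$wavelengths, F_S$intensity / fc$fc * (C_R / C_S),
                      metadata = list(C_R = C_R, C_S = C_S))
}

#' Location of the spectral maximum
#'
#' Argmax over the sampled grid. When the maximum sits on the first or last
#' grid point, `is_boundary` is `TRUE` — the true peak may lie outside the
#' tuning range (as for a dye whose optimum is at or below the 720 nm edge).
#' Ties are broken toward the shorter wavelength and flagged.
#'
#' @param x a [cross_section_curve()] or [spectral_series()].
#' @return list `lambda_max` (nm), `value`, `is_boundary`, `tied`.
#' @export
spectral_peak <- function(x) {
  if (inherits(x, "cross_section_curve")) { w <- x$wavelengths; v <- x$sigma }
  else if (inherits(x, "spectral_series")) { w <- x$wavelengths; v <- x$intensity }
  else stopf("spectral_peak needs a spectral_series or cross_section_curve")
  ok <- is.finite(v)
  w <- w[ok]; v <- v[ok]
  if (length(v) == 0) stopf("no finite values")
  hits <- which(v == max(v))
  i <- hits[1]   # shorter wavelength wins ties (grid is increasing)
  list(lambda_max = w[i], value = v[i],
       is_boundary = i == 1L || i == length(v), tied = length(hits) > 1)
}

#' Power-law exponent of fluorescence vs excitation power
#'
#' Ordinary least squares of log F on log P. A slope of 2 confirms two-photon
#' excitation; 1 indicates a one-photon (linear) process.
#'
#' @param powers excitation powers, all > 0, at least 3 values.
#' @param intensities fluorescence intensities, all > 0.
#' @return list `slope`, `stderr`, `ci95` (length-2), `intercept`.
#' @export
power_exponent <- function(powers, intensities) {
  if (length(powers) < 3 || length(powers) != length(intensities))
    stopf("need >= 3 matched (power, intensity) pairs")
  if (any(powers <= 0) || any(intensities <= 0))
    stopf("powers and intensities must be strictly positive")
  fit <- lm(log(intensities) ~ log(powers))
  # noiseless synthetic series trigger the harmless "essentially perfect fit"
  # warning from summary.lm/confint; the zero standard error is the right answer
  muffle <- function(expr) withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  ci <- muffle(suppressMessages(confint(fit, level = 0.95)))
  list(slope = unname(coef(fit)[2]),
       stderr = unname(muffle(summary(fit))$coefficients[2, 2]),
       ci95 = unname(ci[2, ]),
       intercept = unname(coef(fit)[1]))
}
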