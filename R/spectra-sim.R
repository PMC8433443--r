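#' Simulate paired sample/reference spectral measurements
#'
#' Emulates measuring a sample dye and a reference dye over the same
#' wavelength grid (10 nm steps across 720-1000 nm by default elsewhere)
#' under identical imaging conditions:
#' `F(lambda) = instrument_factor(lambda) * sigma(lambda) * C * P(lambda)^2 * (1 + eps)`,
#' with `eps ~ Normal(0, noise_cv)` multiplicative detector-gain noise. The
#' same instrument factor and laser power apply to both dyes.
#'
#' @param true_sigma_sample,true_sigma_reference ground-truth
#'   [cross_section_curve()]s on a common grid.
#' @param C_S,C_R molar concentrations of sample and reference.
#' @param laser_power per-wavelength average power (scalar or vector), mW.
#' @param instrument_factor per-wavelength instrument response (scalar or
#'   vector).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @return list with `sample` and `reference` [spectral_series()] (power
#'   recorded on each) and `truth` (the inputs).
#' @export
simulate_spectral_series <- function(true_sigma_sample, true_sigma_reference,
                                     C_S, C_R, laser_power = 1,
                                     instrument_factor = 1,
                                     noise_cv = 0, seed = 1L) {
  stopifnot(inherits(true_sigma_sample, "cross_section_curve"),
            inherits(true_sigma_reference, "cross_section_curve"))
  w <- true_sigma_sample$wavelengths
  check_same_grid(w, true_sigma_reference$wavelengths)
  n <- length(w)
  P <- rep_len(laser_power, n)
  G <- rep_len(instrument_factor, n)
  if (any(P <= 0) || any(G <= 0)) stopf("laser_power and instrument_factor must be > 0")
  with_seed(seed, {
    eps_s <- stats::rnorm(n, 0, noise_cv)
    eps_r <- stats::rnorm(n, 0, noise_cv)
    Fs <- G * true_sigma_sample$sigma * C_S * P^2 * (1 + eps_s)
    Fr <- G * true_sigma_reference$sigma * C_R * P^2 * (1 + eps_r)
  })
  list(sample = spectral_series(w, Fs, power = P, metadata = list(seed = seed, dye = "sample")),
       reference = spectral_series(w, Fr, power = P, metadata = list(seed = seed, dye = "reference")),
       truth = list(C_S = C_S, C_R = C_R, laser_power = P, instrument_factor = G,
                    noise_cv = noise_cv))
}

#' Simulate a fluorescence-vs-power series
#'
#' `F = sigma * C * P^exponent * (1 + eps)` with multiplicative Gaussian
#' noise; exponent 2 emulates two-photon excitation, 1 a linear control.
#'
#' @param sigma cross-section scale (arbitrary units).
#' @param C concentration scale.
#' @param powers vector of excitation powers, > 0.
#' @param exponent true power-law exponent.
#' @param noise_cv coefficient of variation of the noise.
#' @param seed RNG seed.
#' @return data.frame with columns `power` and `intensity`.
#' @export
simulate_power_series <- function(sigma = 1, C = 1, powers = seq(1, 10),
                                  exponent = 2, noise_cv = 0, seed = 1L) {
  if (any(powers <= 0)) stopf("powers must be > 0")
  intensity <- with_seed(seed,
    sigma * C * powers^exponent * (1 + stats::rnorm(length(powers), 0, noise_cv)))
  data.frame(power = powers, intensity = intensity)
}
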