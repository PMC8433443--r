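grid_720_1000 <- seq(720, 1000, by = 10)

fg_like_sigma <- function(w = grid_720_1000) {
  # monotone decreasing over the tuning range: true optimum below 720 nm
  cross_section_curve(w, exp(-((w - 640) / 160)^2))
}

ref_sigma <- function(w = grid_720_1000) {
  cross_section_curve(w, 0.5 + exp(-((w - 820) / 90)^2))
}

test_that("power normalization divides out the quadratic excitation term", {
  w <- grid_720_1000
  s <- spectral_series(w, rep(8, length(w)), power = rep(1, length(w)))
  expect_equal(normalize_by_power(s)$intensity, s$intensity)

  p <- rep(1, length(w)); p[5] <- 0.5
  s2 <- spectral_series(w, rep(8, length(w)), power = p)
  out <- normalize_by_power(s2, exponent = 2)
  expect_equal(out$intensity[5], 8 * 4)
  expect_equal(out$intensity[-5], rep(8, length(w) - 1))

  expect_error(normalize_by_power(spectral_series(w, rep(1, length(w)))), "power")
  s3 <- spectral_series(w, rep(1, length(w)), power = rep(0, length(w)))
  expect_error(normalize_by_power(s3), "> 0")
})

test_that("background subtraction floors at zero, flags floored points, keeps the peak", {
  w <- grid_720_1000
  f <- 10 + dnorm(w, 800, 40) * 1000
  s <- spectral_series(w, f)
  z <- background_subtract(s, spectral_series(w, rep(0, length(w))))
  expect_equal(z$intensity, f)

  all0 <- background_subtract(s, s)
  expect_true(all(all0$intensity == 0))
  expect_true(all(all0$metadata$floored | f == 0))

  # constant background shifts values but not the argmax
  const <- background_subtract(s, spectral_series(w, rep(5, length(w))))
  expect_equal(spectral_peak(const)$lambda_max, spectral_peak(s)$lambda_max)

  expect_error(background_subtract(s, spectral_series(w + 5, f)), "grid")
})

test_that("correction curve is the reference quotient and drops zero-sigma points", {
  w <- grid_720_1000
  sig <- ref_sigma()
  FR <- spectral_series(w, sig$sigma)       # F_R == sigma_R
  fc <- correction_curve(FR, sig)
  expect_equal(fc$fc, rep(1, length(w)))

  FR2 <- spectral_series(w, rep(100, length(w)))
  sig2 <- cross_section_curve(w, rep(50, length(w)))
  expect_equal(correction_curve(FR2, sig2)$fc, rep(2, length(w)))

  sig3 <- ref_sigma(); sig3$sigma[3] <- 0
  fc3 <- correction_curve(FR, sig3)
  expect_equal(fc3$dropped, w[3])
  expect_equal(length(fc3$fc), length(w) - 1)
})

test_that("relative cross-section identities hold", {
  w <- grid_720_1000
  sig <- ref_sigma()
  FR <- spectral_series(w, 3 * sig$sigma)
  fc <- correction_curve(FR, sig)
  # applying the pipeline to the reference itself returns sigma_R exactly
  back <- relative_cross_section(FR, fc, C_R = 2, C_S = 2)
  expect_equal(back$sigma, sig$sigma, tolerance = 1e-12)

  FS <- spectral_series(w, rep(10, length(w)))
  fc2 <- structure(list(wavelengths = w, fc = rep(2, length(w)), dropped = numeric(0)),
                   class = "correction_curve")
  out <- relative_cross_section(FS, fc2, C_R = 0.01, C_S = 1)
  expect_equal(out$sigma, rep(0.05, length(w)))

  # scale equivariance: k * F_S -> k * sigma_S
  FSk <- spectral_series(w, 7 * FS$intensity)
  expect_equal(relative_cross_section(FSk, fc2, 0.01, 1)$sigma, 7 * out$sigma)
  expect_error(relative_cross_section(FS, fc2, 0, 1), "> 0")
})

test_that("generator + correction pipeline round-trips the sample cross-section", {
  w <- grid_720_1000
  truth_s <- fg_like_sigma(); truth_r <- ref_sigma()
  P <- seq(2, 3, length.out = length(w))
  G <- 1 + 0.5 * sin(w / 60)
  sim <- simulate_spectral_series(truth_s, truth_r, C_S = 0.0376, C_R = 3.76e-4,
                                  laser_power = P, instrument_factor = G,
                                  noise_cv = 0, seed = 1)
  # noiseless: F_S / F_R = (sigma_S C_S) / (sigma_R C_R) at every wavelength
  expect_equal(sim$sample$intensity / sim$reference$intensity,
               truth_s$sigma * 0.0376 / (truth_r$sigma * 3.76e-4), tolerance = 1e-12)

  fc <- correction_curve(sim$reference, truth_r)
  rec <- relative_cross_section(sim$sample, fc, C_R = 3.76e-4, C_S = 0.0376)
  expect_gt(stats::cor(rec$sigma, truth_s$sigma), 0.999)
  ratio <- rec$sigma / truth_s$sigma      # recovered up to one global scale
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)

  pk <- spectral_peak(rec)
  expect_equal(pk$lambda_max, 720)        # monotone decreasing: boundary max
  expect_true(pk$is_boundary)
})

test_that("power-law quadrupling and peak bookkeeping behave", {
  w <- grid_720_1000
  truth_s <- fg_like_sigma(); truth_r <- ref_sigma()
  base <- simulate_spectral_series(truth_s, truth_r, 1, 1, laser_power = 1, noise_cv = 0, seed = 1)
  P2 <- rep(1, length(w)); P2[4] <- 2
  dbl <- simulate_spectral_series(truth_s, truth_r, 1, 1, laser_power = P2, noise_cv = 0, seed = 1)
  expect_equal(dbl$sample$intensity[4] / base$sample$intensity[4], 4)
  expect_equal(dbl$sample$intensity[-4], base$sample$intensity[-4])

  bump <- spectral_peak(spectral_series(w, dnorm(w, 850, 50)))
  expect_equal(bump$lambda_max, 850)
  expect_false(bump$is_boundary)

  tied <- spectral_peak(spectral_series(w, rep(1, length(w))))
  expect_equal(tied$lambda_max, 720)      # tie broken to the shorter wavelength
  expect_true(tied$tied)
})

test_that("power exponent regression recovers slopes and covers the truth", {
  df2 <- simulate_power_series(powers = 1:10, exponent = 2, noise_cv = 0, seed = 1)
  expect_equal(power_exponent(df2$power, df2$intensity)$slope, 2, tolerance = 1e-9)
  df1 <- simulate_power_series(powers = 1:10, exponent = 1, noise_cv = 0, seed = 1)
  expect_equal(power_exponent(df1$power, df1$intensity)$slope, 1, tolerance = 1e-9)

  covered <- vapply(1:100, function(s) {
    d <- simulate_power_series(powers = 1:10, exponent = 2, noise_cv = 0.01, seed = s)
    ci <- power_exponent(d$power, d$intensity)$ci95
    ci[1] <= 2 && 2 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 90)

  expect_error(power_exponent(c(1, 2), c(1, 4)), ">= 3")
  expect_error(power_exponent(c(1, 2, -3), c(1, 4, 9)), "positive")
})
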