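test_that("mean lifetime follows the amplitude and intensity conventions", {
  p <- decay_params(c(0.5, 0.5), c(1, 3))
  expect_equal(mean_lifetime(p, "amplitude"), 2.0)
  expect_equal(mean_lifetime(p, "intensity"), 2.5)
  p1 <- decay_params(1, 1.7)
  expect_equal(mean_lifetime(p1, "amplitude"), 1.7)
  expect_equal(mean_lifetime(p1, "intensity"), 1.7)

  # bounded by the component lifetimes for random parameters
  set.seed(42)
  for (i in 1:50) {
    taus <- sort(stats::runif(2, 0.05, 5))
    a1 <- stats::runif(1, 0.01, 0.99)
    p <- decay_params(c(a1, 1 - a1), taus)
    for (mode in c("amplitude", "intensity")) {
      m <- mean_lifetime(p, mode)
      expect_gte(m, taus[1]); expect_lte(m, taus[2])
    }
  }
})

test_that("amplitude split solving the 1.4 ns intensity-weighted mean is ~0.94/0.06", {
  a1 <- amplitude_for_mean_lifetime(1.4, 0.1, 2.3, mode = "intensity")
  expect_equal(a1, 0.94, tolerance = 0.01)
  p <- decay_params(c(a1, 1 - a1), c(0.1, 2.3))
  expect_equal(mean_lifetime(p, "intensity"), 1.4, tolerance = 1e-12)
  # and the generator default uses exactly this split
  expect_equal(fg_decay()$amplitudes[1], a1)
})

test_that("noiseless fits recover the truth to numerical precision", {
  irf <- std_irf()
  e <- model_decay(background_decay(1.35), irf, n_photons = 1e6)
  h <- decay_histogram(e, 12500 / 256)
  ft <- fit_monoexponential(h, irf)
  expect_true(ft$converged)
  expect_equal(ft$params$lifetimes, 1.35, tolerance = 1e-6)
  expect_lt(ft$chi2_reduced, 1e-8)

  dirf <- delta_irf(256, 12500 / 256)
  prm <- decay_params(c(0.7, 0.3), c(0.4, 2.3))
  e2 <- model_decay(prm, dirf, n_photons = 5e5)
  ft2 <- fit_biexponential(decay_histogram(e2, 12500 / 256), dirf)
  expect_equal(ft2$params$lifetimes, c(0.4, 2.3), tolerance = 1e-6)
  expect_equal(ft2$params$amplitudes, c(0.7, 0.3), tolerance = 1e-6)
})

test_that("optimizer agrees with the exhaustive grid-search oracle", {
  n <- 64L; bw <- 12500 / n
  dirf <- delta_irf(n, bw)
  truth <- decay_params(c(0.6, 0.4), c(0.5, 3.0))
  counts <- model_decay(truth, dirf, n_photons = 1e5)
  gs <- grid_search_biexp(counts, dirf,
                          tau1_grid = seq(0.2, 1.1, by = 0.1),
                          tau2_grid = seq(2.0, 4.0, by = 0.25),
                          a1_grid = seq(0.3, 0.9, by = 0.05))
  ft <- fit_biexponential(decay_histogram(counts, bw), dirf,
                          fit_opts(fit_shift = FALSE, fit_baseline = FALSE))
  expect_lte(abs(ft$params$lifetimes[1] - gs$tau1), 0.1)
  expect_lte(abs(ft$params$lifetimes[2] - gs$tau2), 0.25)
  expect_lte(abs(ft$params$amplitudes[1] - gs$a1), 0.05)
})

test_that("repeated Poisson fits recover the mono lifetime with <0.5% bias", {
  irf <- std_irf()
  prm <- background_decay(1.35)
  taus <- vapply(1:60, function(s) {
    h <- simulate_decay(prm, irf, acquisition(total_photons = 1e6, seed = s))
    fit_monoexponential(h, irf)$params$lifetimes
  }, numeric(1))
  expect_equal(mean(taus), 1.35, tolerance = 0.005 * 1.35)
})

test_that("flat histograms are flagged instead of silently fitted", {
  n <- 256L
  h <- decay_histogram(rep(500, n), 12500 / n)
  ft <- fit_monoexponential(h, std_irf())
  expect_true(!ft$converged || isTRUE(ft$metadata$at_bound) ||
              length(ft$metadata$warnings) > 0)
})

test_that("low-count histograms are rejected", {
  h <- decay_histogram(rep(1, 256), 12500 / 256)
  expect_error(fit_monoexponential(h, std_irf()), "below the minimum")
})

test_that("nearly equal lifetimes collapse to a flagged mono fit", {
  irf <- std_irf()
  e <- model_decay(background_decay(1.5), irf, n_photons = 1e6)
  h <- decay_histogram(e, 12500 / 256)
  ft <- fit_biexponential(h, irf)
  expect_identical(ft$metadata$model, "mono")
  expect_true(isTRUE(ft$metadata$collapsed_from_biexp))
  expect_equal(ft$params$lifetimes, 1.5, tolerance = 1e-4)
})

test_that("reduced chi-squared is 0 on perfect fits, ~1 on Poisson data, large on misfit", {
  n <- 64L
  dirf <- delta_irf(n, 12500 / n)
  prm <- decay_params(1, 2.0)
  e <- model_decay(prm, dirf, n_photons = 1e5)
  expect_equal(reduced_chi_squared(e, e, n - 2), 0)

  chis <- vapply(1:200, function(s) {
    h <- simulate_decay(prm, dirf, acquisition(n_bins = n, total_photons = 1e5, seed = s))
    reduced_chi_squared(h$counts, e, n)
  }, numeric(1))
  expect_gte(mean(chis), 0.9); expect_lte(mean(chis), 1.1)

  # mono expectation vs strongly biexponential data
  bi <- model_decay(decay_params(c(0.9, 0.1), c(0.1, 3.5)), dirf, n_photons = 1e6)
  mono <- model_decay(decay_params(1, 1.0), dirf, n_photons = 1e6)
  expect_gt(reduced_chi_squared(bi, mono, n - 2), 10)
})

test_that("short-component recovery error shrinks as the IRF narrows", {
  prm <- fg_decay()
  err_for_fwhm <- function(fwhm) {
    irf <- std_irf(fwhm = fwhm)
    e <- vapply(1:10, function(s) {
      h <- simulate_decay(prm, irf, acquisition(total_photons = 1e6, seed = 300 + s))
      abs(fit_biexponential(h, irf)$params$lifetimes[1] - 0.1)
    }, numeric(1))
    mean(e)
  }
  errs <- vapply(c(200, 100, 25), err_for_fwhm, numeric(1))
  expect_true(all(diff(errs) <= 1e-4))   # monotone non-increasing (tiny slack)
})
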