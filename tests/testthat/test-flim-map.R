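small_irf <- function(n = 64L) std_irf(n_bins = n)

test_that("phantom truth masks carry exactly the injected cells", {
  ph0 <- scene_phantom(c(4, 16, 16), cells = list())
  expect_equal(max(phantom_truth(ph0)), 0)

  cells <- place_cells(20, c(48, 96, 96), radius_range = c(6, 9), seed = 3)
  ph <- scene_phantom(c(48, 96, 96), cells = cells)
  truth <- phantom_truth(ph)
  expect_equal(length(unique(truth[truth > 0])), 20)
  expect_false(attr(truth, "overlap"))
  cc <- connected_components(truth > 0, 26L)
  expect_equal(max(cc), 20)   # disjoint spheres stay disjoint components

  # overlapping cells are permitted but flagged
  ov <- scene_phantom(c(8, 16, 16),
                      cells = list(list(center = c(4, 8, 8), radii = 3,
                                        decay = fg_decay(), brightness = 1),
                                   list(center = c(4, 9, 8), radii = 3,
                                        decay = fg_decay(), brightness = 1)))
  expect_true(attr(phantom_truth(ov), "overlap"))
})

test_that("FLIM phantoms put the right decay in the right place, reproducibly", {
  n <- 64L
  irf <- small_irf(n)
  cells <- list(list(center = c(1, 5, 5), radii = 3, decay = fg_decay(), brightness = 1))
  ph <- scene_phantom(c(1, 12, 12), cells = cells, background_brightness = 0.2,
                      photons_per_pixel = 3000)
  acq <- acquisition(n_bins = n, seed = 9)
  ds <- simulate_flim_image(ph, irf, acq)
  expect_equal(dim(ds$data), c(1, 12, 12, n))
  pc <- photon_counts(ds)
  expect_gt(mean(pc[1, , ][ds$truth[1, , ] == 1]), 4 * mean(pc[1, , ][ds$truth[1, , ] == 0]))
  ds2 <- simulate_flim_image(ph, irf, acq)
  expect_identical(ds$data, ds2$data)
})

test_that("per-pixel fits recover the injected lifetimes and respect the photon floor", {
  n <- 64L
  irf <- small_irf(n)
  ph <- scene_phantom(c(1, 10, 10), cells = list(), background_decay = fg_decay(),
                      background_brightness = 1, photons_per_pixel = 5000)
  ds <- simulate_flim_image(ph, irf, acquisition(n_bins = n, seed = 11))
  map <- fit_pixels(ds, spatial_binning = 1, min_photons = 500)
  expect_true(all(map$valid))
  expect_equal(median(map$mean_lifetime, na.rm = TRUE), 1.4, tolerance = 0.05)
  expect_equal(median(map$tau2, na.rm = TRUE), 2.3, tolerance = 0.05 * 2.3)

  # binning shrinks the per-pixel spread
  map0 <- fit_pixels(ds, spatial_binning = 0, min_photons = 500)
  expect_lt(sd(map$mean_lifetime, na.rm = TRUE), sd(map0$mean_lifetime, na.rm = TRUE))

  expect_error(fit_pixels(ds, min_photons = 1e9), "min_photons")
})

test_that("lifetime histograms report mass, mode and emptiness correctly", {
  map <- structure(list(mean_lifetime = matrix(1.4, 5, 5),
                        valid = matrix(TRUE, 5, 5),
                        metadata = list(wavelength = NA_real_)),
                   class = "lifetime_map")
  hh <- lifetime_histogram(map)
  expect_equal(sum(hh$counts), 25)
  expect_equal(hh$mode, 1.4, tolerance = 0.02)   # bin-center resolution

  # bimodal two-population map
  ml <- matrix(c(rep(0.8, 12), rep(2.6, 13)), 5, 5)
  map$mean_lifetime <- ml
  hh2 <- lifetime_histogram(map, n_bins = 50, range = c(0, 5))
  occupied <- which(hh2$counts > 0)
  expect_equal(length(occupied), 2)
  expect_gt(diff(hh2$centers[occupied]), 1)

  hh3 <- lifetime_histogram(map, mask = matrix(FALSE, 5, 5))
  expect_true(hh3$empty)
  expect_true(is.na(hh3$mode))
})

test_that("lifetime contrast is symmetric, zero on identical populations, additive-invariant", {
  mk_map <- function(vals) structure(list(mean_lifetime = vals,
                                          valid = matrix(TRUE, nrow(vals), ncol(vals)),
                                          metadata = list(wavelength = 760)),
                                     class = "lifetime_map")
  fg <- matrix(rep(c(TRUE, FALSE), each = 8), 4, 4)
  bg <- !fg
  vals <- matrix(0, 4, 4); vals[fg] <- 1.4; vals[bg] <- 1.35
  m <- mk_map(vals)
  cr <- lifetime_contrast(m, fg, bg)
  expect_equal(cr$contrast, 0.05, tolerance = 1e-12)
  expect_equal(cr$tau_fg, 1.4); expect_equal(cr$tau_bg, 1.35)

  swapped <- lifetime_contrast(m, bg, fg)
  expect_equal(swapped$contrast, cr$contrast)

  same <- mk_map(matrix(1.4, 4, 4))
  expect_equal(lifetime_contrast(same, fg, bg)$contrast, 0)

  shifted <- mk_map(vals + 0.7)   # common shift leaves absolute contrast unchanged
  expect_equal(lifetime_contrast(shifted, fg, bg)$contrast, cr$contrast)

  expect_error(lifetime_contrast(m, fg, fg), "overlap")
})

test_that("contrast spectrum finds the wavelength of maximum contrast", {
  n <- 64L
  irf <- small_irf(n)
  # two uniform simulations spliced by rows: rows 1-4 = "cells", 5-8 = background
  mk_ds <- function(wl, cell_tau) {
    uni <- function(tau, seed) {
      ph <- scene_phantom(c(1, 8, 8), background_decay = decay_params(1, tau),
                          background_brightness = 1, photons_per_pixel = 2000)
      simulate_flim_image(ph, irf, acquisition(n_bins = n, seed = seed))
    }
    a <- uni(cell_tau, round(wl)); b <- uni(1.35, round(wl) + 1)
    a$data[1, 5:8, , ] <- b$data[1, 5:8, , ]
    a$wavelength <- wl
    a
  }
  # only 760 nm separates the populations
  d1 <- mk_ds(740, 1.35); d2 <- mk_ds(760, 2.6); d3 <- mk_ds(780, 1.36)
  fg <- matrix(FALSE, 8, 8); fg[1:4, ] <- TRUE
  cs <- contrast_spectrum(list(d3, d1, d2), fg, !fg, model = "mono", min_photons = 100)
  expect_equal(cs$lambda_max, 760)
  expect_false(cs$tied)
  expect_equal(nrow(cs$table), 3)
  expect_true(all(diff(cs$table$wavelength) > 0))

  # single wavelength: argmax is that wavelength
  cs1 <- contrast_spectrum(list(d2), fg, !fg, model = "mono", min_photons = 100)
  expect_equal(cs1$lambda_max, 760)
})
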