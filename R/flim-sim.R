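#' Scene phantom: labeled cell bodies over tissue background
#'
#' Describes a synthetic 3D scene of ellipsoidal cell bodies (motoneuron-scale
#' by default) embedded in an autofluorescent background, each region carrying
#' its own decay model and brightness. Used to generate FLIM stacks with
#' [simulate_flim_image()] and intensity volumes with
#' [simulate_intensity_volume()], always together with the ground-truth label
#' mask.
#'
#' @param shape integer vector `c(z, y, x)` of voxel counts.
#' @param voxel_size physical voxel size in um per axis `c(z, y, x)`.
#' @param cells list of cells, each a list with fields `center` (voxel
#'   coordinates `c(z, y, x)`, inside the volume), `radii` (um, length 1 or 3,
#'   all > 0), `decay` (a [decay_params()]) and `brightness` (>= 0 photon
#'   multiplier relative to `photons_per_pixel`).
#' @param background_decay decay of every voxel outside all cells.
#' @param background_brightness photon multiplier of the background.
#' @param photons_per_pixel expected photons in a brightness-1 voxel.
#' @return an object of class `scene_phantom`.
#' @export
scene_phantom <- function(shape, voxel_size = c(1, 1, 1), cells = list(),
                          background_decay = NULL,
                          background_brightness = 0.1,
                          photons_per_pixel = 5000) {
  if (is.null(background_decay)) background_decay <- flimfg::background_decay()
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stopf("shape must be c(z, y, x) positive voxel counts")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) stopf("voxel_size must be positive um")
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    if (!all(c("center", "radii", "decay", "brightness") %in% names(cl)))
      stopf("cell %d must have fields center, radii, decay, brightness", i)
    if (length(cl$radii) == 1L) cells[[i]]$radii <- rep(cl$radii, 3L)
    if (any(cells[[i]]$radii <= 0)) stopf("cell %d has nonpositive radii", i)
    if (length(cl$center) != 3L || any(cl$center < 1) || any(cl$center > shape))
      stopf("cell %d center outside the volume", i)
    if (!inherits(cl$decay, "decay_params")) stopf("cell %d decay must be decay_params", i)
    if (cl$brightness < 0) stopf("cell %d brightness must be >= 0", i)
  }
  if (!inherits(background_decay, "decay_params")) stopf("background_decay must be decay_params")
  if (background_brightness < 0 || photons_per_pixel < 0) stopf("brightness must be >= 0")
  structure(list(shape = shape, voxel_size = voxel_size, cells = cells,
                 background_decay = background_decay,
                 background_brightness = background_brightness,
                 photons_per_pixel = photons_per_pixel),
            class = "scene_phantom")
}

#' Place disjoint spherical cells at seeded random positions
#'
#' Rejection-samples `n` non-overlapping spheres inside the volume (margin of
#' one radius from the faces). Defaults emulate motoneuron somata: radius
#' 10-15 um at 1 um voxels.
#'
#' @param n number of cells.
#' @param shape volume shape `c(z, y, x)` in voxels.
#' @param radius_range min/max sphere radius in um.
#' @param decay decay assigned to every cell.
#' @param brightness cell brightness multiplier.
#' @param seed RNG seed.
#' @param voxel_size um per voxel (isotropic scalar or length 3).
#' @param min_gap minimum surface-to-surface clearance between cells in um;
#'   the default keeps neighbors separated by more than the default
#'   segmentation smoothing scale, as somata are by neuropil.
#' @param max_tries placement attempts before giving up.
#' @return a list of cells suitable for [scene_phantom()].
#' @export
place_cells <- function(n, shape, radius_range = c(10, 15), decay = fg_decay(),
                        brightness = 1, seed = 1L, voxel_size = 1,
                        min_gap = 5, max_tries = 10000L) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  with_seed(seed, {
    cells <- list()
    centers <- matrix(numeric(0), ncol = 3)
    radii <- numeric(0)
    tries <- 0L
    while (length(cells) < n && tries < max_tries) {
      tries <- tries + 1L
      r <- stats::runif(1, radius_range[1], radius_range[2])
      rv <- r / voxel_size   # radius in voxels per axis
      lo <- 1 + rv; hi <- shape - rv
      if (any(hi <= lo)) stopf("volume too small for radius %.3g um", r)
      ctr <- lo + stats::runif(3) * (hi - lo)
      phys <- ctr * voxel_size
      ok <- TRUE
      if (nrow(centers) > 0) {
        d <- sqrt(colSums((t(centers) - phys)^2))
        ok <- all(d > r + radii + min_gap)   # strictly disjoint with clearance
      }
      if (ok) {
        centers <- rbind(centers, phys)
        radii <- c(radii, r)
        cells[[length(cells) + 1L]] <- list(center = ctr, radii = r,
                                            decay = decay, brightness = brightness)
      }
    }
    if (length(cells) < n) stopf("could only place %d of %d disjoint cells", length(cells), n)
    cells
  })
}

# Voxel-wise ellipsoid membership; returns integer label array (0 background),
# first-listed cell wins on overlap, plus an overlap flag.
phantom_labels <- function(phantom) {
  shape <- phantom$shape
  vs <- phantom$voxel_size
  labels <- array(0L, dim = shape)
  claimed <- array(FALSE, dim = shape)
  overlap <- FALSE
  z <- slice.index(labels, 1); y <- slice.index(labels, 2); x <- slice.index(labels, 3)
  for (i in seq_along(phantom$cells)) {
    cl <- phantom$cells[[i]]
    rz <- cl$radii[1] / vs[1]; ry <- cl$radii[2] / vs[2]; rx <- cl$radii[3] / vs[3]
    inside <- ((z - cl$center[1]) / rz)^2 + ((y - cl$center[2]) / ry)^2 +
              ((x - cl$center[3]) / rx)^2 <= 1
    if (any(inside & claimed)) overlap <- TRUE
    labels[inside & !claimed] <- i
    claimed <- claimed | inside
  }
  attr(labels, "overlap") <- overlap
  labels
}

#' Ground-truth label mask of a phantom
#'
#' @param phantom a [scene_phantom()].
#' @return integer array `c(z, y, x)`; 0 = background, i = cell i. Attribute
#'   `overlap` flags whether any cells intersect (first-listed cell wins).
#' @export
phantom_truth <- function(phantom) {
  stopifnot(inherits(phantom, "scene_phantom"))
  phantom_labels(phantom)
}

#' Simulate a FLIM image stack from a phantom
#'
#' Every voxel inside a cell ellipsoid carries that cell's decay; all other
#' voxels carry the background decay. Per-voxel, per-bin counts are Poisson
#' draws around `brightness * photons_per_pixel` photons distributed over the
#' IRF-convolved decay curve. Overlapping cells are permitted and flagged in
#' the metadata.
#'
#' @param phantom a [scene_phantom()].
#' @param irf an [irf_kernel()] matching `acq`.
#' @param acq an [acquisition()]; `total_photons` is ignored (the phantom's
#'   `photons_per_pixel` and brightnesses set the photon budget), `seed` fixes
#'   the draw.
#' @return an object of class `flim_dataset`: `data` is a `c(z, y, x, t)`
#'   count array, plus `bin_width` (ps), `irf`, `truth` (label array),
#'   `wavelength` (NA unless set later) and `metadata`.
#' @export
simulate_flim_image <- function(phantom, irf, acq) {
  stopifnot(inherits(phantom, "scene_phantom"), inherits(irf, "irf_kernel"),
            inherits(acq, "acquisition"))
  n_bins <- acq$n_bins
  if (length(irf$values) != n_bins) stopf("IRF bins (%d) != acquisition bins (%d)", length(irf$values), n_bins)
  labels <- phantom_labels(phantom)
  shape <- phantom$shape
  data <- array(0, dim = c(shape, n_bins))
  nvox <- prod(shape)
  flat <- matrix(0, nrow = nvox, ncol = n_bins)
  regions <- c(list(list(decay = phantom$background_decay,
                         brightness = phantom$background_brightness,
                         mask = as.vector(labels) == 0L)),
               lapply(seq_along(phantom$cells), function(i)
                 list(decay = phantom$cells[[i]]$decay,
                      brightness = phantom$cells[[i]]$brightness,
                      mask = as.vector(labels) == i)))
  with_seed(acq$seed, {
    for (rg in regions) {
      nv <- sum(rg$mask)
      if (nv == 0) next
      curve <- model_decay(rg$decay, irf,
                           n_photons = rg$brightness * phantom$photons_per_pixel)
      flat[rg$mask, ] <- matrix(rpois(nv * n_bins, rep(curve, each = nv)),
                                nrow = nv, ncol = n_bins)
    }
  })
  data <- array(flat, dim = c(shape, n_bins))
  structure(list(data = data, bin_width = acq$period * 1000 / n_bins, irf = irf,
                 truth = labels, wavelength = NA_real_,
                 metadata = list(seed = acq$seed, overlap = attr(labels, "overlap"),
                                 photons_per_pixel = phantom$photons_per_pixel)),
            class = "flim_dataset")
}

#' Simulate a 3D intensity volume from a phantom
#'
#' Time-integrated counterpart of [simulate_flim_image()], for testing the
#' segmentation stage without carrying a time axis: each voxel is a single
#' Poisson draw around `brightness * photons_per_pixel`.
#'
#' @inheritParams simulate_flim_image
#' @param seed RNG seed.
#' @return list with `intensity` (numeric array `c(z, y, x)`) and `truth`
#'   (label array).
#' @export
simulate_intensity_volume <- function(phantom, seed = 1L) {
  stopifnot(inherits(phantom, "scene_phantom"))
  labels <- phantom_labels(phantom)
  mean_img <- array(phantom$background_brightness * phantom$photons_per_pixel,
                    dim = phantom$shape)
  for (i in seq_along(phantom$cells))
    mean_img[labels == i] <- phantom$cells[[i]]$brightness * phantom$photons_per_pixel
  intensity <- with_seed(seed, array(rpois(length(mean_img), mean_img), dim = phantom$shape))
  list(intensity = intensity, truth = labels)
}

#' Total photons per pixel of a FLIM dataset
#'
#' @param ds a `flim_dataset`.
#' @return numeric array `c(z, y, x)` of per-voxel photon counts.
#' @export
photon_counts <- function(ds) {
  stopifnot(inherits(ds, "flim_dataset"))
  d <- dim(ds$data)
  apply(ds$data, seq_len(length(d) - 1L), sum)
}

#' @export
print.flim_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("FLIM dataset: %d x %d x %d voxels x %d time bins (%.3g ps/bin)%s\n",
              d[1], d[2], d[3], d[4], x$bin_width,
              if (is.finite(x$wavelength)) sprintf(", %g nm", x$wavelength) else ""))
  invisible(x)
}
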