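# Shared fixtures: small acquisition geometries and a brute-force grid-search
# oracle for noiseless decay fits.

std_irf <- function(n_bins = 256L, period = 12.5, fwhm = 100, center = 1000) {
  make_irf(fwhm, period * 1000 / n_bins, n_bins, center)
}

# Exhaustive coarse-to-fine grid search over (tau1, tau2, a1) minimizing the
# same Pearson objective as the optimizer, with N fixed to the histogram total
# and no shift/baseline. Independent of the LM path.
grid_search_biexp <- function(counts, irf, tau1_grid, tau2_grid, a1_grid) {
  n_photons <- sum(counts)
  best <- list(obj = Inf)
  for (t1 in tau1_grid) for (t2 in tau2_grid) {
    if (t1 >= t2) next
    for (a1 in a1_grid) {
      prm <- decay_params(c(a1, 1 - a1), c(t1, t2))
      e <- model_decay(prm, irf, n_photons = n_photons)
      obj <- sum((counts - e)^2 / pmax(e, 1))
      if (obj < best$obj) best <- list(obj = obj, tau1 = t1, tau2 = t2, a1 = a1)
    }
  }
  best
}

sphere_mask <- function(shape, center, radius) {
  a <- array(FALSE, dim = shape)
  z <- slice.index(a, 1); y <- slice.index(a, 2); x <- slice.index(a, 3)
  sqrt((z - center[1])^2 + (y - center[2])^2 + (x - center[3])^2) <= radius
}

# Object-level recall/precision of a segmentation against a truth labeling:
# a truth object is recalled if one predicted object covers >50% of it; a
# predicted object is a true positive if >50% of it lies in one truth object.
match_objects <- function(pred, truth) {
  nt <- max(truth); np <- max(pred)
  recalled <- 0L
  for (i in seq_len(nt)) {
    vox <- pred[truth == i]
    vox <- vox[vox > 0]
    if (length(vox) > 0 && max(tabulate(vox, np)) > 0.5 * sum(truth == i))
      recalled <- recalled + 1L
  }
  tp <- 0L
  for (j in seq_len(np)) {
    vox <- truth[pred == j]
    vox <- vox[vox > 0]
    if (length(vox) > 0 && max(tabulate(vox, nt)) > 0.5 * sum(pred == j))
      tp <- tp + 1L
  }
  list(recall = recalled / max(nt, 1), precision = tp / max(np, 1))
}
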