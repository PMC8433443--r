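# --- low-level 3D morphology ----------------------------------------------

# Neighbor offsets for 6- or 26-connectivity in (z, y, x).
neighbor_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dz) + abs(g$dy) + abs(g$dx) == 1, ]
  as.matrix(g)
}

# Shift a 3D array by (dz, dy, dx), padding with `fill`.
shift_array <- function(a, dz, dy, dx, fill) {
  d <- dim(a)
  out <- array(fill, dim = d)
  zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
  out[zs, ys, xs] <- a[zs - dz, ys - dy, xs - dx]
  out
}

#' Connected components of a 3D binary mask
#'
#' Label propagation with pointer jumping: each foreground voxel starts with
#' its own linear index as label; sweeps take the minimum over the chosen
#' neighborhood and path-compress until stable. Deterministic; labels are
#' relabeled contiguously 1..n in first-voxel order.
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (default, standard for blob-like somata) or 6.
#' @return integer array of labels (0 = background).
#' @export
connected_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (length(d) != 3L) stopf("mask must be a 3D array")
  offs <- neighbor_offsets(connectivity)
  lab <- array(0, dim = d)
  lab[mask] <- which(mask)            # provisional label = own linear index
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      nb <- shift_array(lab, offs[r, 1], offs[r, 2], offs[r, 3], fill = 0)
      upd <- mask & nb > 0 & (new == 0 | nb < new)
      new[upd] <- nb[upd]
    }
    # pointer jumping: follow label -> label-at-that-voxel to compress chains
    fg <- new > 0
    repeat {
      jumped <- new
      jumped[fg] <- new[new[fg]]
      if (identical(jumped, new)) break
      new <- jumped
    }
    if (identical(new, lab)) break
    lab <- new
  }
  u <- sort(unique(lab[lab > 0]))
  out <- array(0L, dim = d)
  if (length(u) > 0) out[lab > 0] <- match(lab[lab > 0], u)
  out
}

# Fill interior holes: background components (6-connectivity) not touching the
# volume border become foreground.
fill_holes_3d <- function(mask) {
  bg <- connected_components(!mask, connectivity = 6L)
  d <- dim(mask)
  border_labels <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

# Separable Gaussian smoothing with replicate padding; sigma in voxels per axis.
gaussian_smooth_3d <- function(x, sigma_vox) {
  d <- dim(x)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(-r:r, sd = s); k <- k / sum(k)
    acc <- array(0, dim = d)
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(d[ax]) + j, 1L), d[ax])  # replicate edges
      sh <- switch(ax, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE], x[, , idx, drop = FALSE])
      acc <- acc + k[j + r + 1] * sh
    }
    x <- acc
  }
  x
}

# Otsu threshold on a 256-bin histogram of a numeric array.
threshold_otsu <- function(x) {
  v <- as.vector(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  nb <- 256L
  h <- tabulate(pmin(1L + floor((v - rng[1]) / diff(rng) * nb), nb), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nb) - 0.5) * diff(rng) / nb
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

# Exact squared Euclidean distance transform (lower-envelope method), applied
# separably per axis with physical voxel scaling. Returns distance in um to
# the nearest background voxel.
edt_3d <- function(mask, voxel_size = c(1, 1, 1)) {
  INF <- 1e18
  dt1d <- function(f, step) {
    n <- length(f)
    if (n == 1L) return(f)
    v <- integer(n); zz <- numeric(n + 1L)
    k <- 1L; v[1] <- 1L; zz[1] <- -INF; zz[2] <- INF
    x <- (seq_len(n) - 1) * step
    for (q in 2:n) {
      repeat {
        s <- ((f[q] + x[q]^2) - (f[v[k]] + x[v[k]]^2)) / (2 * x[q] - 2 * x[v[k]])
        if (s <= zz[k] && k > 1L) k <- k - 1L else break
      }
      k <- k + 1L; v[k] <- q; zz[k] <- s; zz[k + 1L] <- INF
    }
    k <- 1L
    out <- numeric(n)
    for (q in seq_len(n)) {
      while (zz[k + 1L] < x[q]) k <- k + 1L
      out[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
    }
    out
  }
  d <- dim(mask)
  f <- array(ifelse(mask, 1e18, 0), dim = d)
  for (ax in 1:3) {
    step <- voxel_size[ax]
    f <- switch(ax,
      { for (j in seq_len(d[2])) for (kk in seq_len(d[3])) f[, j, kk] <- dt1d(f[, j, kk], step); f },
      { for (i in seq_len(d[1])) for (kk in seq_len(d[3])) f[i, , kk] <- dt1d(f[i, , kk], step); f },
      { for (i in seq_len(d[1])) for (j in seq_len(d[2])) f[i, j, ] <- dt1d(f[i, j, ], step); f })
  }
  sqrt(pmin(f, 1e18))
}

# Split touching objects: seeds are local maxima of the distance transform
# within a (2r+1)^3 window; every masked voxel then adopts the label of its
# nearest seed by iterative front propagation (deterministic, lowest label
# wins ties).
watershed_split <- function(mask, voxel_size, min_sep_um = 5) {
  dmap <- edt_3d(mask, voxel_size)
  d <- dim(mask)
  rv <- pmax(1L, round(min_sep_um / voxel_size))
  mx <- dmap
  for (ax in 1:3) {
    r <- rv[ax]
    acc <- mx
    for (j in seq(-r, r)) {
      if (j == 0) next
      idx <- pmin(pmax(seq_len(d[ax]) + j, 1L), d[ax])
      sh <- switch(ax, mx[idx, , , drop = FALSE], mx[, idx, , drop = FALSE], mx[, , idx, drop = FALSE])
      acc <- pmax(acc, sh)
    }
    mx <- acc
  }
  seeds <- mask & dmap > 0 & dmap >= mx - 1e-9
  seed_lab <- connected_components(seeds, 26L)  # one label per seed plateau
  lab <- seed_lab
  offs <- neighbor_offsets(26L)
  repeat {
    changed <- FALSE
    best <- array(0L, dim = d)
    for (r in seq_len(nrow(offs))) {
      nb <- shift_array(lab, offs[r, 1], offs[r, 2], offs[r, 3], fill = 0L)
      take <- mask & lab == 0L & nb > 0L & (best == 0L | nb < best)
      best[take] <- nb[take]
    }
    grow <- best > 0L
    if (any(grow)) { lab[grow] <- best[grow]; changed <- TRUE }
    if (!changed) break
  }
  lab[mask & lab == 0L] <- max(lab) + 1L  # unreachable leftovers (none in practice)
  lab * mask
}

# --- public surface --------------------------------------------------------

#' Segmentation options
#'
#' @param sigma Gaussian smoothing width in um (scaled per axis by the voxel
#'   size).
#' @param threshold `"otsu"` or a fixed numeric intensity.
#' @param min_volume minimum object volume in um^3; smaller objects are
#'   discarded.
#' @param fill_holes fill interior holes of thresholded objects.
#' @param watershed split touching objects on the distance transform.
#' @param watershed_min_sep minimum seed separation in um for the split.
#' @param lifetime_gate optional `c(lo, hi)` in ns: voxels whose lifetime lies
#'   outside the window are removed from the mask before labeling.
#' @return a list of class `segment_opts`.
#' @export
segment_opts <- function(sigma = 2, threshold = "otsu", min_volume = 100,
                         fill_holes = TRUE, watershed = FALSE,
                         watershed_min_sep = 5, lifetime_gate = NULL) {
  structure(list(sigma = sigma, threshold = threshold, min_volume = min_volume,
                 fill_holes = fill_holes, watershed = watershed,
                 watershed_min_sep = watershed_min_sep,
                 lifetime_gate = lifetime_gate),
            class = "segment_opts")
}

#' Segment cell bodies in a 3D intensity volume
#'
#' Classical deterministic pipeline: Gaussian smoothing, global (Otsu or
#' fixed) thresholding, optional lifetime gating, hole filling, 26-connected
#' components, small-object removal, and an optional distance-transform split
#' of touching cells. This is a transparent stand-in for trained pixel
#' classifiers used in commercial segmentation tools, with the same
#' post-processing stages (smoothing, edge-intensity threshold, hole fill).
#'
#' @param intensity numeric 3D array `c(z, y, x)`.
#' @param lifetime optional 3D array of per-voxel lifetimes (ns) for the
#'   lifetime gate.
#' @param opts a [segment_opts()].
#' @param voxel_size um per voxel, scalar or `c(z, y, x)`.
#' @return an object of class `label_volume`: `labels` (integer array,
#'   0 = background, contiguous 1..n), `n_objects`, and `stats` (data.frame:
#'   label, voxels, volume_um3, centroid_z/y/x, mean_intensity,
#'   mean_lifetime).
#' @export
segment_cells <- function(intensity, lifetime = NULL, opts = segment_opts(),
                          voxel_size = 1) {
  if (length(dim(intensity)) != 3L) stopf("intensity must be a 3D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  sm <- gaussian_smooth_3d(intensity, opts$sigma / voxel_size)
  thr <- if (identical(opts$threshold, "otsu")) threshold_otsu(sm) else as.numeric(opts$threshold)
  mask <- sm > thr
  if (!is.null(opts$lifetime_gate)) {
    if (is.null(lifetime)) stopf("lifetime_gate set but no lifetime volume given")
    g <- opts$lifetime_gate
    mask <- mask & lifetime >= g[1] & lifetime <= g[2]
  }
  if (any(mask) && opts$fill_holes) mask <- fill_holes_3d(mask)
  lab <- if (!any(mask)) {
    array(0L, dim = dim(mask))
  } else if (opts$watershed) {
    watershed_split(mask, voxel_size, opts$watershed_min_sep)
  } else {
    connected_components(mask, 26L)
  }
  # drop small objects, relabel contiguously
  vox_vol <- prod(voxel_size)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes * vox_vol >= opts$min_volume)
    lab2 <- array(0L, dim = dim(lab))
    if (length(keep) > 0) lab2[lab %in% keep] <- match(lab[lab %in% keep], keep)
    lab <- lab2
  }
  n <- max(lab)
  stats_df <- if (n == 0) {
    data.frame(label = integer(0), voxels = integer(0), volume_um3 = numeric(0),
               centroid_z = numeric(0), centroid_y = numeric(0),
               centroid_x = numeric(0), mean_intensity = numeric(0),
               mean_lifetime = numeric(0))
  } else {
    z <- slice.index(lab, 1); y <- slice.index(lab, 2); x <- slice.index(lab, 3)
    fg <- lab > 0
    lv <- factor(lab[fg], levels = seq_len(n))
    vox <- tabulate(lab[fg], n)
    data.frame(
      label = seq_len(n), voxels = vox, volume_um3 = vox * vox_vol,
      centroid_z = as.vector(tapply(z[fg], lv, mean)),
      centroid_y = as.vector(tapply(y[fg], lv, mean)),
      centroid_x = as.vector(tapply(x[fg], lv, mean)),
      mean_intensity = as.vector(tapply(intensity[fg], lv, mean)),
      mean_lifetime = if (is.null(lifetime)) NA_real_
                      else as.vector(tapply(lifetime[fg], lv, mean)))
  }
  structure(list(labels = lab, n_objects = n, stats = stats_df,
                 metadata = list(threshold = thr, opts = opts, voxel_size = voxel_size)),
            class = "label_volume")
}

#' Count segmented cells
#'
#' @param lv a `label_volume` from [segment_cells()].
#' @return list with `count` (number of distinct nonzero labels) and `table`
#'   (per-object stats sorted by volume, largest first).
#' @export
count_cells <- function(lv) {
  stopifnot(inherits(lv, "label_volume"))
  tab <- lv$stats[order(-lv$stats$volume_um3), , drop = FALSE]
  rownames(tab) <- NULL
  list(count = lv$n_objects, table = tab)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("Label volume: %d objects in a %s voxel grid\n",
              x$n_objects, paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}
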