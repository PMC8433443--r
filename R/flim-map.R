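# Box-sum of a 2D matrix over a (2b+1)^2 neighborhood, edges truncated to the
# image (pixels near the border sum over their in-image neighbors only).
box_sum2d <- function(m, b) {
  if (b == 0) return(m)
  pad_cum <- function(x) {
    # running sum along rows with window 2b+1 via cumulative sums
    n <- nrow(x)
    cs <- apply(x, 2, cumsum)
    cs <- rbind(matrix(0, 1, ncol(x)), cs)
    hi <- pmin(seq_len(n) + b, n) + 1L
    lo <- pmax(seq_len(n) - b, 1L)
    cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  t(pad_cum(t(pad_cum(m))))
}

#' Per-pixel decay fitting over a FLIM stack
#'
#' Sums each pixel's histogram over a `(2b+1)^2` spatial neighborhood
#' (binning `b`), discards pixels whose summed photon count is below
#' `min_photons`, and fits the remaining pixels with
#' [fit_biexponential()]/[fit_monoexponential()]. A global fit of the summed
#' image seeds the per-pixel fits.
#'
#' @param ds a `flim_dataset` with a single z plane (fit slices separately for
#'   volumetric stacks).
#' @param spatial_binning neighborhood half-width `b` (default 1, i.e. 3x3).
#' @param min_photons minimum photons in the binned histogram (default 500).
#' @param model `"biexp"` (default) or `"mono"` per-pixel model.
#' @param opts a [fit_opts()]; `min_counts` is overridden by `min_photons`.
#' @return an object of class `lifetime_map` with per-pixel matrices
#'   `mean_lifetime` (ns, intensity-weighted), `tau1`, `tau2`, `a1`, `a2`,
#'   `chi2`, `photons`, logical `valid`, and `metadata`. Invalid pixels carry
#'   `NA`.
#' @export
fit_pixels <- function(ds, spatial_binning = 1L, min_photons = 500,
                       model = c("biexp", "mono"), opts = fit_opts()) {
  model <- match.arg(model)
  stopifnot(inherits(ds, "flim_dataset"))
  if (min_photons < 1) stopf("min_photons must be >= 1")
  d <- dim(ds$data)
  if (d[1] != 1L) stopf("fit_pixels expects a single z plane; got %d (fit slices separately)", d[1])
  ny <- d[2]; nx <- d[3]; nt <- d[4]
  b <- as.integer(spatial_binning)

  # spatially bin each time plane
  binned <- array(0, dim = c(ny, nx, nt))
  for (k in seq_len(nt)) binned[, , k] <- box_sum2d(matrix(ds$data[1, , , k], ny, nx), b)
  photons <- apply(binned, c(1, 2), sum)
  valid <- photons >= min_photons
  if (!any(valid))
    stopf("no pixel meets min_photons = %g (%d pixels rejected)", min_photons, ny * nx)

  opts$min_counts <- min_photons
  # global fit seeds the per-pixel fits and keeps them fast
  total <- apply(ds$data, 4, sum)
  ghist <- decay_histogram(total, ds$bin_width)
  gfit <- tryCatch(fit_decay_engine(ghist, ds$irf, model, opts), error = function(e) NULL)
  popts <- opts
  if (!is.null(gfit) && gfit$metadata$model == model) {
    gi <- list(tau2 = max(gfit$params$lifetimes), baseline = 0)
    if (model == "biexp") {
      gi$tau1 <- min(gfit$params$lifetimes)
      gi$a1 <- gfit$params$amplitudes[1]
    }
    popts$init <- modifyList(gi, opts$init)
  }

  mk <- function() matrix(NA_real_, ny, nx)
  out <- list(mean_lifetime = mk(), tau1 = mk(), tau2 = mk(), a1 = mk(),
              a2 = mk(), chi2 = mk())
  n_fail <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    if (!valid[i, j]) next
    h <- decay_histogram(binned[i, j, ], ds$bin_width)
    ft <- tryCatch(fit_decay_engine(h, ds$irf, model, popts), error = function(e) NULL)
    if (is.null(ft)) { n_fail <- n_fail + 1L; valid[i, j] <- FALSE; next }
    tau <- ft$params$lifetimes; a <- ft$params$amplitudes
    out$tau1[i, j] <- tau[1]
    out$tau2[i, j] <- tau[length(tau)]
    out$a1[i, j] <- a[1]
    out$a2[i, j] <- if (length(a) > 1) a[2] else 0
    out$chi2[i, j] <- ft$chi2_reduced
    out$mean_lifetime[i, j] <- mean_lifetime(ft$params, "intensity")
  }
  structure(c(out, list(photons = photons, valid = valid,
                        metadata = list(model = model, spatial_binning = b,
                                        min_photons = min_photons,
                                        n_failed = n_fail,
                                        wavelength = ds$wavelength))),
            class = "lifetime_map")
}

#' Histogram of per-pixel mean lifetimes
#'
#' @param map a `lifetime_map` from [fit_pixels()].
#' @param mask optional logical matrix restricting the pixels.
#' @param n_bins number of histogram bins.
#' @param range lifetime range in ns covered by the bins.
#' @return list with `centers`, `counts`, `mode` (bin center of the highest
#'   bin; ties go to the shorter lifetime), `mean`, `sd`, `n` and `empty`.
#' @export
lifetime_histogram <- function(map, mask = NULL, n_bins = 250L, range = c(0, 5)) {
  stopifnot(inherits(map, "lifetime_map"))
  sel <- map$valid
  if (!is.null(mask)) sel <- sel & mask
  v <- map$mean_lifetime[sel]
  v <- v[is.finite(v)]
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  if (length(v) == 0)
    return(list(centers = centers, counts = rep(0L, n_bins), mode = NA_real_,
                mean = NA_real_, sd = NA_real_, n = 0L, empty = TRUE))
  v <- pmin(pmax(v, range[1]), range[2])
  counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  list(centers = centers, counts = counts, mode = centers[which.max(counts)],
       mean = mean(v), sd = sd(v), n = length(v), empty = FALSE)
}

#' Lifetime contrast between two pixel populations
#'
#' Contrast between labeled cells and background: the absolute definition is
#' `|tau_fg - tau_bg|` in ns, the normalized one
#' `|tau_fg - tau_bg| / (tau_fg + tau_bg)`. The two population lifetimes are
#' medians of the per-pixel mean lifetime over each mask.
#'
#' @param map a `lifetime_map`.
#' @param fg_mask,bg_mask disjoint logical matrices selecting the two
#'   populations.
#' @param definition `"absolute"` (default) or `"normalized"`.
#' @return an object of class `contrast_result`: `wavelength`, `tau_fg`,
#'   `tau_bg`, `contrast`, `definition`.
#' @export
lifetime_contrast <- function(map, fg_mask, bg_mask,
                              definition = c("absolute", "normalized")) {
  definition <- match.arg(definition)
  stopifnot(inherits(map, "lifetime_map"))
  if (any(fg_mask & bg_mask)) stopf("fg and bg masks overlap")
  tf <- median(map$mean_lifetime[map$valid & fg_mask], na.rm = TRUE)
  tb <- median(map$mean_lifetime[map$valid & bg_mask], na.rm = TRUE)
  ctr <- if (definition == "absolute") abs(tf - tb) else abs(tf - tb) / (tf + tb)
  structure(list(wavelength = map$metadata$wavelength, tau_fg = tf, tau_bg = tb,
                 contrast = ctr, definition = definition),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("lifetime contrast (%s): %.4g  [tau_fg %.4g ns, tau_bg %.4g ns%s]\n",
              x$definition, x$contrast, x$tau_fg, x$tau_bg,
              if (is.finite(x$wavelength)) sprintf(", %g nm", x$wavelength) else ""))
  invisible(x)
}

#' Lifetime contrast across excitation wavelengths
#'
#' Fits each wavelength's FLIM dataset, computes the cell/background lifetime
#' contrast, and reports the wavelength of maximum contrast. Ties are broken
#' toward the shorter wavelength and flagged.
#'
#' @param datasets list of `flim_dataset` objects, each with its `wavelength`
#'   field set (nm).
#' @param fg_mask,bg_mask disjoint logical matrices (shared across
#'   wavelengths).
#' @param definition contrast definition, see [lifetime_contrast()].
#' @param ... passed to [fit_pixels()] (e.g. `model`, `min_photons`).
#' @return list with `table` (data.frame wavelength, tau_fg, tau_bg,
#'   contrast), `lambda_max` (nm) and `tied` flag.
#' @export
contrast_spectrum <- function(datasets, fg_mask, bg_mask,
                              definition = c("absolute", "normalized"), ...) {
  definition <- match.arg(definition)
  wl <- vapply(datasets, function(d) as.numeric(d$wavelength), numeric(1))
  if (any(!is.finite(wl))) stopf("every dataset needs a wavelength")
  o <- order(wl)
  rows <- lapply(datasets[o], function(d) {
    m <- fit_pixels(d, ...)
    cr <- lifetime_contrast(m, fg_mask, bg_mask, definition)
    data.frame(wavelength = d$wavelength, tau_fg = cr$tau_fg,
               tau_bg = cr$tau_bg, contrast = cr$contrast)
  })
  tab <- do.call(rbind, rows)
  best <- which(tab$contrast == max(tab$contrast))
  list(table = tab, lambda_max = tab$wavelength[best[1]], tied = length(best) > 1)
}
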