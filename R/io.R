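# One dialect per format: TSV for series, TIFF for images, JSON for
# structured results and sidecar metadata. A sidecar lives at <path>.json.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Read and write TCSPC decay tables
#'
#' Tab-separated text with header columns `time_ps` (bin left edges,
#' ascending) and `counts` (nonnegative integers; scientific notation is
#' accepted when integral-valued). A JSON sidecar at `<path>.json` carries
#' bin width, t0 and any simulation metadata; the round trip is lossless for
#' integer counts.
#'
#' @param hist a [decay_histogram()].
#' @param path output file path.
#' @return `write_decay_table` returns `path` invisibly; `read_decay_table`
#'   returns a [decay_histogram()].
#' @export
write_decay_table <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  df <- data.frame(time_ps = hist$t0 + (seq_along(hist$counts) - 1L) * hist$bin_width,
                   counts = hist$counts)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- hist$metadata
  meta$expected <- NULL   # bulky; regenerable from truth + seed
  if (inherits(meta$truth, "decay_params")) meta$truth <- unclass(meta$truth)
  write_sidecar(path, c(list(format = "decay_table", bin_width_ps = hist$bin_width,
                             t0_ps = hist$t0), meta))
  invisible(path)
}

#' @rdname write_decay_table
#' @export
read_decay_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("%s: need a header plus at least one data row", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2L || hdr[1] != "time_ps" || hdr[2] != "counts")
    stopf("%s: line 1: expected header 'time_ps\\tcounts', got '%s'", path, lines[1])
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "numeric")
  for (i in seq_len(nrow(df))) {
    ln <- i + 1L
    if (!is.finite(df$counts[i]) || df$counts[i] < 0)
      stopf("%s: line %d: negative or non-numeric count", path, ln)
    if (abs(df$counts[i] - round(df$counts[i])) > 1e-9)
      stopf("%s: line %d: counts must be integral", path, ln)
    if (i > 1L && df$time_ps[i] <= df$time_ps[i - 1L])
      stopf("%s: line %d: time axis must be strictly increasing", path, ln)
  }
  meta <- read_sidecar(path)
  bw <- if (!is.null(meta$bin_width_ps)) meta$bin_width_ps else {
    if (nrow(df) < 2L) stopf("%s: cannot infer bin width from one row", path)
    median(diff(df$time_ps))
  }
  decay_histogram(round(df$counts), bin_width = bw, t0 = df$time_ps[1],
                  metadata = if (is.null(meta)) list() else meta)
}

#' Read and write spectral series tables
#'
#' TSV with header `wavelength_nm`, `intensity` and optional `power`,
#' `background` columns.
#'
#' @param s a [spectral_series()].
#' @param path file path.
#' @return `write_spectral_table` returns `path` invisibly;
#'   `read_spectral_table` a [spectral_series()].
#' @export
write_spectral_table <- function(s, path) {
  stopifnot(inherits(s, "spectral_series"))
  df <- data.frame(wavelength_nm = s$wavelengths, intensity = s$intensity)
  if (!is.null(s$power)) df$power <- s$power
  if (!is.null(s$background)) df$background <- s$background
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_sidecar(path, c(list(format = "spectral_table"), s$metadata))
  invisible(path)
}

#' @rdname write_spectral_table
#' @export
read_spectral_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stopf("%s: line 1: expected columns wavelength_nm, intensity", path)
  meta <- read_sidecar(path)
  spectral_series(df$wavelength_nm, df$intensity,
                  power = if ("power" %in% names(df)) df$power else NULL,
                  background = if ("background" %in% names(df)) df$background else NULL,
                  metadata = if (is.null(meta)) list() else meta)
}

#' Read and write image stacks as multi-page TIFF
#'
#' A FLIM dataset is written as one grayscale page per time bin (16-bit
#' integer counts); a volume or parameter map as one page per z slice. The
#' page order, array dimensions and (for float data) the linear scale used to
#' map values into the TIFF range are recorded in the sidecar JSON, so
#' integer data round trip losslessly and 32-bit float maps round trip within
#' float representation.
#'
#' @param data a `flim_dataset`, a 3D numeric array (pages = z), or a 2D
#'   matrix (single page).
#' @param path output `.tif` path.
#' @param kind `"auto"` picks 16-bit for integral nonnegative data below
#'   2^16 and 32-bit float otherwise.
#' @return `write_stack` returns `path` invisibly.
#' @export
write_stack <- function(data, path, kind = c("auto", "uint16", "float32")) {
  kind <- match.arg(kind)
  meta <- list(format = "stack")
  if (inherits(data, "flim_dataset")) {
    d <- dim(data$data)
    if (d[1] != 1L) stopf("only single-plane FLIM stacks are written (got %d z planes)", d[1])
    pages <- lapply(seq_len(d[4]), function(k) matrix(data$data[1, , , k], d[2], d[3]))
    meta <- c(meta, list(page_order = "t", n_pages = d[4], dim = d,
                         bin_width_ps = data$bin_width,
                         wavelength_nm = data$wavelength,
                         irf = list(fwhm = data$irf$fwhm, center = data$irf$center,
                                    bin_width = data$irf$bin_width)),
              data$metadata["seed"])
    arr <- data$data
  } else {
    a <- if (is.matrix(data)) array(data, dim = c(dim(data), 1L)) else data
    if (length(dim(a)) != 3L) stopf("write_stack needs a matrix, 3D array or flim_dataset")
    pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k])
    meta <- c(meta, list(page_order = "z", n_pages = dim(a)[3], dim = dim(a)))
    arr <- a
  }
  integral <- all(arr >= 0) && all(abs(arr - round(arr)) < 1e-9) && max(arr) < 65536
  if (kind == "auto") kind <- if (integral) "uint16" else "float32"
  if (kind == "uint16") {
    if (!integral) stopf("data not representable as 16-bit unsigned integers")
    pages <- lapply(pages, function(p) p / 65535)
    meta$encoding <- list(kind = "uint16", scale = 65535, offset = 0)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    lo <- min(arr); hi <- max(arr)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(pages, function(p) (p - lo) / scale)
    meta$encoding <- list(kind = "float32", scale = scale, offset = lo)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_stack
#' @param irf optional [irf_kernel()] attached when reading a FLIM stack whose
#'   sidecar lacks one.
#' @return `read_stack` returns a `flim_dataset` when the sidecar says pages
#'   are time bins, otherwise a 3D array (pages = z).
#' @export
read_stack <- function(path, irf = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- read_sidecar(path)
  if (is.null(meta)) {
    warning(sprintf("%s: missing sidecar; assuming z-ordered float pages with unit scale", path))
    meta <- list(page_order = "z", encoding = list(kind = "float32", scale = 1, offset = 0))
  }
  if (!is.null(meta$n_pages) && meta$n_pages != length(pages))
    stopf("%s: sidecar says %d pages but file has %d", path, meta$n_pages, length(pages))
  enc <- meta$encoding
  decode <- function(p) {
    v <- p * enc$scale + enc$offset
    if (identical(enc$kind, "uint16")) round(v) else v
  }
  pages <- lapply(pages, decode)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  if (identical(meta$page_order, "t")) {
    arr <- array(0, dim = c(1L, ny, nx, length(pages)))
    for (k in seq_along(pages)) arr[1, , , k] <- pages[[k]]
    if (is.null(irf)) {
      if (is.null(meta$irf)) stopf("%s: FLIM stack needs an IRF (sidecar has none; pass irf=)", path)
      irf <- make_irf(fwhm = meta$irf$fwhm, bin_width = meta$irf$bin_width,
                      n_bins = length(pages), center = meta$irf$center)
    }
    structure(list(data = arr, bin_width = meta$bin_width_ps, irf = irf,
                   truth = NULL,
                   wavelength = if (is.null(meta$wavelength_nm)) NA_real_ else meta$wavelength_nm,
                   metadata = meta),
              class = "flim_dataset")
  } else {
    arr <- array(0, dim = c(ny, nx, length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    arr
  }
}

#' Write a label volume as 16-bit TIFF plus per-object CSV
#'
#' @param lv a `label_volume`.
#' @param path output `.tif` path; the object table goes to `<path>.csv`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(lv, path) {
  stopifnot(inherits(lv, "label_volume"))
  a <- aperm(lv$labels, c(2, 3, 1))   # pages = z
  write_stack(a, path, kind = "uint16")
  utils::write.csv(lv$stats, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
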