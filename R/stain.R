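#' Standard H&E stain optical-density matrix
#'
#' Ruifrok-Johnston optical-density vectors for haematoxylin and eosin, with
#' the residual channel taken as their unit cross product. Rows are normalised
#' to unit length, in the order H, E, residual.
#'
#' @param h,e numeric length-3 OD vectors for haematoxylin and eosin.
#' @return a 3x3 matrix with unit-norm rows.
#' @export
hed_stain_matrix <- function(h = c(0.650, 0.704, 0.286),
                             e = c(0.072, 0.990, 0.105)) {
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- r / sqrt(sum(r^2))
  rbind(H = h, E = e, residual = r)
}

#' Convert RGB intensities to optical densities
#'
#' Applies the Beer-Lambert relation `od = -log10(max(pixel, 1) / i0)` per
#' channel. Intensities are floored at 1 so that pure black maps to a finite
#' absorbance.
#'
#' @param image numeric array `h x w x 3` (or matrix for a single channel)
#'   with intensities in `[0, 255]`.
#' @param i0 incident (white) intensity, default 255.
#' @return array of the same shape holding non-negative optical densities
#'   (for inputs `<= i0`).
#' @export
rgb_to_od <- function(image, i0 = 255) {
  stopifnot_scalar_pos(i0, "i0")
  -log10(pmax(image, 1) / i0)
}

#' Invert optical densities back to RGB intensities
#'
#' Exact inverse of [rgb_to_od()] up to the integer rounding of intensities.
#'
#' @inheritParams rgb_to_od
#' @param od numeric array of optical densities.
#' @param round round to integer intensity levels (default `TRUE`).
#' @export
od_to_rgb <- function(od, i0 = 255, round = TRUE) {
  stopifnot_scalar_pos(i0, "i0")
  x <- i0 * 10^(-od)
  x <- pmin(pmax(x, 0), i0)
  if (round) round(x) else x
}

#' Separate an H&E image into stain intensity channels
#'
#' Colour deconvolution: per-pixel optical densities are linearly unmixed with
#' the inverse of the stain OD matrix, giving haematoxylin, eosin and residual
#' concentration fields. Negative concentrations (numerical leakage between
#' non-orthogonal stain vectors) are clipped to zero and the residual is
#' discarded.
#'
#' @param image numeric array `h x w x 3`, intensities in `[0, 255]`.
#' @param stain_matrix 3x3 matrix of unit-norm stain OD row vectors
#'   (H, E, residual); default [hed_stain_matrix()].
#' @param i0 incident intensity for the OD transform.
#' @param mask optional binary matrix aligned with `image` (0 = background).
#' @return a `stain_pair` object: list with matrices `h`, `e` and the `mask`.
#' @export
deconvolve_stains <- function(image, stain_matrix = hed_stain_matrix(),
                              i0 = 255, mask = NULL) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (!is.matrix(stain_matrix) || !all(dim(stain_matrix) == 3L)) {
    stop("`stain_matrix` must be a 3x3 matrix")
  }
  det_m <- det(stain_matrix)
  if (!is.finite(det_m) || abs(det_m) < 1e-8) stop("`stain_matrix` is singular")
  h <- dim(image)[1]; w <- dim(image)[2]
  if (!is.null(mask) && !all(dim(mask)[1:2] == c(h, w))) {
    stop("`mask` must have the same height and width as `image`")
  }
  od <- matrix(rgb_to_od(image, i0), h * w, 3L)
  conc <- od %*% solve(stain_matrix)
  conc[conc < 0] <- 0
  new_stain_pair(matrix(conc[, 1L], h, w), matrix(conc[, 2L], h, w), mask)
}

new_stain_pair <- function(h, e, mask = NULL) {
  stopifnot(all(dim(h) == dim(e)))
  structure(list(h = h, e = e, mask = mask), class = "stain_pair")
}

#' @export
print.stain_pair <- function(x, ...) {
  cat("<stain_pair> ", nrow(x$h), " x ", ncol(x$h),
      if (is.null(x$mask)) " (no mask)" else " (masked)", "\n", sep = "")
  invisible(x)
}

#' Downscale an image or channel by integer block averaging
#'
#' Each output pixel is the mean of a `factor x factor` block of input pixels;
#' partial blocks at the right/bottom edge average over the pixels available,
#' so no border tissue is discarded. Output dimensions are
#' `ceiling(dim / factor)`.
#'
#' @param x matrix or `h x w x 3` array.
#' @param factor positive integer; 4 maps a 20x scan to the 5x analysis scale.
#' @export
downscale <- function(x, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    stop("`factor` must be a positive integer")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  if (length(dim(x)) == 3L) {
    out <- lapply(seq_len(dim(x)[3]), function(k) downscale(x[, , k], factor))
    return(array(unlist(out), c(dim(out[[1]]), dim(x)[3])))
  }
  gr <- as.integer(ceiling(nrow(x) / factor))
  gc <- as.integer(ceiling(ncol(x) / factor))
  ri <- rep(seq_len(gr), each = factor, length.out = nrow(x))
  ci <- rep(seq_len(gc), each = factor, length.out = ncol(x))
  s <- rowsum(t(rowsum(x, ri)), ci)              # gc x gr block sums
  n <- tabulate(ri, gr) %o% tabulate(ci, gc)     # pixels per block
  out <- t(s) / n
  dimnames(out) <- NULL
  out
}

#' Background mask from pixel intensities
#'
#' Where no tumour mask is available, near-white pixels (all three channels at
#' or above `threshold`) are treated as background.
#'
#' @param image numeric `h x w x 3` array of intensities in `[0, 255]`.
#' @param threshold intensity at or above which a channel counts as white.
#' @return binary matrix, 1 = tissue, 0 = background.
#' @export
background_mask <- function(image, threshold = 240) {
  stopifnot(length(dim(image)) == 3L)
  white <- (image[, , 1] >= threshold) & (image[, , 2] >= threshold) &
    (image[, , 3] >= threshold)
  1 - white * 1
}

#' Is a patch usable tissue?
#'
#' A patch is excluded only when *more than* half of its pixels are
#' background; exactly 50% background is still valid. The patch may be a
#' binary mask crop or a fractional tissue-coverage value in `[0, 1]`
#' (as produced by downscaling a binary mask).
#'
#' @param mask_patch numeric matrix, 0 = background (values in `[0, 1]` are
#'   read as tissue fractions).
#' @return `TRUE` if the background fraction is `<= 0.5`.
#' @export
patch_is_valid <- function(mask_patch) {
  bg_frac <- 1 - mean(mask_patch)
  bg_frac <= 0.5
}

#' Per-patch validity over a full mask
#'
#' Tiles the mask with non-overlapping `patch_px` squares anchored at the top
#' left corner (partial edge patches are dropped, matching the descriptor
#' grid) and applies the more-than-50%-background exclusion rule to each.
#'
#' @param mask matrix, 0 = background; fractional coverage values allowed.
#' @param patch_px patch side in pixels (default 32).
#' @return logical matrix of dimension `floor(dim(mask) / patch_px)`.
#' @export
patch_validity <- function(mask, patch_px = 32L) {
  gr <- nrow(mask) %/% patch_px
  gc <- ncol(mask) %/% patch_px
  if (gr < 1L || gc < 1L) stop("mask smaller than one patch")
  m <- mask[seq_len(gr * patch_px), seq_len(gc * patch_px), drop = FALSE]
  frac <- downscale(m, patch_px)   # mean tissue coverage per patch
  (1 - frac) <= 0.5
}

#' Read an 8-bit RGB TIFF as a 0-255 intensity array
#' @param path file path.
#' @export
read_rgb_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' Read a single-channel mask TIFF (0 = background)
#' @param path file path.
#' @export
read_mask_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x > 0) * 1
}

#' Write and read stain channels as 32-bit float TIFFs
#'
#' Writes `h.tiff` and `e.tiff` (and `mask.tiff` when present) under `dir`.
#' TIFF samples live in `[0, 1]`, so channels are stored divided by `scale`
#' (concentrations above `scale` would clip; the default of 4 OD units is
#' far above anything an H&E image produces) and the scale is recorded in
#' `scale.txt`. [read_stain_tiff()] inverts the encoding.
#'
#' @param stains a `stain_pair`.
#' @param dir output directory (created if missing).
#' @param scale full-scale concentration mapped to TIFF sample 1.0.
#' @export
write_stain_tiff <- function(stains, dir, scale = 4) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  enc <- function(x) pmin(pmax(x / scale, 0), 1)
  tiff::writeTIFF(enc(stains$h), file.path(dir, "h.tiff"),
                  bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(enc(stains$e), file.path(dir, "e.tiff"),
                  bits.per.sample = 32L, reduce = FALSE)
  if (!is.null(stains$mask)) {
    tiff::writeTIFF(pmin(pmax(stains$mask * 1, 0), 1),
                    file.path(dir, "mask.tiff"),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  writeLines(sprintf("%.17g", scale), file.path(dir, "scale.txt"))
  invisible(dir)
}

#' @rdname write_stain_tiff
#' @export
read_stain_tiff <- function(dir) {
  scale <- as.numeric(readLines(file.path(dir, "scale.txt")))
  h <- tiff::readTIFF(file.path(dir, "h.tiff")) * scale
  e <- tiff::readTIFF(file.path(dir, "e.tiff")) * scale
  mask_path <- file.path(dir, "mask.tiff")
  mask <- if (file.exists(mask_path)) tiff::readTIFF(mask_path) else NULL
  new_stain_pair(h, e, mask)
}

#' Preprocess an RGB image into masked 5x stain channels
#'
#' Convenience wrapper for the standard preparation: establish the background
#' mask, downscale 20x input to the 5x analysis scale (factor 4), and unmix
#' the stains.
#'
#' @param image numeric `h x w x 3` intensity array.
#' @param mask optional binary matrix (0 = background) at the input scale; if
#'   absent, near-white pixels are taken as background.
#' @param in_mag `"20x"` (downscaled by 4) or `"5x"` (used as is).
#' @param stain_matrix stain OD matrix, see [hed_stain_matrix()].
#' @param background_threshold intensity threshold for [background_mask()].
#' @return a `stain_pair` at the 5x scale with a (possibly fractional) mask.
#' @export
prepare_stains <- function(image, mask = NULL, in_mag = c("20x", "5x"),
                           stain_matrix = hed_stain_matrix(),
                           background_threshold = 240) {
  in_mag <- match.arg(in_mag)
  if (is.null(mask)) mask <- background_mask(image, background_threshold)
  factor <- if (in_mag == "20x") 4L else 1L
  image <- downscale(image, factor)
  mask <- downscale(mask, factor)
  deconvolve_stains(image, stain_matrix, mask = mask)
}
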