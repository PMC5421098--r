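#' Sample patch descriptors from one image
#'
#' Uniform sample without replacement among the image's *valid* patches
#' (invalid patches never contribute to codebook fitting). When fewer than
#' `n` valid patches exist, all of them are returned.
#'
#' @param desc_tbl descriptor tibble from [image_descriptors()].
#' @param n sample size per image (default 1000).
#' @param seed integer seed.
#' @return the sampled descriptor rows, or `NULL` (with a warning) when the
#'   image has no valid patch.
#' @export
sample_patch_descriptors <- function(desc_tbl, n = 1000L, seed = 1L) {
  valid <- which(desc_tbl$valid)
  if (!length(valid)) {
    warning("image has no valid patch; skipped")
    return(NULL)
  }
  if (length(valid) <= n) return(desc_tbl[valid, ])
  idx <- withr::with_seed(derive_seed(seed, "l1sample"),
                          sample(valid, n, replace = FALSE))
  desc_tbl[idx, ]
}

#' Fit the generic patch-level (L1) codebook
#'
#' Descriptors are z-scored per dimension (degenerate dimensions get unit
#' scale) and clustered with [kmeans_pp()]. The standardiser is stored with
#' the codebook and reused for all later encoding.
#'
#' @param descriptors numeric matrix (or descriptor tibble) of pooled training
#'   patch descriptors.
#' @param k1 number of codewords (default 128).
#' @param seed integer seed.
#' @param restarts,iter_max,tol clustering controls, see [kmeans_pp()].
#' @return a `codebook_l1`: list with `centroids` (`k1 x p`, standardised
#'   space), `center`, `scale` and `k1`.
#' @export
fit_codebook_l1 <- function(descriptors, k1 = 128L, seed = 1L, restarts = 5L,
                            iter_max = 300L, tol = 1e-4) {
  x <- if (is.matrix(descriptors)) descriptors else descriptor_matrix(descriptors)
  if (nrow(unique(x)) < k1) stop("fewer distinct descriptors than `k1`")
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  fit <- kmeans_pp(xs, k1, seed = derive_seed(seed, "l1fit"),
                   restarts = restarts, iter_max = iter_max, tol = tol)
  structure(list(centroids = fit$centers, center = center, scale = scale,
                 k1 = as.integer(k1), tot_withinss = fit$tot_withinss),
            class = "codebook_l1")
}

standardize_descriptors <- function(x, cb) {
  sweep(sweep(x, 2L, cb$center), 2L, cb$scale, "/")
}

#' Recode an image as a grid of L1 codes
#'
#' Every valid patch is assigned the 1-based index of its nearest codeword
#' (Euclidean distance in the standardised descriptor space, ties to the
#' lowest index); invalid patches get `NA`.
#'
#' @param desc_tbl descriptor tibble from [image_descriptors()].
#' @param cb a `codebook_l1`.
#' @return a `code_grid`: integer matrix (`patch rows x patch cols`, `NA` =
#'   invalid) with attribute `k1`.
#' @export
encode_l1 <- function(desc_tbl, cb) {
  stopifnot(inherits(cb, "codebook_l1"))
  x <- descriptor_matrix(desc_tbl)
  if (ncol(x) != ncol(cb$centroids)) stop("descriptor dimension mismatch")
  gr <- max(desc_tbl$patch_row) + 1L
  gc <- max(desc_tbl$patch_col) + 1L
  codes <- rep(NA_integer_, gr * gc)
  valid <- desc_tbl$valid
  if (any(valid)) {
    xs <- standardize_descriptors(x[valid, , drop = FALSE], cb)
    idx <- desc_tbl$patch_row[valid] * gc + desc_tbl$patch_col[valid] + 1L
    codes[idx] <- assign_nearest(xs, cb$centroids)
  }
  grid <- matrix(codes, gr, gc, byrow = TRUE)
  structure(grid, class = c("code_grid", "matrix"), k1 = cb$k1)
}

# Sliding-window sums of a matrix via 2-D cumulative sums; returns the
# (nr-W+1) x (nc-W+1) matrix of W x W window sums at every stride-1 position.
window_sums <- function(m, W) {
  S <- apply(apply(m, 2L, cumsum), 1L, cumsum)  # transposed cumsum matrix
  S <- t(S)
  nr <- nrow(m); nc <- ncol(m)
  Z <- matrix(0, nr + 1L, nc + 1L)
  Z[-1L, -1L] <- S
  i <- seq_len(nr - W + 1L); j <- seq_len(nc - W + 1L)
  Z[i + W, j + W, drop = FALSE] - Z[i, j + W, drop = FALSE] -
    Z[i + W, j, drop = FALSE] + Z[i, j, drop = FALSE]
}

# Frequencies of each L1 code over every stride-1 window of the grid.
# Returns list(freqs = npos x k1 matrix, valid = logical npos,
# window_row/window_col = 0-based positions, row-major order).
all_window_descriptors <- function(grid, window_patches = 15L) {
  k1 <- attr(grid, "k1")
  W <- window_patches
  if (nrow(grid) < W || ncol(grid) < W) stop("grid smaller than one window")
  nwr <- nrow(grid) - W + 1L
  nwc <- ncol(grid) - W + 1L
  nvalid <- window_sums((!is.na(grid)) * 1, W)
  counts <- vapply(seq_len(k1), function(cc) {
    window_sums((!is.na(grid) & grid == cc) * 1, W)
  }, matrix(0, nwr, nwc))
  valid <- (W * W - nvalid) / (W * W) <= 0.5   # > 50% invalid members => drop
  freqs <- matrix(counts, nwr * nwc, k1)       # column-major position order
  freqs <- freqs / as.vector(nvalid)
  list(freqs = freqs, valid = as.vector(valid),
       window_row = rep(0:(nwr - 1L), times = nwc),
       window_col = rep(0:(nwc - 1L), each = nwr))
}

#' Neighbourhood code-frequency (L2) descriptor
#'
#' Frequencies of the L1 codes among the valid patches of one
#' `window_patches x window_patches` neighbourhood. The window is unusable
#' when more than half of its member patches are invalid.
#'
#' @param grid a `code_grid` from [encode_l1()].
#' @param window_row,window_col 0-based top-left patch coordinates.
#' @param window_patches window side in patches (default 15, i.e. 480 px).
#' @return numeric vector of length `k1` summing to 1, or `NULL` when the
#'   window is invalid.
#' @export
l2_descriptor <- function(grid, window_row, window_col, window_patches = 15L) {
  W <- window_patches
  if (window_row < 0 || window_col < 0 || window_row + W > nrow(grid) ||
      window_col + W > ncol(grid)) {
    stop("window out of bounds")
  }
  codes <- grid[window_row + seq_len(W), window_col + seq_len(W)]
  n_invalid <- sum(is.na(codes))
  if (n_invalid / (W * W) > 0.5) return(NULL)
  tabulate(codes[!is.na(codes)], attr(grid, "k1")) / sum(!is.na(codes))
}

#' Sample L2 descriptors from one image
#'
#' Draws up to `n` window descriptors at uniformly random *valid* stride-1
#' window positions (all valid positions when fewer exist).
#'
#' @inheritParams l2_descriptor
#' @param n sample size per image (default 500).
#' @param seed integer seed.
#' @return numeric matrix with `k1` columns (possibly 0 rows).
#' @export
sample_l2_descriptors <- function(grid, n = 500L, window_patches = 15L,
                                  seed = 1L) {
  wd <- all_window_descriptors(grid, window_patches)
  idx <- which(wd$valid)
  if (!length(idx)) {
    warning("image has no valid window; skipped")
    return(matrix(0, 0L, attr(grid, "k1")))
  }
  if (length(idx) > n) {
    idx <- withr::with_seed(derive_seed(seed, "l2sample"),
                            sample(idx, n, replace = FALSE))
  }
  wd$freqs[idx, , drop = FALSE]
}

#' Fit the pair of class-specific L2 codebooks
#'
#' Clusters the pooled L2 descriptors of each class independently with
#' [kmeans_pp()] (no standardisation: frequency vectors are already
#' commensurate). The concatenated codeword index space is `1 .. 2 k2` with
#' the positive-class block first.
#'
#' @param pos_descriptors,neg_descriptors numeric matrices of pooled training
#'   L2 descriptors for the positive and negative class.
#' @param k2 codewords per class (default 128).
#' @param seed integer seed.
#' @param restarts,iter_max,tol clustering controls, see [kmeans_pp()].
#' @return a `codebook_l2_pair`: list with `positive` and `negative`
#'   centroid matrices and `k2`.
#' @export
fit_codebook_l2_pair <- function(pos_descriptors, neg_descriptors, k2 = 128L,
                                 seed = 1L, restarts = 5L, iter_max = 300L,
                                 tol = 1e-4) {
  fit_one <- function(x, tag) {
    if (nrow(unique(x)) < k2) {
      stop("class '", tag, "' has fewer distinct L2 descriptors than `k2`")
    }
    # same sub-seed for both blocks: identical class inputs give identical
    # codebooks, and the fits are independent either way
    kmeans_pp(x, k2, seed = derive_seed(seed, "l2fit"),
              restarts = restarts, iter_max = iter_max, tol = tol)$centers
  }
  structure(list(positive = fit_one(pos_descriptors, "positive"),
                 negative = fit_one(neg_descriptors, "negative"),
                 k2 = as.integer(k2)),
            class = "codebook_l2_pair")
}

#' Encode an image as a 2K2-bin codeword histogram
#'
#' Tiles the code grid with non-overlapping `window_patches` windows anchored
#' at patch (0, 0), assigns each valid window to its nearest codeword over the
#' concatenated positive-then-negative centroids (ties to the lowest index),
#' and normalises the assignment histogram to relative frequencies.
#'
#' @inheritParams l2_descriptor
#' @param pair a `codebook_l2_pair`.
#' @return an `image_histogram`: list with `bins` (length `2 k2`, summing to
#'   1) and a `windows` tibble (`window_row`, `window_col`, `valid`, `code`).
#' @export
encode_image <- function(grid, pair, window_patches = 15L) {
  stopifnot(inherits(pair, "codebook_l2_pair"))
  W <- window_patches
  nwr <- nrow(grid) %/% W
  nwc <- ncol(grid) %/% W
  if (nwr < 1L || nwc < 1L) stop("grid smaller than one window")
  pos <- expand.grid(window_row = (0:(nwr - 1L)) * W,
                     window_col = (0:(nwc - 1L)) * W)
  descs <- purrr::map2(pos$window_row, pos$window_col,
                       ~l2_descriptor(grid, .x, .y, W))
  valid <- !purrr::map_lgl(descs, is.null)
  if (!any(valid)) stop("image has no valid window; cannot be encoded")
  centroids <- rbind(pair$positive, pair$negative)
  codes <- rep(NA_integer_, nrow(pos))
  codes[valid] <- assign_nearest(do.call(rbind, descs[valid]), centroids)
  bins <- tabulate(codes[valid], 2L * pair$k2) / sum(valid)
  structure(list(bins = bins,
                 windows = tibble::tibble(window_row = pos$window_row,
                                          window_col = pos$window_col,
                                          valid = valid, code = codes)),
            class = "image_histogram")
}

#' @export
print.image_histogram <- function(x, ...) {
  cat("<image_histogram> ", length(x$bins), " bins, ",
      sum(x$windows$valid), "/", nrow(x$windows), " valid windows\n", sep = "")
  invisible(x)
}
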