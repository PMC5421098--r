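#' Real Gabor kernel
#'
#' Evaluates the real part of the Gabor filter on an odd square support:
#' `G(x, y) = exp(-(x^2 + y^2) / (2 sigma^2)) * cos(2 pi nu (x cos(theta) + y sin(theta)))`
#' where `x` is the column offset and `y` the row offset from the centre.
#' The kernel is used verbatim: no DC correction or normalisation.
#'
#' @param nu spatial frequency in cycles/pixel.
#' @param theta orientation in radians.
#' @param sigma Gaussian bandwidth in pixels.
#' @param support odd kernel side length; default the smallest odd integer
#'   `>= 6 * sigma + 1`.
#' @return a `support x support` numeric matrix.
#' @export
gabor_kernel <- function(nu, theta, sigma, support = gabor_support(sigma)) {
  stopifnot_scalar_pos(nu, "nu")
  stopifnot_scalar_pos(sigma, "sigma")
  if (support < 3L || support %% 2L == 0L) {
    stop("`support` must be an odd integer >= 3")
  }
  r <- (support - 1L) / 2L
  y <- matrix(seq(-r, r), support, support)        # row offsets
  x <- t(y)                                        # column offsets
  exp(-(x^2 + y^2) / (2 * sigma^2)) *
    cos(2 * pi * nu * (x * cos(theta) + y * sin(theta)))
}

#' @rdname gabor_kernel
#' @export
gabor_support <- function(sigma) {
  s <- as.integer(ceiling(6 * sigma + 1))
  max(3L, s + (1L - s %% 2L))
}

# Rank-1 separable factors of the real Gabor kernel:
# cos(a x + b y) = cos(a x) cos(b y) - sin(a x) sin(b y), each term the outer
# product of a column-offset factor (u) and a row-offset factor (v).
gabor_separable <- function(nu, theta, sigma, support = gabor_support(sigma)) {
  r <- (support - 1L) / 2L
  t <- seq(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  a <- 2 * pi * nu * cos(theta)
  b <- 2 * pi * nu * sin(theta)
  list(u1 = g * cos(a * t), v1 = g * cos(b * t),
       u2 = g * sin(a * t), v2 = -g * sin(b * t))
}

#' Build the fixed Gabor filter bank
#'
#' One kernel per element of the Cartesian product of the parameter sets, in
#' sigma-major order (then theta, then nu). The defaults give the fixed
#' 24-filter bank: `sigma` in `{1, 2 sqrt(2)}`, `theta` in `{0, pi/4, pi/2,
#' 3 pi/4}` and `nu` in `{3/4, 3/8, 3/16}` cycles/pixel.
#'
#' @param sigma,theta,nu numeric parameter sets (non-empty).
#' @return a `gabor_bank`: list with a `params` tibble (`sigma`, `theta`,
#'   `nu`, `support`) and a `kernels` list of matrices.
#' @export
gabor_bank <- function(sigma = c(1, 2 * sqrt(2)),
                       theta = pi / 4 * (0:3),
                       nu = c(3 / 4, 3 / 8, 3 / 16)) {
  if (!length(sigma) || !length(theta) || !length(nu)) {
    stop("parameter sets must be non-empty")
  }
  sigma_col <- rep(sigma, each = length(theta) * length(nu))
  theta_col <- rep(rep(theta, each = length(nu)), times = length(sigma))
  nu_col <- rep(nu, times = length(sigma) * length(theta))
  params <- tibble::tibble(sigma = sigma_col, theta = theta_col, nu = nu_col)
  params$support <- vapply(params$sigma, gabor_support, integer(1))
  kernels <- purrr::pmap(params, function(sigma, theta, nu, support) {
    gabor_kernel(nu, theta, sigma, support)
  })
  separable <- purrr::pmap(params, function(sigma, theta, nu, support) {
    gabor_separable(nu, theta, sigma, support)
  })
  structure(list(params = params, kernels = kernels, separable = separable),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat("<gabor_bank> ", nrow(x$params), " kernels (sigma-major order)\n", sep = "")
  print(x$params, n = 6)
  invisible(x)
}

#' @export
length.gabor_bank <- function(x) nrow(x$params)

#' Filter a channel with every kernel of a bank
#'
#' Computes the 2-D cross-correlation of the channel with each kernel, with
#' symmetric (reflect) border padding; responses have the same dimensions as
#' the input.
#'
#' @param channel numeric matrix.
#' @param bank a [gabor_bank()].
#' @return list of response matrices, one per kernel, in bank order.
#' @export
filter_channel <- function(channel, bank) {
  stopifnot(inherits(bank, "gabor_bank"), is.matrix(channel))
  if (min(dim(channel)) < max(bank$params$support)) {
    stop("channel smaller than the largest kernel support")
  }
  cpp_bank_responses(channel, bank$separable)
}

#' Gabor descriptor of one patch
#'
#' Mean and population variance of every filter response over one
#' `patch_px x patch_px` patch, concatenated as
#' `[H means, H variances, E means, E variances]` (96 values for the default
#' 24-filter bank).
#'
#' @param h_resp,e_resp response stacks from [filter_channel()] on the
#'   haematoxylin and eosin channels.
#' @param patch_row,patch_col 0-based patch-grid coordinates.
#' @param patch_px patch side in pixels.
#' @return numeric vector of length `4 * nfilters`.
#' @export
patch_descriptor <- function(h_resp, e_resp, patch_row, patch_col,
                             patch_px = 32L) {
  h <- nrow(h_resp[[1]]); w <- ncol(h_resp[[1]])
  rows <- patch_row * patch_px + seq_len(patch_px)
  cols <- patch_col * patch_px + seq_len(patch_px)
  if (patch_row < 0 || patch_col < 0 || max(rows) > h || max(cols) > w) {
    stop("patch out of bounds")
  }
  pop_var <- function(v) mean(v^2) - mean(v)^2
  stat <- function(stack, f) {
    vapply(stack, function(r) f(r[rows, cols]), numeric(1))
  }
  c(stat(h_resp, mean), stat(h_resp, pop_var),
    stat(e_resp, mean), stat(e_resp, pop_var))
}

#' All patch descriptors of a stain pair
#'
#' Tiles the image with non-overlapping `patch_px` patches anchored at the
#' top-left corner and computes the Gabor descriptor of every patch, plus its
#' validity under the more-than-50%-background exclusion rule. Patches are
#' 0-based and row-major.
#'
#' @param stains a `stain_pair` at the analysis scale.
#' @param bank a [gabor_bank()].
#' @param patch_px patch side in pixels (default 32).
#' @return a tibble with `patch_row`, `patch_col`, `valid` and descriptor
#'   columns `v1 ... v96`.
#' @export
image_descriptors <- function(stains, bank = gabor_bank(), patch_px = 32L) {
  stopifnot(inherits(stains, "stain_pair"))
  gr <- nrow(stains$h) %/% patch_px
  gc <- ncol(stains$h) %/% patch_px
  if (gr < 1L || gc < 1L) stop("image smaller than one patch")
  mh <- cpp_bank_patch_moments(stains$h, bank$separable, as.integer(patch_px))
  me <- cpp_bank_patch_moments(stains$e, bank$separable, as.integer(patch_px))
  desc <- cbind(mh$means, mh$vars, me$means, me$vars)
  colnames(desc) <- paste0("v", seq_len(ncol(desc)))
  if (is.null(stains$mask)) {
    valid <- rep(TRUE, gr * gc)
  } else {
    valid <- as.vector(t(patch_validity(stains$mask, patch_px)))  # row-major
  }
  out <- tibble::tibble(
    patch_row = rep(0:(gr - 1L), each = gc),
    patch_col = rep(0:(gc - 1L), times = gr),
    valid = valid
  )
  dplyr::bind_cols(out, tibble::as_tibble(desc))
}

descriptor_matrix <- function(desc_tbl) {
  cols <- grep("^v[0-9]+$", names(desc_tbl), value = TRUE)
  m <- as.matrix(desc_tbl[cols])
  storage.mode(m) <- "double"
  m
}
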