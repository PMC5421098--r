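#' Derive a reproducible sub-seed from a base seed and a key
#'
#' All stochastic stages (patch sampling, k-means restarts, fold splitting,
#' cohort rendering) draw their seeds through this function, so that a stage's
#' randomness depends only on the base seed and on *what* is being computed
#' (e.g. the sorted ids of the training images), never on unrelated state such
#' as the composition of a held-out fold.
#'
#' @param seed integer base seed.
#' @param ... character or numeric keys mixed into the hash, in order.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- paste(vapply(list(...), paste, "", collapse = "|"), collapse = "|")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(keys)) h <- (h * 31 + code) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that class counts per fold
#' differ by at most one within each class.
#'
#' @param y factor or vector of class labels.
#' @param k number of folds.
#' @param seed integer seed for the within-class shuffle.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (any(table(y) < k)) {
    stop("each class must have at least `k` samples to stratify into ", k, " folds")
  }
  folds <- integer(length(y))
  withr::with_seed(derive_seed(seed, "folds", length(y), k), {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a positive scalar")
  }
  invisible(x)
}
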