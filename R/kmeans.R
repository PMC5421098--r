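#' k-means with k-means++ initialisation
#'
#' Lloyd iterations from a k-means++ start, stopping when the relative drop
#' of the within-cluster sum of squares falls below `tol` or after `iter_max`
#' iterations; the best of `restarts` independent starts (by final objective)
#' is returned. Nearest-centroid ties go to the lowest centroid index, and
#' empty clusters are re-seeded at the point farthest from its centroid, so
#' the fit is fully deterministic given the seed.
#'
#' @param x numeric matrix, one observation per row.
#' @param k number of clusters (`>= 1`, at most the number of distinct rows).
#' @param seed integer seed.
#' @param restarts independent k-means++ starts (default 5).
#' @param iter_max maximum Lloyd iterations per start (default 300).
#' @param tol relative objective-change tolerance (default 1e-4).
#' @return list with `centers` (`k x p`), `cluster` (1-based assignments) and
#'   `tot_withinss`.
#' @export
kmeans_pp <- function(x, k, seed = 1L, restarts = 5L, iter_max = 300L,
                      tol = 1e-4) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (k < 1L) stop("`k` must be >= 1")
  if (nrow(unique(x)) < k) stop("fewer distinct points than clusters")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- withr::with_seed(derive_seed(seed, "kmeanspp", r), {
      centers <- kmeanspp_init(x, k)
      lloyd(x, centers, iter_max, tol)
    })
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  best
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    if (all(d2 <= 0)) {
      i <- sample.int(n, 1L)
    } else {
      i <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

# Squared Euclidean distances between rows of x (n x p) and centers (k x p).
dist2_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

# Nearest centroid, ties to the lowest index.
assign_nearest <- function(x, centers) {
  max.col(-dist2_to_centers(x, centers), ties.method = "first")
}

lloyd <- function(x, centers, iter_max, tol) {
  n <- nrow(x); k <- nrow(centers)
  obj_prev <- Inf
  cl <- integer(n)
  for (it in seq_len(iter_max)) {
    d2 <- dist2_to_centers(x, centers)
    cl <- max.col(-d2, ties.method = "first")
    obj <- sum(d2[cbind(seq_len(n), cl)])
    sizes <- tabulate(cl, k)
    if (any(sizes == 0L)) {
      # re-seed each empty cluster at the currently worst-fitted point
      for (j in which(sizes == 0L)) {
        far <- which.max(d2[cbind(seq_len(n), cl)])
        centers[j, ] <- x[far, ]
        cl[far] <- j
        d2[far, ] <- Inf
      }
      sizes <- tabulate(cl, k)
    }
    centers <- rowsum(x, cl) / sizes
    if (is.finite(obj_prev) && (obj_prev - obj) <= tol * obj_prev) break
    obj_prev <- obj
  }
  d2 <- dist2_to_centers(x, centers)
  cl <- max.col(-d2, ties.method = "first")
  dimnames(centers) <- NULL
  list(centers = centers, cluster = cl,
       tot_withinss = sum(d2[cbind(seq_len(n), cl)]))
}
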