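# Independent brute-force oracles used across tests. These deliberately avoid
# the package's own implementation paths.

# Direct 2-D cross-correlation with symmetric (reflect) padding.
oracle_corr2d <- function(img, k) {
  r <- (nrow(k) - 1) / 2
  h <- nrow(img); w <- ncol(img)
  refl <- function(i, n) {
    i <- ifelse(i < 0, -i - 1, i)
    ifelse(i >= n, 2 * n - i - 1, i)
  }
  out <- matrix(0, h, w)
  for (dy in -r:r) {
    for (dx in -r:r) {
      ii <- refl(refl((seq_len(h) - 1) + dy, h), h) + 1
      jj <- refl(refl((seq_len(w) - 1) + dx, w), w) + 1
      out <- out + k[dy + r + 1, dx + r + 1] * img[ii, jj]
    }
  }
  out
}

# Block means by explicit looping (partial edge blocks over available pixels).
oracle_block_mean <- function(x, f) {
  gr <- ceiling(nrow(x) / f); gc <- ceiling(ncol(x) / f)
  out <- matrix(0, gr, gc)
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      ri <- ((i - 1) * f + 1):min(i * f, nrow(x))
      ci <- ((j - 1) * f + 1):min(j * f, ncol(x))
      out[i, j] <- mean(x[ri, ci, drop = FALSE])
    }
  }
  out
}

# Exhaustive-partition k-means objective: minimum total within-cluster sum of
# squares over all assignments of n points to k labels.
oracle_kmeans_objective <- function(x, k) {
  n <- nrow(x)
  stopifnot(n <= 12, k <= 3)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      obj <- 0
      for (c in unique(assign)) {
        xi <- x[assign == c, , drop = FALSE]
        ctr <- colMeans(xi)
        obj <- obj + sum(sweep(xi, 2, ctr)^2)
      }
      best <- min(best, obj)
    }
    i <- 1L
    while (i <= n && assign[i] == k) {
      assign[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# Pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "pos"]
  neg <- scores[labels == "neg"]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Closed-form Yates-corrected chi-squared for a 2x2 table.
oracle_chi2_yates <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((pmax(abs(tab - e) - 0.5, 0))^2 / e)
}

# Agresti-Coull interval straight from the definition.
oracle_agresti_coull <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  nt <- n + z^2
  pt <- (x + z^2 / 2) / nt
  c(max(0, pt - z * sqrt(pt * (1 - pt) / nt)),
    min(1, pt + z * sqrt(pt * (1 - pt) / nt)))
}
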