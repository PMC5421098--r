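test_that("kmeans_pp reaches the exhaustive-partition optimum on small data", {
  for (s in 1:4) {
    x <- withr::with_seed(s, matrix(rnorm(10 * 2), 10, 2))
    k <- 2L + s %% 2L
    fit <- kmeans_pp(x, k, seed = s)
    expect_equal(fit$tot_withinss, oracle_kmeans_objective(x, k),
                 tolerance = 1e-8)
  }
})

test_that("kmeans_pp agrees with stats::kmeans on well-separated blobs", {
  x <- withr::with_seed(10, rbind(matrix(rnorm(100, 0), 50, 2),
                                  matrix(rnorm(100, 8), 50, 2)))
  fit <- kmeans_pp(x, 2, seed = 1)
  ref <- withr::with_seed(1, stats::kmeans(x, 2, nstart = 10))
  expect_equal(fit$tot_withinss, ref$tot.withinss, tolerance = 1e-6)
  # centroids within 3 standard errors of the blob means
  ctr <- fit$centers[order(fit$centers[, 1]), ]
  expect_lt(max(abs(ctr[1, ] - 0)), 3 / sqrt(50))
  expect_lt(max(abs(ctr[2, ] - 8)), 3 / sqrt(50))
})

test_that("kmeans_pp with k = n returns the points themselves", {
  x <- withr::with_seed(2, matrix(rnorm(8), 4, 2))
  fit <- kmeans_pp(x, 4, seed = 1)
  expect_equal(fit$tot_withinss, 0, tolerance = 1e-12)
  expect_equal(x[order(x[, 1]), ], fit$centers[order(fit$centers[, 1]), ])
  expect_error(kmeans_pp(x[c(1, 1, 2), ], 3), "distinct")
})

test_that("kmeans_pp beats a random-assignment baseline", {
  x <- withr::with_seed(3, matrix(rnorm(60 * 4), 60, 4))
  fit <- kmeans_pp(x, 5, seed = 9)
  base <- withr::with_seed(99, {
    cl <- sample(1:5, 60, replace = TRUE)
    sum(vapply(1:5, function(c) {
      xi <- x[cl == c, , drop = FALSE]
      if (!nrow(xi)) return(0)
      sum(sweep(xi, 2, colMeans(xi))^2)
    }, numeric(1)))
  })
  expect_lt(fit$tot_withinss, base)
})

test_that("patch sampling caps at the valid-patch count and is deterministic", {
  tbl <- tibble::tibble(patch_row = rep(0:9, each = 10),
                        patch_col = rep(0:9, times = 10),
                        valid = rep(c(TRUE, FALSE), c(60, 40)))
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(matrix(rnorm(100 * 4), 100, 4,
                          dimnames = list(NULL, paste0("v", 1:4)))))
  s1 <- sample_patch_descriptors(tbl, n = 30, seed = 5)
  expect_equal(nrow(s1), 30L)
  expect_true(all(s1$valid))
  expect_identical(s1, sample_patch_descriptors(tbl, n = 30, seed = 5))
  expect_equal(nrow(sample_patch_descriptors(tbl, n = 1000, seed = 5)), 60L)
  none <- dplyr::mutate(tbl, valid = FALSE)
  expect_warning(out <- sample_patch_descriptors(none, 10, 1), "no valid patch")
  expect_null(out)
})

test_that("L1 codebook recovers well-separated descriptor blobs", {
  x <- withr::with_seed(4, rbind(matrix(rnorm(300, 0, 1), 100, 3),
                                 matrix(rnorm(300, 10, 1), 100, 3)))
  cb <- fit_codebook_l1(x, k1 = 2, seed = 1)
  raw <- sweep(sweep(cb$centroids, 2, cb$scale, "*"), 2, -cb$center)
  raw <- raw[order(raw[, 1]), ]
  expect_lt(max(abs(raw[1, ] - 0)), 3 / sqrt(100))
  expect_lt(max(abs(raw[2, ] - 10)), 3 / sqrt(100))
  expect_error(fit_codebook_l1(x[1:3, ], k1 = 5), "fewer distinct")
})

test_that("L1 encoding assigns nearest codewords with low-index ties", {
  cb <- structure(list(centroids = rbind(c(0, 0), c(1, 0), c(2, 0)),
                       center = c(0, 0), scale = c(1, 1), k1 = 3L),
                  class = "codebook_l1")
  tbl <- tibble::tibble(patch_row = c(0L, 0L, 1L, 1L),
                        patch_col = c(0L, 1L, 0L, 1L),
                        valid = c(TRUE, TRUE, TRUE, FALSE),
                        v1 = c(1, 0.5, 2.2, 9), v2 = c(0, 0, 0, 9))
  grid <- encode_l1(tbl, cb)
  expect_equal(grid[1, 1], 2L)          # exact centroid match
  expect_equal(grid[1, 2], 1L)          # equidistant 1 and 2 -> lowest index
  expect_equal(grid[2, 1], 3L)
  expect_true(is.na(grid[2, 2]))        # invalid patch -> sentinel
  expect_true(all(grid[!is.na(grid)] %in% 1:3))
})

test_that("L2 descriptors are valid frequency vectors with the >50% rule", {
  g <- make_code_grid(matrix(5L, 20, 20), k1 = 8)
  d <- l2_descriptor(g, 0, 0, 15)
  expect_equal(d, c(0, 0, 0, 0, 1, 0, 0, 0))

  mixed <- matrix(rep(c(1L, 2L), length.out = 225), 15, 15)
  gm <- make_code_grid(mixed, k1 = 4)
  dm <- l2_descriptor(gm, 0, 0, 15)
  expect_equal(sum(dm), 1)

  # 113 of 225 member patches invalid: just over half -> window unusable
  codes <- matrix(1L, 15, 15)
  codes[seq_len(113)] <- NA_integer_
  gi <- make_code_grid(codes, k1 = 4)
  expect_null(l2_descriptor(gi, 0, 0, 15))
  codes[113] <- 1L  # 112/225 invalid: valid again
  expect_false(is.null(l2_descriptor(make_code_grid(codes, k1 = 4), 0, 0, 15)))

  expect_error(l2_descriptor(g, 10, 0, 15), "out of bounds")
})

test_that("sampled L2 descriptors match direct window evaluation", {
  codes <- withr::with_seed(12, matrix(sample(1:4, 30 * 24, TRUE), 30, 24))
  g <- make_code_grid(codes, k1 = 4)
  s <- sample_l2_descriptors(g, n = 10, seed = 3)
  expect_equal(nrow(s), 10L)
  expect_equal(rowSums(s), rep(1, 10))
  # all stride-1 windows, against l2_descriptor directly
  all_w <- histocode:::all_window_descriptors(g, 15L)
  i <- which(all_w$window_row == 3 & all_w$window_col == 7)
  expect_equal(all_w$freqs[i, ], l2_descriptor(g, 3, 7, 15))
})

test_that("the L2 pair is deterministic and spans 2 k2 codewords", {
  x <- withr::with_seed(13, matrix(abs(rnorm(200 * 4)), 200, 4))
  x <- x / rowSums(x)
  p1 <- fit_codebook_l2_pair(x, x, k2 = 3, seed = 7)
  p2 <- fit_codebook_l2_pair(x, x, k2 = 3, seed = 7)
  expect_equal(p1$positive, p1$negative)   # identical input per class
  expect_equal(p1, p2)
  expect_equal(nrow(rbind(p1$positive, p1$negative)), 6L)
  expect_error(fit_codebook_l2_pair(x[1:2, ], x, k2 = 3), "positive")
})

test_that("class-exclusive motifs sort into the matching codebook block", {
  # class descriptors concentrated on disjoint code supports
  make_class <- function(n, support, k1 = 8, seed) {
    withr::with_seed(seed, {
      f <- matrix(0, n, k1)
      for (i in seq_len(n)) {
        w <- abs(rnorm(length(support))) + 0.2
        f[i, support] <- w / sum(w)
      }
      f
    })
  }
  pos <- make_class(120, 1:4, seed = 21)
  neg <- make_class(120, 5:8, seed = 22)
  pair <- fit_codebook_l2_pair(pos[1:100, ], neg[1:100, ], k2 = 4, seed = 2)
  centroids <- rbind(pair$positive, pair$negative)
  held <- rbind(pos[101:120, ], neg[101:120, ])
  truth <- rep(c("pos", "neg"), each = 20)
  assigned <- histocode:::assign_nearest(held, centroids)
  block <- ifelse(assigned <= 4, "pos", "neg")
  expect_gte(mean(block == truth), 0.9)
})

test_that("image encoding tiles windows, normalises, and is order-invariant", {
  codes <- withr::with_seed(14, matrix(sample(1:4, 30 * 30, TRUE), 30, 30))
  g <- make_code_grid(codes, k1 = 4)
  pos <- withr::with_seed(15, matrix(abs(rnorm(12)), 3, 4)); pos <- pos / rowSums(pos)
  neg <- withr::with_seed(16, matrix(abs(rnorm(12)), 3, 4)); neg <- neg / rowSums(neg)
  pair <- structure(list(positive = pos, negative = neg, k2 = 3L),
                    class = "codebook_l2_pair")
  h <- encode_image(g, pair)
  expect_length(h$bins, 6L)
  expect_equal(sum(h$bins), 1)
  expect_equal(nrow(h$windows), 4L)

  # single-window grid whose descriptor equals positive centroid 1
  g1 <- make_code_grid(matrix(1L, 15, 15), k1 = 4)
  pair1 <- structure(list(positive = rbind(c(1, 0, 0, 0), c(0, 0, 0, 1)),
                          negative = rbind(c(0, 1, 0, 0), c(0, 0, 1, 0)),
                          k2 = 2L), class = "codebook_l2_pair")
  h1 <- encode_image(g1, pair1)
  expect_equal(h1$bins, c(1, 0, 0, 0))

  all_na <- make_code_grid(matrix(NA_integer_, 15, 15), k1 = 4)
  expect_error(encode_image(all_na, pair1), "no valid window")
})

test_that("histogram length defaults to 256 with K2 = 128", {
  pair <- structure(list(positive = matrix(runif(128 * 4), 128, 4),
                         negative = matrix(runif(128 * 4), 128, 4),
                         k2 = 128L), class = "codebook_l2_pair")
  g <- make_code_grid(matrix(2L, 15, 15), k1 = 4)
  expect_length(encode_image(g, pair)$bins, 256L)
})

test_that("histograms are invariant to whole-window translation of the mosaic", {
  base <- withr::with_seed(17, matrix(sample(1:4, 15 * 15, TRUE), 15, 15))
  tiled <- rbind(cbind(base, base), cbind(base, base))   # 30 x 30 periodic
  g <- make_code_grid(tiled, k1 = 4)
  shifted <- tiled[c(16:30, 1:15), c(16:30, 1:15)]       # shift by one window
  gs <- make_code_grid(shifted, k1 = 4)
  pos <- withr::with_seed(18, matrix(abs(rnorm(8)), 2, 4)); pos <- pos / rowSums(pos)
  neg <- withr::with_seed(19, matrix(abs(rnorm(8)), 2, 4)); neg <- neg / rowSums(neg)
  pair <- structure(list(positive = pos, negative = neg, k2 = 2L),
                    class = "codebook_l2_pair")
  expect_equal(encode_image(g, pair)$bins, encode_image(gs, pair)$bins)
})
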