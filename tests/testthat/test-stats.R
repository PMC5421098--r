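test_that("confusion matrices match a brute-force tally", {
  pred <- c("pos", "pos", "neg", "neg", "pos")
  truth <- c("pos", "neg", "pos", "neg", "pos")
  cm <- confusion(pred, truth)
  expect_equal(unlist(cm[c("tn", "fp", "fn", "tp")], use.names = FALSE),
               c(1L, 1L, 1L, 2L))
  withr::with_seed(30, {
    p <- sample(c("pos", "neg"), 20, TRUE)
    t <- sample(c("pos", "neg"), 20, TRUE)
  })
  cm2 <- confusion(p, t)
  expect_equal(cm2$tp, sum(p == "pos" & t == "pos"))
  expect_equal(cm2$tn, sum(p == "neg" & t == "neg"))
  expect_equal(cm2$fp, sum(p == "pos" & t == "neg"))
  expect_equal(cm2$fn, sum(p == "neg" & t == "pos"))
  perfect <- confusion(t, t)
  expect_equal(perfect$fp + perfect$fn, 0L)
  expect_error(confusion(p[1:3], t), "equal length")
})

test_that("sensitivity and accuracy reproduce the published cross-validated values", {
  cm <- structure(list(tn = 221L, fp = 11L, fn = 9L, tp = 50L),
                  class = "confusion_matrix")
  m <- binary_metrics(cm)
  expect_equal(m$sensitivity, 50 / 59)
  expect_lt(abs(m$sensitivity - 0.848), 1e-3)  # published rounding
  expect_equal(round(m$accuracy, 3), 0.931)
  expect_equal(round(m$specificity, 3), 0.953)
  all_right <- binary_metrics(confusion(c("neg", "pos"), c("neg", "pos")))
  expect_equal(unlist(all_right, use.names = FALSE), c(1, 1, 1))
  degenerate <- binary_metrics(structure(list(tn = 0L, fp = 0L, fn = 2L, tp = 3L),
                                         class = "confusion_matrix"))
  expect_true(is.na(degenerate$specificity))
  expect_false(is.na(degenerate$sensitivity))
})

test_that("Agresti-Coull intervals match published intervals and the closed form", {
  se <- agresti_coull_ci(50, 59)
  expect_equal(round(c(se$lower, se$upper), 3), c(0.733, 0.920))
  acc <- agresti_coull_ci(271, 291)
  expect_equal(round(c(acc$lower, acc$upper), 3), c(0.896, 0.956))
  sp <- agresti_coull_ci(221, 232)
  expect_equal(round(sp$upper, 3), 0.974)
  zero <- agresti_coull_ci(0, 10)
  expect_equal(zero$lower, 0)
  expect_error(agresti_coull_ci(11, 10), "x <= n")
  withr::with_seed(41, {
    for (i in 1:20) {
      n <- sample(5:500, 1)
      x <- sample(0:n, 1)
      ci <- agresti_coull_ci(x, n)
      expect_equal(c(ci$lower, ci$upper), oracle_agresti_coull(x, n),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC equals the pairwise-comparison oracle and handles ties", {
  expect_equal(auc(c(1, 2, 3, 10, 11), c("neg", "neg", "neg", "pos", "pos")), 1)
  expect_equal(auc(rep(1, 6), rep(c("neg", "pos"), 3)), 0.5)
  withr::with_seed(42, {
    for (i in 1:10) {
      s <- sample(1:6, 12, TRUE)  # plenty of ties
      y <- c(rep("pos", 5), rep("neg", 7))
      expect_equal(auc(s, y), oracle_auc(s, y))
    }
  })
  expect_error(auc(1:3, rep("pos", 3)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(43, {
    s <- rnorm(40)
    y <- rep(c("pos", "neg"), 20)
  })
  a <- auc(s, y)
  expect_equal(auc(exp(s), y), a)
  expect_equal(auc(2 * s - 7, y), a)
  expect_equal(auc(atan(s), y), a)
})

test_that("bootstrap AUC intervals are deterministic and cover the point", {
  y <- rep(c("pos", "neg"), c(10, 30))
  withr::with_seed(44, s <- c(rnorm(10, 1.5), rnorm(30)))
  ci1 <- bootstrap_auc_ci(s, y, reps = 500, seed = 9)
  ci2 <- bootstrap_auc_ci(s, y, reps = 500, seed = 9)
  expect_equal(ci1, ci2)
  expect_lte(ci1$lower, ci1$point)
  expect_gte(ci1$upper, ci1$point)

  perfect <- bootstrap_auc_ci(c(1, 2, 3, 11, 12), c("neg", "neg", "neg", "pos", "pos"),
                              reps = 200, seed = 1)
  expect_equal(c(perfect$lower, perfect$upper), c(1, 1))
  expect_warning(bootstrap_auc_ci(s, y, reps = 50, seed = 1), "100")
})

test_that("the bootstrap interval covers the point AUC across cohorts", {
  hits <- 0
  for (i in 1:50) {
    withr::with_seed(100 + i, {
      y <- rep(c("pos", "neg"), c(8, 22))
      s <- c(rnorm(8, 1), rnorm(22))
    })
    ci <- bootstrap_auc_ci(s, y, reps = 200, seed = i)
    hits <- hits + (ci$point >= ci$lower && ci$point <= ci$upper)
  }
  expect_gte(hits, 48)
})

test_that("chi-squared 2x2 uses the Yates closed form", {
  even <- matrix(c(50, 50, 50, 50), 2)
  r <- chi2_2x2(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  sep <- matrix(c(10, 0, 0, 10), 2)
  r2 <- chi2_2x2(sep)
  expect_lt(r2$p_value, 0.01)
  expect_equal(r2$statistic, oracle_chi2_yates(sep), tolerance = 1e-12)
  withr::with_seed(46, {
    for (i in 1:10) {
      tab <- matrix(sample(5:60, 4, TRUE), 2)
      expect_equal(chi2_2x2(tab)$statistic, oracle_chi2_yates(tab),
                   tolerance = 1e-10)
    }
  })
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("independent 2x2 tables give approximately uniform p-values", {
  ps <- vapply(1:500, function(i) {
    withr::with_seed(1000 + i, {
      a <- rbinom(1, 250, 0.5)
      b <- rbinom(1, 250, 0.5)
      tab <- rbind(c(a, 250 - a), c(b, 250 - b))
    })
    chi2_2x2(tab)$p_value
  }, numeric(1))
  # Yates correction makes the test conservative; uniformity is approximate
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(mean(ps > 0.5), 0.4)
  expect_gt(ks$p.value, 1e-6)
})

test_that("feature polarity follows the logistic slope sign", {
  withr::with_seed(47, {
    y <- rep(c("pos", "neg"), c(40, 60))
    noise <- rnorm(100, 0, 0.05)
  })
  f_pos <- (y == "pos") + noise
  expect_equal(feature_polarity(f_pos, y)$polarity, "positive")
  expect_equal(feature_polarity(1 - (y == "pos") + noise, y)$polarity, "negative")
  expect_equal(feature_polarity(rep(2, 100), y)$polarity, "undetermined")
})

test_that("polarity detects a planted odds-ratio-3 feature with high power", {
  correct <- 0
  for (i in 1:100) {
    withr::with_seed(2000 + i, {
      x <- rnorm(300)
      p <- plogis(log(3) * x - 1)
      y <- ifelse(runif(300) < p, "pos", "neg")
    })
    if (length(unique(y)) == 2 &&
        feature_polarity(x, y)$polarity == "positive") {
      correct <- correct + 1
    }
  }
  expect_gte(correct, 95)
})

test_that("spatial feature maps are disjoint and confined to valid windows", {
  codes <- withr::with_seed(48, matrix(sample(1:4, 30 * 30, TRUE), 30, 30))
  codes[1:15, 1:15] <- NA_integer_   # one unusable window
  g <- make_code_grid(codes, k1 = 4)
  pos <- withr::with_seed(49, matrix(abs(rnorm(8)), 2, 4)); pos <- pos / rowSums(pos)
  neg <- withr::with_seed(50, matrix(abs(rnorm(8)), 2, 4)); neg <- neg / rowSums(neg)
  pair <- structure(list(positive = pos, negative = neg, k2 = 2L),
                    class = "codebook_l2_pair")
  pol <- tibble::tibble(feature_index = 1:4,
                        coefficient_sign = c(1L, 1L, -1L, -1L),
                        polarity = c("positive", "positive", "negative", "negative"))
  maps <- spatial_feature_map(g, pair, selected = 1:4, polarity = pol)
  expect_false(any(maps$positive & maps$negative))
  valid <- matrix(maps$assignments$valid[order(maps$assignments$window_row,
                                               maps$assignments$window_col)],
                  2, 2, byrow = TRUE)
  expect_true(all((maps$positive | maps$negative) <= valid))
  expect_error(spatial_feature_map(g, pair, selected = 1:4, polarity = pol[1:2, ]),
               "cover")
})

test_that("an all-positive-motif image is covered by the positive map", {
  g <- make_code_grid(matrix(1L, 30, 30), k1 = 4)
  pair <- structure(list(positive = rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)),
                         negative = rbind(c(0, 0, 1, 0), c(0, 0, 0, 1)),
                         k2 = 2L), class = "codebook_l2_pair")
  pol <- tibble::tibble(feature_index = 1:4,
                        coefficient_sign = c(1L, 1L, -1L, -1L),
                        polarity = c("positive", "positive", "negative", "negative"))
  maps <- spatial_feature_map(g, pair, selected = 1:4, polarity = pol)
  expect_gte(mean(maps$positive), 0.9)
})

test_that("threshold sweep trades sensitivity against specificity monotonically", {
  withr::with_seed(51, {
    s <- rnorm(60)
    y <- rep(c("pos", "neg"), 30)
  })
  sweep_tbl <- threshold_sweep(s, y)
  expect_true(all(diff(sweep_tbl$sensitivity) <= 1e-12))
  expect_true(all(diff(sweep_tbl$specificity) >= -1e-12))
})
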