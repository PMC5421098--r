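#' Confusion matrix of binary predictions
#'
#' Cross-tabulates predictions against the ground truth (rows = truth,
#' columns = prediction in the `tn/fp/fn/tp` naming).
#'
#' @param pred_labels,true_labels equal-length label vectors, coercible by
#'   [as_class_factor()].
#' @return a `confusion_matrix`: list with counts `tn`, `fp`, `fn`, `tp`.
#' @export
confusion <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) {
    stop("prediction and truth vectors must have equal length")
  }
  pred <- as_class_factor(pred_labels)
  truth <- as_class_factor(true_labels)
  structure(list(
    tn = sum(truth == negative_level & pred == negative_level),
    fp = sum(truth == negative_level & pred == positive_level),
    fn = sum(truth == positive_level & pred == negative_level),
    tp = sum(truth == positive_level & pred == positive_level)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("neg", "pos"),
                              predicted = c("neg", "pos")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy
#'
#' `Se = tp / (tp + fn)`, `Sp = tn / (tn + fp)`,
#' `Acc = (tp + tn) / total`. A metric whose denominator is zero is returned
#' as `NA` (flagged, never silently 0).
#'
#' @param cm a `confusion_matrix` (or list with `tn`, `fp`, `fn`, `tp`).
#' @return list with `sensitivity`, `specificity`, `accuracy`.
#' @export
binary_metrics <- function(cm) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = ratio(cm$tp, cm$tp + cm$fn),
       specificity = ratio(cm$tn, cm$tn + cm$fp),
       accuracy = ratio(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn))
}

#' Agresti-Coull interval for a binomial proportion
#'
#' With `z` the standard-normal quantile at `(1 + level) / 2`, the adjusted
#' count is `n~ = n + z^2`, the adjusted proportion
#' `p~ = (x + z^2 / 2) / n~`, and the interval
#' `p~ +/- z sqrt(p~ (1 - p~) / n~)`, clipped to `[0, 1]`.
#'
#' @param x successes (`0 <= x <= n`).
#' @param n trials (`>= 1`).
#' @param level confidence level (default 0.95).
#' @return tibble with `point` (`x / n`), `lower`, `upper`, `level`.
#' @export
agresti_coull_ci <- function(x, n, level = 0.95) {
  if (n < 1 || x < 0 || x > n) stop("need 0 <= x <= n with n >= 1")
  z <- qnorm((1 + level) / 2)
  n_t <- n + z^2
  p_t <- (x + z^2 / 2) / n_t
  hw <- z * sqrt(p_t * (1 - p_t) / n_t)
  tibble::tibble(point = x / n,
                 lower = max(0, p_t - hw),
                 upper = min(1, p_t + hw),
                 level = level)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimate: the probability that a random
#' positive scores above a random negative, ties counted half. Scores are
#' never reoriented; an AUC below 0.5 is reported as is.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels class labels, see [as_class_factor()].
#' @export
auc <- function(scores, labels) {
  y <- as_class_factor(labels)
  n_pos <- sum(y == positive_level)
  n_neg <- sum(y == negative_level)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == positive_level]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified bootstrap percentile interval for the AUC
#'
#' Resamples within each class (keeping both class sizes fixed) and returns
#' the percentile interval of the resampled AUCs.
#'
#' @inheritParams auc
#' @param reps bootstrap replicates (default 2000; fewer than 100 warns).
#' @param level confidence level.
#' @param seed integer seed.
#' @return tibble with `point`, `lower`, `upper`, `level`.
#' @export
bootstrap_auc_ci <- function(scores, labels, reps = 2000L, level = 0.95,
                             seed = 1L) {
  if (reps < 100L) warning("fewer than 100 bootstrap replicates")
  y <- as_class_factor(labels)
  pos <- which(y == positive_level)
  neg <- which(y == negative_level)
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  point <- auc(scores, y)
  boots <- withr::with_seed(derive_seed(seed, "bootauc"), {
    vapply(seq_len(reps), function(b) {
      i <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
      auc(scores[i], y[i])
    }, numeric(1))
  })
  q <- stats::quantile(boots, c((1 - level) / 2, (1 + level) / 2),
                       names = FALSE, type = 7)
  tibble::tibble(point = point, lower = q[1], upper = q[2], level = level)
}

#' Chi-squared test of a 2x2 contingency table
#'
#' Pearson chi-squared with Yates continuity correction, 1 degree of
#' freedom. All row and column margins must be positive.
#'
#' @param table 2x2 matrix of counts.
#' @return list with `statistic` and `p_value`.
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("`table` must be 2x2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  ct <- stats::chisq.test(table, correct = TRUE)
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Direction of a feature's association with the class
#'
#' Fits a univariable logistic regression of the class (positive coded 1) on
#' the feature; the sign of the slope gives the polarity. Constant features,
#' non-convergent fits and essentially-zero slopes are reported as
#' `"undetermined"` rather than raising an error.
#'
#' @param feature_column numeric feature values.
#' @param labels class labels.
#' @return tibble with `coefficient_sign` (+1, -1 or 0) and `polarity`
#'   (`"positive"`, `"negative"`, `"undetermined"`).
#' @export
feature_polarity <- function(feature_column, labels) {
  y <- as_class_factor(labels)
  out <- function(s) {
    tibble::tibble(coefficient_sign = s,
                   polarity = unname(c(`1` = "positive", `-1` = "negative",
                                       `0` = "undetermined")[as.character(s)]))
  }
  if (stats::sd(feature_column) == 0 || length(unique(y)) < 2L) return(out(0L))
  fit <- tryCatch(
    suppressWarnings(glm((y == positive_level) ~ feature_column,
                         family = binomial())),
    error = function(e) NULL
  )
  if (is.null(fit)) return(out(0L))
  slope <- coef(fit)[["feature_column"]]
  if (!is.finite(slope) || abs(slope) < 1e-10) return(out(0L))
  out(as.integer(sign(slope)))
}

#' Polarity of every selected feature
#'
#' @param X histogram feature matrix (rows = images).
#' @param labels class labels.
#' @param features feature indices to test (default all columns).
#' @return tibble with `feature_index`, `coefficient_sign`, `polarity`.
#' @export
feature_polarities <- function(X, labels, features = seq_len(ncol(X))) {
  dplyr::bind_cols(
    tibble::tibble(feature_index = as.integer(features)),
    dplyr::bind_rows(purrr::map(features, function(j) {
      feature_polarity(X[, j], labels)
    }))
  )
}

#' Spatial maps of class-associated features
#'
#' Marks each non-overlapping encoding window of an image whose assigned
#' codeword is one of the model's selected features: in the positive map when
#' that feature has positive polarity, in the negative map when negative.
#' Invalid (low-tissue / low-contrast) windows appear in neither map, and the
#' maps are disjoint by construction.
#'
#' @param grid a `code_grid` of the image (encoded with the model's L1
#'   codebook).
#' @param pair the model's `codebook_l2_pair`.
#' @param selected integer indices of the model's selected features
#'   (codewords in `1 .. 2 k2`).
#' @param polarity polarity table from [feature_polarities()], covering every
#'   selected feature.
#' @param window_patches encoding window side in patches.
#' @return a `feature_maps`: list of logical window matrices `positive` and
#'   `negative`, plus the window `assignments` tibble.
#' @export
spatial_feature_map <- function(grid, pair, selected, polarity,
                                window_patches = 15L) {
  if (!all(selected %in% polarity$feature_index)) {
    stop("`polarity` must cover every selected feature")
  }
  enc <- encode_image(grid, pair, window_patches)
  w <- enc$windows
  pol <- polarity$polarity[match(w$code, polarity$feature_index)]
  sel <- w$valid & w$code %in% selected
  nwr <- length(unique(w$window_row))
  nwc <- length(unique(w$window_col))
  shape <- function(flag) {
    m <- matrix(FALSE, nwr, nwc)
    m[cbind(w$window_row %/% window_patches + 1L,
            w$window_col %/% window_patches + 1L)] <- flag
    m
  }
  structure(list(positive = shape(sel & !is.na(pol) & pol == "positive"),
                 negative = shape(sel & !is.na(pol) & pol == "negative"),
                 assignments = w),
            class = "feature_maps")
}

#' @export
print.feature_maps <- function(x, ...) {
  cat("<feature_maps> ", sum(x$positive), " positive / ", sum(x$negative),
      " negative windows of ", length(x$positive), "\n", sep = "")
  invisible(x)
}

#' @describeIn spatial_feature_map tile plot of the positive/negative window
#'   maps.
#' @param object a `feature_maps`.
#' @param ... unused.
#' @export
autoplot.feature_maps <- function(object, ...) {
  lab <- matrix("uninvolved", nrow(object$positive), ncol(object$positive))
  lab[object$positive] <- "positive"
  lab[object$negative] <- "negative"
  df <- tibble::tibble(
    row = as.vector(row(lab)), col = as.vector(col(lab)),
    class = factor(as.vector(lab),
                   levels = c("positive", "negative", "uninvolved"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(positive = "#d7301f",
                                          negative = "#225ea8",
                                          uninvolved = "grey85")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "window column", y = "window row",
                  title = "Spatial distribution of class-associated features") +
    ggplot2::theme_minimal()
}

#' Sensitivity/specificity trade-off across thresholds
#'
#' Sweeps the decision threshold over the observed score range and reports
#' the operating point at each candidate threshold (label positive iff
#' `score > threshold`).
#'
#' @inheritParams auc
#' @param thresholds candidate thresholds; default the sorted unique scores
#'   plus flanking values.
#' @return tibble with `threshold`, `sensitivity`, `specificity`.
#' @export
threshold_sweep <- function(scores, labels, thresholds = NULL) {
  y <- as_class_factor(labels)
  if (is.null(thresholds)) {
    u <- sort(unique(scores))
    thresholds <- c(min(u) - 1, u)
  }
  purrr::map_dfr(thresholds, function(t) {
    cm <- confusion(scores > t, y)
    m <- binary_metrics(cm)
    tibble::tibble(threshold = t, sensitivity = m$sensitivity,
                   specificity = m$specificity)
  })
}
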