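#' Fit the full bag-of-visual-words + SVM model on a training set
#'
#' Runs every training-dependent stage on the supplied images only: samples
#' patch descriptors and fits the L1 codebook, recodes the training images,
#' samples neighbourhood descriptors per class and fits the class-specific L2
#' codebook pair, builds the training histogram matrix, ranks features by
#' RFE, selects the subset size by inner-CV AUC and trains the final RBF SVM.
#' All stage seeds are derived from `seed` and the sorted training image ids,
#' so the fit depends on nothing outside the training set.
#'
#' @param features named list of per-image descriptor tibbles (from
#'   [image_descriptors()]), names = image ids.
#' @param labels tibble with `image_id` and `label` columns covering every
#'   training image.
#' @param config a [pipeline_config()].
#' @param seed integer seed.
#' @return a `histo_model`: codebooks, ranking, tuned SVM and the config.
#' @export
fit_bovw <- function(features, labels, config = pipeline_config(), seed = 1L) {
  ids <- sort(names(features))
  labs <- labels$label[match(ids, labels$image_id)]
  if (anyNA(labs)) stop("missing labels for some training images")
  y <- as_class_factor(labs)
  fseed <- derive_seed(seed, "fit", paste(ids, collapse = ","))

  pooled <- purrr::map(ids, function(id) {
    sample_patch_descriptors(features[[id]], n = config$n_l1_samples,
                             seed = derive_seed(seed, "img", id))
  })
  pooled <- descriptor_matrix(dplyr::bind_rows(pooled[!purrr::map_lgl(pooled, is.null)]))
  l1 <- fit_codebook_l1(pooled, k1 = config$k1, seed = fseed,
                        restarts = config$kmeans_restarts,
                        iter_max = config$kmeans_iter_max,
                        tol = config$kmeans_tol)

  grids <- purrr::map(ids, function(id) encode_l1(features[[id]], l1))
  names(grids) <- ids

  l2_samples <- purrr::map(ids, function(id) {
    sample_l2_descriptors(grids[[id]], n = config$n_l2_samples,
                          window_patches = config$window_patches,
                          seed = derive_seed(seed, "img", id))
  })
  pos <- do.call(rbind, l2_samples[y == positive_level])
  neg <- do.call(rbind, l2_samples[y == negative_level])
  l2 <- fit_codebook_l2_pair(pos, neg, k2 = config$k2, seed = fseed,
                             restarts = config$kmeans_restarts,
                             iter_max = config$kmeans_iter_max,
                             tol = config$kmeans_tol)

  X <- do.call(rbind, purrr::map(grids, function(g) {
    encode_image(g, l2, config$window_patches)$bins
  }))
  rownames(X) <- ids

  ranking <- rfe_rank(X, y, step = config$rfe_step)
  sizes <- config$subset_sizes[config$subset_sizes <= ncol(X)]
  if (!length(sizes)) stop("no subset size is <= the feature count")
  sel <- select_subset_size(X, y, ranking, sizes = sizes,
                            cost_grid = config$cost_grid,
                            gamma_grid = config$gamma_grid,
                            inner_folds = config$inner_folds, seed = fseed)
  svm <- train_final(X, y, ranking, sel$f_star, sel$cost, sel$gamma)

  structure(list(l1 = l1, l2 = l2, svm = svm, ranking = ranking,
                 f_star = sel$f_star, tuning = sel$table, config = config,
                 seed = seed, train_ids = ids),
            class = "histo_model")
}

#' @export
print.histo_model <- function(x, ...) {
  cat("<histo_model> K1=", x$l1$k1, ", K2=", x$l2$k2, ", ", x$f_star,
      "/", 2L * x$l2$k2, " features, trained on ", length(x$train_ids),
      " images\n", sep = "")
  invisible(x)
}

#' Encode an image with a fitted model's codebooks
#'
#' @param model a `histo_model`.
#' @param desc_tbl descriptor tibble of the image.
#' @return an `image_histogram`.
#' @export
encode_with_model <- function(model, desc_tbl) {
  grid <- encode_l1(desc_tbl, model$l1)
  encode_image(grid, model$l2, model$config$window_patches)
}

#' Predict an image with a fitted model
#'
#' @param object a `histo_model`.
#' @param newdata a descriptor tibble, an `image_histogram`, or a numeric
#'   histogram matrix.
#' @param ... unused.
#' @return tibble with `margin` and `label`.
#' @export
predict.histo_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- encode_with_model(object, newdata)
  predict(object$svm, newdata)
}

#' Outer stratified cross-validation of the whole pipeline
#'
#' Splits the cohort into `k` class-stratified folds and, for each fold,
#' refits *everything* (L1 codebook, both L2 codebooks, descriptor
#' standardiser, feature ranking, hyperparameter tuning and the final SVM) on
#' the training images only, then encodes and scores the held-out images
#' with the training-fold model. Every image is predicted exactly once, from
#' the fold that did not see it.
#'
#' @param features named list of per-image descriptor tibbles.
#' @param labels tibble with `image_id` and `label`.
#' @param k outer folds (default 10).
#' @param config a [pipeline_config()].
#' @param seed integer seed.
#' @return a `histo_cv` with a `predictions` tibble (`image_id`, `fold`,
#'   `margin`, `label`, `truth`), a per-fold `fold_summary`, and
#'   `fold_assignments`.
#' @export
outer_cv <- function(features, labels, k = 10L, config = pipeline_config(),
                     seed = 1L) {
  ids <- names(features)
  stopifnot(!is.null(ids), all(ids %in% labels$image_id))
  labs <- labels$label[match(ids, labels$image_id)]
  y <- as_class_factor(labs)
  folds <- stratified_folds(y, k, derive_seed(seed, "outer"))
  preds <- vector("list", k)
  fold_info <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- ids[folds != f]
    te <- ids[folds == f]
    model <- fit_bovw(features[tr], labels, config, seed)
    p <- purrr::map(te, function(id) predict(model, features[[id]]))
    preds[[f]] <- tibble::tibble(
      image_id = te, fold = f,
      margin = purrr::map_dbl(p, "margin"),
      label = factor(purrr::map_chr(p, ~as.character(.x$label)),
                     levels = c(negative_level, positive_level)),
      truth = y[match(te, ids)]
    )
    fold_info[[f]] <- tibble::tibble(fold = f, f_star = model$f_star,
                                     cost = model$svm$cost,
                                     gamma = model$svm$gamma)
  }
  structure(list(predictions = dplyr::bind_rows(preds),
                 fold_summary = dplyr::bind_rows(fold_info),
                 fold_assignments = stats::setNames(folds, ids),
                 config = config, seed = seed),
            class = "histo_cv")
}

#' @export
print.histo_cv <- function(x, ...) {
  g <- glance(x)
  cat("<histo_cv> ", nrow(x$predictions), " out-of-fold predictions in ",
      max(x$predictions$fold), " folds; AUC ", round(g$auc, 3),
      ", Acc ", round(g$accuracy, 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn outer_cv out-of-fold predictions, one row per image.
#' @param x a `histo_cv`.
#' @export
tidy.histo_cv <- function(x, ...) x$predictions

#' @describeIn outer_cv one-row performance summary (AUC, sensitivity,
#'   specificity, accuracy with Agresti-Coull 95% intervals).
#' @export
glance.histo_cv <- function(x, ...) {
  p <- x$predictions
  cm <- confusion(p$label, p$truth)
  m <- binary_metrics(cm)
  se_ci <- agresti_coull_ci(cm$tp, cm$tp + cm$fn)
  sp_ci <- agresti_coull_ci(cm$tn, cm$tn + cm$fp)
  acc_ci <- agresti_coull_ci(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn)
  tibble::tibble(
    auc = auc(p$margin, p$truth),
    sensitivity = m$sensitivity, se_lower = se_ci$lower, se_upper = se_ci$upper,
    specificity = m$specificity, sp_lower = sp_ci$lower, sp_upper = sp_ci$upper,
    accuracy = m$accuracy, acc_lower = acc_ci$lower, acc_upper = acc_ci$upper,
    n = nrow(p)
  )
}

#' Cross-validation performance with confidence intervals
#'
#' Point estimates and 95% intervals for the out-of-fold predictions:
#' Agresti-Coull intervals for sensitivity, specificity and accuracy, and a
#' stratified bootstrap percentile interval for the AUC.
#'
#' @param cv a `histo_cv`.
#' @param level confidence level.
#' @param boot_reps bootstrap replicates for the AUC interval.
#' @param seed integer seed for the bootstrap.
#' @return tibble with `metric`, `estimate`, `lower`, `upper`.
#' @export
cv_metrics <- function(cv, level = 0.95, boot_reps = 2000L, seed = 1L) {
  p <- cv$predictions
  cm <- confusion(p$label, p$truth)
  m <- binary_metrics(cm)
  se_ci <- agresti_coull_ci(cm$tp, cm$tp + cm$fn, level)
  sp_ci <- agresti_coull_ci(cm$tn, cm$tn + cm$fp, level)
  acc_ci <- agresti_coull_ci(cm$tp + cm$tn, sum(unlist(cm[c("tn", "fp", "fn", "tp")])), level)
  auc_ci <- bootstrap_auc_ci(p$margin, p$truth, reps = boot_reps,
                             level = level, seed = seed)
  tibble::tibble(
    metric = c("auc", "sensitivity", "specificity", "accuracy"),
    estimate = c(auc_ci$point, m$sensitivity, m$specificity, m$accuracy),
    lower = c(auc_ci$lower, se_ci$lower, sp_ci$lower, acc_ci$lower),
    upper = c(auc_ci$upper, se_ci$upper, sp_ci$upper, acc_ci$upper)
  )
}

#' @describeIn outer_cv margin strip plot of the out-of-fold predictions by
#'   true class (the margin acts as prediction confidence).
#' @param object a `histo_cv`.
#' @export
autoplot.histo_cv <- function(object, ...) {
  p <- object$predictions
  ggplot2::ggplot(p, ggplot2::aes(x = .data$truth, y = .data$margin,
                                  colour = .data$label == .data$truth)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f02"),
                                 name = "correct") +
    ggplot2::labs(x = "true class", y = "SVM margin",
                  title = "Out-of-fold margins") +
    ggplot2::theme_minimal()
}
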