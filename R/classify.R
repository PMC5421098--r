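positive_level <- "pos"
negative_level <- "neg"

#' Coerce labels to the canonical two-level factor
#'
#' Internally the positive (minority, biomarker-positive) class is the factor
#' level `"pos"` and the negative class `"neg"`. Logical vectors, 0/1 vectors
#' and factors/characters with the levels `"pos"`/`"neg"` are accepted.
#'
#' @param y labels.
#' @return factor with levels `c("neg", "pos")`.
#' @export
as_class_factor <- function(y) {
  if (is.logical(y)) y <- ifelse(y, positive_level, negative_level)
  if (is.numeric(y)) y <- ifelse(y > 0, positive_level, negative_level)
  y <- as.character(y)
  bad <- setdiff(unique(y), c(positive_level, negative_level))
  if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "))
  factor(y, levels = c(negative_level, positive_level))
}

inverse_freq_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

# Fit an e1071 SVM with inverse-frequency class weights and no feature
# scaling (histogram features are already commensurate proportions).
fit_svm_raw <- function(X, y, kernel, cost, gamma = NULL) {
  args <- list(x = X, y = y, kernel = kernel, cost = cost, scale = FALSE,
               class.weights = inverse_freq_weights(y))
  if (!is.null(gamma)) args$gamma <- gamma
  do.call(e1071::svm, args)
}

# Signed decision values oriented so that positive values favour the
# positive class, regardless of which class e1071 saw first.
svm_margins <- function(model, X) {
  dv <- attr(predict(model, X, decision.values = TRUE), "decision.values")
  flip <- if (model$levels[model$labels[1L]] == positive_level) 1 else -1
  as.numeric(dv) * flip
}

#' Rank features by SVM recursive feature elimination
#'
#' Repeatedly fits a linear-kernel SVM (cost 1, inverse-frequency class
#' weights) and removes the `step` features with the smallest absolute
#' weight until none remain. Features eliminated last (and, within the final
#' survivors, those with the largest weights) rank as most important.
#'
#' @param X numeric feature matrix (rows = images).
#' @param y class labels, see [as_class_factor()].
#' @param step features removed per iteration (default 5).
#' @param cost linear-SVM cost parameter (default 1).
#' @return integer permutation of `1:ncol(X)`, most important first.
#' @export
rfe_rank <- function(X, y, step = 5L, cost = 1) {
  y <- as_class_factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  if (ncol(X) < 2L) stop("need at least two features")
  remaining <- seq_len(ncol(X))
  eliminated <- integer(0)
  while (length(remaining) > 0L) {
    fit <- fit_svm_raw(X[, remaining, drop = FALSE], y, "linear", cost)
    w <- as.numeric(crossprod(fit$coefs, fit$SV))
    ord <- order(abs(w))                      # least important first
    drop_n <- min(step, length(remaining))
    if (length(remaining) <= step) drop_n <- length(remaining)
    drop_idx <- ord[seq_len(drop_n)]
    # eliminate the weakest `drop_n`, recording weaker ones first
    eliminated <- c(eliminated, remaining[drop_idx])
    remaining <- remaining[-drop_idx]
  }
  rev(eliminated)
}

#' Tune an RBF SVM on a fixed feature subset
#'
#' Grid search over `(cost, gamma)` maximising the mean AUC across stratified
#' inner cross-validation folds, with the out-of-fold decision values scored
#' per fold. Ties prefer the smallest cost, then the smallest gamma.
#'
#' @param X numeric feature matrix (already restricted to the candidate
#'   subset).
#' @param y class labels.
#' @param cost_grid,gamma_grid numeric grids (non-empty).
#' @param inner_folds stratified folds (default 5).
#' @param seed integer seed for the fold split.
#' @return list with `cost`, `gamma`, `auc` and the full `table` tibble.
#' @export
tune_svm <- function(X, y, cost_grid = 2^seq(-5, 15, 2),
                     gamma_grid = 2^seq(-15, 3, 2), inner_folds = 5L,
                     seed = 1L) {
  if (!length(cost_grid) || !length(gamma_grid)) stop("empty parameter grid")
  y <- as_class_factor(y)
  folds <- stratified_folds(y, inner_folds, derive_seed(seed, "inner"))
  grid <- expand.grid(gamma = sort(gamma_grid), cost = sort(cost_grid))
  fold_sets <- lapply(seq_len(inner_folds), function(f) {
    list(train = which(folds != f), test = which(folds == f))
  })
  aucs <- vapply(seq_len(nrow(grid)), function(g) {
    per_fold <- vapply(fold_sets, function(fs) {
      fit <- fit_svm_raw(X[fs$train, , drop = FALSE], y[fs$train], "radial",
                         grid$cost[g], grid$gamma[g])
      auc(svm_margins(fit, X[fs$test, , drop = FALSE]), y[fs$test])
    }, numeric(1))
    mean(per_fold)
  }, numeric(1))
  tbl <- tibble::tibble(cost = grid$cost, gamma = grid$gamma, auc = aucs)
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$auc), .data$cost, .data$gamma)
  list(cost = tbl$cost[1L], gamma = tbl$gamma[1L], auc = tbl$auc[1L],
       table = tbl)
}

#' Choose the number of features by inner-CV AUC
#'
#' For each candidate size `f` the top-`f` ranked features are tuned with
#' [tune_svm()]; the size with the maximum inner AUC wins, ties going to the
#' smallest size.
#'
#' @param X full feature matrix.
#' @param y class labels.
#' @param ranking feature ranking from [rfe_rank()].
#' @param sizes candidate subset sizes (default `30, 50, ..., 130`), each
#'   `<= ncol(X)`.
#' @inheritParams tune_svm
#' @return list with `f_star`, the winning `cost`/`gamma`, and a per-size
#'   `table` tibble.
#' @export
select_subset_size <- function(X, y, ranking, sizes = seq(30L, 130L, 20L),
                               cost_grid = 2^seq(-5, 15, 2),
                               gamma_grid = 2^seq(-15, 3, 2),
                               inner_folds = 5L, seed = 1L) {
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes > ncol(X))) stop("subset sizes exceed the feature count")
  if (any(sizes < 1L)) stop("subset sizes must be positive")
  rows <- purrr::map(sizes, function(f) {
    tuned <- tune_svm(X[, ranking[seq_len(f)], drop = FALSE], y,
                      cost_grid, gamma_grid, inner_folds,
                      seed = derive_seed(seed, "size", f))
    tibble::tibble(f = f, cost = tuned$cost, gamma = tuned$gamma,
                   auc = tuned$auc)
  })
  tbl <- dplyr::bind_rows(rows)
  best <- which.max(tbl$auc)   # first maximum = smallest size on ties
  list(f_star = tbl$f[best], cost = tbl$cost[best], gamma = tbl$gamma[best],
       table = tbl)
}

#' Train the final RBF SVM on the selected features
#'
#' Fits on the top `f_star` ranked features with inverse-frequency class
#' weights, then extracts the support-vector expansion into a plain-list
#' model whose decision values are computed by the package itself (making
#' predictions independent of the fitting library's object internals and
#' exactly reproducible after text serialisation).
#'
#' @param X full training feature matrix.
#' @param y class labels.
#' @param ranking feature ranking from [rfe_rank()].
#' @param f_star number of features to keep.
#' @param cost,gamma RBF-SVM hyperparameters.
#' @param threshold decision-value cutoff for the class call (default 0).
#' @return a `histo_svm` model.
#' @export
train_final <- function(X, y, ranking, f_star, cost, gamma, threshold = 0) {
  y <- as_class_factor(y)
  features <- ranking[seq_len(f_star)]
  fit <- fit_svm_raw(X[, features, drop = FALSE], y, "radial", cost, gamma)
  flip <- if (fit$levels[fit$labels[1L]] == positive_level) 1 else -1
  structure(list(sv = unname(as.matrix(fit$SV)),
                 coefs = as.numeric(fit$coefs) * flip,
                 rho = as.numeric(fit$rho) * flip,
                 gamma = gamma, cost = cost,
                 features = as.integer(features),
                 threshold = threshold),
            class = "histo_svm")
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Predict margins and labels from a `histo_svm`
#'
#' The margin is the signed RBF decision value
#' `sum_i coef_i K(sv_i, x) - rho`, oriented so positive margins favour the
#' positive class; the label is positive iff the margin strictly exceeds the
#' model threshold.
#'
#' @param object a `histo_svm` from [train_final()].
#' @param newdata feature matrix over the *full* feature space (the model
#'   selects its own columns) or a single `image_histogram`.
#' @param ... unused.
#' @return tibble with `margin` and `label`.
#' @export
predict.histo_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "image_histogram")) newdata <- rbind(newdata$bins)
  if (is.null(dim(newdata))) newdata <- rbind(newdata)
  if (ncol(newdata) < max(object$features)) {
    stop("feature dimension mismatch: model expects at least ",
         max(object$features), " columns")
  }
  Xs <- newdata[, object$features, drop = FALSE]
  margin <- as.numeric(rbf_kernel(Xs, object$sv, object$gamma) %*%
                         object$coefs) - object$rho
  tibble::tibble(margin = margin,
                 label = factor(ifelse(margin > object$threshold,
                                       positive_level, negative_level),
                                levels = c(negative_level, positive_level)))
}

#' @export
print.histo_svm <- function(x, ...) {
  cat("<histo_svm> RBF SVM: ", length(x$features), " features, ",
      nrow(x$sv), " support vectors, cost ", format(x$cost),
      ", gamma ", format(x$gamma), "\n", sep = "")
  invisible(x)
}
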