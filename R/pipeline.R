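#' Pipeline configuration
#'
#' Collects every tunable of the coding and classification pipeline with its
#' default: 32 px patches, 15-patch (480 px) neighbourhood windows, K1 = K2 =
#' 128 codewords, 1000 patch / 500 neighbourhood descriptors sampled per
#' image, candidate feature-subset sizes 30 to 130 in steps of 20, the
#' standard RBF-SVM search lattice, 5 inner and 10 outer stratified folds.
#' Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    patch_px = 32L, window_patches = 15L,
    k1 = 128L, k2 = 128L,
    n_l1_samples = 1000L, n_l2_samples = 500L,
    subset_sizes = seq(30L, 130L, 20L),
    cost_grid = 2^seq(-5, 15, 2), gamma_grid = 2^seq(-15, 3, 2),
    inner_folds = 5L, outer_folds = 10L, rfe_step = 5L,
    kmeans_restarts = 5L, kmeans_iter_max = 300L, kmeans_tol = 1e-4,
    background_threshold = 240
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  structure(modifyList(defaults, overrides), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", paste(format(x[[nm]]), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips without loss; unknown keys in the file are rejected.
#'
#' @param path file path.
#' @param config a [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  int_keys <- c("patch_px", "window_patches", "k1", "k2", "n_l1_samples",
                "n_l2_samples", "subset_sizes", "inner_folds", "outer_folds",
                "rfe_step", "kmeans_restarts", "kmeans_iter_max")
  for (k in intersect(names(vals), int_keys)) {
    vals[[k]] <- as.integer(vals[[k]])
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

config_hash <- function(config) {
  s <- paste(names(config),
             vapply(config, function(v) paste(format(v, digits = 17),
                                              collapse = ","), character(1)),
             sep = "=", collapse = ";")
  format(derive_seed(0L, s))
}

#' Load a cohort from a directory of TIFF images
#'
#' Expects `labels.tsv` (columns `image_id`, `label`) plus `<image_id>.tiff`
#' and optional `<image_id>_mask.tiff` files, and reduces every image to its
#' descriptor table.
#'
#' @param dir cohort directory.
#' @param in_mag input magnification (`"20x"` is downscaled by 4 to the 5x
#'   analysis scale).
#' @param bank Gabor bank.
#' @param config a [pipeline_config()].
#' @return list with `features` and `labels`, as for [outer_cv()].
#' @export
load_cohort_dir <- function(dir, in_mag = c("5x", "20x"),
                            bank = gabor_bank(), config = pipeline_config()) {
  in_mag <- match.arg(in_mag)
  labels <- utils::read.delim(file.path(dir, "labels.tsv"),
                              colClasses = "character")
  features <- vector("list", nrow(labels))
  names(features) <- labels$image_id
  for (id in labels$image_id) {
    img <- read_rgb_tiff(file.path(dir, paste0(id, ".tiff")))
    mask_path <- file.path(dir, paste0(id, "_mask.tiff"))
    mask <- if (file.exists(mask_path)) read_mask_tiff(mask_path) else NULL
    stains <- prepare_stains(img, mask, in_mag,
                             background_threshold = config$background_threshold)
    features[[id]] <- image_descriptors(stains, bank, config$patch_px)
  }
  list(features = features,
       labels = tibble::tibble(image_id = labels$image_id,
                               label = labels$label))
}

#' Run the full pipeline and write a run directory
#'
#' End-to-end driver: obtain the cohort (either a [cohort_spec()] rendered on
#' the fly or a directory of TIFFs with labels), compute descriptors, run the
#' outer stratified cross-validation with per-fold recoding, and write the
#' out-of-fold predictions, the performance metrics with confidence
#' intervals, the configuration and a machine-readable JSON summary.
#'
#' @param input a [cohort_spec()] or a cohort directory path.
#' @param out_dir run directory to create.
#' @param config a [pipeline_config()].
#' @param seed integer seed for every stochastic stage.
#' @param in_mag input magnification for directory input.
#' @return the `histo_cv` result, invisibly.
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config(),
                         seed = 1L, in_mag = "5x") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bank <- gabor_bank()
  cohort <- if (inherits(input, "cohort_spec")) {
    cohort_descriptors(input, bank = bank, patch_px = config$patch_px)
  } else {
    load_cohort_dir(input, in_mag, bank, config)
  }
  cv <- outer_cv(cohort$features, cohort$labels, k = config$outer_folds,
                 config = config, seed = seed)
  metrics <- cv_metrics(cv, seed = seed)

  utils::write.table(
    transform(as.data.frame(cv$predictions),
              label = as.character(label), truth = as.character(truth)),
    file.path(out_dir, "predictions.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(metrics), file.path(out_dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  summary <- list(
    config_hash = config_hash(config), seed = seed,
    n_images = nrow(cv$predictions),
    folds = max(cv$predictions$fold),
    f_star = cv$fold_summary$f_star,
    metrics = stats::setNames(as.list(metrics$estimate), metrics$metric),
    ci = stats::setNames(purrr::map2(metrics$lower, metrics$upper, c),
                         metrics$metric)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cv)
}
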