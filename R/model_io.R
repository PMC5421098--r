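## Structured-text serialisation of codebooks and fitted models.
## Everything is written as plain text at full double precision (17
## significant digits), so a reloaded model reproduces margins to well below
## 1e-9.

fmt_num <- function(x) sprintf("%.17g", x)

write_block <- function(con, name, x) {
  if (is.matrix(x)) {
    writeLines(sprintf("%s matrix %d %d", name, nrow(x), ncol(x)), con)
    writeLines(apply(x, 1L, function(r) paste(fmt_num(r), collapse = " ")), con)
  } else if (is.character(x)) {
    writeLines(sprintf("%s character %d", name, length(x)), con)
    writeLines(x, con)
  } else {
    writeLines(sprintf("%s numeric %d", name, length(x)), con)
    writeLines(paste(fmt_num(x), collapse = " "), con)
  }
}

read_blocks <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
    name <- hdr[1L]; type <- hdr[2L]
    if (type == "matrix") {
      nr <- as.integer(hdr[3L]); nc <- as.integer(hdr[4L])
      rows <- lines[i + seq_len(nr)]
      vals <- as.numeric(unlist(strsplit(rows, " ", fixed = TRUE)))
      out[[name]] <- matrix(vals, nr, nc, byrow = TRUE)
      i <- i + 1L + nr
    } else if (type == "character") {
      n <- as.integer(hdr[3L])
      out[[name]] <- lines[i + seq_len(n)]
      i <- i + 1L + n
    } else {
      out[[name]] <- as.numeric(strsplit(lines[i + 1L], " ", fixed = TRUE)[[1L]])
      i <- i + 2L
    }
  }
  out
}

#' Save / load a fitted model bundle as structured text
#'
#' Writes the L1 codebook (centroids plus standardiser), both class-specific
#' L2 codebooks, the feature ranking, the support-vector expansion of the
#' final SVM and the configuration into a directory of plain-text files.
#' A reloaded bundle reproduces decision margins to better than 1e-9.
#'
#' @param model a `histo_model` from [fit_bovw()].
#' @param dir bundle directory (created).
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "codebooks.txt"), "w")
  write_block(con, "l1_centroids", model$l1$centroids)
  write_block(con, "l1_center", model$l1$center)
  write_block(con, "l1_scale", model$l1$scale)
  write_block(con, "l2_positive", model$l2$positive)
  write_block(con, "l2_negative", model$l2$negative)
  close(con)
  con <- file(file.path(dir, "classifier.txt"), "w")
  write_block(con, "ranking", model$ranking)
  write_block(con, "sv", model$svm$sv)
  write_block(con, "coefs", model$svm$coefs)
  write_block(con, "rho_gamma_cost_thr",
              c(model$svm$rho, model$svm$gamma, model$svm$cost,
                model$svm$threshold))
  write_block(con, "features", model$svm$features)
  write_block(con, "seed_fstar", c(model$seed, model$f_star))
  write_block(con, "train_ids", model$train_ids)
  close(con)
  write_config(model$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  cb <- read_blocks(file.path(dir, "codebooks.txt"))
  cl <- read_blocks(file.path(dir, "classifier.txt"))
  config <- read_config(file.path(dir, "config.yaml"))
  l1 <- structure(list(centroids = cb$l1_centroids, center = cb$l1_center,
                       scale = cb$l1_scale, k1 = nrow(cb$l1_centroids)),
                  class = "codebook_l1")
  l2 <- structure(list(positive = cb$l2_positive, negative = cb$l2_negative,
                       k2 = nrow(cb$l2_positive)),
                  class = "codebook_l2_pair")
  svm <- structure(list(sv = cl$sv, coefs = cl$coefs,
                        rho = cl$rho_gamma_cost_thr[1L],
                        gamma = cl$rho_gamma_cost_thr[2L],
                        cost = cl$rho_gamma_cost_thr[3L],
                        features = as.integer(cl$features),
                        threshold = cl$rho_gamma_cost_thr[4L]),
                   class = "histo_svm")
  structure(list(l1 = l1, l2 = l2, svm = svm,
                 ranking = as.integer(cl$ranking),
                 f_star = as.integer(cl$seed_fstar[2L]),
                 config = config, seed = as.integer(cl$seed_fstar[1L]),
                 train_ids = cl$train_ids),
            class = "histo_model")
}

#' Write image histograms as a delimited table
#'
#' @param histograms named list of `image_histogram`s (names = image ids).
#' @param labels optional tibble with `image_id` and `label`.
#' @param path output TSV path.
#' @export
write_histograms <- function(histograms, path, labels = NULL) {
  bins <- do.call(rbind, purrr::map(histograms, "bins"))
  colnames(bins) <- paste0("b", seq_len(ncol(bins)))
  df <- data.frame(image_id = names(histograms), check.names = FALSE)
  if (!is.null(labels)) {
    df$label <- as.character(labels$label[match(df$image_id, labels$image_id)])
  }
  utils::write.table(cbind(df, as.data.frame(bins)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
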