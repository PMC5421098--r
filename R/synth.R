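#' Define a synthetic texture motif
#'
#' A motif is a small generative texture model standing in for a recurring
#' tissue pattern: an oriented sinusoidal grating, an isotropic band-pass
#' noise field, or a field of Gaussian blobs. Its stain loadings decide how
#' strongly it appears in the haematoxylin and eosin channels. Grating
#' frequencies should sit inside the sensitive range of the default Gabor
#' bank (`3/16` to `3/4` cycles/pixel at the analysis scale).
#'
#' @param id unique motif identifier.
#' @param kind `"grating"`, `"bandpass"` or `"blobs"`.
#' @param theta grating orientation in radians.
#' @param nu grating frequency in cycles/pixel.
#' @param radius blob radius / band-pass inner smoothing scale in pixels.
#' @param amplitude peak stain concentration (OD units).
#' @param h_weight,e_weight non-negative loadings of the two stain channels.
#' @return a `motif` list.
#' @export
motif <- function(id, kind = c("grating", "bandpass", "blobs"), theta = 0,
                  nu = 3 / 8, radius = 3, amplitude = 0.8, h_weight = 1,
                  e_weight = 0.3) {
  kind <- match.arg(kind)
  stopifnot(h_weight >= 0, e_weight >= 0, amplitude > 0)
  structure(list(id = id, kind = kind, theta = theta, nu = nu,
                 radius = radius, amplitude = amplitude,
                 h_weight = h_weight, e_weight = e_weight),
            class = "motif")
}

#' Default motif set
#'
#' Six motifs in two groups of three. At full class divergence the positive
#' class draws only from the first group and the negative class only from
#' the second, so the groups define what "class-specific texture" means for
#' the generator. Orientations and frequencies match the default Gabor bank.
#'
#' @export
default_motifs <- function() {
  list(
    motif("pos_grating_h", "grating", theta = 0, nu = 3 / 8,
          amplitude = 0.8, h_weight = 1, e_weight = 0.25),
    motif("pos_grating_d", "grating", theta = pi / 4, nu = 3 / 4,
          amplitude = 0.7, h_weight = 0.6, e_weight = 0.6),
    motif("pos_blobs", "blobs", radius = 3, amplitude = 1.0,
          h_weight = 1, e_weight = 0.15),
    motif("neg_grating_v", "grating", theta = pi / 2, nu = 3 / 8,
          amplitude = 0.8, h_weight = 0.25, e_weight = 1),
    motif("neg_grating_lo", "grating", theta = 3 * pi / 4, nu = 3 / 16,
          amplitude = 0.7, h_weight = 0.7, e_weight = 0.5),
    motif("neg_bandpass", "bandpass", radius = 2, amplitude = 0.9,
          h_weight = 0.3, e_weight = 1)
  )
}

gaussian_taps <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  t <- seq(-r, r)
  exp(-t^2 / (2 * sigma^2))
}

#' Render one motif tile as stain concentration fields
#'
#' @param m a [motif()].
#' @param tile_px tile side in pixels (`>= 32`).
#' @param seed integer seed for the tile's randomness (phase, noise, blob
#'   positions).
#' @return list with non-negative matrices `h` and `e`.
#' @export
render_motif_tile <- function(m, tile_px = 480L, seed = 1L) {
  if (tile_px < 32L) stop("`tile_px` must be >= 32")
  base <- withr::with_seed(derive_seed(seed, "tile", m$id), {
    switch(m$kind,
      grating = {
        phase <- runif(1, 0, 2 * pi)
        y <- matrix(seq_len(tile_px) - 1L, tile_px, tile_px)
        x <- t(y)
        0.5 + 0.5 * sin(2 * pi * m$nu * (x * cos(m$theta) + y * sin(m$theta))
                        + phase)
      },
      bandpass = {
        z <- matrix(rnorm(tile_px^2), tile_px, tile_px)
        g1 <- gaussian_taps(m$radius)
        g2 <- gaussian_taps(2.5 * m$radius)
        bp <- cpp_separable_corr(z, g1 / sum(g1), g1 / sum(g1)) -
          cpp_separable_corr(z, g2 / sum(g2), g2 / sum(g2))
        bp <- bp / max(stats::sd(bp), 1e-12)
        pmin(pmax(0.5 + 0.35 * bp, 0), 1)
      },
      blobs = {
        n_blobs <- rpois(1, tile_px^2 / (40 * m$radius^2))
        imp <- matrix(0, tile_px, tile_px)
        if (n_blobs > 0) {
          ij <- cbind(sample.int(tile_px, n_blobs, replace = TRUE),
                      sample.int(tile_px, n_blobs, replace = TRUE))
          imp[ij] <- 1
        }
        g <- gaussian_taps(m$radius)   # peak-1 bump per impulse
        pmin(cpp_separable_corr(imp, g, g), 1)
      }
    )
  })
  field <- m$amplitude * base
  list(h = field * m$h_weight, e = field * m$e_weight)
}

#' Synthesize an RGB image from stain concentration fields
#'
#' Exact forward model of the colour deconvolution: the per-pixel optical
#' density is `h * H_vec + e * E_vec`, transmitted intensity
#' `i0 * 10^(-OD)` per channel, plus optional Gaussian pixel noise, rounded
#' and clipped to `[0, 255]`.
#'
#' @param h_field,e_field non-negative concentration matrices.
#' @param stain_matrix stain OD matrix, see [hed_stain_matrix()].
#' @param i0 incident intensity.
#' @param noise_sd Gaussian pixel-noise standard deviation (intensity
#'   levels).
#' @param seed integer seed for the noise (ignored when `noise_sd = 0`).
#' @return numeric `h x w x 3` intensity array.
#' @export
forward_stain <- function(h_field, e_field, stain_matrix = hed_stain_matrix(),
                          i0 = 255, noise_sd = 0, seed = 1L) {
  stopifnot(all(dim(h_field) == dim(e_field)),
            all(h_field >= 0), all(e_field >= 0))
  d <- dim(h_field)
  od <- outer(h_field, stain_matrix[1L, ]) + outer(e_field, stain_matrix[2L, ])
  rgb <- i0 * 10^(-od)
  if (noise_sd > 0) {
    rgb <- rgb + withr::with_seed(derive_seed(seed, "noise"),
                                  array(rnorm(length(rgb), 0, noise_sd),
                                        dim(rgb)))
  }
  array(pmin(pmax(round(rgb), 0), 255), c(d, 3L))
}

#' Specify a synthetic pseudo-H&E cohort
#'
#' The generator emulates the structure the coding pipeline is built for:
#' each image is a white frame around a mosaic of motif tiles whose side
#' equals the neighbourhood-coding footprint (480 px), so class signal lives
#' at exactly the scale the class-specific codebooks capture, while
#' within-tile texture drives the patch-level codebook. The two classes
#' share motifs at divergence 0 and use disjoint motif groups at
#' divergence 1.
#'
#' @param n_images cohort size (default 60).
#' @param prevalence positive-class probability (default 0.203, a typical
#'   biomarker-positive rate in colorectal cancer cohorts).
#' @param image_px `c(height, width)` in pixels at the 5x analysis scale.
#' @param motif_tile_px motif tile side (default 480).
#' @param background_margin_px white frame width (default 32).
#' @param divergence class mixture separation in `[0, 1]`.
#' @param noise_sd pixel noise of the forward stain model.
#' @param motifs motif list; the first half is the positive-class group.
#' @param seed integer cohort seed; all per-image randomness derives from it.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_images = 60L, prevalence = 0.203,
                        image_px = c(1024L, 1024L), motif_tile_px = 480L,
                        background_margin_px = 32L, divergence = 1,
                        noise_sd = 2, motifs = default_motifs(), seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, divergence >= 0, divergence <= 1)
  tiles <- (image_px - 2L * background_margin_px) %/% motif_tile_px
  if (any(tiles < 1L)) stop("image too small for one motif tile plus margins")
  m <- length(motifs)
  pos_set <- seq_len(ceiling(m / 2))
  neg_set <- setdiff(seq_len(m), pos_set)
  mix <- function(set) {
    (1 - divergence) / m + divergence * (seq_len(m) %in% set) / length(set)
  }
  structure(list(n_images = as.integer(n_images), prevalence = prevalence,
                 image_px = as.integer(image_px),
                 motif_tile_px = as.integer(motif_tile_px),
                 background_margin_px = as.integer(background_margin_px),
                 divergence = divergence, noise_sd = noise_sd,
                 motifs = motifs, tiles = as.integer(tiles),
                 mixture_pos = mix(pos_set), mixture_neg = mix(neg_set),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate the cohort manifest
#'
#' Draws labels (independent Bernoulli at the specified prevalence) and the
#' per-image tile layout. The manifest alone reconstructs every image
#' exactly: [render_cohort_image()] is a pure function of the spec and one
#' manifest row.
#'
#' @param spec a [cohort_spec()].
#' @return tibble with `image_id`, `label`, `image_seed` and the tile motif
#'   `layout` (list column of motif-id matrices).
#' @export
generate_cohort <- function(spec) {
  ids <- sprintf("img%03d", seq_len(spec$n_images))
  labels <- withr::with_seed(derive_seed(spec$seed, "labels"), {
    ifelse(runif(spec$n_images) < spec$prevalence,
           positive_level, negative_level)
  })
  layouts <- purrr::map2(ids, labels, function(id, lab) {
    p <- if (lab == positive_level) spec$mixture_pos else spec$mixture_neg
    withr::with_seed(derive_seed(spec$seed, "layout", id), {
      matrix(sample.int(length(spec$motifs), prod(spec$tiles), replace = TRUE,
                        prob = p),
             spec$tiles[1L], spec$tiles[2L])
    })
  })
  tibble::tibble(image_id = ids,
                 label = factor(labels,
                                levels = c(negative_level, positive_level)),
                 image_seed = purrr::map_int(ids, ~derive_seed(spec$seed, "img", .x)),
                 layout = layouts)
}

#' Render one cohort image from its manifest row
#'
#' @param spec the [cohort_spec()] used to build the manifest.
#' @param manifest_row one row of the [generate_cohort()] manifest.
#' @return list with the RGB `image`, binary `mask` (tiles = tissue) and the
#'   `label`.
#' @export
render_cohort_image <- function(spec, manifest_row) {
  hpx <- spec$image_px[1L]; wpx <- spec$image_px[2L]
  tp <- spec$motif_tile_px; mg <- spec$background_margin_px
  h_field <- matrix(0, hpx, wpx)
  e_field <- matrix(0, hpx, wpx)
  mask <- matrix(0, hpx, wpx)
  layout <- manifest_row$layout[[1L]]
  iseed <- manifest_row$image_seed
  for (tr in seq_len(nrow(layout))) {
    for (tc in seq_len(ncol(layout))) {
      tile <- render_motif_tile(spec$motifs[[layout[tr, tc]]], tp,
                                seed = derive_seed(iseed, "pos", tr, tc))
      ri <- mg + (tr - 1L) * tp + seq_len(tp)
      ci <- mg + (tc - 1L) * tp + seq_len(tp)
      h_field[ri, ci] <- tile$h
      e_field[ri, ci] <- tile$e
      mask[ri, ci] <- 1
    }
  }
  image <- forward_stain(h_field, e_field, i0 = 255,
                         noise_sd = spec$noise_sd, seed = iseed)
  list(image = image, mask = mask, label = manifest_row$label)
}

#' Descriptor tables for a whole synthetic cohort
#'
#' Streams through the cohort: renders each image, separates the stains and
#' reduces it to its patch-descriptor table, never holding more than one
#' image's pixels in memory. Descriptors are independent of the class labels
#' and fold structure, so they are computed once and shared by all
#' cross-validation conditions.
#'
#' @param spec a [cohort_spec()].
#' @param manifest manifest from [generate_cohort()] (regenerated when
#'   omitted).
#' @param bank Gabor bank (default [gabor_bank()]).
#' @param patch_px patch side in pixels.
#' @return list with `features` (named list of descriptor tibbles), `labels`
#'   tibble and the `manifest`.
#' @export
cohort_descriptors <- function(spec, manifest = generate_cohort(spec),
                               bank = gabor_bank(), patch_px = 32L) {
  features <- vector("list", nrow(manifest))
  names(features) <- manifest$image_id
  for (i in seq_len(nrow(manifest))) {
    img <- render_cohort_image(spec, manifest[i, ])
    stains <- deconvolve_stains(img$image, mask = img$mask)
    features[[i]] <- image_descriptors(stains, bank, patch_px)
  }
  list(features = features,
       labels = tibble::tibble(image_id = manifest$image_id,
                               label = manifest$label),
       manifest = manifest)
}

#' Write a synthetic cohort to disk
#'
#' Emits 8-bit RGB image TIFFs, mask TIFFs, a `labels.tsv` table and a
#' `manifest.tsv` (tile layout flattened row-major) under `dir`.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory.
#' @param manifest optional precomputed manifest.
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(spec, dir, manifest = generate_cohort(spec)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(manifest))) {
    img <- render_cohort_image(spec, manifest[i, ])
    id <- manifest$image_id[i]
    tiff::writeTIFF(img$image / 255, file.path(dir, paste0(id, ".tiff")),
                    bits.per.sample = 8L)
    tiff::writeTIFF(img$mask, file.path(dir, paste0(id, "_mask.tiff")),
                    bits.per.sample = 8L)
  }
  utils::write.table(
    data.frame(image_id = manifest$image_id,
               label = as.character(manifest$label),
               image_seed = manifest$image_seed,
               layout = vapply(manifest$layout,
                               function(m) paste(as.vector(t(m)), collapse = ","),
                               character(1))),
    file.path(dir, "manifest.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(
    data.frame(image_id = manifest$image_id,
               label = as.character(manifest$label)),
    file.path(dir, "labels.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(manifest)
}
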