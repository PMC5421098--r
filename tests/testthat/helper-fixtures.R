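# Shared small fixtures, built in code at test time.

# A small stain pair with known concentration fields, via the forward model.
# Concentrations stay below 0.8 OD per stain: summed optical densities beyond
# ~1.6 leave almost no transmitted light, a regime real H&E tissue does not
# occupy and where intensity quantisation dominates any signal.
make_known_stains <- function(h = 96, w = 96, seed = 42, noise_sd = 0) {
  withr::with_seed(seed, {
    hf <- matrix(runif(h * w, 0, 0.8), h, w)
    ef <- matrix(runif(h * w, 0, 0.8), h, w)
    list(h = hf, e = ef,
         image = forward_stain(hf, ef, noise_sd = noise_sd, seed = seed))
  })
}

# Descriptor table of a single synthetic image, small enough for fast tests.
make_small_features <- function(seed = 1, image_px = c(544L, 544L),
                                n_images = 10L, prevalence = 0.4,
                                divergence = 1) {
  spec <- cohort_spec(n_images = n_images, prevalence = prevalence,
                      image_px = image_px, divergence = divergence,
                      seed = seed)
  cohort_descriptors(spec)
}

# Config scaled for fast unit tests.
tiny_config <- function(...) {
  pipeline_config(k1 = 4L, k2 = 4L, subset_sizes = c(4L, 8L),
                  cost_grid = 2^seq(-3, 7, 2), gamma_grid = 2^seq(-7, 1, 2),
                  inner_folds = 2L, outer_folds = 2L, ...)
}

# A deterministic code grid with the given codes (NA = invalid patch).
make_code_grid <- function(codes, k1) {
  structure(codes, class = c("code_grid", "matrix"), k1 = as.integer(k1))
}
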