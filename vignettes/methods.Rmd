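---
title: "Two-level visual-word coding of H&E images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level visual-word coding of H&E images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histocode)
```

## The problem

Histopathology slides stained with haematoxylin and eosin (H&E) are produced
for essentially every solid tumour, while molecular assays — gene-expression
signatures in particular — are not. When a genomic score separates patients
into clinically meaningful groups, a classifier that predicts the
*dichotomised* score from the routine H&E image acts as a surrogate
biomarker: a cheap, always-available pre-screen for the molecular test.
`histocode` implements such a pipeline for binary labels of whole tissue
images (the motivating case is the "BRAF-positive" group of colorectal
cancers, defined by the sign of a 64-gene signature score, with roughly 20%
prevalence), together with the statistics needed to evaluate it honestly and
a synthetic image generator that makes every stage testable without any
patient data.

The working hypothesis is purely textural: local tissue appearance, at two
spatial scales, carries enough signal to predict the label. No nuclei are
segmented, no hand-crafted pathology features are defined.

## The pipeline

### Stain separation

An RGB image is converted to optical densities, `od = -log10(max(v, 1) /
i0)` per channel with `i0 = 255` (intensities are floored at one level so
black pixels stay finite), and unmixed with the inverse of a stain matrix
whose rows are unit-norm OD vectors for haematoxylin, eosin, and a residual.
The default matrix is the standard Ruifrok–Johnston H&E pair with the unit
cross product as residual; it is an argument everywhere, so measured stain
vectors can be substituted. Negative unmixed concentrations are numerical
leakage between the non-orthogonal stain vectors and are clipped to zero;
the residual channel is discarded. Analysis happens at 5x magnification:
20x input is block-mean downscaled by 4 (partial edge blocks average over
the pixels present, so border tissue is kept). Downscaling precedes
deconvolution because it is four times cheaper and the two orders differ
only through the nonlinearity of the log — a sub-quantisation effect at
these noise levels.

Background is whatever the tumour mask excludes (mask value 0); when no
mask is supplied, near-white pixels (all three channels at or above 240)
are treated as background. A 32 × 32 patch is *excluded* only when more
than half of its pixels are background — exactly half keeps the patch, and
removing tissue pixels can only push a patch towards exclusion.

### Texture descriptors

Each stain channel is filtered with a fixed bank of real Gabor kernels

\[ G(x, y) = \exp\!\left(-\tfrac{x^2+y^2}{2\sigma^2}\right)
   \cos\!\big(2\pi\nu\,(x\cos\theta + y\sin\theta)\big) \]

over all combinations of bandwidth $\sigma \in \{1, 2\sqrt2\}$ pixels,
orientation $\theta \in \{0, \pi/4, \pi/2, 3\pi/4\}$ and frequency $\nu \in
\{3/4, 3/8, 3/16\}$ cycles/pixel — 24 filters, ordered bandwidth-major.
The two-octave $\sigma$ pair is the only two-element reading compatible
with a 24-filter bank and matches the three-octave frequency ladder.
Kernels are used exactly as written: no DC correction, no normalisation.
Support is the smallest odd integer at least $6\sigma + 1$ (three standard
deviations each side). Filtering is cross-correlation with
symmetric-reflect border padding, computed image-wide rather than
per-patch so patch statistics near patch borders see real neighbouring
tissue instead of zero padding; each kernel is applied as two rank-1
separable passes (the cosine of a sum splits into two outer products),
which is exact and an order of magnitude faster than dense 2-D
correlation.

A patch descriptor is the mean and the *population* variance (divide by
$n$: the descriptor is a moment of the response distribution over the
patch, not an estimate from a sample) of each filter response over the
32 × 32 window, for both channels: `[H means, H variances, E means,
E variances]`, 96 values.

### Two-level coding

*Level 1.* Up to 1000 valid-patch descriptors are sampled uniformly
without replacement per training image, pooled, z-scored per dimension
(mean- and variance-typed entries differ by orders of magnitude;
unstandardised Euclidean k-means would be governed by a handful of
dimensions — degenerate dimensions get unit scale), and clustered into
$K_1 = 128$ codewords. Every valid patch of every image is then assigned
its nearest codeword (1-based; ties to the lowest index), producing a code
grid with an NA sentinel on excluded patches.

*Level 2.* A neighbourhood is 15 × 15 patches (480 px). Its descriptor is
the frequency vector of L1 codes among its valid member patches,
normalised to sum to one; a window with more than half of its member
patches invalid is itself invalid. For codebook fitting, up to 500
descriptors are sampled per training image at uniformly random *valid*
stride-1 window positions — random placement maximises coverage for
clustering. Two class-specific codebooks of $K_2 = 128$ codewords each are
fitted independently on the positive- and negative-class training images
(no standardisation: frequencies are already commensurate), giving a
concatenated index space $1 \ldots 2K_2$ with the positive block first.
The design separates the scales deliberately: L1 captures structures of a
few cells, L2 captures their arrangements, and per-class L2 codebooks
guarantee the minority class its own representational budget in an
imbalanced cohort.

*Image histogram.* The final representation tiles the code grid with
non-overlapping 15 × 15 windows anchored at patch (0, 0) — non-overlap
avoids double counting — assigns each valid window its nearest codeword
over the $2K_2$ concatenated centroids, and normalises the histogram of
assignments to relative frequencies, since image area varies widely and
raw counts would confound size with content.

### Classifier

Features (histogram bins) are ranked by recursive feature elimination
using a linear SVM with cost 1: at each round the five features with the
smallest absolute weight are dropped (a step of 5 trades ranking
resolution against cost), and elimination order read backwards is the
ranking. The linear criterion is retained even though the final model is
nonlinear — weight-based RFE is only defined for linear kernels. For each
candidate subset size (default 30, 50, …, 130), an RBF SVM is tuned over
the standard lattice $C \in \{2^{-5}, 2^{-3}, \ldots, 2^{15}\}$,
$\gamma \in \{2^{-15}, 2^{-13}, \ldots, 2^{3}\}$ by mean AUC across
stratified inner folds (default 5); ties prefer the smaller size, then
smaller $C$, then smaller $\gamma$. All SVM fits weight classes inversely
to their frequency and skip feature scaling (proportions are already
bounded and commensurate). The final model is refitted at the winning
size and hyperparameters; its support-vector expansion is extracted into
a plain list so that decision values are computed by the package itself —
margins survive text serialisation to better than 1e-9 and the decision
value's sign is fixed to favour the positive class regardless of
fitting-library internals. The class call is positive iff the margin
*strictly* exceeds the threshold, 0 by default (the conventional SVM
operating point); sweeping the threshold trades sensitivity against
specificity monotonically.

### Honest evaluation

Everything the training data touches — descriptor standardiser, both
codebook levels, ranking, tuning, final SVM — is refitted from scratch
inside each fold of a stratified outer cross-validation (default 10
folds), and held-out images are encoded with the training fold's
codebooks. Every stage seed derives from the global seed plus the sorted
training-image ids, so a fold's fit is provably independent of which
images sit in its test set; the test suite checks this by refit equality
after deleting a held-out image.

Out-of-fold predictions feed the evaluation utilities: the confusion
matrix and its ratios (a zero denominator yields NA, never a silent 0);
Agresti–Coull intervals for proportions; rank-based (Mann–Whitney) AUC
with a stratified bootstrap percentile interval (2000 replicates by
default; the replicate count is a convention, the percentile method is
the basic choice); Yates-corrected $\chi^2$ on 2 × 2 tables for
associations with categorical covariates; and univariable logistic
regressions whose slope sign gives each selected feature a polarity,
from which spatial maps mark the encoding windows assigned to positive-
or negative-polarity codewords (invalid windows appear in neither map).
AUC is never reoriented — a value below 0.5 is reported as is, so an
anti-learning bug cannot masquerade as signal. No multiplicity adjustment
is applied anywhere.

## The synthetic cohort

The generator emulates exactly the structure the pipeline is designed to
detect, at both scales. A *motif* is a small texture model — an oriented
sinusoidal grating, isotropic band-pass noise, or a Gaussian blob field —
with stain loadings that place it in the haematoxylin and/or eosin
channel; grating parameters sit inside the bank's sensitive range. An
image is a white frame (background margins) around a mosaic of 480-px
motif tiles — the tile equals the L2 window footprint, so class signal
lives at precisely the neighbourhood-coding scale while within-tile
texture drives L1. Each class draws tiles from its own motif mixture; a
divergence parameter interpolates from identical mixtures (0: no signal)
to disjoint motif groups (1: fully class-specific texture). Labels are
independent Bernoulli draws at 20.3% prevalence — a typical
biomarker-positive rate in colorectal cancer cohorts — which exercises
the stratification and class-weighting paths. Stain mixing is the exact
forward model of the deconvolution (OD composition, then $10^{-OD}$,
Gaussian pixel noise of 2 intensity levels, rounding), so recovery is
checkable: noise-free round trips correlate above 0.999 with the true
fields, noisy ones above 0.98. The manifest (label, per-image seed, tile
layout) reconstructs every image bit-for-bit.

What the generator does *not* emulate: nuclear morphology, mucin, colour
variation between staining batches, scanner artefacts, pen markings,
JPEG artefacts, or irregular tumour-region shapes. Passing tests
therefore demonstrate that the implementation recovers two-scale,
stain-separated texture structure when it exists — not that the method
reaches any particular accuracy on real slides.

## Problem sizes used in tests

The full clinical-scale configuration ($n = 291$ images of roughly
$25000 \times 12500$ px at 5x, $K_1 = K_2 = 128$, 10 outer folds) is far
beyond what a test suite should run, so the CI-grade study conditions are
a deliberate scale-down, chosen once: 60 images of 1024 × 544 px (two
480-px tiles inside a 32-px white margin), $K_1 = K_2 = 16$, subset sizes
$\{8, 16, 24, 32\}$, 3 outer and 3 inner folds, five cohort seeds. Three
inner folds (not the default five) because a 20%-prevalence cohort of
this size cannot always stratify five folds within an outer training
split. Under these conditions the acceptance suite requires a median
out-of-fold AUC of at least 0.90 at divergence 1 and a median within
[0.30, 0.70] after label permutation. Smaller unit-test fixtures shrink
further (down to $K_1 = K_2 = 4$, twelve images) where only mechanics are
under test.

## Numerical choices

* **k-means** is k-means++ initialisation followed by Lloyd iterations,
  stopping when the relative objective drop falls below 1e-4 or after 300
  iterations, best of 5 restarts. Implemented in the package (with BLAS
  matrix distances) because the protocol — seeding, tolerance,
  deterministic lowest-index tie-breaking, farthest-point re-seeding of
  empty clusters — is part of the contract; `stats::kmeans` and an
  exhaustive-partition enumeration serve as independent cross-checks in
  the tests.
* **Ties** in every nearest-centroid assignment go to the lowest index;
  subset-size ties to the smallest size; tuning ties to the smallest
  $C$, then $\gamma$. Determinism everywhere is what makes the
  leak-freedom check meaningful.
* **Seeds.** One global seed; every stage derives a sub-seed by hashing
  the seed with a stage key (and, for fold fits, the sorted training
  ids). Reruns are bit-for-bit identical.
* **Degenerate inputs** fail loudly and early: singular stain matrices,
  even kernel supports, out-of-bounds patches or windows, images with no
  valid patch or window, single-class label vectors, empty tuning grids,
  zero-margin contingency tables. Constant features in the polarity test
  return "undetermined" rather than erroring, because they occur
  naturally in sparse histograms.

## Known limitations

* Stain vectors are fixed, not estimated per slide; images with unusual
  staining will leak between channels.
* The NDPI/whole-slide reading step is out of scope: inputs are
  pre-exported TIFFs (or in-memory arrays).
* Survival analysis of predictions is out of scope; the evaluation layer
  stops at association tests.
* With very small cohorts the inner tuning loop sees folds with one or
  two positives; AUC estimates there are coarse, which is why tuning
  ties are broken conservatively.

## A minimal run

```{r example, eval = FALSE}
spec <- cohort_spec(n_images = 60, image_px = c(1024L, 544L),
                    divergence = 1, seed = 1)
cd <- cohort_descriptors(spec)
cfg <- pipeline_config(k1 = 16L, k2 = 16L, subset_sizes = c(8L, 16L, 24L, 32L),
                       inner_folds = 3L, outer_folds = 3L)
cv <- outer_cv(cd$features, cd$labels, k = 3, config = cfg, seed = 1)
glance(cv)
cv_metrics(cv, seed = 1)
autoplot(cv)
```
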