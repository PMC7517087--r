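---
title: "Texture-based grading of retinal fundus images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based grading of retinal fundus images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Diabetic retinopathy (DR) disturbs the fine texture of the retina: as the
disease progresses, microaneurysms and dot hemorrhages appear as small dark
blobs, exudates as bright deposits, and the background granularity of the
fundus photograph coarsens. `fundustex` operationalizes this observation as
a classical texture-analysis pipeline on 2-D 8-bit fundus rasters:

1. **Preprocessing** — grayscale conversion, histogram equalization,
   Gaussian denoising, optional Gabor filter bank diagnostics.
2. **Segmentation (CARGS)** — clustering-based automated region growing:
   quadrant partition, irregular-polygon seed groups, homogeneity region
   growing, K-means refinement on intensities.
3. **Hybrid feature extraction** — 245 features per region of interest:
   220 gray-level co-occurrence (GLCM), 15 run-length (GLRLM), 6 first-order
   histogram, 4 Haar wavelet subband energies.
4. **Feature selection** — Fisher ratio, probability-of-error + average
   correlation (POE+AC), and mutual information each nominate 10 features
   (30 pre-optimized); correlation-based feature selection (CFS) with
   symmetric uncertainty picks the final post-optimized subset.
5. **Evaluation** — stratified 10-fold cross-validation with a pooled
   confusion matrix and the panel {overall accuracy, per-class accuracy,
   Cohen's kappa, weighted TP/FP rates, one-vs-rest ROC area, MAE, RMSE}.

A synthetic five-class generator (`make_fundus_like`, `make_dataset`)
emulates a healthy retina plus four DR severities, so every stage is
testable without clinical images.

# Preprocessing

Histogram equalization maps level $r$ with empirical CDF $F(r)$ to
$\lfloor 255\,F(r)\rfloor$. The floor convention was chosen (over
round-half-away) because it makes an exactly uniform histogram a fixed
point of the mapping, which is the natural idempotence property for an
equalizer; the mapping is monotone either way.

Gaussian smoothing uses the separable zero-mean kernel
$\psi(y,z) \propto e^{-(y^2+z^2)/2\sigma^2}$, truncated at $\pm 3\sigma$
and renormalized to sum to one (so constant rasters are fixed points),
with replicate edge padding. Output is re-quantized by round-half-away
then clipped to $[0,255]$. Default $\sigma = 1$ px.

The Gabor bank evaluates
$g(y,z) = e^{-(y'^2+\gamma^2 z'^2)/2\sigma^2}\,e^{i(2\pi y'/\lambda + \eta)}$
at 8 orientations $\theta_k = k\pi/8$ and 5 scales (wavelength multipliers
1..5), 40 magnitude rasters total. Defaults: base $\lambda = 4$ px,
$\gamma = 0.5$, $\eta = 0$, $\sigma = 0.56\lambda$ — standard values for a
half-response spatial-frequency bandwidth of one octave. The bank is kept
as a diagnostic attachment: nothing downstream consumes it, because the
source methodology names the filter but never routes its responses into
the feature set.

# CARGS segmentation

The raster is split into four quadrants (odd rows/columns go to the
bottom/right tiles). Within each quadrant, seed groups are sampled as
irregular star-shaped polygons: vertex count uniform in 5..12, sorted
angular positions, per-vertex radii uniform in 20–100% of the centroid's
distance to the nearest border. Star-shapedness guarantees a simple
polygon; rasterization keeps the largest 8-connected pixel component so
the seed group is connected.

Region growing is wave-based: all frontier pixels (8-neighbors of the
region) whose intensity differs from the current region mean by at most
$\tau$ join simultaneously, then the mean is updated. The growth criterion
is not stated in the source methodology; the running-mean aggregation rule
(Adams–Bischof seeded region growing) is the classical choice, with
default $\tau = 10$ gray levels. At $\tau = 0$ the procedure reduces
exactly to the connected component of the seed's intensity plateau, which
the test suite verifies against an independent graph-based labeling.

K-means refinement runs Lloyd iterations on the masked intensities with
Euclidean distance (Eq.-style assignment/update): deterministic
initialization at $K$ evenly spaced intensity quantiles, ties to the
lowest center index, emptied clusters re-seeded at the farthest pixel,
convergence when the largest center shift drops below 0.5 gray level
(cap: 100 iterations). The working range $K \in [7, 12]$ is enforced
softly — values outside warn, $K > 12$ is clamped because segmentation
quality is reported to degrade there. Default $K = 8$, the midpoint of
the working range. Final cluster masks are split into 8-connected
components so each returned region is spatially coherent.

Because the source methodology never states how many ROIs feed the
classifier per image, the pipeline's default classification mode uses one
full-image ROI; CARGS mode (`roi_mode = "cargs"`) is selectable and keeps
the largest regions.

# Hybrid texture features

All second-order matrices use $N_g = 64$ gray levels (uniform binning
$v \mapsto \lfloor v N_g/256 \rfloor$), the common texture-analysis
convention; first-order histogram features use the raw 0–255 scale.

**GLCM block (220).** For distances $d \in \{1..5\}$ and angles
$\{0°, 45°, 90°, 135°\}$, pairs are accumulated symmetrically (both
orders) and normalized to sum to one. Eleven statistics per matrix:
energy, contrast, correlation, variance, inverse difference moment,
difference variance, sum average, sum variance, entropy, sum entropy,
difference entropy — entropies in bits with $0\log 0 := 0$. Correlation is
defined as 0 when a marginal standard deviation vanishes. Names follow
the MaZda offset convention, e.g. `S(5,0)Entropy`, `S(5,-5)Contrast`.

**GLRLM block (15).** Maximal equal-level runs along each of the four
directions, truncated at mask boundaries; gray levels are indexed 1-based
so the $1/l^2$ weights are defined. The fifteen statistics are SRE, LRE,
GLN(+normalized), RLN(+normalized), run percentage, low/high gray-level
emphasis, the four joint short/long × low/high emphases, and the
gray-level and run-length variances (each with its own marginal mean —
the printed formulas share a garbled mean symbol). The default block
averages the four directions, which preserves the printed 245-feature
total; a per-direction mode (4 × 15, `Horzl_`/`Vertl_`/`45dgr_`/`135dr_`
prefixes) is available because the published post-optimized feature names
are per-direction.

**Histogram block (6).** Mean, variance, skewness (third standardized
moment; 0 for constant regions), energy, entropy, and the 1st percentile
(`Perc.01%`, nearest rank). The source counts "6 histogram features"
without enumerating them; this set covers all histogram features that
appear in its post-optimized table. Pearson mode skewness is exposed as
an auxiliary function but excluded from the default vector.

**Wavelet block (4).** Orthonormal Haar decomposition; at the requested
scale, each subband's energy is the mean squared coefficient over the
coefficients whose $2^s \times 2^s$ support block intersects the ROI.
Subbands must be at least 8 × 8, so a 256 px (128 px) raster admits scales
1..5 (1..4). Default scale 4, matching the published `..._s-4` names. At
scale 1 with a full mask the four energies satisfy Parseval's identity,
which the tests assert.

# Feature selection

The three pre-optimization rankings:

- **Fisher**: $F_j = \sum_{i<j} p_i p_j (m_i - m_j)^2 / \sum_i p_i v_i$
  (class priors $p$, per-class means $m$ and variances $v$). The printed
  formula in the source is typographically damaged; this is the classical
  multi-class Fisher ratio it names. Zero within-class variance with
  separated means yields an infinite sentinel ranked first.
- **POE+AC**: the first feature minimizes the resubstitution error of a
  per-feature nearest-class-mean classifier; feature $k$ minimizes
  $\mathrm{POE}(f) + \frac{1}{k-1}\sum_{j<k} |\rho(f, f_j)|$. The
  classifier behind POE is unspecified in the source; nearest class mean
  is the convention of the texture software it cites.
- **MI**: mutual information in bits between the equal-frequency
  discretized feature (10 bins) and the class label.

Each method contributes its top 10 features; a feature already
contributed is replaced by that method's next-best unused one, so the
pool is exactly 30 distinct features. Tables whose distinct-valued
columns cannot fill the three quotas raise an error.

**CFS** discretizes features (equal-frequency, 10 bins) and scores
subsets by Hall's merit $k\,\bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$
with $\bar r$ the mean symmetric uncertainty
$SU(X,Y) = 2\,[H(X)+H(Y)-H(X,Y)]/[H(X)+H(Y)]$. The search is best-first
forward expansion, stopping after 5 consecutive non-improving expansions;
the merit function itself is not printed in the source (only SU is), so
the standard CFS formulation is used. The selected subset size is an
outcome, not a target — the published "13 post-optimized features" is a
dataset-dependent result and is not forced.

Equal-frequency discretization makes MI and CFS invariant to monotone
rescaling of features; the Fisher ratio is affine-invariant analytically.

# Evaluation

Folds are stratified: each class is shuffled and dealt round-robin, so
per-fold class counts deviate from proportionality by at most one.
Out-of-fold predictions are pooled into a single confusion matrix
(matching the single printed matrix of the source, rather than averaging
per-fold metrics). Kappa uses the standard marginal chance correction.
MAE and RMSE follow the WEKA convention — mean absolute / root mean
square difference between predicted class-probability vectors and 0/1
indicators, averaged over samples and classes — because the source prints
but never defines them. ROC area is the prevalence-weighted mean of
one-vs-rest Mann–Whitney statistics.

`metrics_from_confusion` accepts stated class totals as accuracy
denominators, because the published confusion matrix under-sums its
stated row totals by up to four instances; using the stated totals
reproduces the published overall and per-class accuracies.

Classifiers are consumed through an adapter contract
(`fit`/`predict_prob`), not re-implemented: the reference adapter is a
multinomial logistic model (glmnet, fitted down a short ridge path to a
light penalty of $10^{-3}$ — near-separable data makes a single
unpenalized fit numerically fragile), plus a dependency-free
nearest-centroid baseline.

# Synthetic data: what it emulates, and what it does not

`make_fundus_like` draws a bright disc (the imaged retina) on a dark
surround, adds correlated Gaussian noise (correlation length = smoothing
sigma of a white-noise field; 1–3 px increasing with grade), and places
Poisson-count lesions: dark blobs (microaneurysm/hemorrhage-like, 60% of
the count budget, intensity −95) and bright blobs (exudate-like, 40%,
+80). Class mean lesion counts are {0, 4, 10, 20, 35} for grades 0–4, so
lesion density and texture granularity both increase monotonically with
grade — the two properties the feature families are designed to measure.

Default image size is 128 px. The stated world of the source uses
256 px images; 128 px is the smallest size at which the default wavelet
scale 4 is admissible ($128/2^4 = 8$) while keeping the full end-to-end
acceptance run around two minutes on one CPU. The generator accepts any
size ≥ 64.

The generator does **not** emulate vessel trees, optic discs,
illumination gradients, camera noise statistics, or inter-patient
variability. A green end-to-end test therefore establishes that the
pipeline separates texture classes whose differences resemble DR's
lesion-density and granularity signal — not that it grades clinical
fundus photographs at the published accuracy. The published clinical
tables cannot be reproduced without the original hospital images, which
are not publicly available.

# Numerical conventions

- Intermediate arithmetic in double precision; 8-bit re-quantization by
  round half away from zero, then clipping.
- Entropies in bits, $0\log 0 := 0$ throughout.
- K-means ties to the lowest center index; deterministic quantile
  initialization by default.
- All randomness (polygons, folds, synthetic data) flows through explicit
  integer seeds; child seeds are derived linearly modulo a prime below
  $2^{31}$.
- PNG I/O is a self-contained 8-bit codec over R's zlib bindings
  (grayscale written; grayscale/gray-alpha/RGB/RGBA read, color reduced by
  BT.601 luma weights 0.299/0.587/0.114). PGM/PPM are supported as
  plain-text-friendly formats. TIFF/BMP/JPEG are not supported: no codec
  is available in the dependency environment, and hand-rolling lossy
  decoders is out of scope.

# Known limitations

- CARGS composition (how grown regions and K-means clusters reconcile,
  polygon counts) is one faithful reading of a loosely specified
  procedure; the composite is deterministic and property-tested, but
  other readings exist.
- GLCM features are computed per (distance, angle) pair; no
  angle-averaged GLCM variant is provided.
- The run-length per-direction mode yields 290 features and therefore
  does not preserve the 245 total; it exists for name compatibility with
  the published post-optimized table.
- Best-first CFS is exact only on small tables (verified against
  exhaustive enumeration up to 8 features); on larger tables it is a
  heuristic, as in every practical CFS implementation.
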