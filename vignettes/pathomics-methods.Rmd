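---
title: "Methods: from H&E tiles to treatment-response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from H&E tiles to treatment-response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathomics)
```

## The problem

Whole-slide H&E histology of ovarian tumors carries morphological
information — nuclear size and shape, chromatin texture, cytoplasmic
staining patterns, cell packing — that correlates with how a tumor will
respond to anti-angiogenic therapy (bevacizumab). `pathomics` implements a
classical (non-deep-learning) pipeline that turns slide exports into a
case-level binary prediction: tile the slide, keep tissue-rich tiles,
separate the stains, segment nuclei/cells/cytoplasm, extract quantitative
features per object and per tile, pool them into one vector per patient,
select features by mutual information, and classify with a nested
cross-validated SVM.

Every stage is exercisable without clinical data through a seeded synthetic
cohort generator with exact ground-truth masks.

## Stain model and deconvolution

Transmitted light follows Beer–Lambert: for incident intensity $I_0$ and
per-stain concentrations $c_H, c_E$ with unit absorption vectors
$s_H, s_E \in \mathbb{R}^3$,

$$ I_k = I_0 \cdot 10^{-(c_H s_{H,k} + c_E s_{E,k})}, \qquad k \in \{R,G,B\}. $$

`rgb_to_od()` inverts the exponential with a one-intensity-level guard
(`eps = 1`) against saturated black pixels; `deconvolve()` solves the
per-pixel least-squares system with the Moore–Penrose pseudoinverse of the
2×3 stain matrix and clamps negative concentrations. Defaults are the
Ruifrok–Johnston H&E vectors, H = (0.650, 0.704, 0.286) and
E = (0.072, 0.990, 0.105) (normalized); both are configurable. The exact
mix–unmix identity holds on float renders with `eps = 0`; with 8-bit
quantization round-trips are accurate to one intensity level. No automatic
stain estimation (Macenko/Vahadane) or cross-slide normalization is
attempted. All texture and intensity features downstream are computed on
the OD concentration channels, not on re-inverted grayscale.

## Tiling and the tissue filter

Slides are cut into non-overlapping square tiles (default 1000 px);
partial border strips are discarded rather than padded, and tile $(r,c)$
holds the half-open pixel block $[rs,(r{+}1)s) \times [cs,(c{+}1)s)$. A
tile is kept when at least half of its pixels are tissue. "Tissue" is
deliberately simple and deterministic: HSV saturation above 0.05 **or**
luminance below 220/255 — the standard whitespace rule. The 50% cut is
inclusive. There is no manual quality review anywhere in the pipeline; the
fold detector below is its automated stand-in.

## Segmentation

**Tissue folds.** Folds are double-thickness artifacts: macro-scale
regions roughly twice as dark as typical tissue in both stains. Per-pixel
thresholds cannot isolate them because nuclei are individually darker than
fold stroma. The detector therefore (i) applies a grayscale morphological
opening of total OD with a nucleus-scale disc (radius 8 px), erasing
nucleus-sized peaks while preserving macro-scale plateaus and their
boundaries; (ii) thresholds the opened image at the larger of the
minimum-cross-entropy (Li) threshold over stained pixels and
`fold_factor` (default 2, i.e. double thickness) times their median; and
(iii) keeps only connected components of at least 0.25% of the tile area.
A near-constant tile yields a degenerate histogram, an unreachable
threshold, and an empty mask. Fold pixels are excluded from every
downstream stage.

**Nuclei.** Otsu threshold on the hematoxylin channel, hole filling,
declumping by watershed on the Euclidean distance transform with an
h-minima tolerance of 2 px, then an equivalent-diameter filter of
8–60 px — typical nuclear sizes at 20× (≈0.5 µm/px). Labels are
canonicalized to raster order so identical inputs give identical label
geometry.

**Cells by propagation.** Nuclei seed a shortest-path region growing over
the foreground (total OD above its Li threshold): the step cost between
4-adjacent pixels is $\sqrt{(\Delta g)^2 + \lambda^2}$, accumulated along
paths and minimized Dijkstra-style (implemented in C++; ties resolved by
deterministic insertion order). Small $\lambda$ (default 0.05) lets stain
gradients steer boundaries; large $\lambda$ approaches the nearest-seed
Voronoi partition. Every cell inherits its seed nucleus label, and
cytoplasm is the exact per-label set difference, so
area(cell) = area(nucleus) + area(cytoplasm) pixel-exactly.

**Li threshold implementation.** The minimum-cross-entropy criterion is
implemented as Li & Lee's fixed-point iteration
$t \leftarrow (\mu_b - \mu_f)/(\log \mu_b - \log \mu_f)$ on values shifted
strictly positive, with `Inf` returned for near-constant input (empty
foreground by convention).

## Feature families

Per object (nuclei against the hematoxylin channel, cytoplasm against
eosin):

* **Intensity** — integrated/mean/median/sd/raw MAD/min/max/quartiles and
  mean boundary intensity.
* **Radial distribution** — 4 equal-width rings of normalized centroid
  distance: `FracAtD` (ring share of intensity), `MeanFrac` (ring share
  normalized by pixel share), `RadialCV` (CV over 8 angular wedges).
* **Haralick texture** — region intensities quantized to 8 levels over the
  region min–max, symmetric GLCMs at 1-px offsets in 4 directions, 13
  statistics (including InfoMeas1/2 and difference entropy) averaged over
  directions; natural logarithms; constant regions yield zeros by
  convention.
* **Zernike shape** — moment magnitudes $|Z_{nm}|$, $n \le 9$, $n-m$ even
  (30 values), on the unit disk defined by the object's centroid-centered
  minimum enclosing circle, with the indicator normalized to unit mass.
  This normalization (rather than a bounding-box circle) is what makes a
  disk map to the full unit disk, so higher-order magnitudes vanish for
  circles and magnitudes are exactly invariant under 90° rotations.
  Rasterization on the square lattice leaks ~2×10⁻³ into the $m = 4k$
  harmonics at 100-px radius (more at smaller radii); the tests bound this
  rather than pretend it away.
* **Geometry** — area, corner-corrected chain-code perimeter
  (Vossepoel–Smeulders weights; a rasterized r = 50 circle comes out
  within 2% of $2\pi r$), form factor $4\pi A/P^2$ clamped to 1, extent,
  solidity against the convex-hull lattice count, moment-based axes /
  eccentricity / orientation, Feret diameters from rotating hull
  projections.
* **Neighborhoods** (nuclei only) — neighbor count and percent of boundary
  pixels within 5 px of another object, via exact Euclidean distance maps.

Per tile: Haralick features of each stain channel, 16-scale granularity
spectra (volume removed by disc openings of increasing radius), stain
colocalization (Pearson, overlap, Manders with Otsu auto-thresholds, over
stained pixels; zero-variance channels give r = 0), image quality (log–log
radial power-spectrum slope as a focus score, percent saturated/minimal
pixels), channel intensity summaries, object counts, and tissue fraction.

No attempt is made to reproduce any external tool's exact feature
inventory; each family is implemented from its literature definition and
the emitted columns are enumerated by `feature_manifest()` under the
stable `compartment_family_measure` naming scheme.

## Aggregation and pruning

All of a case's objects are pooled across tiles before any statistic is
computed, as are its per-tile image rows; aggregation is therefore
invariant to tile order and associative. Each unique feature yields 12
statistics — mean, median, sd, and the nine interior deciles (10th–90th,
type-7 linear-interpolation quantiles). "Deciles" is read as the nine
interior deciles; the definition is configurable. A compartment with zero
objects across a whole case aggregates to zeros with a raised
`*_missing` flag, keeping the matrix rectangular without losing the
information. Pruning drops exact duplicate columns (first-by-order kept)
and columns whose variance after median scaling falls below 1e-10, with a
per-column reasons report; it is idempotent.

## Feature selection and modeling

Mutual information between each feature and the binary label uses the
Ross (2014) k-nearest-neighbor estimator (k = 3, clamped to the smallest
class size minus one): the distance to the k-th same-class neighbor
defines a radius, and $\psi$-terms over the strictly-closer neighbor count
(including the point itself) yield the estimate in nats, clamped at 0. A
tiny seeded jitter — one shared vector scaled per column — breaks ties, so
duplicated columns score identically and results are reproducible.
Selection is either inclusive thresholding (`score >= 0.29` retains the
boundary) or top-k (default k = 100, ties by column order).

Classification is a nested stratified 5×5-fold SVM (`e1071`), linear or
RBF. Per outer fold: z-scoring and (by default) MI selection are fit on
the training cases only; the inner grid search over
C ∈ {0.01, 0.1, 1, 10, 100} (and γ = scale heuristic plus any supplied
grid for RBF) maximizes mean inner-fold AUC; the refit model scores the
held-out fold. Every case is scored exactly once; the pooled confusion
matrix uses decision threshold 0. The historical protocol of selecting
features once on the whole dataset before cross-validation leaks test
information into selection; it remains available as
`selection_scope = "whole_dataset"` for fidelity, but the leakage-free
per-fold scope is the default. AUC is the rank (Mann–Whitney) statistic;
reports carry per-fold AUCs (mean ± sd) and the pooled-score AUC.

Confusion metrics follow the predicted-denominator conventions
(precision = PPV = TP/(TP+FP), NPV = TN/(TN+FN)); undefined ratios are
reported as 0 with a flag.

## The synthetic cohort generator

`cohort_spec()`/`generate_cohort()` emulate exactly what the pipeline
assumes about its inputs: elliptical nuclei (area-preserving eccentricity
parameterization, non-overlapping by rejection sampling with a 1000-retry
budget, so ground-truth counts are exact), surrounding cell ellipses with
contested pixels resolved to the nearest nucleus center, a smooth-field
tissue region thresholded at the background quantile (making the tissue
fraction exact), Beer–Lambert rendering through the configured stain
matrix, per-pixel Gaussian OD noise plus low-frequency multiplicative
modulation (so texture features are non-degenerate), and optional fold
blobs rendered as double-thickness tissue
(concentrations $2\max(c, c_{\text{cytoplasm}})$, since a folded flap
covers background too). The two classes differ only through the
per-class parameters (nuclear radius, eccentricity, texture noise), so a
zero effect size gives exchangeable classes by construction.

Default cohort structure mirrors the clinical setting the pipeline is
calibrated around: 44 responders vs 35 non-responders. The generator does
not attempt photorealism: no scanner defocus beyond an optional Gaussian
blur, no pyramidal WSI container, no inter-slide stain variation, no
spatially organized tissue architecture. Passing the calibration tests
below therefore demonstrates that the machinery is correct and sensitive
to the morphology it models — not that the classifier would reach any
particular performance on clinical slides.

## Calibration checks and problem sizes

Simulation-backed tests run in a small-cohort regime chosen once as the
smallest configuration that keeps all stages non-trivial: 128-px tiles, 12
nuclei per tile, one tile per case, 10 + 10 cases; base nuclear radius
5 px with the responder class offset by 0–3 px. Under zero effect size the
mean nested-CV AUC over 10 replicate cohorts must lie in [0.4, 0.6];
across radius offsets {0, 1, 2, 3} px (5 replicates each) the mean AUC
must be non-decreasing up to fold noise and clearly higher at 3 px than at
0; and on two 6σ-separated Gaussian clusters the nested CV must reach
≥95% accuracy. A low-noise cohort must give a nuclei count error ≤5% with
best-match boundary Jaccard ≥0.8 and the pixel-exact area identity.

## Numerical conventions and edge cases

* Degenerate histograms: Li and Otsu thresholds return `Inf` (empty
  foreground), constant Haralick regions return zeros, zero-variance
  channels give r = 0, empty granularity input gives a zero spectrum.
* Quantiles are R's default type 7 throughout.
* Propagation ties are resolved by deterministic insertion order; label
  IDs are canonicalized by raster order of first appearance.
* Seeds: one integer seed fully determines a cohort; the pipeline derives
  stage seeds (cohort, MI jitter, folds) from its global seed by hashing,
  so runs are bitwise reproducible end to end.
* EBImage grayscale morphology operates on [0, 1]; OD images are rescaled
  around openings to avoid clipping.

## Known limitations

* The fold detector's factor-of-two anchor presumes fold staining roughly
  doubles typical tissue OD; faint folds or heavily stained normal regions
  at macro scale can defeat it (both parameters are exposed).
* Zernike magnitudes carry the square-lattice rasterization leakage noted
  above; comparisons across very different object sizes inherit it.
* Perimeter, solidity and Feret values are chain-code/lattice estimates
  with ~2% bias on small objects.
* The MI estimator's O(n²) per-column cost is fine for case-level cohorts
  (tens to hundreds of rows) but not for per-object modeling, which is out
  of scope by design — aggregation is strictly case-level.
* The cytoplasm of a cell that propagation could not grow beyond its
  nucleus is empty; such objects appear in nuclei tables only.
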