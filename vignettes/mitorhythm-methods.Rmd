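---
title: "Methods: mitochondrial morphology scoring and rhythm detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial morphology scoring and rhythm detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorhythm)
```

## Scope

`mitorhythm` quantifies the fission/fusion state of the mitochondrial
network from single-channel fluorescence microscopy images, and asks
whether that state — or any other scalar read-out sampled over time —
oscillates with a fixed (circadian, 24 h) period. The package covers the
full chain: synthetic ground-truth generation, segmentation, per-organelle
morphology, per-cell and per-timepoint aggregation, and two rhythm
statistics (parametric cosinor regression and a nonparametric JTK-style
rank test). Derived assay quantities used alongside imaging in circadian
immunometabolism studies — Mito Stress respiration parameters from
oxygen-consumption traces and delta-delta-Ct qPCR fold changes — are
included so a complete study analysis can be reproduced from tidy tables.

## The segmentation model

Images are carried as `calibrated_image` objects: an intensity matrix plus
an explicit `pixel_size_um`. Every geometric parameter is given in
micrometres and converted internally, so one parameter set transfers
across magnifications; the calibration is never inferred from file
metadata.

The pipeline mirrors the classic ImageJ-macro design for MitoTracker
images:

1. **Normalisation** (`normalize_image`): linear min–max mapping onto the
   16-bit range, round-half-up (`floor(x + 0.5)`). A constant image maps
   to zeros by definition rather than erroring.
2. **Cell masks** (`segment_cells`): Gaussian smoothing
   (`cell_smooth_sigma_um`, default 1 µm — large enough to merge
   organelle texture with the dim cytoplasm into one body), Otsu or
   IsoData auto-thresholding, hole filling, a distance-transform watershed
   to separate touching cells (`cell_split_prominence_um`, default 1 µm, a
   cell-scale prominence), and removal of objects below
   `min_cell_area_um2` (default 5 µm², far below any cell body but above
   debris).
3. **Mitochondrial enhancement** (`bandpass_filter`): difference of
   Gaussians with `bandpass_sigma_small_um` (default 0.1 µm, the tube
   radius scale) and `bandpass_sigma_large_um` (default 1 µm, the
   background scale); negative lobes are clipped at zero. DoG was chosen
   because "band-pass" in the macro tradition means exactly this
   separable filter; it annihilates constants and smooth gradients, which
   the tests verify directly.
4. **Thresholding**: Otsu by default for cross-implementation
   determinism; IsoData (iterative intermeans, the ImageJ default) and a
   fixed threshold are selectable because the choice is a genuine degree
   of freedom in published macros.
5. **Tiny-object removal**: `min_object_area_um2`, default 0.1 µm² —
   below the smallest resolvable mitochondrion at a 0.4 µm tube width but
   above shot-noise specks.
6. **Splitting touching mitochondria** (`split_touching`): Euclidean
   distance transform inside the binary mask, light Gaussian
   regularisation of the distance map (0.7 px; see *Numerical choices*),
   then a watershed whose basins are limited to regional maxima of
   prominence at least `hmax_prominence_um` (default 0.1 µm). The
   watershed partitions the mask exactly: no foreground pixel is lost or
   created, and label counts are monotone in the prominence.
7. **Restriction to cells**: mitochondrial pixels outside every cell mask
   are discarded, then labels are made contiguous.

Manual mask editing, which some imaging workflows allow, is deliberately
excluded: the pipeline is fully automatic and therefore reproducible.

## Morphology and fission/fusion scoring

`measure_objects` emits one record per organelle:

* `area_um2` — pixel count × pixel area.
* `length_um` — the object's extent along the major axis of the
  intensity-unweighted best-fit ellipse (orientation from second central
  moments with the 1/12 finite-pixel term), plus one pixel of footprint
  compensation. For a tube this is the end-to-end length. The raw
  moment-ellipse axis (`4·sqrt(λ₁)`) is also reported as
  `ellipse_major_um`; it is the textbook quantity but reads roughly 15 %
  long on rectangles and thin tubes, which is why the extent is the
  primary length here.
* `feret_um` — maximal caliper diameter from the convex hull of the
  sub-pixel boundary, for comparability with Feret-based workflows.
* `aspect_ratio` — major/minor moment-ellipse axes, clipped to ≥ 1.
* `circularity` — `4πA/P²`, clipped to ≤ 1 (digitised discs can exceed 1
  under any finite-resolution perimeter estimator).

Organelles are assigned to the cell under their centroid, with a
majority-pixel fallback on the rare centroid-on-background case
(strongly bent or diagonal objects).

Fission/fusion scoring follows the three length classes used in
mitochondrial dynamics work: short < 1 µm, mid 1–3 µm, long > 3 µm, with
both boundaries closed on the mid class ("1–3 µm" read literally). The
per-cell short fraction is the fission score and the long fraction the
fusion score. Cells without any detected mitochondria are retained with
`NA` medians rather than dropped, because silently removing them would
bias per-timepoint means towards mitochondria-rich cells.

## Rhythm statistics

### Cosinor

For a fixed period τ (24 h by default) the model is linearised as

Y&#8342; = M + β·cos(2πt&#8342;/τ) + γ·sin(2πt&#8342;/τ) + ε&#8342;

and fitted by ordinary least squares with all replicates pooled — pooling
preserves residual degrees of freedom for the F test, and a fit to
per-time means is a strict information loss. Amplitude is
A = √(β² + γ²) (an identity the tests check to machine precision) and the
acrophase is

Φ = atan2(γ, β) · τ/(2π) mod τ,

the full-quadrant form under which the reported time is literally the
maximum of the fitted curve; the textbook `tan⁻¹(−γ/β)` expression is the
same quantity up to quadrant folding. The zero-amplitude test compares
against the intercept-only model,
F = ((SS₀ − SS₁)/df₁)/(SS₁/df₂), df₁ = rank − 1, df₂ = n − rank, giving
the usual F(2, n − 3) for a fully identified design.

Degenerate inputs have defined outcomes rather than failures: constant
data give M = value, A = 0, p = 1 and an undefined (NA) acrophase; a
perfect noiseless fit reports p at an underflow floor (< 1e-15); designs
that alias one harmonic — e.g. 12 h sampling of a 24 h period, whose sine
column is numerically zero — drop the aliased column and adjust the test
degrees of freedom, so a cosine-phase rhythm is still detected with the
correct 0 h or 12 h acrophase.

### JTK-style test

For each candidate acrophase on a grid (default spacing: the sampling
interval), Kendall's τ-b is computed between the observations and a
cosine reference evaluated at the observation times; the per-phase
p-value is one-sided (concordance). The exact null distribution of the
Kendall S statistic (inversion-count recursion) is used when n ≤ 9 and
neither ranking has ties; otherwise the tie-corrected normal
approximation applies — with repeated sampling phases the reference
always carries ties, so a 12-point two-cycle design takes the normal
path. The minimum p over phases is Bonferroni-multiplied by the number of
phases, which makes the test conservative under white noise (verified at
2000 simulated null series). This is a deliberately reduced variant of
the JTK_CYCLE family: one fixed period, cosine references, no lag/period
scan — matching how a fixed-24 h screen is typically run.

Times are folded into one period and references rounded at 1e-9 before
ranking, so that replicate phases tie exactly and antiphase references
negate exactly; without this, floating-point cosine evaluation produces
near-ties that break the τ ∈ [−1, 1] bound and the 12 h antiphase
symmetry.

`batch_rhythm` screens a tidy `(analyte, time_h, value)` table with
either or both tests; analytes with too few observations are flagged
`"insufficient data"`, never silently dropped. Per-analyte p-values are
reported unadjusted by default (the common per-gene reporting
convention); Benjamini–Hochberg across analytes is available by flag.

## Assay quantities

`mito_stress_params` implements the standard Mito Stress derivation:
non-mitochondrial respiration = mean of the rotenone/antimycin-A phase;
basal = last baseline measurement minus non-mitochondrial (the last
pre-injection point is the equilibrated one; a mean-of-baseline option
exists because conventions differ); maximal = highest post-FCCP
measurement minus non-mitochondrial; spare capacity = maximal − basal,
also expressed as 100·maximal/basal %. Negative corrected rates are
returned as-is with a quality flag — clamping would hide a failed assay.

`ddct_fold_change` computes per-sample ΔCt against the reference gene,
ΔΔCt against the mean ΔCt of the control condition per target gene, and
fold change 2^(−ΔΔCt). Fold changes are invariant to uniform Ct shifts
and the control condition geometric-means to 1 by construction; both
properties are tested.

## The synthetic-data generators

`generate_mito_image` draws mitochondria as capsules — rectangles with
semicircular caps, optionally with a mild quadratic-Bézier bend (off by
default so the analytic truth is exact). Capsules give a closed-form
ground truth: end-to-end length = centreline + width (the same convention
as the measured `length_um`) and area = centreline·width + π(width/2)².
The forward model is anti-aliased rasterisation → Gaussian PSF blur →
additive Gaussian read noise, the standard image-formation chain for a
single confocal slice.

Default conditions: 0.1 µm/pixel (a plausible sampling for a 63× oil
objective; the calibration is always explicit, never implied), 0.4 µm
tube width, PSF σ 0.1 µm, cell radius 5 µm (a dendritic-cell-scale body
with room for several > 3 µm tubes), a dim cytoplasm at 15 % of the
foreground contrast so cell masks are recoverable by thresholding, and
class lengths drawn uniformly within each class band. Class labels for a
cell are drawn up front from the requested mix and tubes placed
longest-first, so the realised class distribution is exactly multinomial;
placement that cannot satisfy the clearance constraint after bounded
retries raises an error naming the cell rather than silently relaxing the
conditions. When `allow_touching = FALSE`, surfaces are kept at least
`2·psf_sigma` (and two pixels) apart so truth objects remain resolvable.
Cells sit on a jittered grid with clearance scaling with the cell radius,
as in a subconfluent field.

What the generator does *not* emulate: 3-D structure, photobleaching,
organelle texture, intensity heterogeneity along tubes, and densely
entangled networks. Passing the recovery tests therefore demonstrates
correctness of the measurement chain on resolvable 2-D geometry, not
segmentation performance on saturated or highly confluent real images.

`generate_timeseries` and `generate_ocr_trace` embed their truth directly
(cosine parameters; per-phase rates with the four-phase injection order)
and are seeded: identical spec + seed gives bit-identical output, which
the determinism tests assert for all three generators.

`simulate_timecourse` plants a rhythm in the short-length fraction:
short(t) = mesor + A·cos(2π(t − Φ)/24) clipped to [0.05, 0.9], remainder
split 60/40 between mid and long. Defaults follow the targeted study
design — a 48 h course sampled every 12 h (or 4 h), ~20 cells per time
point, acrophase 12 h, amplitude 0.25.

## Numerical choices

* **Perimeter**: length of the 0.5-level contour (marching squares via
  `contourLines`) of the mask after 0.7 px Gaussian smoothing. Raw
  pixel-edge counts overestimate smooth perimeters by up to 4/π and push
  disc circularity to ~0.6; chain-code weight schemes overshoot squares.
  The smoothed sub-pixel contour keeps both discs (~0.97) and squares
  (~0.83) within their analytic tolerance bands.
* **Distance-map regularisation**: the Euclidean distance transform of a
  thin anti-aliased tube is a ridge with sub-pixel bumps; a watershed
  seeded on raw maxima either fragments tubes (low prominence) or misses
  true contacts (high prominence). A 0.7 px Gaussian on the distance map
  — a discretisation-scale constant, like the contour smoothing —
  removes the bumps, after which a 0.1 µm prominence resolves 2·PSF
  contacts without oversplitting.
* **Watershed ties**: 8-connectivity; deterministic basin assignment (the
  EBImage implementation), so reruns are byte-identical.
* **Normalisation rounding**: round-half-up, stated explicitly because
  round-half-even would differ at exactly `.5` codes.
* **Rank-deficient cosinor designs**: harmonic columns with numerically
  zero norm are dropped *before* QR — pivoted QR cannot flag a column
  that is tiny from the start, and keeping it produces meaningless
  ~1e14 coefficients.
* **Seeds**: every stochastic generator takes an explicit integer seed
  and restores the caller's RNG state afterwards.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
analytic shapes (discs, squares, capsules) for morphology; a brute-force
distance transform and saddle-height search for the watershed split; full
permutation enumeration at n = 6 for the exact Kendall null; a dense
(M, A, Φ) grid search that the OLS cosinor must never lose to; and
Monte-Carlo calibration of both rhythm tests (2000 null replicates;
power curves over amplitude). End-to-end, a planted 12 h-acrophase
rhythm in the short fraction of a 5-timepoint, 20-cells-per-timepoint
course must be detected with the acrophase recovered within 2 h, while
flat courses are accepted at the nominal rate (30 seeds). Segmentation
recovery uses 100 single-cell noiseless fixtures; cohort-level
correlation uses a 50-cell field. These sizes were chosen as the smallest
that make the binomial/Monte-Carlo tolerances meaningful.

## Known limitations

* 2-D only; organelles overlapping in z merge.
* The JTK variant scans phase at one fixed period; it is not a
  replacement for full period-scanning implementations when the period is
  unknown.
* The cosinor assumes Gaussian, homoscedastic residuals; fraction-valued
  metrics near 0 or 1 violate this mildly (the planted-rhythm
  calibration covers the regime actually used).
* Circularity of near-resolution-limit objects saturates at the clip.
* The generator's intensity model is additive-Gaussian; Poisson shot
  noise is not simulated.
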