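# mitorhythm

Quantification of mitochondrial fission/fusion state from fluorescence
microscopy, and detection of circadian (fixed-period) rhythms in the
resulting time courses.

Immune-cell function tracks the circadian clock, and one of its cellular
correlates is mitochondrial morphology: networks swing between a
*fragmented* state (many short organelles, fission) and a *fused* state
(few elongated tubules). Quantifying that swing from confocal images and
testing it for 24 h rhythmicity requires a chain of well-defined steps —
segmentation, per-organelle shape measurement, length-class scoring,
and rhythm statistics — each of which is easy to get subtly wrong.
`mitorhythm` implements the whole chain as tested, reusable R functions,
together with the derived assay quantities that accompany such studies
(Mito Stress respiration parameters, ΔΔCt qPCR fold changes) and
ground-truthed synthetic data generators so that every stage is
verifiable without any raw data.

## The core models

**Segmentation** follows the classic macro design for MitoTracker
images: 16-bit normalisation → cell masks (smoothing, auto-threshold,
hole filling, watershed separation) → difference-of-Gaussians band-pass →
auto-threshold → tiny-object removal → marker-controlled watershed
splitting of touching mitochondria, seeded from prominent maxima of the
(regularised) Euclidean distance transform. All geometric parameters are
in micrometres and transfer across magnifications.

**Fission/fusion scoring** uses the standard three length classes:
short < 1 µm, mid 1–3 µm (closed boundaries), long > 3 µm. The per-cell
short fraction is the fission score, the long fraction the fusion score.

**Cosinor regression** fits, for fixed period τ = 24 h,

    Y_i = M + β·cos(2π t_i/τ) + γ·sin(2π t_i/τ) + ε_i

by OLS (replicates pooled), reporting mesor M, amplitude
A = √(β² + γ²), acrophase Φ = atan2(γ, β)·τ/2π mod τ (the time of the
fitted peak), and a zero-amplitude F test of H₀: β = γ = 0.

**JTK-style testing** ranks the data against phase-shifted cosine
references via Kendall's τ-b (exact null for small untied samples,
tie-corrected normal otherwise) and Bonferroni-adjusts the minimum p
over candidate phases — a fixed-period variant of the JTK_CYCLE idea.

## Worked example

```r
library(mitorhythm)

# a synthetic two-cell field with known ground truth
sim    <- generate_mito_image(synthetic_image_spec(
            n_cells = 2, mito_per_cell = 6, image_size = c(256, 256),
            seed = 42))
params <- segmentation_params()
cells  <- segment_cells(sim$image, params)
mito   <- segment_mitochondria(sim$image, params, cells)
recs   <- measure_objects(mito, sim$image, cells)
classify_by_length(recs)$cell_fractions[, c("cell_id", "n_mito",
                                            "fission_score", "fusion_score")]
#>   cell_id n_mito fission_score fusion_score
#> 1       1      6     0.3333333    0.3333333
#> 2       2      6     0.1666667    0.5000000
```

Both cells and all 12 planted mitochondria are recovered; cell 2 drew
more long tubes, hence its higher fusion score (fraction of objects
longer than 3 µm).

```r
# rhythm detection on a noisy simulated series (truth: M=10, A=2, Phi=6 h)
ts <- generate_timeseries(rhythm_sim_spec(mesor = 10, amplitude = 2,
                                          acrophase_h = 6, noise_sd = 1,
                                          seed = 1))
fit_cosinor(ts)
#> Cosinor fit (period 24 h, n = 39)
#>   mesor 10.08  amplitude 2.155  acrophase 6.013 h
#>   zero-amplitude p = 3.55e-11

jtk_test(ts)
#> JTK rhythm test (period 24 h, n = 39, 6 phases)
#>   best phase 8 h  tau 0.613  adjusted p = 2.28e-06
```

The cosinor recovers the planted mesor, amplitude and acrophase to
within the noise, and both tests reject the flat null decisively; the
JTK best phase is quantised to the 4 h sampling grid.

End-to-end, `run_morphology_timecourse()` drives images → morphology →
per-timepoint fission/fusion fractions, median length and MFI → rhythm
tests, from a YAML config (`validate_config()`), a manifest CSV, or
in-memory images from `simulate_timecourse()`. A thin command-line
front end over these functions ships in `inst/cli/mitorhythm.R`.

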