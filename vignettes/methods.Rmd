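---
title: "Per-nucleus quantification of nuclear inclusions: models and methods"
author: "nsbquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-nucleus quantification of nuclear inclusions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsbquant)
options(nsbquant.verbose = FALSE)
```

## The measurement problem

Chronic cellular stress can drive diffusely distributed nuclear RNA-binding
proteins (RBM45, SAFB and related nuclear-stress-body components) into
punctate intranuclear inclusions. Quantifying that transition in
fluorescence micrographs requires three per-field measurements:

1. **How many cells are in the field** — segmented from a DAPI nuclear
   channel.
2. **How many inclusions each nucleus carries** — punctate foci in the
   inclusion channel, restricted to the nuclear mask and gated to the
   published size range of nuclear stress bodies.
3. **How much nuclear signal each channel carries per cell** — measured
   through the nuclear mask and standardized as Z-scores so different
   proteins and staining batches share a scale.

Per-cell inclusion counts are strongly right-skewed with a large zero
fraction, so group comparisons use the Mann-Whitney U test with Bonferroni
correction over all pairs; reference-protein loss with increasing inclusion
load is assessed by ordinary least-squares regression.

## Segmentation model

Nuclei are binarized by a fixed *fractional* threshold: a pixel is nuclear
iff `I >= min + f (max - min)` with `f = 0.25` by default. Expressing the
cutoff relative to the per-image dynamic range makes 8-bit, 16-bit and
float inputs behave identically; the absolute grey value a particular
microscope produces is not meaningful across experiments. Connected
components (8-connectivity by default) become nucleus candidates and are
gated by:

* area 40–300 µm² (granule-cell and HEK293 nuclear cross-sections lie well
  inside this window at 0.102 µm/px),
* circularity `4πA/P² ∈ [0.3, 1.0]`,
* border contact (touching nuclei are censored — their area and intensity
  are truncated by the field edge).

The perimeter `P` is estimated by a four-direction Cauchy–Crofton count of
boundary crossings (rows, columns, both diagonals, with `1/√2` weights on
the diagonal grids). This estimator is unbiased for discs, so a round
nucleus scores ≈ 1 while a 1-px line scores far below the 0.3 gate.
Discretization can push the raw estimate ~0.2% above 1 on perfect discs;
estimates are therefore capped at 1.0 so the gate's upper bound keeps its
meaning. Touching nuclei are *not* split: the generator and the gating are
designed around non-overlapping nuclei, and no watershed is attempted.

## Foci detection: gradient-weighted local thresholding (RATS)

The inclusion channel is masked to nuclear pixels and thresholded with a
re-implementation of Robust Automatic Threshold Selection. The image is
subdivided as a uniform quadtree — `2^d` regions per axis with
`d = ceil(log2(extent / min_leaf_px))`, `min_leaf_px = 16` — and each leaf
computes

    T = sum(g^p I) / sum(g^p),

the gradient-magnitude-weighted mean intensity (central differences,
`p = 2`). Weights are zeroed where `g <= λσ_g` (`λ = 3`,
`σ_g = 0.02` on the native [0, 1] scale), so noise gradients do not vote.
Two provisions keep the estimator honest on masked fluorescence data:

* **Gradient support.** Thresholding a *masked* image creates an
  artificial step at the mask boundary. The nuclear mask is eroded by 2 px
  and only interior pixels contribute weights; otherwise leaf thresholds
  anchor to the mask edge's mid-level and the diffuse nucleoplasm floods
  the mask.
* **Leaf validity floor.** A leaf is only trusted when its total weight
  exceeds `8 (λσ_g)^p` — more edge evidence than a handful of isolated
  noise-level gradients. Invalid leaves inherit the nearest valid
  ancestor's threshold (up to the root); with `σ_g = 0` the floor is
  inactive and a single leaf reduces exactly to the direct formula, which
  the test suite verifies to 1e-9 relative error.

Leaf thresholds are interpolated bilinearly between leaf centers (constant
beyond the outer centers), and the mask is `I > T`. Thresholded particles
are gated to 0.2–3.0 µm² — the area window corresponding to published
nuclear-stress-body diameters of roughly 0.5–2 µm — and assigned to the
nucleus owning the majority of their pixels (ties to the lower id). A
diffuse-only nucleus typically thresholds as one nucleus-sized blob that
the upper gate removes, which is exactly the desired "zero foci" reading.

## Intensity and Z-scores

Per-nucleus channel intensities are means and integrated sums over the
nucleus pixel set (`integrated = mean × pixel count` exactly). The
*integrated* intensity is the primary "total nuclear signal" statistic;
redistribution of a protein into puncta lowers it even when peak
brightness rises. Z-scores are computed per channel over a configurable
pool — by default all nuclei of all conditions in the analysis, since
cross-condition comparisons require a common scale — with sample sd
(`ddof = 1`). Z-scoring is invariant to affine rescaling of the raw
channel, so gain and offset differences between sessions drop out.

## Statistical battery

* `mann_whitney()` computes U from midranks. For `n1 + n2 <= 12` the
  two-sided p value is obtained by full enumeration of all group
  assignments (correct under ties, unlike the classical exact tables);
  larger samples use the normal approximation with tie-corrected variance
  and continuity correction.
* `bonferroni_adjust()` multiplies by the family size — all pairwise
  comparisons actually run (6 for four groups) — and caps at 1.
* `anova_tukey()` wraps `aov()` + `TukeyHSD()`; `linear_regression()` wraps
  `lm()` with a t test on `n − 2` df.
* `two_proportion_test()` uses the pooled-variance z test, falling back to
  Fisher's exact test when any expected 2×2 cell is ≤ 5 (the boundary case
  is deliberately sent to Fisher; the z approximation is weakest exactly
  there).
* `summarize_group()` reports the tissue-style schema: total cells,
  mean/SEM cells per field (SEM over fields), mean/SEM inclusions per cell
  (SEM over cells). Published tables of this kind rarely state the SEM
  denominator; both choices are documented here because they are not
  interchangeable.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` renders 1024×1024 px fields at 0.102 µm/px (≈ 104 µm
square), with:

* 40–52 non-overlapping elliptical nuclei (radius 3.8–5.2 µm, axis ratio
  ≤ 1.15, ≥ 1 µm edge separation, placed largest-first by rejection
  sampling; an overcrowded spec errors rather than overlapping),
* per-nucleus inclusion counts from a zero-inflated Poisson capped at 17 —
  the observed per-cell range in tissue — with presets matching published
  per-cell means: control-like 0.44, AD-like 0.98, ALS-like 1.49,
  FTLD-like 2.38,
* foci as isotropic Gaussian spots (FWHM 0.6–1.2 µm, amplitude 0.55 over a
  0.08 diffuse nucleoplasmic level; peak-to-noise ≈ 27 at the default read
  noise of 0.02), placed far enough apart to remain resolvable,
* a reference ("SAFB-like") nuclear level `max(0, b0 − β k)` with
  `b0 = 0.55`, `β = 0.04` per focus and 0.04 between-nucleus noise —
  emulating the observed decline of SAFB immunoreactivity with inclusion
  load,
* Gaussian optical blur (σ = 1 px), optional Poisson shot noise, Gaussian
  read noise, and quantization to the 16-bit grid so TIFF round-trips are
  pixel-exact and regeneration from a seed is byte-identical.

Studies add subject-level heterogeneity (lognormal 10% jitter of each
subject's nucleus target and focus rate) and 8 fields per subject.

The generator intentionally omits: realistic point-spread functions and
deconvolution artifacts, tissue autofluorescence and lipofuscin, chromatin
texture inside nuclei, touching/overlapping nuclei, and cytoplasmic
inclusion morphology. Passing recovery tests on these images therefore
demonstrates that the *algorithms* are implemented correctly and hit the
95% agreement criterion at a realistic noise level — not that the pipeline
would reach the same accuracy on tissue sections, where shading,
autofluorescence and nuclear crowding dominate the error budget.

## Numerical and design choices

* Z-stacks are max-projected before segmentation (projection preserves
  puncta; the analysis masks are planar). Mean projection is available via
  the config.
* Intensities stay on their native scale until Z-scoring; nothing is
  rescaled.
* Component labels are assigned in column-major first-occurrence order;
  particle-to-nucleus ties break to the lower nucleus id; all output row
  orders are fixed and doubles are written at 6 significant digits, so
  identical inputs give byte-identical outputs.
* Degenerate inputs are first-class: constant images produce empty masks
  with a warning (segmentation) or silently zero foci (a structureless
  inclusion channel); constant intensity pools refuse to Z-score; a
  zero-cell field reports totals of zero with per-cell statistics marked
  `NA`.
* Background subtraction (grayscale opening with a disc, radius 50 px) is
  off by default — synthetic fields carry no shading — and is available
  for real micrographs. Flat-field shading correction requires reference
  images and is out of scope.

## Problem sizes used by the test suite

The suite regenerates everything from seeds at run time: 100 small
noise-free fields for exact cell-count recovery, 200 nuclei across 40
small fields for per-nucleus focus recovery (≥ 95% exact agreement), 12
fields per condition for the chronic-stress Z-score sign check, 30 fields
for the β-recovery closed loop, 700 draws per group for the ordered-burden
power check, and 20 full-size default-noise fields for the validation
criterion. These sizes keep the full suite in the minutes range while
leaving each check statistically comfortable; all effect sizes are the
generator defaults above, not quantities tuned per test.

## Known limitations

* No watershed: touching nuclei in real tissue will merge and be dropped
  or miscounted; the cell-count agreement criterion on real data depends
  on nuclear density.
* RATS leaf inheritance means large edge-free regions borrow thresholds
  from ancestors covering unrelated image content; only behavior near
  detected edges is locally adaptive.
* The Fisher fallback and the tie-corrected normal approximation are
  two-sided only; one-sided hypotheses are not exposed.
* Cytoplasmic inclusions are accepted only as an externally supplied count
  column (they were counted manually in the motivating protocol); nothing
  in the pipeline detects them.
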