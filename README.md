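# nsbquant

Per-nucleus quantification of nuclear stress body-like protein inclusions
in multi-channel fluorescence micrographs.

Chronic cellular stress redistributes diffusely nuclear RNA-binding
proteins (RBM45, SAFB and other nuclear-stress-body components) into
punctate intranuclear inclusions, and in neurodegenerative disease tissue
the inclusion burden per cell separates patient groups. `nsbquant`
implements the image-analysis pipeline behind that kind of measurement:

* **Nuclei** are segmented from a DAPI channel by fixed-fraction intensity
  thresholding (`I >= min + f (max − min)`, default `f = 0.25`), labeled as
  connected components, and gated by area (40–300 µm²), circularity
  (`4πA/P²` in [0.3, 1], Crofton perimeter) and border contact.
* **Foci** are detected inside the nuclear mask with a from-scratch
  re-implementation of Robust Automatic Threshold Selection (RATS):
  quadtree decomposition with per-leaf thresholds
  `T = Σ g^p I / Σ g^p` (gradient-magnitude weights, `p = 2`, noise cutoff
  `λσ_g`), bilinear interpolation between leaves, and a particle size gate
  of 0.2–3.0 µm² matching published nuclear-stress-body dimensions.
* **Intensities** are measured per nucleus through the mask (mean and
  integrated) and standardized as Z-scores per channel across conditions.
* **Statistics**: all pairwise Mann-Whitney U tests on per-cell inclusion
  counts (exact by enumeration for `n1+n2 ≤ 12`, ties handled by midranks;
  tie-corrected normal otherwise) with Bonferroni correction; one-way
  ANOVA + Tukey HSD; OLS regression of reference-protein immunoreactivity
  on inclusion count; pooled-z / Fisher two-proportion tests; tissue-style
  group summaries (cells/field, inclusions/cell, with SEMs).
* **Synthetic data**: a generator renders calibrated multi-channel fields
  (0.102 µm/px) of non-overlapping elliptical nuclei with zero-inflated
  Poisson focus counts (capped at 17) and a reference channel whose level
  decreases by β per focus, with full per-nucleus ground truth — so every
  stage is testable without microscope data.

See `vignettes/methods.Rmd` for the full model description, parameter
rationale, and limitations.

## Worked example

Simulate a two-group study (control-like vs FTLD-like inclusion burden),
quantify it, and test the group difference:

```r
library(nsbquant)

specs <- list(
  control = group_preset("control", image_size_px = 384, n_nuclei = 5,
                         n_nuclei_cv = 0),
  FTLD    = group_preset("FTLD", image_size_px = 384, n_nuclei = 5,
                         n_nuclei_cv = 0))
dir <- tempfile()
generate_study(specs, c(control = 2, FTLD = 2), seed = 11,
               fields_per_subject = 4, out_dir = dir)
res <- run_pipeline(pipeline_config(), dir)

res$group_summaries[, c("group_label", "total_cells",
                        "mean_nuclear_inclusions_per_cell")]
#>   group_label total_cells mean_nuclear_inclusions_per_cell
#> 1     control          40                              0.4
#> 2        FTLD          40                              2.5

res$stats$pairwise[, c("comparison", "statistic", "p_adjusted")]
#>        comparison statistic p_adjusted
#> 1 control vs FTLD       283   1.12e-07

res$stats$regression
#>    slope intercept r_squared  p_slope  n
#> 1 -0.275     0.399     0.257 1.63e-06 80
```

The control-like group averages 0.4 inclusions per cell against 2.5 in the
FTLD-like group; the Mann-Whitney comparison separates them decisively,
and the regression of the reference channel's per-nucleus Z-score on
inclusion count recovers the generated negative coupling (less reference
protein signal in nuclei with more inclusions).

A thin CLI wraps the same functions
(`Rscript inst/cli/nsbquant-cli.R <simulate|quantify|stats|validate> ...`).

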