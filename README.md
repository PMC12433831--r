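# xirplesion

Semi-automatic quantification of xirp 1/2-positive sarcomeric lesions in
immunofluorescence images of skeletal muscle cross-sections.

In myofibrillar myopathies (for example desminopathies caused by mutant
desmin), focal myofibrillar damage shows up in stained soleus muscle
cross-sections as bright punctate-to-patchy spots wherever the xin
actin-binding repeat-containing proteins 1 and 2 (xirp 1/2) have enriched at
damaged sarcomeres. Counting and measuring these lesions by eye does not
scale and is hard to standardise. This package implements a trainable,
deterministic workflow for that measurement, aimed at muscle researchers who
quantify sarcomeric damage across genotypes and exercise interventions:

1. **Pixel classification** — per-pixel multiscale features (Gaussian,
   gradient magnitude, Laplacian of Gaussian, structure-tensor eigenvalues
   at σ ∈ {0.5, 1, 2, 4, 8} px) feed a small multilayer perceptron trained
   from sparse two-class polygon annotations ("lesion" vs "ignore"). The
   classifier is trained iteratively; a checkpoint is kept after each
   training image and the deployed iteration is chosen by pixel F1 on
   validation images — the best compromise between detection sensitivity
   and false positives.
2. **Lesion morphometry** — within a manually drawn region of interest
   (ROI, with artefact exclusions), classified pixels are grouped into
   8-connected components, calibrated by the pixel size (0.13 μm/px at full
   resolution), filtered at a minimum detection size of ≥ 0.01 μm², and
   flagged as macrolesions when the area strictly exceeds 10 μm². Seven
   readout parameters summarise each section: ROI area (μm²), lesion count,
   mean lesion size (μm²), macrolesion count, lesion density (/mm²),
   macrolesion fraction (%), macrolesion density (/mm²).
3. **Group statistics** — a decision tree mirroring the study design:
   Anderson–Darling normality per group; Bartlett and Brown–Forsythe
   variance tests; then either ordinary one-way ANOVA + Tukey, Welch and
   Brown–Forsythe ANOVA + Dunnett T3, or Kruskal–Wallis +
   Bonferroni–Holm-corrected Mann–Whitney. Two-sample contrasts route to
   Student/Welch t or Mann–Whitney the same way. Interobserver concordance
   (Pearson r, identity fit, paired mean difference) quantifies analyst
   agreement.
4. **Synthetic ground truth** — a generator for soleus-like sections
   (fibre-mosaic background, Poisson-placed elliptical lesions with a
   micro/macro lognormal area mixture, PSF blur, read noise) and for whole
   six-group cohorts (WT/HET/HOM × no run/run), so every stage is testable
   end to end without microscope data.

## Worked example

```r
library(xirplesion)

## simulate an annotated training set and a held-out section
sims <- lapply(11:14, function(s) generateTissueImage(TissueSpec(
  fieldSizePx = c(384L, 384L), lesionDensityPerMm2 = 30000,
  roiCoverage = c(0.45, 0.65), macroWeight = 0.05, seed = s)))
stacks <- lapply(sims, function(s) computeFeatureStack(s$image))
labels <- lapply(seq_along(sims), function(i) {
  ann <- annotationsFromTruth(sims[[i]]$truth, sims[[i]]$roi,
                              nPerClass = 100L, seed = 110L + i)
  suppressWarnings(rasterizeAnnotations(ann, sims[[i]]$image))
})
clf <- trainClassifier(stacks, labels, seed = 7L)

## pick the deployed iteration on validation images with known truth
vals <- lapply(21:22, function(s) generateTissueImage(TissueSpec(
  fieldSizePx = c(384L, 384L), lesionDensityPerMm2 = 30000,
  roiCoverage = c(0.45, 0.65), macroWeight = 0.05, seed = s)))
clf <- selectClassifier(clf,
  lapply(vals, function(s) computeFeatureStack(s$image)),
  lapply(vals, function(s) s$truth@mask))
clf
#> PixelClassifier: 4 checkpoints, selected #1; 25 features, hidden = 32, seed = 7
#>   validation F1: 0.977, 0.974, 0.960, 0.971

## quantify a held-out section inside its ROI
sim <- generateTissueImage(TissueSpec(
  fieldSizePx = c(384L, 384L), lesionDensityPerMm2 = 30000,
  roiCoverage = c(0.45, 0.65), macroWeight = 0.05, seed = 31L))
res <- quantifyImage(sim$image, clf, sim$roi)
res$readout[, c("lesion_count", "lesion_density_per_mm2",
                "mean_lesion_size_um2", "macro_count")]
```

On this section the pipeline printed

```
  lesion_count lesion_density_per_mm2 mean_lesion_size_um2 macro_count
1           39               32181.35               0.8307           1
```

i.e. 39 detected lesions in the ~0.00121 mm² ROI (a density of ~32,181
lesions/mm², this is a deliberately lesion-rich synthetic regime), a mean
lesion size of 0.83 μm², and 1 macrolesion (> 10 μm²). Compare
`groundTruthReadout(sim$truth)` to see the generator's ground truth for the
same section.

A cohort-level analysis takes a readout table with `genotype` and
`condition` columns:

```r
cohort <- generateCohort(baseSeed = 1L)$cohort   # six groups, n = 8/9/10/9/9/12
report <- runStudyAnalysis(cohort)
subset(report$table, metric == "lesion_density_per_mm2")[, c("comparison", "test", "p_raw", "stars")]
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/xirplesion.R` (`train`, `select`, `quantify`, `stats`,
`concordance`, `simulate`, `run` subcommands).

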