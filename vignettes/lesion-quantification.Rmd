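---
title: "Quantifying xirp-positive sarcomeric lesions: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying xirp-positive sarcomeric lesions: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the design choices made where the design was genuinely open.
It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The measurement problem

In desminopathy and other myofibrillar myopathies, focal sarcomeric damage
(Z-disc streaming and dissolution) can be visualised in muscle
cross-sections by immunostaining for xirp 1/2, proteins that rapidly enrich
at damaged sarcomeres. Each lesion appears as a bright spot or patch over a
textured autofluorescent background. The quantities of interest per muscle
section are the seven readout parameters: ROI area (µm²), lesion count,
mean lesion size (µm²), macrolesion count, lesion density (/mm²),
macrolesion fraction (%), and macrolesion density (/mm²), where a
macrolesion is a lesion whose cross-sectional area strictly exceeds
10 µm². (In longitudinal sections micro- and macrolesions are instead
described by sarcomere span; this package implements only the
cross-sectional area criterion and notes the dual definition here.)

The workflow is deliberately semi-automatic: the investigator contributes
only the region of interest (the soleus outline, plus artefact exclusions);
detection and measurement are then deterministic, which is what makes the
interobserver concordance of the method a property of the ROI placement
alone.

## Pixel classification

### Features

Every pixel receives a 25-dimensional feature vector: five base features —
Gaussian-smoothed intensity, Gaussian gradient magnitude, Laplacian of
Gaussian, and the maximum and minimum eigenvalues of the Gaussian-smoothed
structure tensor — at five scales σ ∈ {0.5, 1, 2, 4, 8} px. This is a
standard texture/blobness basis for bright-blob detection: the smoothed
intensity separates lesion from background level, the Laplacian responds to
blob cores, the gradient and structure-tensor eigenvalues distinguish
edges, ridges and isotropic patches. The composition of the feature basis
is a documented stand-in for a "default multiscale features" setting whose
exact contents are not recoverable; it claims adequacy for the task, not
bit-compatibility with any particular tool. The basis and scales are
recorded in the feature-stack and classifier manifests, and classification
refuses stacks whose manifest differs from the training manifest.

Numerics: kernels are sampled Gaussians with moment corrections (smoothing
kernels sum to 1; first-derivative kernels have zero sum and unit ramp
response; second-derivative kernels additionally have unit response to
x²/2), with radius ⌈3σ⌉ and symmetric (reflect) border padding. Filtering
is separable correlation; the structure tensor is integrated at the same σ
as its derivatives. These choices make a constant image yield exactly
constant/zero features and make feature extraction translation-equivariant
away from borders — both asserted in the test suite, together with
agreement of the impulse response against a direct-convolution oracle.

### Classifier

The classifier is a multilayer perceptron with one hidden layer of 32
logistic units trained with cross-entropy loss for up to 200 epochs (via
`nnet`), on features standardized to zero mean/unit variance using
training-pixel statistics stored in the classifier. The architecture is a
desk-scale choice: small enough to train in seconds on sparse annotations,
expressive enough for a 25-dimensional, nearly separable problem.

Supervision is sparse: "lesion" polygons are positives, "ignore" polygons
(background, noise signal, connective tissue) are negatives, and unlabeled
pixels are excluded. Object counts are balanced by guideline (≥ 100 objects
per class, equal numbers — violations warn but do not fail); *pixel*-level
imbalance is handled by inverse-frequency sample weights, since balancing
object counts does not balance pixel counts. When one class exceeds 10,000
labeled pixels, a seeded subsample of that size is used to bound training
time.

Training is iterative: checkpoint *k* is fitted on the pooled labeled
pixels of training images 1..*k*, and every checkpoint is retained. The
deployed iteration is the one maximising pixel-level F1 over pooled
validation pixels (ties to the earliest checkpoint). F1 was chosen to
operationalize "the best compromise between detection sensitivity and false
positives" because it penalises exactly those two error types; accuracy
would be dominated by the overwhelming background class.

All randomness flows from an explicit seed; identical inputs and seed give
bit-identical classifier decisions, which the tests assert.

## Lesion morphometry

Classified pixels are intersected with the ROI mask *before* component
analysis, so a lesion straddling the ROI border contributes only its inside
pixels. Components are extracted at 8-connectivity by default. The paper
trail for connectivity is silent, so the package makes the standard
bright-blob choice (8-neighbour, merging diagonal chains that visually read
as one lesion) and keeps a 4-connectivity flood-fill oracle in the tests to
document the sensitivity of counts to this decision.

Areas are pixel counts times the squared pixel size, with no sub-pixel
boundary smoothing — matching the semantics of a pixel classifier's output.
The minimum detection size (≥ 0.01 µm²) is inclusive; the macrolesion
threshold (> 10 µm²) is strict. At the reference calibration of 0.13 µm/px
one pixel is already 0.0169 µm², so the minimum-size filter is inert at
full resolution (and therefore it is immaterial whether mean lesion size is
averaged before or after it; the package averages after). A zero-lesion
section reports missing (not zero) mean size and macrolesion fraction, so
cohort means are not deflated by empty sections.

Polygon semantics everywhere (annotations, ROI): 0-based pixel-center
coordinates, even-odd fill, a pixel belongs to a polygon iff its center is
inside. ROI area is the included pixel count times the squared pixel size.

## Group statistics

The decision tree reproduces the study's routing:

* per-group Anderson–Darling normality (case 3, estimated mean and
  variance — the standard approximation; which variant the original
  statistics software used is unknowable, so the standard one is used);
* equality of standard deviations by *both* Bartlett and Brown–Forsythe
  (Levene with median centering). The sources name both tests without a
  combination rule; the package requires both to be non-significant for the
  equal-variance branch, so either one firing routes to the
  unequal-variance branch;
* branches: (i) all normal + similar SD → ordinary one-way ANOVA with
  Tukey HSD; (ii) all normal + dissimilar SD → Welch ANOVA (reported as the
  omnibus p) together with the Brown–Forsythe adjusted-F ANOVA, followed by
  Dunnett T3 over all pairs; (iii) any group non-normal → Kruskal–Wallis
  with Bonferroni–Holm-corrected pairwise Mann–Whitney tests.

Two-sample contrasts route analogously: both samples normal → Student or
Welch t depending on a two-sided F test of variances (the simplest
variance-equality test consistent with the t family; the sources do not
name one); otherwise Mann–Whitney, exact when the smaller sample has ≤ 8
untied observations, normal approximation with tie correction otherwise.
Dunnett T3 uses pairwise Welch statistics with Welch–Satterthwaite degrees
of freedom and studentized-maximum-modulus adjusted p-values
(1 − (2F(|t|) − 1)^k over the k comparisons). The Anderson–Darling
approximation requires n ≥ 8; smaller samples cannot be assessed and are
treated as consistent with normality, which routes them parametrically.

The six-group study analysis runs, per metric (lesion density, mean lesion
size, macrolesion density), the three-genotype omnibus within each exercise
condition plus the within-genotype no-run vs run contrasts. Those contrasts
are reported unadjusted: they are the pre-planned "two specific datasets of
interest" comparisons, and the package's default pair selection is exactly
the within-genotype condition contrasts. Summaries are mean ± SEM;
significance stars at 0.05/0.01/0.001/0.0001.

All parametric p-values are pinned to closed-form oracles at 1e-10 in the
tests, the exact Mann–Whitney to a full enumeration, Tukey to `TukeyHSD`,
and the whole tree's type-I error under a normal equal-variance null is
measured over 2000 replicates (asserted within 0.05 ± 0.02).

## The synthetic tissue and cohort generator

The generator exists so that the classifier, the morphometry and the
statistics can be validated end to end with known ground truth. One
simulated section consists of:

* a soleus-like ROI: a smooth radial blob (low-order cosine modulation of a
  circle) covering 30–70% of the field, with optional small artefact
  exclusion disks;
* background: a Voronoi fibre mosaic (≈ 45 µm fibre calibre) with per-fibre
  level jitter (±25%) and a gentle smooth texture (10%), emulating
  residual Z-disc staining and fibre-to-fibre autofluorescence variation;
* lesions: a homogeneous spatial Poisson process inside the ROI; areas from
  a two-component lognormal mixture — a micro mode (log-sd 0.8) and a macro
  mode (mean 18 µm², log-sd 0.5) — with elliptical shapes (axis ratio
  uniform on 1–3, random orientation); overlapping placements merge, and
  the ledger is recomputed from the merged, ROI-clipped mask so ground
  truth stays exactly self-consistent;
* optics and noise: Gaussian PSF blur (σ = 1 px), Gaussian read noise
  (SD 4 at background level 20 and lesion peak 100, i.e. lesion:background
  ratio 5), optional Poisson shot noise.

For a given group regime (target mean lesion size and macrolesion
fraction), `solveSizeMixture()` solves the micro-mode mean and the
macro-mode weight so the mixture reproduces both moments. The six-group
cohort generator is parameterized at the study's printed group means —
lesion densities 1874/3473/16924 (no run) and 5232/5468/18149 (run) per
mm² for WT/HET/HOM, mean sizes ≈ 0.7/0.9/1.4 (no run) and 0.8/1.0/1.4
(run) µm², macrolesion densities 16/39/341 and 49/62/337 per mm² — with
the study's group sizes n = 8/9/10/9/9/12. Between-animal variability is a
lognormal multiplier on density with CV 0.3; the true animal-to-animal
variance is not printed anywhere, so this is a stand-in chosen to give
scatter of plausible magnitude, exposed as a parameter (`animalCv`) and not
a claim about the real cohort. Per-animal ROI areas are drawn uniformly
from 0.4–0.8 mm², a realistic soleus cross-section range; at these areas
Poisson counting noise is negligible next to the CV-0.3 animal effect.

Cohorts are generated ledger-only by default (counts and areas, no pixel
rendering), which is what the statistics consume; `render = TRUE`
additionally rasterises full images for pipeline-level validation.

What the generator does **not** emulate: staining chemistry and batch
effects, physically accurate optics/photon statistics, longitudinal-section
geometry, per-fiber lesion assignment, and spatial clustering of lesions
(placement is homogeneous Poisson). Passing tests on this synthetic
material therefore demonstrate the correctness and stability of the
*measurement machinery* under controlled conditions — not classifier
performance on real stained tissue, which depends on staining and
acquisition standardisation outside the software's control.

### Fixture regimes and problem sizes

The validation fixtures are sized for a desk-scale run: training/validation
sections of 384×384 px at 0.13 µm/px (≈ 50×50 µm) with a dense lesion
regime (30,000/mm², macro weight 0.05) so that each annotated section
contains on the order of 20–50 lesions of both classes — the macro-rich
regime matters, because a classifier trained without macrolesion examples
systematically misses macrolesion interiors. Density-recovery runs use
640×640 px fields at the 2000/mm² regime over 10 seeds; the cohort-pattern
check uses 50 ledger-only cohorts. These sizes are the package's choice of
validation scale; all of them are parameters, not limits.

## Known limitations and honest failure modes

* **Pattern-recovery rate.** Under the defaults above (printed group means,
  CV 0.3, two-tailed unadjusted contrasts), the joint five-component
  significance pattern of the six-group study — HET and HOM above WT at
  baseline, an exercise effect in WT and HET, no exercise effect in HOM —
  is recovered in roughly 70–75% of simulated cohorts, not more. The
  binding components are the HET exercise contrast (mean ratio 1.57 at
  n = 9 vs 9, power ≈ 0.85) and the HOM "no effect" guard (the HOM means
  do differ by 7%, so ~7% of cohorts flag it). A higher recovery rate would
  require assuming smaller between-animal variability than the CV-0.3
  stand-in or one-sided tests; the package does neither, and reports the
  measured rate as-is.
* The classifier quantifies a blurred, noisy rendering against a pre-blur
  ground-truth footprint; at SNR 5 this costs a percent-level halo/miss
  trade-off at lesion boundaries (held-out pixel F1 ≈ 0.93–0.97 on the
  fixture regimes, recomputed by the acceptance script each run).
* TIFF resolution metadata is honoured when the reader exposes it, but the
  bundled TIFF writer cannot store resolution tags, so synthetic images
  carry their pixel size through configuration; the metadata-vs-config
  precedence (configuration wins, with a warning) is unit-tested at the
  attribute level.
* The statistics engine implements the study's decision tree, not a
  recommendation: with six groups and three metrics, family-wise control
  exists within each omnibus family only, and the planned contrasts are
  deliberately unadjusted.
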