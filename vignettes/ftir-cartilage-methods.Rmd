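---
title: "Methods: chemometric analysis of FTIR images of osteoarthritic cartilage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric analysis of FTIR images of osteoarthritic cartilage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices behind
`cartFTIR`. The package analyses hyperspectral Fourier-transform infrared
(FTIR) absorbance images of articular cartilage sections and relates their
chemistry to the histopathological OARSI grade of osteoarthritis (OA). All
of its stages run end-to-end on synthetic layered-cartilage phantoms, so
every claim below is backed by a test that executes in minutes on one CPU.

## The measurement and its preprocessing

A sample is a pixel grid (21.6 um pixels) of absorbance spectra on a common
wavenumber axis. The pipeline works in the fingerprint region, 950-1800
cm^-1 at a 4 cm^-1 step (213 grid points); the axis is stored ascending and
band positions such as 1064 or 1338 cm^-1 need not fall on the grid.

Preprocessing runs in a fixed order:

1. **Quality filter.** A pixel is rejected when its amide I maximum is
   below 0.1 AU (too little material), above 2.0 AU (saturation), or when
   its signal-to-noise ratio -- amide I peak height over the standard
   deviation of the linearly detrended 1760-1800 cm^-1 window -- falls
   below 10. The thresholds are configurable
   (`quality_thresholds()`); these defaults were chosen once for the
   phantom signal levels, where tissue pixels sit near 1 AU. A noise floor
   of 1e-8 AU keeps noise-free synthetic spectra finite in the ratio.
   Rejected pixels render black in all images.
2. **Scatter correction.** Extended multiplicative signal correction
   (EMSC): each spectrum `s` is fitted by least squares as
   `s = b * reference + polynomial(wavenumber)` with the cohort mean of
   quality-passing spectra as reference and a polynomial baseline of
   order 2; the corrected spectrum is `(s - baseline)/b`. Pixels with
   `b <= 1e-6` are flagged degenerate and dropped. This is deliberately a
   non-iterative correction: the pipeline's downstream contracts depend on
   the removal of multiplicative and smooth additive artifacts, which EMSC
   removes exactly (it is exact on `b*ref + linear` by construction and
   scale-equivariant). A full iterative resonant-Mie correction is out of
   scope and is named as such wherever the correction is logged.
3. **Branches.** Vector normalization (unit Euclidean norm) feeds
   clustering, so that clusters reflect spectral shape rather than section
   thickness. Savitzky-Golay second derivatives (9 smoothing points,
   polynomial order 3 -- the window is the emulated protocol's choice, the
   order our default) feed the univariate second-derivative parameters and
   the regression models. Edge points use the one-sided polynomial fits of
   the same filter, so derivative spectra keep the full axis length. A
   linear two-point baseline is applied only inside the collagen-integrity
   parameter, to its two regions individually.

Absorbance bands become negative minima in a second derivative; the
package reports the *negated* second derivative at a peak so that larger
values always mean more absorbing material.

## Segmentation and depth

Bone is detected chemically: PCA on the mean-centred carbohydrate-region
(985-1140 cm^-1) spectra of **all samples jointly**; the first principal
component contrasts bone mineral phosphate with cartilage carbohydrate.
The PC1 scores are thresholded automatically by Otsu's criterion (the
threshold is centred when the criterion is flat across an empty gap), and
the side holding the bottom image margin is labelled bone. An automatic
threshold replaces visual inspection for reproducibility; a manual
threshold can be supplied. A warning is raised when PC1 explains less than
5% of variance, and sections known to lack a bone margin can skip the
stage (`expect_bone = FALSE`).

Within the tissue mask, depth is normalized per image column: the first
tissue pixel from the top is the articular surface (d = 0), the last
before bone the tidemark (d = 100). Columns with fewer than three tissue
pixels are excluded and reported. Zones follow the percent-thickness
convention: surface 0-15, deep 65-100, middle 15-65 (the middle zone is
defined by complement; the sources the bounds come from never bound it
explicitly). Depth profiles average a per-pixel parameter in 20
equal-width depth bins by default.

## Univariate parameters

Per pixel: integrated amide I area (1585-1720 cm^-1, collagen content),
integrated carbohydrate area (985-1140 cm^-1, proteoglycan content), their
ratio (invariant to overall scale, hence to section thickness), the
collagen integrity ratio -- two-point-baselined CH2 side-chain area
(1300-1360 cm^-1) over two-point-baselined amide II area (1485-1585
cm^-1), which decreases as the collagen network denatures -- and the
negated second-derivative peaks at 1202 cm^-1 (collagen) and 1064 cm^-1
(PG), located as the minimum within +-8 cm^-1 of the nominal position.
Integration is trapezoidal on the native grid; regions are closed
intervals, so contiguous regions share a boundary point when it lies on
the grid. Ratios with near-zero denominators are flagged undefined and
excluded from summaries rather than imputed.

## Clustering

K-means (K = 5, Euclidean distance, at most 20 Lloyd iterations, single
seeded run) on the vector-normalized spectra of all samples combined,
restricted to the carbohydrate region by default -- the region that best
exposes the superficial/middle/deep layering. Centroids initialize from K
distinct spectra drawn uniformly; an emptied cluster is re-seeded from the
farthest point. Cluster means are reported over the full fingerprint axis
together with their second derivatives; label images use a fixed palette
with black for removed pixels.

## Grade regression

One observation per sample: the mean over all pixels of a zone (surface or
deep) of either the vector-normalized spectra or their second derivatives.
Per-sample leave-one-out cross-validation (LOOCV) with one observation per
sample means pixel pseudo-replication can never leak across folds.

* **PLSR** is NIPALS: sequential latent variables (LVs) with mutually
  orthogonal scores; with as many LVs as the predictor rank it reproduces
  least squares, which the tests verify against `lm.fit`.
* **LV count** is chosen per LOOCV fold by nested 5-fold cross-validation
  on the training fold (deterministic response-stratified folds,
  minimizing RMSECV), capped at 20. The search starts at 2 LVs whenever
  possible: a single-LV model on strongly collinear spectra collapses onto
  one score direction and its out-of-fold predictions are then dominated
  by leverage and fold-mean artifacts rather than signal; the emulated
  workflow's reported models likewise use 2-6 LVs.
* **CARS** selects wavenumbers: over 50 iterations, a PLSR model is fitted
  on a random 80% Monte-Carlo subset of samples, variables are weighted by
  absolute regression coefficient, and the retained count follows the
  exponentially decreasing enforced schedule `r_i = round(p a e^{-k i})`
  with `r_1 = p` and `r_last = 2`. The adaptive reweighted step draws
  exactly `r_i` survivors without replacement with probability
  proportional to the weights, so subset sizes follow the schedule while
  elimination pressure stays coefficient-driven (a with-replacement draw
  collapses the subset far below the schedule and loses informative
  variables to pure chance). Each iteration's subset is scored by 5-fold
  RMSECV; because a single chain is stochastic, five independent chains
  run by default and the minimum-RMSECV subset wins, ties going to fewer
  variables, then the earlier iteration, then the earlier chain.
* **Metrics**: Spearman rank correlation (two-sided p) between reference
  and LOOCV-predicted grades, and the mean percent error
  `E = (100/n) * sum |pred - ref| / ref`; grades in scope are >= 1, so the
  denominator is safe. The error formula is documented here because the
  quantity is conventionally named but rarely defined.

Note a structural property the tests make explicit: variable selection
runs once on the full cohort *before* LOOCV (as is conventional in
chemometric practice). Re-selecting variables on permuted responses and
then cross-validating yields strongly optimistic correlations; the
package's null-safety test therefore permutes grades and re-evaluates the
LOOCV on a fixed variable set, which is the leakage the LOOCV itself can
and must avoid.

## Cohort statistics

All statistics operate on per-sample zonal summaries, never on pixels.
Spearman correlation is used for every association with grade. For group
comparisons the grades pool into early (1.0-2.5), intermediate (3.0-3.5)
and severe (4.0-4.5) OA; the omnibus test is Kruskal-Wallis with tie
correction and the pairwise comparisons are Dunn tests with Bonferroni
adjustment -- the default pairwise convention of mainstream statistics
software. Significance is annotated at 0.05 and 0.01. All-identical values
are reported as "no difference" rather than an error.

## The synthetic cohort

No imaging data are deposited for the study conditions this package
emulates, so the generator (`generate_phantom()`) is a first-class,
tested module. Its defaults are the study conditions: 28 samples, grades
10/9/9 across the three OA groups, all grades in [1.0, 4.5] (arthroplasty
tissue is never completely healthy; cartilage is denuded above grade 4.5).
Each phantom is a 60 x 20 pixel section: cartilage rows over a 6-row
subchondral bone margin, per-sample thickness jitter, and per-pixel
spectra formed as nonnegative mixtures of three Gaussian-band components
(collagen with amide I/II, amide III, 1202 and a separately scaled 1338
cm^-1 integrity band; proteoglycan concentrated >= 70% in the carbohydrate
region; a bone mineral proxy with a sharp 1030 cm^-1 phosphate band),
plus a per-pixel linear baseline, a multiplicative scatter scale
U(0.7, 1.3), Gaussian detector noise (0.005 AU), and 2% dead pixels that
the quality filter must catch. Bands are Gaussian rather than mixed
Gauss/Lorentz because every downstream contract depends only on band
areas and positions, and Gaussian areas have a closed form usable as a
test oracle. Optional sharp water-vapor lines (1500-1700 cm^-1) exist and
default off.

Degradation with grade g: proteoglycan is multiplied by
`exp(-alpha g (1 - d/100))` with `alpha = log(2)/3.5`, so grade 4.5 halves
surface PG relative to grade 1.0 while the deep tissue is spared; the
collagen integrity factor falls linearly from 1.0 (grade 1) to 0.5
(grade 4.5) at the surface, with only 15% of that decline remaining at the
tidemark; from grade 4.0 the top `0.3 (g - 3.5)` fraction of cartilage
rows is eroded to background (surface wear). Between-sample biology is
modelled explicitly: log-normal jitter on the degradation parameters (8%),
on the compositional depth profiles (15%: collagen level, PG offset and
slope), and a grade-independent additive offset on the integrity factor
(sd 0.05). The last two matter beyond realism: without them the cohort's
zone-mean spectra collapse onto an effectively one-dimensional manifold,
which no real cohort exhibits, and because the grade-driven integrity
signal is surface-weighted while the additive biological noise is
depth-uniform, the deep zone genuinely carries less grade information --
the asymmetry the surface-vs-deep model comparison is about.

What the phantoms do **not** model: chondrocyte-scale morphology, curved
articular surfaces (depth is per image column, sections oriented
surface-up), physical Mie scattering (the baselines are polynomial
surrogates), mixed Gauss/Lorentz band shapes, and any absolute
concentration scale -- all concentration units are generator conventions.
Passing tests therefore demonstrate that the pipeline recovers what it is
designed to recover under controlled artifacts; they do not certify
performance on real tissue.

## Numerical and interface choices

* Cube files use a sectioned plain-text container with 17-significant-digit
  serialization -- a write/read round trip is bit-exact -- plus a CSV
  per-pixel export; vendor formats are out of scope.
* Degenerate inputs fail loudly and specifically: zero-norm spectra name
  the pixel, missing container sections name the field, empty zones name
  the sample, zero-variance responses abort only the grade models while
  the rest of the pipeline completes.
* Every random stage (phantom generation, K-means initialization, CARS)
  takes an explicit integer seed; `run_pipeline()` derives stage seeds
  from one master seed, and a rerun with the same configuration is
  bit-identical in all CSV artifacts.
* Test and acceptance problem sizes are chosen for minutes-scale runs on
  one CPU: the default cohort is 28 samples of 60 x 20 pixels (33,600
  spectra); the planted-signal benchmark for CARS uses 8 informative among
  200 columns at n = 60 over 25 seeds; the permutation null uses 100
  grade shuffles.

## Known limitations

The EMSC reference is the cohort mean, so corrected spectra are defined
relative to the cohort being analysed; models fitted on one cohort do not
transfer to another without refitting. CARS selection happens outside the
LOOCV (see above), so reported LOOCV metrics share the selection optimism
of the standard workflow; the null-safety test quantifies the LOOCV's own
behaviour, not that optimism. Depth normalization assumes surface-up
orientation and roughly vertical columns; strongly curved or torn sections
would need a parameterized surface, which is out of scope.
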