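# cartFTIR

Chemometric analysis of Fourier-transform infrared (FTIR) microspectroscopic
images of articular cartilage, for spectroscopists and cartilage researchers
who want to relate matrix chemistry to the histopathological severity of
osteoarthritis (OA).

An FTIR image of a cartilage section holds one absorbance spectrum per
21.6 µm pixel over the fingerprint region (950–1800 cm⁻¹, 4 cm⁻¹ step).
Collagen dominates the amide I (1585–1720 cm⁻¹) and amide II (1485–1585
cm⁻¹) bands, proteoglycans (PG) the carbohydrate region (985–1140 cm⁻¹).
From such images the package computes, per pixel and per depth zone:

- **Univariate parameters** — integrated amide I and carbohydrate areas,
  their ratio, the **collagen integrity** ratio

  `CI = area(CH₂ side chain, 1300–1360 cm⁻¹) / area(amide II, 1485–1585 cm⁻¹)`

  (both areas after individual two-point linear baselines; CI falls as the
  collagen network denatures), and negated second-derivative peak values at
  1202 cm⁻¹ (collagen) and 1064 cm⁻¹ (PG);
- **K-means cluster images** (K = 5, Euclidean, carbohydrate region) on the
  combined multi-sample matrix, which expose the superficial/middle/deep
  layering of cartilage;
- **OARSI-grade prediction** by partial least squares regression (NIPALS)
  on zone-mean spectra (surface 0–15 % and deep 65–100 % of thickness; raw
  vector-normalized or Savitzky–Golay second-derivative representation),
  with wavenumber selection by **competitive adaptive reweighted sampling**
  (CARS: Monte-Carlo PLS fits, coefficient-weighted elimination along an
  exponential retention schedule r₁ = p … r_last = 2), validated by
  per-sample leave-one-out cross-validation and summarized by Spearman's
  rank correlation and the mean percent error
  `E = (100/n) Σ |ŷᵢ − yᵢ| / yᵢ`;
- **Cohort statistics** — Spearman correlations with grade and
  Kruskal–Wallis tests with Dunn–Bonferroni pairwise comparisons across the
  early (grades 1.0–2.5), intermediate (3.0–3.5) and severe (4.0–4.5) OA
  groups, always on per-sample summaries, never on pixels.

Upstream of all this sit spectral quality control (peak-intensity and SNR
thresholds), EMSC scatter correction (per-pixel multiplicative scale plus
polynomial baseline against the cohort mean), PCA-based bone/cartilage
segmentation with an automatic Otsu threshold, and per-column depth
normalization (0 % articular surface → 100 % tidemark).

Because the patient images the workflow was designed around are not
publicly deposited, the package ships a first-class synthetic-data module:
layered cartilage phantoms with depth-dependent collagen/PG composition,
grade-dependent surface PG depletion and collagen-network degradation,
surface erosion at high grades, scatter baselines, detector noise and dead
pixels — with full ground truth, so every stage is tested against known
answers. See the methods vignette (`vignettes/ftir-cartilage-methods.Rmd`)
for the models, parameters and design decisions.

## Worked example

Run the complete analysis on the default synthetic cohort (28 samples,
OARSI grades 1.0–4.5 in the 10/9/9 group design, 60 × 20 pixel sections):

```r
library(cartFTIR)

res <- run_pipeline(pipeline_config(seed = 42))

res$models$surface_second_derivative
#> <grade_model> surface zone, second_derivative: 29 variables, 8 LVs
#>   LOOCV Spearman r = 0.990 (p = 7.3e-24), mean percent error = 3.13%
res$models$deep_second_derivative
#> <grade_model> deep zone, second_derivative: 24 variables, 18 LVs
#>   LOOCV Spearman r = 0.989 (p = 3e-23), mean percent error = 4.12%

subset(res$statistics, parameter == "collagen_integrity",
       select = c(parameter, zone, spearman_r, spearman_p, kw_p, signif))
#>           parameter    zone spearman_r   spearman_p         kw_p signif
#>  collagen_integrity surface -0.9276477 1.255032e-12 4.255223e-05     **
#>  collagen_integrity    deep -0.7798099 1.000013e-06 8.449166e-04     **

res$cluster
#> <cluster_result> K = 5 on carbohydrate region, 25902 spectra, inertia 13.48 (20 iterations)

sprintf("bone-mask agreement vs ground truth: %.1f%%",
        100 * res$diagnostics$bone_mask_agreement)
#> [1] "bone-mask agreement vs ground truth: 100.0%"
```

Reading the output: the surface-zone second-derivative model ranks the 28
samples almost perfectly by simulated OARSI grade (Spearman r = 0.99) with
a 3.1 % mean percent error, and beats the deep-zone model (4.1 %) — the
simulated degradation is surface-weighted, so this is the expected
ordering. The collagen-integrity parameter correlates negatively with
grade in both zones, more strongly at the surface, and differs between the
pooled OA groups (Kruskal–Wallis p < 0.001). `run_pipeline(config,
out_dir = "...")` additionally writes all tables as CSV, cluster label
images as PNG, and a JSONL parameter log; reruns with the same seed are
bit-identical.

Cubes can also be read from disk (`read_cube()`, plain-text container with
a CSV pixel export) and analysed with
`pipeline_config(phantom = NULL, input_dir = "...")`; YAML configuration
files are supported via `read_pipeline_config()`.

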