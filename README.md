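# stainslice

Grey-level intensity slicing and prognostic morphometry of pan cytokeratin
immunohistochemistry images.

## The problem

Pan cytokeratin (AE1/AE3) immunostaining labels epithelial cells, so in a
breast-tumor section it draws the malignant "tumor nests" dark against a
light stroma. On an 8-bit greyscale image (0 = black = maximal stain,
255 = white = no stain) the staining *intensity* carries information of its
own: intense staining marks well-differentiated epithelium, moderate
staining the bulk of the malignant nests, and the weakest levels the
stroma. `stainslice` implements a pipeline that asks where the prognostic
information lives along this intensity axis:

1. **Grey-level slicing** — each image is segmented into seven discrete
   narrow ranges (0–130, 130–160, 160–180, 180–200, 200–220, 220–240,
   240–255, with 220 the cutoff between specific epithelial and
   non-specific stromal staining). Out-of-range pixels become white
   (255); the kept-pixel mask is carried alongside.
2. **Computational morphology** — each slice (and the original) is
   scored by 33 features: five grey-level co-occurrence matrix (GLCM)
   texture features (ASM, contrast, correlation, IDM, entropy), 23
   monofractal features from box-counting over 12 repositioned grids
   (box dimension D_B, mass dimension D_M, optimal-cover dimension D_X,
   their dispersions, standard errors and intercepts, and the lacunarity
   family Λ), and five threshold-limited first-order statistics (area,
   IntDen, RawIntDen, skewness, excess kurtosis) computed strictly on the
   kept pixels.
3. **Prognostic evaluation** — features are averaged per patient and
   tested against a binary metastasis endpoint: Mann–Whitney AUC with
   DeLong confidence intervals, AUC folding (`max(a, 1-a)`) for range-level
   averages, sums of significant AUC improvements over the original
   images, bootstrap optimism correction (1000 resamples),
   chi-square-maximising cutoff selection, Spearman redundancy checks, and
   forward/backward stepwise logistic regression (entry and remain
   p ≤ 0.05), plus the Hanley–McNeil ROC sample-size computation.

Because studies of this kind rarely deposit their image sets, the package
ships a **synthetic cohort generator**: tumor-nest images built from
random merged ellipses whose seven-range intensity shares are calibrated
to the reported average distribution (6/9/10/8/8/29/30 %), and patient
cohorts in which a latent image property (nest area fraction) separates
metastasis-positive from negative patients with an analytically chosen
AUC (binormal construction). Every stage of the pipeline can therefore be
verified against a known ground truth.

## Worked example

Simulate a 40-patient cohort (3 images each, designed latent AUC 0.85,
30% prevalence), extract GLCM and first-order features for all ten ranges
and evaluate them:

```r
library(stainslice)
coh <- generateCohort(
  cohortSpec(nPatients = 40, imagesPerPatient = 3, effectAuc = 0.85,
             prevalence = 0.3, prevalenceMode = "exact", seed = 7),
  nestImageSpec(width = 128L, height = 128L, nestCount = 10L))
manifest <- merge(coh$images[, c("patient_id", "image_id")],
                  coh$patients[, c("patient_id", "outcome", "age",
                                   "tumor_size", "er_status")],
                  by = "patient_id")
cfg <- pipelineConfig(families = c("glcm", "first_order"), bootstrap = 200)
res <- runPipeline(manifest, "demo_out", cfg, images = cohortImages(coh))
head(res$aucTable[order(res$aucTable$p),
     c("feature", "range_label", "auc", "ci_lo", "ci_hi", "p")], 5)
```

```
     feature range_label   auc  ci_lo ci_hi        p
 correlation     130-160 0.149 0.0202 0.277 8.67e-08
 correlation     160-180 0.155 0.0251 0.284 1.80e-07
        area     200-220 0.842 0.7034 0.981 1.35e-06
     int_den     200-220 0.842 0.7034 0.981 1.35e-06
 raw_int_den     200-220 0.842 0.7034 0.981 1.35e-06
```

The designed effect (nest coverage) surfaces both directly — stained area
in the moderate ranges, AUC 0.84 toward high risk — and through texture:
GLCM correlation in the 130–180 ranges has AUC 0.15, i.e. a folded AUC of
0.85 associated with the *negative* class, exactly the mirrored behaviour
the folding convention exists for. `runPipeline()` also writes
`features_long.csv`, `cohort_wide.csv`, `auc_table.csv`,
`range_summary.csv`, `stepwise_model.csv` and a hashed JSON run config to
the output directory.

Single images work the same way without the cohort machinery:

```r
img <- generateImage(nestImageSpec(seed = 7))
round(100 * rangeShare(img), 1)
#>   0-130 130-160 160-180 180-200 200-220 220-240 240-255
#>     6.2     8.9     9.9     8.0     8.0    27.6    27.9

s <- sliceImage(img, intensityRange(160, 180))
s
#> SlicedImage 160-180: 256 x 256, 6467 kept pixels (9.9%)
round(glcmFeatures(glcm(s)), 4)
#>         asm    contrast correlation         idm     entropy
#>      0.6818   1101.7731      0.1461      0.8286      1.2147
round(fractalFeatures(s)[c("d_b", "sd_d_b", "lam", "lam_prime")], 4)
#>    d_b sd_d_b    lam lam_prime
#> 1.8625 0.0023 0.2356   0.2311
```

A thin command-line wrapper (`inst/scripts/stainslice.R`) exposes
`simulate`, `slice` and `run` subcommands over the same functions.

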