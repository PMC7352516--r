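---
title: "Grey-level slicing morphometry: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-level slicing morphometry: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainslice)
```

This vignette is the package's own account of the science it implements:
the measurement model behind each feature family, the numerical
conventions that had to be fixed where the field leaves them open, what
the synthetic generator does and does not emulate, and the limitations a
user should keep in mind.

## 1. The measurement model

The object of study is an 8-bit greyscale image of a pan
cytokeratin-stained tumor section in the brightfield convention: 0 is
black (maximal stain), 255 white (no stain). Lower grey level therefore
always means stronger staining, and all range semantics in this package
are documented in those terms. RGB input is first reduced to the blue
(cytokeratin) channel by standard optical-density colour deconvolution
(`decomposeStains()`): per pixel, `OD = -log10(I/255)` is projected onto
two configurable unit absorbance vectors (hematoxylin-like and DAB-like
defaults) plus an orthogonal residual, and each density is rendered back
to grey as `255 * 10^(-density)`. The stain vectors of the original
acquisition are generally unknown, so they are declared configuration,
never inferred.

### Grey-level slicing

`sliceImage()` keeps the pixels of one intensity interval and paints
everything else white. The kept rule is taken from the two-command
thresholding macro that defines the operation operationally: a pixel `v`
survives the range `(lo, hi)` iff `lo < v < hi` — *both* shared boundary
levels are whitened, even though prose labels the ranges inclusively.
With the default seven ranges this makes the kept sets pairwise disjoint
and their union everything except the six shared boundary levels
{130, 160, 180, 200, 220, 240} and white 255 (the conservation law
asserted in the tests: 249 of 256 levels are kept somewhere). Two edge
cases are fixed as follows and are configurable via `boundary =
"inclusive-lower"` for users who prefer the prose semantics:

* `lo = 0`: there is no lower command, so level 0 is kept;
* level 255 never counts as kept, in any range: native white is
  indistinguishable from fill, which is why the kept mask — not the
  white-filled image — is the authoritative record and travels with every
  `SlicedImage`.

### GLCM texture

`glcm()` accumulates the joint probability of grey-level pairs at a fixed
offset over the full 256-level scale. The construction parameters are not
universal across tools, so the defaults follow the common texture-plugin
convention — distance 1, angle 0°, symmetric accumulation, natural-log
entropy, no quantisation — and all are exposed. The five features are the
classical ones: `ASM = Σp²`, `contrast = Σ(i−j)²p`,
`correlation = Σ(i−μx)(j−μy)p/(σxσy)`, `IDM = Σp/(1+(i−j)²)`,
`entropy = −Σp·log p`. Correlation is undefined (NA, flagged — never a
silent zero) when a marginal variance vanishes, e.g. on a constant or
fully white-filled slice. For sliced images the white fill participates
fully in the matrix; this is deliberate: the spatial arrangement of a
narrow intensity range against its background *is* the texture of
interest.

### Fractal features

`scanGrid()` tiles the image with boxes of sizes 5–575 px in 3-px steps
(191 sizes; sizes beyond the shorter image side are dropped) from a given
grid anchor, and `fractalFeatures()` repeats this at 12 grid positions —
the reference anchor (0,0) plus 11 seeded uniform offsets inside
`[0, ε_min)²` — because box-counting estimates depend on grid placement
and their dispersion is itself a heterogeneity readout.

Two numerical conventions needed fixing:

* **Edge correction.** Only boxes lying fully inside the image are
  scanned, and counts are rescaled by (image area)/(covered area).
  Without this, the floor/ceiling noise of partial boxes biases the
  log–log slope by up to ±0.2 at the largest sizes; with it, a constant
  image yields `N(ε) = WH/ε²` exactly and the fitted dimension is 2.000
  to machine precision, which the tests assert.
* **Counting rule.** The default is classic binary support counting: a
  box counts 1 if it contains any non-white pixel. For white-filled
  slices this measures the geometry of the stained support, which is the
  quantity of interest here, and it gives the textbook dimensions on
  analytic fixtures (log 8/log 3 ≈ 1.893 on a level-6 Sierpinski carpet,
  reproduced to 0.055 in the acceptance suite). Two greyscale rules are
  available behind `counting=`: Sarkar–Chaudhuri differential counting
  (`n_b = ⌊max/h⌋ − ⌊min/h⌋ + 1`, grey-box height `h = ε·256/min(W,H)`),
  which measures the dimension of the intensity surface (between 2 and 3;
  on a binary carpet it gives ≈ 2.9, the surface of the indicator, not
  the set), and a span rule `n_b = 1 + (max−min)·scale`. The binary
  default was chosen because the analytic fixtures and the white-fill
  slicing design both describe support geometry; users analysing
  unsliced greyscale originals may prefer `"differential"`.

From the per-grid regressions of `log N` on `log(1/ε)` come `d_b` (mean
slope), `sd_d_b` (dispersion across grids — a heterogeneity feature, not
an error bar), the extrema, the slope of the best-r² grid, and, from the
regression on grid-averaged counts, the slope standard error and
intercept (`se_d_b`, `yint_d_b`); SD and SE are deliberately distinct
quantities. The mass dimension family repeats this with `log(mean box
mass)` on `log ε`, where mass is inverted intensity `Σ(255−v)` so that
stain-dense boxes are heavy. The optimal-cover dimension `d_x_best_r2`
regresses on the per-size *minimum* count across grids — the tightest
cover the repositioned grids found. This is a declared convention: the
quantity is named in the field's feature lists but nowhere defined
precisely, so the package documents its reading rather than claiming
provenance. Lacunarity is `λ(ε,g) = (σ/μ)²` of box masses; `lam` averages
over sizes at the reference grid (again a declared convention), `lam_prime`
over sizes and grids, with per-grid extrema and two coefficients of
variation completing the 23-feature set. All lacunarity features are 0
for homogeneous images and grow when mass concentrates, which the tests
check against a blob-versus-scattered fixture at equal total mass.

### First-order statistics

`firstOrder()` computes area, IntDen (= mean × area), RawIntDen (= Σv),
skewness and kurtosis *strictly on the kept pixels* — the opposite
white-fill convention from the texture families, mirroring how
threshold-limited measurements behave in common image tools. Moments use
population (biased) estimators by default (`sample = TRUE` switches to
bias-corrected ones) and kurtosis is the excess convention (Gaussian ⇒ 0;
asserted at n = 10⁵ within |k| < 0.1). Skewness and kurtosis are flagged
NA when the kept SD is zero or fewer than 4 pixels are kept; an empty
kept set yields zero area and densities, never an exception. The mean is
emitted as a derived auxiliary column alongside the canonical five, since
range-mean intensity is routinely reported even though it is redundant
given IntDen and area.

## 2. Prognostic evaluation

Features are averaged per patient over that patient's images (NA values
excluded pairwise with a logged count — averaging in silent zeros would
bias every downstream AUC). Each feature × range column is then scored
against the binary metastasis endpoint:

* **AUC** by the Mann–Whitney estimator with half-credit ties, direction
  fixed so that AUC < 0.5 means association with the negative class;
  DeLong variance supplies the 95% CI and the two-sided p against 0.5.
  The estimator is verified against exhaustive pair counting.
* **Folding**: for averaging across features, AUCs reflect to
  `max(a, 1−a)`; 0.34 and 0.66 are the same discrimination strength with
  opposite orientation.
* **Range summaries**: per range, the mean folded AUC over all evaluated
  features, and the sum of significant improvements
  `max(0, |AUC_range − 0.5| − |AUC_orig − 0.5|)` per feature family —
  counted only for features significant in that range *and* possessing an
  original-image AUC. The clip at zero and the two gating conditions are
  exactly what reproduces the published worked arithmetic in the
  acceptance tests.
* **Bootstrap optimism**: the apparent folded AUC is corrected by the
  mean over 1000 patient-level resamples of (folded AUC on the resample −
  AUC that the resample-chosen direction attains on the original data).
  Direction selection is the optimistic step for a raw continuous marker;
  degenerate single-class resamples are redrawn and counted. Under
  permuted outcomes the corrected AUC collapses to 0.5 ± 0.06.
* **Cutoff selection** re-implements the chi-square-maximisation
  principle: candidate cutoffs are midpoints of consecutive unique scores
  inside the 10th–90th percentile window, the uncorrected 2×2 chi-square
  is maximised, ties break toward the smaller cutoff. The
  Miller–Siegmund minimum-p correction is available behind `correct =
  TRUE` and off by default, since the selected cutoff itself is
  unaffected.
* **Stepwise logistic regression**: forward selection with backward
  elimination on likelihood-ratio p-values (entry and remain 0.05),
  continuous inputs, hazard ratios as `exp(β)` with Wald CIs.
  (Quasi-)separation is detected scale-invariantly — a coefficient moving
  the linear predictor by > 30 log-odds per predictor SD, or fitted
  probabilities pinned at 0/1 — and such candidates are excluded with a
  warning rather than silently dominating the model. Collinear
  duplicates contribute nothing by the LRT (df = 0 guarded) and exactly
  one of each pair survives.
* **Sample size** (`rocSampleSize()`): the minimal positive count (and
  total, at a fixed negative:positive ratio) for which
  `z_α√V(A₀) + z_β√V(A₁) ≤ A₁ − A₀`, with the Hanley–McNeil variance
  `V(A) = [A(1−A) + (n₊−1)(Q₁−A²) + (n₋−1)(Q₂−A²)]/(n₊n₋)`,
  `Q₁ = A/(2−A)`, `Q₂ = 2A²/(1+A)`, iterated upward in n. Two-sided by
  default; the implementation is cross-checked against an independent
  power-curve search and, by Monte-Carlo simulation of the AUC z-test,
  attains the nominal power at the returned n (e.g. 29 positives / 145
  total for detecting 0.67 at 4:1, simulated power ≈ 0.83). No family-wise
  multiplicity correction is applied anywhere in the evaluation; the
  feature-count context is visible in the output tables instead.

## 3. The synthetic generator: what it emulates and what it does not

`generateImage()` builds a stroma background scattered with dark tumor
nests: unions of randomly placed, randomly oriented ellipses (radius
N(18, 6) truncated at 2 px, aspect 0.45–1), merged where they overlap —
the minimal machinery that produces nests "of variable sizes and shapes".
Nest pixels draw from a five-component intensity mixture over the
specific ranges (weights 6:9:10:8:8), stroma pixels from a two-component
mixture over 220–240/240–255 (29:30); draws avoid the boundary levels so
mixture weights translate directly into measured range shares. Additive
Gaussian noise (SD 1 grey level) is clipped to [0, 255], with a message
when more than 1% of pixels clip. The default ellipse count (33 at
256 × 256) was set once so that expected nest coverage is ≈ 41% of the
frame, which makes the seven-range shares average 6/9/10/8/8/29/30 %
within the ±3-point band the calibration tests assert; nest size and
shape distributions are free parameters documented here, not fitted to
any data.

Cohorts (`generateCohort()`) first draw outcomes (binomial, or an exact
count for reproducing a fixed design such as 20 positives in 102), then a
latent patient level `z ~ N(δ·outcome, 1)` with `δ = √2·Φ⁻¹(effectAuc)`,
so the latent feature's population AUC is the target by construction —
the binormal route was chosen over a logistic link precisely because it
makes the designed AUC analytic. The latent level shifts each patient's
expected nest coverage on the logit scale (0.35 per SD) and is converted
to an ellipse count through the Boolean-model relation
`coverage = 1 − exp(−λ)`; the measured stained area is then a noisy
monotone readout of `z`, and averaging five images per patient keeps the
attenuation of the measured AUC within the tolerance the recovery test
asserts (designed 0.8 → measured ≈ 0.81 at 200 patients). Covariates
(age ~ N(57, 10) years clipped to 30–85, tumor size ~ logN(log 20, 0.35)
mm, ER positivity 0.69) reproduce the marginal shape of an early
node-negative breast-cancer cohort and are independent of outcome — they
exist to exercise the multivariate machinery, not to encode confounding.

What the generator does **not** emulate: chromogen optics and RGB stain
physics (images are born greyscale), cell-level texture inside nests
(nest interiors are i.i.d. mixture draws, so within-nest texture is
white), spatial correlation of stroma, scanner artefacts, and any
survival-time structure. Consequently, passing recovery tests show that
the pipeline measures what was designed into the images — not that the 33
features would rank identically on real tissue, where within-nest texture
and stroma structure carry additional signal.

## 4. Problem sizes and numerical choices

The test and acceptance suites run at deliberately modest scales chosen
as the package's own verification conditions: 8 × 8 oracles for GLCM
algebra, 20 × 20 for the box-scan oracle, 600 × 600 constants and the
729 × 729 level-6 carpet for fractal analytics, 20 default images for
share calibration, and a 200-patient × 5-image cohort at 128 × 128 (ellipse
count 10, scaled with frame area to keep the ≈ 41% coverage operating
point) for parameter recovery. OLS fits use the closed form with slope
SE from residual variance; r² is clamped to [0, 1]; lacunarity is defined
0 where mean box mass is 0; coefficients of variation are 0 when their
mean is 0 (homogeneous images). Grid offsets, bootstrap resamples,
cohort draws and image synthesis are all driven by explicit integer
seeds through isolated RNG scopes, so every result in the package is a
pure function of (inputs, config, seed) — byte-identical outputs on
re-run are asserted in the tests.

## 5. Known limitations

* The 8-bit forward quantisation of real cameras limits stain-channel
  recovery to ~±2 grey levels at high optical densities; the
  deconvolution round-trip is exact only for unquantised input.
* Binary support counting degenerates to dimension ≈ 2 on images with no
  white pixels (e.g. unsliced originals); choose `"differential"`
  counting for such inputs.
* The optimal-cover dimension and the unprimed lacunarity are declared
  conventions (per-size minimum across grids; reference-grid average):
  other tools may report different quantities under the same names.
* `rocSampleSize()` follows the Hanley–McNeil variance; published
  sample-size figures computed with other tools can differ substantially
  from a correct power iteration at the same nominal inputs, and this
  package reports what the stated procedure actually yields.
* Bootstrap optimism correction addresses direction selection for a raw
  marker; it does not correct for cutoff selection *and* modelling in
  combination, and no multiplicity correction is applied across the
  feature × range grid.
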