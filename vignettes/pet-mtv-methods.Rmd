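---
title: "Methods: MTV delineation, heterogeneity parameters and response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MTV delineation, heterogeneity parameters and response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petmtv)
```

## Scope and model

`petmtv` implements a pretherapeutic FDG-PET analysis pipeline for pediatric
Hodgkin's lymphoma: delineation of the total metabolic tumor volume (MTV) on
3D SUV images, extraction of metabolic and heterogeneity parameters,
EuroNet-PHL treatment-group/level (TG/TL) assignment and early-response
(IR/AR) classification, and the stratified ROC / optimal-cutoff /
diagnostic-accuracy statistics that relate a high baseline MTV to inadequate
response after two cycles of induction chemotherapy.

Because no patient images or per-patient tables are distributable with such a
study, the package is exercised end-to-end on two synthetic stand-ins that
are first-class, tested modules:

* a **phantom generator** (analytic lesions, Gaussian point-spread function,
  additive noise, ground-truth masks), and
* a **cohort simulator** calibrated to the published marginal structure of a
  50-patient pediatric cohort.

## Delineation

Three thresholding schemes are provided, all with 26-connected component
labeling, inclusive thresholds (SUV >= T) and a 2-voxel minimum lesion size:

* **Fixed absolute threshold** (conventional SUV 2.5).
* **Relative-maximum threshold** (`t41`: 41% of the in-ROI maximum).
* **Background-adapted iterative threshold** (the primary scheme):
  `T_{k+1} = BG_k + q * (Imax - BG_k)` with `q = 0.39` by default, where
  `BG_k` is the mean SUV in a shell obtained by dilating the current mask
  between 2 and 4 voxel steps (other lesions excluded), and `Imax` is the
  maximum of the current component. Iteration stops when successive
  thresholds differ by `< 0.01` SUV or after 20 iterations (non-convergence
  is recorded, the last mask returned). An empty shell falls back to the
  median of all non-lesion voxels.

The published description of the clinical algorithm does not fix the shell
construction, the stopping rule or the value of `q`; the scheme above is the
package's canonical interpretation, chosen because it has a closed-form
fixed point on piecewise-constant images (`T* = BG + q (Imax - BG)`),
which makes it testable: on a plateau lesion of uptake 10 over background 1
the threshold must converge to 4.51 in at most 3 iterations, and it does.
On a blurred 30 mm sphere (7 mm FWHM) the recovered volume is within 15% of
ground truth. Seeds are supplied as explicit voxel indices (configuration
files, not interactive clicks) so "semi-automatic" runs are reproducible;
the seed hill-climbs to its local maximum before delineation.

Manual correction is encoded as two directive types mirroring clinical
practice: `override_threshold` (re-delineate one lesion at a manually chosen
SUV) and `split_subvolume` (delineate a missed low-uptake lesion separately
inside a stated region). The criterion for *when* a human would intervene is
observer-dependent and is deliberately not modeled.

## Feature definitions

For the union of all lesion voxels (the total MTV):

* `mtv` (ml): voxel count x voxel volume (product of spacings / 1000).
* `suv_max`, `suv_mean`; `tlg = mtv * suv_mean` holds exactly by
  construction.
* `suv_peak`: mean SUV over voxels whose centers lie within 6 mm of the
  hottest voxel's center (12 mm sphere). Among tied maxima (plateau
  phantoms) the tied voxel closest to the mask centroid is used, which keeps
  the sphere inside uniform lesions and is deterministic. The sphere is
  clipped at the grid border (flagged). Note that on a 4 mm grid the 12 mm
  sphere contains 19 voxel centers - the 6 face neighbors *and* the 12 edge
  diagonals at 5.66 mm.
* `csh_auc`: area under the cumulative SUV-volume histogram. F(t) is the
  MTV fraction with SUV >= t x SUVmax for t = 0, 1/n, ..., 1 (n = 100);
  the scalar is the trapezoidal area of F over [0, 1]. It is invariant
  under positive rescaling of all SUVs and equals 1 for uniform uptake.
* **GLCM texture** (`entropy` in bits, `energy`, `contrast`,
  `local_homogeneity`): voxel SUVs are quantized into 64 equal-width bins
  over the lesion min-max; a single pooled symmetric co-occurrence matrix is
  accumulated over the 13 unique distance-1 3D directions, with both voxels
  of a pair required to lie inside the mask, then normalized to joint
  probabilities. The published study reports homogeneity values far above 1,
  so its internal definitions were scaled or non-standard; the standard
  Haralick forms are implemented and no claim is made of reproducing those
  numeric ranges. Pooled (not per-lesion) computation is used since the
  study computed parameters "for the whole MTV". Constant lesions return
  the degenerate single-bin matrix (0, 1, 0, 1), flagged.
* `asp` (asphericity, percent):
  `ASP = 100 ((H^3 / (36 pi V^2))^{1/3} - 1)`, 0 for a sphere, 24.1% for a
  cube, 26.0% for two equal disjoint spheres.

### Surface-area estimator for ASP

Voxel-face counting overestimates the area of smooth surfaces by up to 50%
(a digitized sphere exposes 1.5x its true area in faces), which would bias
ASP far upward. The default estimator is therefore the **co-area form**: the
binary mask is smoothed with a half-voxel Gaussian and the surface area is
the integral of the gradient magnitude of the smoothed field. This is exact
for planar interfaces of *any* orientation, so the staircase bias vanishes;
the residual error is curvature at the half-voxel scale (about +1% for a
30 mm sphere at 2 mm voxels) and corner rounding for polyhedra (cube error
shrinks linearly with voxel size; a two-resolution Richardson extrapolation
lands within 2 points of the 24.1% limit, which is how the tests check
convergence). A marching-tetrahedra mesh mode and the voxel-face mode are
retained for comparison. ASP is clipped at 0 because the sphere is the
analytic minimum and small negative estimates are pure discretization error.

## Phantoms

A voxel belongs to a lesion iff its center lies inside the analytic shape,
giving a one-voxel-layer error bound against analytic volumes. Defaults
emulate clinical whole-body PET: 64^3 grid, 4 mm isotropic voxels,
background SUV 1.0, 7 mm FWHM Gaussian PSF. Noise is additive Gaussian on
the blurred image, clipped at zero - an adequate desk-scale stand-in for
reconstructed-image noise; Poisson projection noise, motion and
reconstruction artifacts are *not* modeled, so green phantom tests establish
correctness of the geometry/feature pipeline, not clinical robustness.
Ground-truth labels are frozen before blur and noise. Blur uses an
edge-renormalized separable Gaussian, so constants are preserved and
interior structure is conserved to well under 0.1%.

## Cohort simulator

The simulator states the cohort the statistics stage is designed for
(50 patients unless overridden):

* Stage distribution 1/26/7/16 over I-IV; stage-conditional MTV follows a
  log-normal matched to the published median (exactly) and IQR (sigma from
  the quartile ratio); stage I is a 7.0 ml point mass (a single-patient
  stratum in the reference cohort). Note the published stage-II median does
  not equal the geometric mean of its IQR, so median and IQR cannot both be
  matched exactly by a two-parameter log-normal; the median is prioritized.
* ASP follows stage-conditional log-normals correlated 0.5 with log MTV
  (the published data quantify no such correlation; 0.5 is a flagged
  modeling choice). Secondary parameters (SUVs, texture, CSH) are drawn at
  the published scales with mild couplings whose signs follow the published
  cutoff directions; they are plausible stand-ins, not calibrated claims.
* Substage/covariate rates (B-symptoms 0.5/0.4 in stages II/III, extranodal
  0.08-0.30 rising with stage, ESR and bulk rates split low-risk vs other)
  were chosen once so that the *expected* TG/TL margins under the protocol
  rule tables fall near the published 12/17/21 - an explicitly stated
  calibration goal of the design - and were not adjusted afterwards. A drawn
  50-patient cohort is checked against 95% binomial bands of the published
  margins.
* Response: `logit P(IR) = b0(g) + b1(g) log MTV` per TG/TL group, with
  coefficients solved (deterministic quadrature + L-BFGS-B) so that the
  mean IR probability above/below the published per-group MTV cutoffs
  (80/160/410 ml) matches the published conditional rates (85.7/0, 80.0/28.6,
  90.0/27.3%). The 0% target is not attainable by a finite logistic; the
  slope bound (12) leaves a sub-1% residual rate, which the tests tolerate.

## Statistics

* **ROC**: empirical, test-positive = value > threshold; AUC is computed via
  midranks and equals the Mann-Whitney U divided by n1 n2 (ties half) - an
  identity the tests enforce against exhaustive pair counting. The AUC CI is
  DeLong + normal approximation, clipped to [0, 1]; the source study's SPSS
  CI method is undisclosed, so no numeric CI agreement is claimed.
* **Optimal cutoff**: minimal distance `d = sqrt((1-sens)^2 + (1-spec)^2)`
  to (0, 1); ties break toward higher specificity, then higher threshold.
  The cutoff is invariant under strictly monotone transforms.
* **Diagnostic accuracy**: sens/spec/NPV/PPV with Clopper-Pearson exact CIs;
  display values round half-up to whole percent (half-up reproduces every
  reconstructed cell of the reference tables; raw fractions are retained).
* **Mann-Whitney**: midrank U; exact enumeration of all rank splits when
  n1 + n2 <= 12, else normal approximation with tie correction.
* **Log-linear association**: saturated model on 2x2(x2) tables with effect
  coding and +0.5 in every cell; z = estimate/SE per interaction. With
  delta = 0 on a 2x2 table this reduces exactly to the Wald log-odds-ratio
  z, which is the tested anchor. The published z values came from
  undisclosed SPSS internals and are not acceptance targets.
* Polarity: high biomarker predicts IR for all parameters except entropy
  and contrast, whose published cutoffs point downward; these are negated
  internally and reported with "<" direction. No multiple-testing
  correction is applied, matching the reference analysis.

## Reference-table reconstruction

The per-stratum 2x2 tables behind the published diagnostic-accuracy rows are
uniquely determined integers: stratum sizes and IR counts fix the margins,
and the printed IR rates above/below the MTV cutoff (one decimal) pin
(tp, fp) and (fn, tn) by exhaustive integer search
(`reconstruct_table_from_rates()`). The asphericity rows print no
conditional rates, so their tables are reconstructed from the rounded
sensitivity/specificity instead (`reconstruct_table_from_sens_spec()`),
which is also unique at whole-percent rounding. The acceptance tests verify
that `diagnostic_accuracy()` then reproduces every printed percentage and
every exact-binomial CI bound for both parameters in all five strata.

## Numerical choices and degenerate inputs

* Thresholds are inclusive (>=): deterministic and monotone in ties.
* Components under 2 voxels are discarded as noise specks by default.
* Empty segmentations are legal delineation results but undefined inputs
  for features (error), and single-voxel masks warn on ASP.
* NIfTI I/O is a minimal NIfTI-1 implementation (gzip-aware, sform/pixdim
  spacing, float32/int16 writing); masks are validated against their image
  for shape and spacing within 1e-6 before use.
* All simulation entry points take explicit integer seeds, restore the
  caller's RNG state, and are bitwise reproducible.

## Known limitations

No DICOM, decay or scanner calibration; no PSF-matched segmentation or
deep-learning delineation; phantom noise is Gaussian, not reconstruction
noise; the cohort simulator reproduces margins and stated conditional rates,
not joint covariate structure; survival endpoints are out of scope by
design. Texture values are standard Haralick quantities and intentionally
not matched to the reference study's non-standard scales.
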