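# petmtv

Quantitative FDG-PET analysis for pediatric Hodgkin's lymphoma: total
metabolic tumor volume (MTV) delineation, metabolic and heterogeneity
parameters, EuroNet-PHL risk-group and early-response rules, and the
stratified diagnostic-accuracy statistics that test whether a **high
baseline MTV predicts inadequate response (IR) to induction chemotherapy**.

## Who this is for

Nuclear-medicine / imaging researchers who want a reproducible, scriptable
re-implementation of a PET biomarker pipeline:

* **Delineation** of lesions on 3D SUV volumes (NIfTI) by three threshold
  schemes: background-adapted iterative `T = BG + q·(Imax − BG)` (default
  `q = 0.39`), relative-maximum (`t41`, 41% of max) and fixed SUV 2.5, with
  manual-correction directives (threshold override, sub-volume split) and
  total-MTV aggregation.
* **Parameters** on the total MTV: SUVmax, SUVmean, SUVpeak (12 mm sphere),
  TLG = MTV·SUVmean, asphericity
  `ASP = 100·((H³/(36πV²))^{1/3} − 1)`, gray-level co-occurrence texture
  (entropy, energy, contrast, local homogeneity) and the cumulative
  SUV-volume histogram scalar (AUC-CSH).
* **Clinical rules**: EuroNet-PHL-C1/C2 treatment group/level assignment
  from stage, ESR, bulk and extranodal disease; IR/AR early-response
  classification (Deauville ≥ 4, qPET ≥ 1.3, bulk reduction < 50%,
  non-assessable sites); `qPET = SUVpeak / liver reference`.
* **Statistics**: empirical ROC with AUC (= Mann-Whitney U / n₁n₂) and
  DeLong CI, minimal-distance optimal cutoffs
  `d = √((1−sens)² + (1−spec)²)`, sens/spec/NPV/PPV with Clopper-Pearson
  exact CIs, Mann-Whitney tests, saturated log-linear association — all
  stratified by stage group (I/II vs III/IV) or TG/TL 1-3.
* **Synthetic data**: PET phantoms with ground-truth masks (analytic
  lesions, Gaussian PSF, noise) and a 50-patient cohort simulator
  calibrated to the published marginal structure (stages 1/26/7/16, TG/TL
  12/17/21, 28 IR; stage-conditional log-normal MTV; logistic IR model
  matched to the published conditional rates at cutoffs 80/160/410 ml).

## Worked example

Delineate a 30 mm calibration sphere phantom (7 mm PSF) with the
background-adapted scheme and extract all parameters:

```r
library(petmtv)
suite <- reference_phantom_suite(psf_fwhm = 7)
ph  <- generate_phantom(suite$calibration_sphere)
res <- delineate_background_adapted(ph$image, seed = c(32, 32, 32))
res$threshold                      # 4.509 after 2 iterations
res$segmentation                   # <segmentation> 1 lesion(s), total MTV 13.31 ml
round(unclass(extract_all(ph$image, res$segmentation)), 3)
#>               mtv           suv_max          suv_mean          suv_peak
#>            13.312             9.997             7.897             9.908
#>               tlg               asp           entropy            energy
#>           105.124             0.609             5.572             0.024
#>          contrast local_homogeneity           csh_auc
#>           616.792             0.218             0.789
ph$truth$total_mtv                 # 13.312 ml ground truth -> exact recovery
```

The recovered MTV equals the ground truth exactly here (the converged
threshold 4.51 sits at the plateau fixed point `1 + 0.39·(10 − 1)`); ASP is
near 0 for a sphere, TLG is exactly `mtv × suv_mean`, and the near-uniform
uptake gives entropy ≈ 5.6 bits only because of PSF-induced edge gradients.

Simulate the default 50-patient cohort and run the stage-stratified
analysis:

```r
co  <- simulate_cohort(cohort_sim_config(seed = 1))
rep <- run_stratified_analysis(co, "stage_groups")
subset(rep$results, feature %in% c("mtv", "asp"))[,
  c("stratum", "feature", "auc", "cutoff", "sens_pct", "spec_pct")]
#>  stratum feature       auc   cutoff sens_pct spec_pct
#>     I/II     mtv 0.9285714 117.7391       90       79
#>     I/II     asp 0.7000000 110.0804       80       71
#>   III/IV     mtv 0.8250000 393.0832       63      100
#>   III/IV     asp 0.6312500 220.2740       56       70
```

MTV attains the top AUC in both strata with cutoffs on the published scale
(~100 ml in low stages, ~400 ml in high stages).

Reconstruct a published-style 2×2 table from stratum margins (16 IR / 11 AR)
and the conditional IR rates 78.9% vs 12.5%, then report accuracy:

```r
tab <- reconstruct_table_from_rates(16, 11, 78.9, 12.5)
diagnostic_accuracy(tab)
#> <diagnostic_accuracy> tp=15 fn=1 fp=4 tn=7
#>   sensitivity   94% (70 to 100%)
#>   specificity   64% (31 to 89%)
#>   NPV           88% (47 to 100%)
#>   PPV           79% (54 to 94%)
```

## Command line

Thin wrappers under `inst/cli/` (or call `cli_*()` from R):

```sh
Rscript inst/cli/delineate --image scan.nii.gz --method bg \
    --seeds seeds.json --out mask.nii.gz --report seg.csv
Rscript inst/cli/features --image scan.nii.gz --mask mask.nii.gz --out features.csv
Rscript inst/cli/simulate-cohort --seed 7 --out cohort.csv
Rscript inst/cli/analyze --cohort cohort.csv --strata stage --out report/
```

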