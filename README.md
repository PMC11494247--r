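# spathet

Spatial (inter-lesion) heterogeneity indicators from multi-lesion FDG
PET/CT, and a gradient-boosted classifier of platinum resistance built on
them.

## Who this is for

Quantitative-imaging researchers working with cancers that present as
multiple lesions per patient — the motivating case is high-grade serous
ovarian cancer with peritoneal spread — who want to measure how *different a
patient's lesions are from one another* and use that as a predictor of
treatment response. The package takes, per patient, a CT volume (HU), a
co-registered PET volume (SUV) and an integer lesion label map (the
FDG-avid solid component of each lesion), and produces a 107-entry
indicator vector plus model reports. A synthetic phantom cohort generator
with known ground truth makes every stage verifiable without patient data.

## What it computes

**104 conventional indicators.** Eight features per lesion VOI — mean CT
value, minor/major axis length (IBSI convention, 4·√eigenvalue of the
coordinate covariance), voxel count, TLG = SUVmean × volume, SUVmean,
SUVpeak (1 cm³ sphere, exhaustive search), SUVmax — each aggregated across
the patient's lesions by 13 statistics (mean, SD, median, quartile
deviation, binned mode, variance, range, SEM, uncorrected/corrected sum of
squares, CV, bias-corrected kurtosis, adjusted Fisher–Pearson skewness),
giving 13 × 8 = 104 columns named `<feature>_<statistic>` (`Max_SM`,
`HU_Kurtosis`, ...).

**3 texture-cluster indicators.** Per VOI the CT is min–max rescaled to 256
gray levels, discretized with bin width 32, and a GLCM is computed *per
voxel* over a 5³ window (13 unique unit offsets, symmetric); each voxel gets
the Haralick 4-vector (Energy, Entropy, Contrast, Homogeneity). Voxels
pooled over all lesions are clustered by a Gaussian mixture (BIC over
K = 1..8); a *subregion* is one lesion's voxels in one cluster. With D the
matrix of Euclidean distances between subregion mean texture vectors and
π the subregion voxel shares:

- `cSE` — Rao's quadratic entropy over cross-site subregion pairs,
  Σ π_i π_j D_ij / Σ π_i π_j (pairs from different lesions);
- `cluDev` — generalized Jensen–Shannon divergence of the lesions'
  cluster-occupancy profiles, H(Σ w_s p_s) − Σ w_s H(p_s);
- `cludiss` — sample SD of the cross-site entries of D.

All three are 0 for a patient whose lesions share one texture phenotype and
grow with genuine between-lesion texture diversity (a tested property).

**Lesion handling.** VOIs must strictly exceed 5 mm on every bounding-box
axis; each lesion gets one of nine abdominopelvic region codes (AR0
umbilical, AR1 right-upper, clockwise to AR8) from its mask centroid under
the 3×3 partition by two sagittal and two transverse planes (+x = patient
right, +z = superior).

**Modeling.** A gradient-boosted tree classifier (logistic loss, native
missing-value routing — indicator cells undefined at small lesion counts
stay missing) with stratified seeded 5-fold CV, for three feature groups:
conventional (clinical + 104), heterogeneity (clinical + 3), integrated
(union). Reports carry MSE, RMSE, logloss, mean per-class error, AUC,
AUCPR, Gini = 2·AUC − 1, R², per-fold accuracy/specificity, normalized
importances, calibration and gains/lift tables, and a learning curve.

**Associations.** Spearman correlation (tie-aware, exact permutation p for
n ≤ 9) for indicators vs immunohistochemistry scores, and ICC(2,1) for
segmentation test–retest agreement (> 0.75 = "good").

## Worked example

```r
library(spathet)

cfg <- phantom_config()          # the stated synthetic world
p   <- generate_patient(cfg, seed = 7)
pi  <- patient_indicators(p$ct, p$pet, p$label_map,
                          planes = cfg$region_planes, seed = 7)
length(pi$indicators)
#> [1] 107
round(tail(pi$indicators, 3), 4)
#>     cSE  cluDev cludiss
#>  0.1598  0.2491  0.1160

# a cohort whose labels are driven by the cSE signal itself
co  <- generate_cohort(150, cfg, seed = 11)
tab <- cohort_indicator_table(co, K_range = 1:3, n_init = 1)
z   <- as.numeric(scale(tab$cSE))
set.seed(12); y <- rbinom(nrow(tab), 1, plogis(3 * z))
rep <- fit_cv(model_spec("heterogeneity", seed = 11), tab, y)
rep
#> <model_report heterogeneity> train AUC 1.000 | CV AUC 0.852 (acc 0.780 +/- 0.051)
round(head(variable_importance(rep), 4), 4)
#>     cSE  cluDev cludiss   ca125
#>  1.0000  0.2275  0.1761  0.1254
```

Patient 7's lesions all carry one texture phenotype, so its three texture
indicators are small (a fully homogeneous patient would approach 0; the
floor is set by window-estimation noise). On the 150-patient cohort with
labels planted on standardized cSE, the heterogeneity-group model recovers
the dependence out-of-fold (CV AUC 0.852, accuracy 0.780 ± 0.051 across
folds) and `cSE` dominates the normalized importance ranking, with the
clinical noise stand-ins (e.g. `ca125`) far behind — exactly the behaviour
expected when outcome depends on spatial heterogeneity alone.

## Layout

- `R/`, `src/` — implementation (phantom, NIfTI I/O, VOI handling,
  conventional indicators, texture chain, GMM clustering, indicators,
  boosted trees, metrics, associations)
- `inst/cli/spathet.R` — command-line interface (`phantom`, `extract`,
  `features`, `texture`, `train`, `assoc`)
- `vignettes/spatial-heterogeneity.Rmd` — methods notes: model,
  parameters, the phantom world and its limits, design decisions
- `tests/testthat/` — unit, property and acceptance suites
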