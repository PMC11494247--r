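---
title: "Quantifying inter-lesion heterogeneity from multi-lesion PET/CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-lesion heterogeneity from multi-lesion PET/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-grade serous ovarian cancer typically presents as a primary adnexal
mass plus peritoneal metastases scattered over the abdominopelvic cavity.
Lesions within one patient can differ markedly from each other — in
density, size, metabolic activity and internal texture — and this
*inter-lesion* ("spatial") heterogeneity carries prognostic information:
patients whose lesions are more dissimilar from one another tend to respond
less uniformly to platinum-based chemotherapy. `spathet` turns a paired
FDG-PET/CT study with per-lesion segmentations into a per-patient vector of
107 spatial-heterogeneity indicators and feeds it into a gradient-boosted
classifier of platinum resistance (disease progression within six months of
completing platinum therapy).

The package operates on three inputs per patient: a CT volume in Hounsfield
units, a co-registered PET volume in SUV, and an integer label map whose
label *i* marks the FDG-avid solid component of lesion *i* (the VOI). Every
stage is also exercised end-to-end by a synthetic phantom generator, so the
full pipeline is testable without patient data.

## Lesion handling

**Size filter.** Each VOI must be *strictly greater* than 5 mm in physical
bounding-box extent on *every* axis. This is the most literal reading of a
"greater than 5 × 5 × 5 mm" rule; it is spacing-independent and applied
per axis (a 6 × 6 × 4 mm lesion is rejected).

**Nine-region scheme.** Two sagittal planes and two transverse planes
partition the abdomen 3 × 3. The central (umbilical) cell is AR0; AR1 is
the right-upper cell, and AR1–AR8 proceed clockwise, ending right-middle
(AR8). Orientation is pinned to the NIfTI RAS convention (+x patient right,
+z superior). Each VOI receives exactly one code, determined by its mask
centroid; a centroid exactly on a plane goes to the middle band (toward
AR0). The paper-level scheme uses anatomical landmarks for the planes; in
phantoms the planes are configuration constants at thirds of the field.

## The 104 conventional indicators

Eight features per lesion: mean CT value (HU), minor and major axis length
(mm), voxel count, TLG, SUVmean, SUVpeak, SUVmax. Thirteen statistics of
each feature across a patient's lesions: mean, SD, median, quartile
deviation, mode, variance, range, SEM, uncorrected and corrected sums of
squares, CV, kurtosis, skewness — 13 × 8 = 104 columns named
`<feature>_<statistic>` (e.g. `Max_SM` = SEM of SUVmax, `HU_Kurtosis`).

Pinned numerical choices, where the underlying definitions are ambiguous on
continuous data or at small n:

* **CT value** = mean HU over the VOI (a single per-lesion summary is only
  meaningful as an aggregate; the mean is the obvious one and is
  documented).
* **Axis lengths** follow the IBSI convention: 4·sqrt(eigenvalue) of the
  population covariance of the mask voxels' physical coordinates; major =
  largest, minor = second-largest eigenvalue in 3-D.
* **SUVpeak**: exhaustive search over all mask voxels of the mean SUV in a
  1 cm³ sphere (PERCIST-style; configurable). The sphere includes all
  in-grid voxels; if the mask is smaller than the sphere the mean is over
  the available in-sphere voxels.
* **TLG** = SUVmean × volume, volume = voxel count × voxel volume in cm³.
* **Quantiles** use linear interpolation between order statistics (R type
  7), so the quartile deviation is reproducible across software.
* **Mode** of continuous data is the midpoint of the most frequent
  fixed-width bin (1 HU for CT, 0.1 mm for axis lengths, 1 for counts,
  0.01 for SUV-derived values), lowest bin on ties.
* **Kurtosis** is bias-corrected excess kurtosis (needs n ≥ 4);
  **skewness** is the adjusted Fisher–Pearson coefficient (n ≥ 3). At
  smaller n — or CV when the mean is 0 — the cell is *missing*, never
  imputed; the downstream boosted trees route missing values natively.

## The texture chain and the three cluster indicators

Per VOI, on CT only: min–max rescale of in-mask intensities to 256 gray
levels, discretization with bin width 32 (8 bins), then a per-voxel GLCM
over a 5³ window (radius 2, the smallest stable window; configurable) using
the 13 unique unit 3-D offsets with symmetric accumulation, restricted to
voxel pairs inside the window ∩ mask. Four Haralick features per voxel:
Energy, Entropy, Contrast, Homogeneity (natural log). The per-VOI rescale
makes all three indicators invariant to affine transforms of the raw CT.

Voxels pooled over all of a patient's VOIs are clustered by a
full-covariance Gaussian mixture (EM, 5 seeded k-means initializations per
K, K ∈ 1..8 selected by BIC; features z-scored within patient for the fit).
A *subregion* is the set of voxels of one lesion site carrying one cluster
label. Subregion mean texture vectors are expressed on a *fixed* unit-range
scale (Energy and Homogeneity already in (0,1]; Entropy divided by
ln(bins²); Contrast by (bins−1)²) and their pairwise Euclidean distances
form the dissimilarity matrix D.

The three indicators are diversity indices over this decomposition:

* **cSE (cluster site entropy)** — Rao's quadratic entropy over cross-site
  subregion pairs: Σ π_i π_j D_ij / Σ π_i π_j over pairs from different
  sites, with π the subregion voxel shares. Zero when all sites share one
  texture signature; grows with between-site textural dissimilarity.
* **cluDev (cluster diversity)** — the generalized Jensen–Shannon
  divergence of the sites' cluster-occupancy profiles,
  H(Σ w_s p_s) − Σ w_s H(p_s): the between-site ("beta") diversity of
  texture habitats. Zero iff all sites use clusters in identical
  proportions; ln S for S equal sites with disjoint habitats.
* **cludiss** — the sample SD of the cross-site entries of D.

The group diversity matrix (GDM) — the K × K histogram of cross-site
subregion label pairs, symmetrized — is retained as a descriptive output.

**Why these definitions.** The inter-site heterogeneity literature names
these three indicators without a single canonical formula, so the
definitions here are this package's own, pinned behind a stable
interface. Two empirically decisive facts shaped them. First,
voxel-level Haralick features of even a perfectly homogeneous texture form
a continuous, multi-modal cloud (window-estimation noise plus
boundary-versus-interior window effects), so BIC routinely selects many
mixture components per texture phenotype; any indicator that relies on the
cluster count tracking the number of true phenotypes is unreliable. Second,
per-patient z-scoring pins the pooled feature variance, so distance
*magnitudes* computed in that space carry no between-patient information,
and entropies of *normalized* distance distributions are scale-invariant
by construction — a patient whose subregions are all near-identical can
score *higher* on such an entropy than a genuinely diverse one, simply
because its many tiny distances are more uniform. Rao's quadratic entropy and the
generalized Jensen–Shannon divergence are the canonical diversity indices
that remain valid under both effects: splitting one phenotype into several
clusters leaves cross-site signatures (and site occupancy proportions)
essentially unchanged, and the fixed unit-range feature scale preserves
magnitude information across patients. Both are verified to recover the
planted heterogeneity ordering (1 < 2 < 4 texture classes) in the
acceptance suite.

## The phantom world

`phantom_config()` states the emulated world; its defaults are fixed once:

* 52 × 52 × 40 voxels at 2 mm isotropic (a 104 × 104 × 80 mm abdominal
  window; clinical CT is finer in-plane, but texture statistics here only
  require a stable lattice).
* 5 lesions per patient — a desk-scale stand-in for the clinical median of
  6–7 lesions per patient.
* Lesions are axis-aligned ellipsoids, semi-axes 8–13 mm, with 40–70% of
  the volume solid. The cystic core is a scaled copy of the ellipsoid
  shifted off-centre, so the solid component is a thick crescent — windowed
  texture needs interior voxels, and real cystic-solid lesions have
  eccentric solid portions rather than uniform rinds.
* Solid SUV 4–10 vs cystic 0.5–1.5 (solid component is the FDG-avid part);
  solid HU 30–50 vs cystic 5–15; additive scanner noise 5 HU / 0.1 SUV.
* Texture classes are smoothed Gaussian random fields (seeded white noise
  convolved with a Gaussian kernel), defined by correlation length and
  amplitude. The four defaults differ in correlation length (0.6 / 2.5 /
  5 / 9 mm at 60 HU amplitude), the robust driver of co-occurrence
  statistics; their Haralick signatures are separable at the default chain
  settings (a tested invariant).
* Per patient the number of distinct texture classes is uniform on 1..4
  ("variable" assignment), then classes are assigned round-robin over a
  random subset: patients genuinely differ in phenotype diversity, which is
  the ground-truth spatial heterogeneity (class-mixture entropy H).
* The resistance label is Bernoulli(plogis(a + 2·H)). The intercept is
  calibrated *analytically* (by enumerating the exact entropy
  distribution of the assignment scheme) so the expected prevalence is
  0.35, inside the 32–39% clinical range. The slope 2 is a fixed stated
  value: strong enough that heterogeneity genuinely drives outcome, weak
  enough that labels stay noisy.

What a green test does *not* establish: the phantom has no anatomy, no
scanner physics (PSF, OSEM reconstruction, correlated noise), no partial
volume effects, axis-aligned geometry only, and clinical covariates that
are pure noise stand-ins. Pipeline-recovery results on phantoms say the
machinery is correct, not that clinical effect sizes are reproduced.

## Classifier and evaluation

One gradient-boosted tree learner (logistic loss, Newton leaf steps,
exact greedy splits, native missing-value routing with a learned default
direction per split, row subsampling) stands in for a multi-algorithm
AutoML leaderboard — in clinical radiomics comparisons of this kind the
boosted-tree learner consistently wins, so only that winner is
implemented, with a small fixed
hyperparameter surface (150 trees, depth 3, learning rate 0.1, subsample
0.8, ridge 1 by default). Three feature groups: *conventional* = clinical
covariates + 104 indicators; *heterogeneity* = clinical + cSE/cluDev/
cludiss; *integrated* = the union. Model selection criterion is CV AUC.

Evaluation is stratified, seed-deterministic 5-fold CV. The report carries
MSE, RMSE, logloss, mean per-class error (0.5 threshold), AUC (midrank
Mann–Whitney), AUCPR (average precision with tie grouping), Gini = 2·AUC−1
(exact identity, by construction), and R² on the probability scale against
the 0/1 labels; per-fold accuracy/specificity mean ± SD; gain-based
importances normalized to max 1; calibration and gains/lift tables on the
out-of-fold predictions; a training-logloss learning curve; and an optional
seeded bootstrap CI for the AUC (2000 resamples; the CI method is a
pinned choice of this package).

## Association statistics

`spearman()` uses average ranks for ties (rank-then-Pearson), an exact
permutation p-value for n ≤ 9 and the t approximation otherwise.
`icc()` is ICC(2,1) — two-way random effects, absolute agreement, single
measurement — from the ANOVA mean squares, the form recommended for
test–retest agreement with fixed raters; agreement > 0.75 is classified
"good". Clinical correlation strengths between heterogeneity indicators and
p53 / Ki-67 scores cannot be reproduced without patients' IHC data; the
package ships the machinery, not the numbers.

## Numerical and I/O choices

* NIfTI-1 is read and written natively (base R I/O, gzip transparent,
  either endianness, uint8/int16/int32/float32/float64, axis-aligned
  sform). Volumes default to float64 so round-trips are bit-exact; spacing
  and origin are rounded to 7 significant digits on read (all the format's
  float32 header can carry), so values stated at that precision round-trip
  exactly.
* Degenerate conventions are total and documented: constant VOI ⇒ gray
  level 0 with a flag; zero-pair GLCM windows ⇒ degenerate voxels excluded
  from clustering; single subregion or no cross-site pair ⇒ indicators 0;
  single-site patients ⇒ error (spatial heterogeneity undefined).
* GMM covariances carry a 1e-6 ridge; EM stops at 1e-8 relative
  log-likelihood change or 200 iterations.
* All randomness flows through explicit seeds; per-patient and per-fold
  seeds derive from master seeds by a counter-based scheme, so any cohort
  member is regenerable in isolation.

## Known limitations

* The names cSE, cluDev and cludiss come from the inter-site
  tumour-heterogeneity literature, where the exact formulas vary between
  reports; the definitions implemented here (above) are documented,
  isolated behind one interface, and swappable.
* BIC order selection over-segments continuous texture manifolds (it
  saturates at the top of K_range on real-ish textures). The indicators are
  designed to be insensitive to this, but the reported K should not be
  read as "number of texture phenotypes".
* Large cohort runs use a reduced clustering search (`K_range = 1:3`,
  `n_init = 1`) for speed — a deliberate scale-down. cSE is stable under
  it (tested: well under 35% relative change on phantom patients, usually
  a few percent) because it is a magnitude index over cross-site
  signatures. cluDev and cludiss scale with the available cluster count,
  so their *values* are only comparable within one K setting — their
  orderings across patients, which is what the models and the
  monotonicity criteria consume, are preserved.
* The per-class error threshold is fixed at 0.5 rather than an
  F1-maximizing threshold; calibration bins are equal-width.
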