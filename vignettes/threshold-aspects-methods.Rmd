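---
title: "Threshold-based ASPECTS from CTA source images: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based ASPECTS from CTA source images: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspectscta)
```

## The problem and the model

In anterior-circulation large vessel occlusion (LVO) stroke, tissue that is
already irreversibly injured at admission appears hypo-attenuating on CT
angiography (CTA) source images, because attenuation during contrast transit
tracks cerebral blood flow. The Alberta Stroke Program Early CT Score
(ASPECTS) summarises the extent of such injury over ten regions of the
middle cerebral artery territory: three subcortical (caudate, internal
capsule, lentiform nucleus) and seven cortical (insular cortex, M1–M6). One
point is deducted from 10 per affected region.

This package automates that reading. For a patient with a unilateral LVO,
each ASPECTS region $r$ on the occluded side gets a **relative Hounsfield
unit** measurement

$$\mathrm{rHU}_r \;=\; \frac{\overline{HU}_r^{\,\text{ipsi}}}{\overline{HU}_r^{\,\text{contra}}},$$

the mean attenuation of the region divided by that of its mirror region in
the other hemisphere. Both means include only voxels with attenuation in the
inclusive range **1–250 HU**; the ratio and the filter together absorb
between-scan differences in contrast bolus timing and small coregistration
errors, and exclude bone, air/CSF, and contrast-filled vessels. An rHU of 1
means hemispheric symmetry; values below 1 mean relative hypo-attenuation.

The region masks live in a template space and are carried into each
subject's native CTA (and DWI) grid by applying a user-supplied world-mm
affine — the inverse of the subject-to-template registration — with
nearest-neighbour sampling, which keeps masks binary so that voxel-count
arithmetic stays exact.

**Ground truth.** A region is labelled *finally infarcted* when at least
30 % of its voxels (counted on the subject DWI grid, after resampling)
intersect the manually segmented infarct lesion on follow-up DWI. The
boundary is inclusive, and the comparison is carried out on integer voxel
counts, so fractions landing exactly on the threshold behave predictably.
DWI-ASPECTS is 10 minus the number of labelled regions.

**The fitted model.** For each region independently, the training data
(one rHU value and one infarct label per patient) determine the cut point
$t_r$ maximising the Youden index
$J(t) = \text{sensitivity}(t) + \text{specificity}(t) - 1$ under the rule
*predict infarction iff rHU < t*. A region in a new patient is predicted
infarcted when its rHU lies strictly below $t_r$; the **threshold-based
ASPECTS** is 10 minus the number of predicted regions.

## Numerical conventions

Several small conventions are fixed so the estimator is deterministic and
reproducible:

* **Candidate thresholds** are the midpoints between consecutive distinct
  observed scores, plus $-\infty$ and $+\infty$. The published convention
  (midpoint versus an observed value) is not standardised across software,
  and the choice can move a reported cut point in the third decimal.
* **Ties in J** are broken by the smallest candidate threshold.
* **Prediction is strict**: rHU exactly at the cut point is predicted
  non-infarcted ("below the threshold" read literally).
* **AUC orientation is fixed**, not auto-detected: the Mann–Whitney AUC is
  the probability that a random infarcted region has *lower* rHU than a
  random non-infarcted one, ties counted ½. An AUC below 0.5 therefore
  signals mis-ranked classes rather than being silently flipped.
* **Degenerate inputs** fail loudly: single-class regions are named in the
  error; metrics whose class is absent are `NA` and flagged, never silently
  zero; a region left empty by the HU filter raises an error carrying the
  region id.
* The **overlap rule** compares `n_intersect / n_region` to the threshold
  via integer arithmetic (threshold taken to 4 decimals), avoiding
  floating-point boundary surprises at exactly 30 %.

## Evaluation machinery

* **Cross-validation**: single-round k-fold (k = 10 by default) with
  unstratified random allocation of *patients* (not region rows) to folds,
  seeded and reported. Per fold and region, cut points fitted on the other
  folds are applied to the held-out patients. Fold×region cells where a
  metric is undefined (a class absent in the held-out fold, or a
  single-class training region) are excluded from the aggregate mean ± SD
  and counted; zero-filling them would bias the aggregate downward.
* **Spearman correlations** (threshold-based ASPECTS against DWI-ASPECTS
  and final infarct volume) use average ranks for ties and a patient-level
  percentile bootstrap for the 95 % CI (2000 replicates by default).
  Integer ASPECTS scores are heavily tied, which undermines the Fisher-z
  normal approximation; the bootstrap also matches the comparison test
  below, so both correlation and comparison rest on the same resampling
  scheme.
* **Comparing two readings** (threshold-based vs visual ASPECTS, sharing
  one outcome) uses the percentile bootstrap for dependent overlapping
  correlations: resample patients, form the difference of the two Spearman
  correlations per replicate, and read a two-sided p off the bootstrap
  distribution's position relative to zero.
* **Outcome AUC**: the risk score is $10 - \text{ASPECTS}$ against poor
  functional outcome (3-month mRS > 2), so the orientation is explicit.
  Paired AUCs are compared with DeLong's placement-value z-test; when both
  score vectors are identical the variance of the difference is exactly
  zero and the test returns $\Delta = 0$, $p = 1$ by convention. The
  DeLong computation is implemented in-package (placement values and the
  2×2 covariance), and the test suite cross-checks it against the pROC
  implementation on random paired instances.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `hu_min`, `hu_max` | 1, 250 | HU | inclusive attenuation filter; excludes air/CSF (<1) and bone/vessel contrast (>250) |
| `overlap_threshold` | 0.30 | fraction | inclusive DWI-overlap rule defining final infarction of a region |
| `k` | 10 | folds | patient-level cross-validation |
| `bootstrap_reps` | 2000 | replicates | percentile bootstrap for CIs and correlation comparison; below 1000 a warning is issued |
| `seed` | 1 | — | fold allocation and all bootstraps; echoed in every report |

## The synthetic data and what it does (not) show

Real CTA/DWI volumes cannot ship with the package, so every stage is
exercised against two seeded generators whose ground truth is known
exactly.

**Volume phantoms** (`make_phantom_pair()`): a mirror-symmetric "block
atlas" of 20 disjoint cuboids (400 voxels each) in a 40×40×26 grid of 2 mm
voxels; background parenchyma at 40 HU with optional Gaussian noise;
per-region ipsilateral attenuation multipliers that plant the true rHU; a
DWI lesion filling a stated fraction of chosen regions (so the 30 % rule
can be probed exactly at its boundary); and an optional small rigid
misregistration (≤5°/≤5 mm, the range within which nearest-neighbour
resampling at this resolution remains well-behaved) whose correcting
transform is returned. At zero noise the full pipeline — write NIfTI, read,
resample, measure, label — must reproduce the planted rHU values and labels
*exactly*, and the tests require this.

**Tabular cohorts** (`simulate_tabular()`): per patient and region, an
infarct label drawn from the region's prevalence, then an rHU value from
the class-conditional Gaussian, truncated at 0 (the minimal distributional
model consistent with a mean/SD parameterisation). The defaults are the
modelled study conditions, chosen once: 368 patients (the training-cohort
size), per-region prevalences equal to the published validation-cohort
infarct frequencies (0.12–0.43), class means 0.87 (infarcted) and 0.97
(non-infarcted), and a common SD of 0.13, which gives a binormal AUC of
$\Phi(0.10/(0.13\sqrt{2})) \approx 0.71$ — matching the discrimination
actually observed per region in clinical data. `simulate_cohort()` adds the
patient-level metadata the outcome statistics consume: a visual reading
(DWI-ASPECTS plus reader noise, SD 1.5 points), a log-normal infarct volume
increasing with infarct burden (median ≈ 30 mL, mean ≈ 45 mL), and an mRS
whose poor-outcome probability rises with the burden (≈57 % overall).

Two features of real data are deliberately **not** emulated. First, region
labels are drawn independently within a patient, whereas real infarcts are
spatially contiguous and hit neighbouring regions together; patient-level
statistics on synthetic cohorts (Spearman of threshold-based against
DWI-ASPECTS, outcome AUC) are therefore attenuated relative to clinical
values, and passing tests on them demonstrate correct computation, not
clinical effect sizes. Second, the phantoms contain no CT physics (beam
hardening, streak artefacts) and no anatomical geometry, so they validate
the resampling and measurement arithmetic, not registration quality on real
heads.

## Calibration checks and their tolerances

* The Youden search is compared against an exhaustive counting oracle on
  hundreds of random small instances; agreement is exact.
* With class means 0.87/0.97 and SD 0.05 at 2000 cases per class, the
  empirical AUC must fall within 3 Monte-Carlo standard errors
  (Hanley–McNeil, ≈0.0045 here) of the closed-form binormal value
  $\Phi(\sqrt 2) \approx 0.921$.
* Boundary recovery: with each class mean 2 SD from a planted boundary of
  0.92 (SD 0.025) and 400 rows per region, fitted cut points are expected
  within ±0.01 of the boundary. That tolerance is ≈2.2 sampling SDs of the
  midpoint-Youden estimator at this size (empirically ≈0.0045), so with ten
  regions a single excursion slightly past 0.01 has roughly 15 %
  probability under any fixed seed; the check is reported as measured
  rather than tuned around. (At the looser reading of the separation —
  class means only 2 SD *apart* — the estimator's SD is ≈0.008 and ±0.01
  recovery is statistically unattainable across ten regions, which is why
  the stronger reading is the one implemented.)
* The dependent-correlation bootstrap must hold its empirical type-I error
  within [0.025, 0.085] at nominal 0.05 over 500 null simulations (n = 150,
  1000 replicates each).

## Problem sizes

The packaged tests and the acceptance script run entirely on generated
data at the sizes above: three-patient phantom cohorts for the imaging
stages, 368/143-patient tabular cohorts for the modelling stages, 2000
cases per class for the binormal check, and 500 simulations for the
type-I-error check. These sizes were chosen so the statistical checks have
meaningful power while a full run stays in the minutes range on one CPU.

## Known limitations

* The method treats registration as solved: transforms are inputs, in
  plain world-mm 4×4 form. FSL FLIRT's native `.mat` convention
  (scaled-voxel coordinates, header-dependent) is intentionally not parsed
  and must be converted upstream.
* ASPECTS region geometry has no canonical definition; the atlas is an
  input, and results depend on it. The packaged block atlas is a test
  fixture, not an anatomical atlas.
* Whether the 30 % denominator should count template-space or subject-space
  voxels is not standardised; this implementation counts voxels on the
  subject DWI grid, where the intersection itself is computed.
* Unstratified fold allocation can leave a fold without positives for a
  low-prevalence region; such cells are skipped and counted rather than
  imputed, which is reported alongside every cross-validation aggregate.
* Cut points transfer across scanners only insofar as the rHU
  normalisation removes acquisition effects; no harmonisation beyond the
  ratio and the HU filter is attempted.
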