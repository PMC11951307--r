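---
title: "Predicting coronary positive remodeling from calcium-scoring CT: methods"
author: "ctcsPR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting coronary positive remodeling from calcium-scoring CT: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcsPR)
```

# The problem

Positive remodeling (PR) — compensatory outward expansion of the coronary
vessel wall around a plaque — is a marker of plaque vulnerability. It is
normally assessed on contrast-enhanced coronary CT angiography, yet many
more patients receive only a non-contrast calcium-scoring scan (CTCS). This
package implements a pipeline that predicts patient-level PR from CTCS-derived
information alone — clinical covariates, Agatston-score-derived features,
and epicardial-fat ("fat-omics") features — and then asks whether the
predicted label stratifies the risk of major adverse cardiovascular events
(MACE) the way the true label does.

# The PR ground truth: remodeling index

For a coronary segment with an outer-diameter profile along its centerline,
the remodeling index is

$$\mathrm{RI} \;=\;
\frac{\max_{\text{plaque span}} d}
     {\tfrac12\!\left(\overline{d}_{\text{proximal ref}}
     + \overline{d}_{\text{distal ref}}\right)},$$

the maximum outer diameter over the plaque divided by the mean of the mean
diameters of the reference segments directly proximal and distal to it. A
segment is PR iff $\mathrm{RI} > 1.1$ — strictly: a plaque exactly 10% above
the reference is *not* PR. A patient is PR if at least one
proximal/mid/distal segment of the LAD, LCX, or RCA is PR. Two design points
were open and are resolved here as follows:

* The plaque-site summary statistic is the **maximum** over the plaque span,
  the usual convention for a "greater than reference" criterion; the
  reference is the unweighted mean of the two interval means.
* The left main is scored for calcium but contributes no PR label; the
  patient rule quantifies over LAD/LCX/RCA only.

Centerline extraction and lumen/wall segmentation are out of scope: diameter
profiles are inputs (`diameterProfile()`), produced in practice by dedicated
plaque-analysis software or, here, synthetically.

# Agatston scoring and derived features

`findLesions()` implements the standard Agatston procedure, which the source
material leaves implicit; each rule is a configurable knob with these
defaults:

| rule | default |
|---|---|
| attenuation threshold | 130 HU |
| in-plane connectivity | 8 (4 available) |
| minimum lesion area | 1 mm² |
| density weight | 1/2/3/4 for peak HU 130–199/200–299/300–399/≥400 |
| slice normalization | × slice thickness / 3 mm |

A lesion on a slice scores `area × weight × thickness/3`; per-vessel scores
sum lesions within an artery territory mask, and `scorePanel()` derives the
feature block: per-vessel and total scores, `log10(score + 1)` (base 10 —
the radiology convention; the published log-score means are consistent with
it but do not uniquely identify the base, so the transform is centralized
and easy to change), the diffusivity index
$1 - \max_v S_v / \sum_v S_v$ (0 when the total is 0; the most affected
vessel *includes* the LM, which is scored like any other vessel), and the
high-CAC flag, strict: total > 1000. Connected-component labeling is a small
compiled routine with a configurable 4/8 neighborhood; the test suite checks
the whole engine against an independent brute-force voxel-enumeration oracle
with a different traversal order on randomized phantoms.

# Fat-omics

Fat-omics features summarize the epicardial adipose tissue (EAT) inside the
pericardium; EAT segmentation itself is out of scope (masks are inputs).
Three families are produced by `extractFeatures()`:

* **Morphological** — volume (voxel count × voxel volume), principal axis
  lengths (4√λ of the voxel-coordinate covariance eigenvalues, in mm), and
  mean/max fat thickness.
* **Intensity** — min/max/mean HU, skewness (moment estimator), and
  histogram-bin probabilities over the adipose window.
* **Spatial** — `SR{k}_Pro_{a}_{b}`: the probability that an EAT voxel in
  ribbon *k* has HU in [−a, −b), for consecutive 20-HU bins; `SS{k}` features
  analogously per slab.

Geometry (`assignSlabsRibbons()`): slabs are four equal-thickness bands of
the slice range the EAT occupies (slab 1 = top). Ribbons are equal-width
bands of Euclidean distance — in mm, respecting anisotropic spacing — from
the pericardial boundary inward, computed against the set of pericardium
voxels adjacent to the exterior; ribbon 1 is outermost. Although the spatial
division is described in the source field as "four equidistant ribbons",
feature names up to `SR5` appear in published importance rankings, so
`n_ribbons` defaults to **5**, outer-first, and is configurable. Outer-first
indexing follows the published association of SR4/SR5 with the outer fat
layers.

Numerical choices worth stating:

* The adipose window defaults to [−190, −30] HU with 20-HU bins — every bin
  named in published feature lists ([−170,−150), [−150,−130), [−90,−70), …)
  falls on this grid. Probabilities are normalized within each nonempty
  ribbon/slab over voxels inside the window, so they sum to 1 there; an
  empty ribbon emits zeros with a warning rather than NaN.
* Fat thickness is measured per slice by casting rays at 1° steps from the
  per-slice pericardial centroid and accumulating the sampled path length
  through EAT (step 0.2 × in-plane spacing). No thickness algorithm is
  prescribed by the source; ray casting matches how EAT thickness is read
  clinically (a radial caliper). It is exact for bands crossed radially,
  and a single-voxel EAT degenerates to the in-plane voxel extent. Because
  the measure is per-slice and in-plane, a spherical cap (rays crossing the
  cap face-on) reads thicker than the band — phantoms used for calibration
  checks therefore use cylinder-like geometry. Sampled rounding at voxel
  boundaries means thickness is reproducible but only translation-invariant
  to ~0.01 mm, unlike every other feature, which is exactly invariant.
* This module guarantees the three families and the named SR features — 90
  features at the defaults — not bitwise parity with any particular
  211-feature catalogue, whose exact membership is not public.

# Synthetic data: what it emulates, and what it does not

**Phantoms** (`generatePhantom()`): an ellipsoidal pericardium whose outer
shell (normalized radius ≥ `eatShellRho`, default 0.75) carries EAT with HU
drawn from a Gaussian mixture restricted to the adipose window; spherical
calcium lesions (uniform or radial-falloff HU) assigned to artery
territories, rasterized by the voxel-center-inside-sphere rule — exactly the
rule the brute-force test oracle mirrors. Lesions below 130 HU peak are
allowed deliberately as negative controls. No cardiac anatomy, gating, or
scanner noise is modeled: phantoms exist to exercise the imaging operators
with known geometry, not to look like hearts.

**Cohorts** (`generateCohort()`): the generator's defaults transcribe
published arm-wise moments — PR prevalence 32.4%; for each of 21 clinical
covariates a normal (mean ± SD) or Bernoulli model per arm, with the BMI ≥ 30
and age-band indicators derived from their continuous draws (23 clinical
features in all); per-vessel Agatston scores via arm-specific normals on the
log10(score + 1) scale clamped at zero (the clamp produces the point mass of
calcium-free patients), from which the 12 derived features follow by the
panel identities. The calibration tables ship as CSVs under `inst/extdata/`
and are honest approximations: **only means/SDs are transcribed; covariates
are drawn independently given the PR label** (cross-covariances are not
published), so multivariate classifiers face an easier problem than on real
data — synthetic AUCs run high and test *machinery*, not clinical
attainability. The fat-omics block has no published moments at all; its
calibration file is labeled synthetic and encodes modest arm shifts in the
direction of the published importance ranking (higher-HU ribbon
probabilities elevated in PR, lipid-dense bins reduced, larger volume).

**Events**: exponential baseline hazard (default 0.02 per person-year —
a realistic MACE rate for a referred chest-pain population) multiplied by
exp(log HR) for PR (default HR 6.5, the published actual-PR association);
administrative censoring at 5 years plus a 10% uniform early-censoring
mechanism. The follow-up distribution of the source cohorts is not
published; this is the simplest model consistent with a fixed recruitment
window.

`plantedCohortSpec()` is the null-clinical variant used by the property
tests: clinical arms share parameters while the imaging blocks keep moderate
separation (0.8 pooled-SD per-vessel log-score shift), so the nested model
ordering Model 1 < Model 2 < Model 3 is attributable to the planted signal.

# Selection, classification, evaluation

* **Elastic net** (`selectFeatures()`, via glmnet): α = 0.5, a path of 100
  log-spaced λ values starting at the value that zeroes every coefficient
  (the solver may stop the path early once deviance saturates), penalty
  chosen by stratified 5-fold CV, features standardized internally.
  Importance is the absolute standardized coefficient; optional bootstrap
  refits at the chosen λ give percentile CIs (500 resamples recommended
  when reporting; tests use fewer).
* **Classifier** (`trainClassifier()`): the default backend is a
  gradient-boosted tree ensemble with iterations 100, learning rate 0.01,
  depth 6, L2 leaf regularization 3, per-tree feature subsampling 0.75, 64
  histogram bins, logloss, Bernoulli row subsampling 0.6, one thread.
  Random-forest, RBF-SVM, and a conventionally tuned boosted-tree backend
  are available for model comparison. Missing values are median-imputed
  with medians fit on training data only.
* **Cross-validation** (`crossValidate()`): repeated stratified 5-fold CV.
  The operating threshold for sensitivity/specificity is 0.5 on the
  predicted probability — the only parameter-free choice, since no
  operating point is published. By default feature selection is **re-run
  inside each training fold** (leak-free); `selection = "once"` reproduces
  the alternative reading in which selection precedes CV, and
  `selection = "none"` disables it. Repetitions default to 25 at the desk
  scale; 1000 is available. Tests and examples in this package use 1–5
  repetitions on cohorts of 200–600 patients — sizes chosen so the full
  suite, including 200 survival-recovery cohorts of n = 2000 and 40 seeded
  nested-model runs, completes in a few minutes.
* **Comparison** (`compareModels()`): McNemar's χ² without continuity
  correction on discordant correct/incorrect pairs (p = 1 when no pair is
  discordant), and DeLong's paired test on the AUC difference. Evaluations
  are reduced to per-patient mean out-of-fold scores.

# Survival

`kmFit()` and `coxFit()` wrap the survival package: product-limit curves
with log-log 95% bands and the log-rank test; Cox partial likelihood with
**Efron** tie handling (Breslow available), Wald CI, Harrell's C. Complete
separation (all events in one arm, or a monotone likelihood) is an explicit
error, never a silently diverged fit. Stratification for the KM comparison
defaults to the binary predicted label; a median-risk split of the
continuous score is available (`split = "median-risk"`), reflecting two
descriptions of the published analysis. The reported C-index is that of the
fitted binary covariate; with a binary predictor Harrell's C is bounded
below 1 by tied-predictor pairs, which is why a strong HR of 6.5 coexists
with C ≈ 0.7.

# Conventions, degenerate inputs, limitations

* Voxel indices are 0-based in world coordinates: position = index ×
  spacing (mm); the slice axis is the third array axis, and `readVolume()`
  canonicalizes permuted NIfTI inputs. Missing spacing metadata is an
  error, never assumed 1 mm.
* Determinism: every randomized stage consumes an explicit seed; identical
  spec + seed reproduces phantoms, cohorts, folds, and fitted scores
  bit-exactly.
* Degenerate inputs have defined behavior throughout: empty EAT masks,
  empty ribbons, constant features, all-zero score panels, cohorts without
  events, single-class folds — each either errors with a named cause or
  returns the documented convention (see the operation help pages).
* The main limitations are inherited from what is not public: real
  covariate correlations, the exact fat-omics catalogue, the follow-up
  distribution, and the operating threshold. Each is a documented,
  configurable assumption rather than a hidden constant.
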