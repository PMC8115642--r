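---
title: "Washout-index analysis of breast DCE-MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Washout-index analysis of breast DCE-MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(washoutMRI)
```

## The model

A three-phase DCE study measures each region of interest three times:
before contrast (`SI_pre`), at 1–2 minutes (`SI_early`) and at 5–6
minutes (`SI_delay`). The washout index

$$WI = \frac{SI_{early} - SI_{delay}}{SI_{pre}} \times 100\,\%$$

is a semi-quantitative summary of delayed-phase washout, normalised by
the pre-contrast signal so that it is invariant to joint rescaling of
all three signals (receiver gain, windowing). It makes no
pharmacokinetic assumptions — no arterial input function, no Tofts
model — which is exactly its appeal for multi-protocol retrospective
material: it only requires the standard three-timepoint DCE acquisition.

A lesion is a *fast-washout curve type* when the initial enhancement
ratio $SI_{early}/SI_{pre} \times 100$ strictly exceeds 200 % **and**
$WI \ge 10$ %. The strict/inclusive asymmetry is deliberate and tested:
a ratio of exactly 200 % is *not* fast washout, a WI of exactly 10 %
(with ratio above 200 %) *is*. The complement ("other") is everything
else — including plateau and persistent patterns; the package does not
subdivide them, because the downstream analyses only use the binary
split. Negative WI is a legal value meaning persistent enhancement, not
an error; it is itself a predictor (below).

Both thresholds are arguments of `kinetic_thresholds()` with the
conventional defaults, so sensitivity analyses can move them without
touching any classification code.

## ROI search geometry

Readers in practice place multiple small ROIs inside a lesion and keep
the highest WI. `lesion_max_wi()` replaces that manual search by an
exhaustive one:

* the ROI is a **flat disc** of diameter 3 mm (default) within a single
  slice; membership is *voxel-centre within radius* of the centre
  voxel's centre, using the two in-plane voxel spacings (anisotropic
  grids supported); a $10^{-9}$ mm tolerance guards exact-boundary
  floating-point comparisons;
* a placement is valid only when **every** member voxel is inside the
  lesion mask — full containment prevents partial-volume contamination
  from outside the lesion;
* slices are taken from **all three orthogonal plane families**
  (axial-only via `planes = "axial"`), since reading workstations allow
  reformatted planes;
* the per-phase ROI signal is the arithmetic mean of the member voxels,
  and WI is maximised over all placements; **ties** are broken by the
  deterministic enumeration order (plane, slice, row, column — first
  wins), so results are bit-stable;
* placements whose mean pre-contrast signal is non-positive are skipped
  with a warning (they indicate corrupted or out-of-body signal).

Lesions too small to contain any disc signal a `washout_no_placement`
condition by default, mirroring the exclusion of undersized lesions in
practice; `fallback = "voxel"` instead degrades to single-voxel ROIs.

World coordinates are `index × spacing` on an axis-aligned grid; oblique
volumes must be resampled upstream. Grid compatibility (shape and
spacing per axis) is validated whenever phases and mask meet.

The lesion **longest diameter** is the maximal in-plane Feret diameter —
the largest centre-to-centre distance between two mask voxels within any
single slice — maximised over the three plane families, matching a
longest-diameter measurement on reformatted planes. Centre-to-centre is
the simplest defensible convention (a single voxel has diameter 0) and
is stated here so fixtures are reproducible. RECIST categories follow
from baseline/follow-up diameters with inclusive thresholds (−30 % for
PR, +20 % for PD, follow-up 0 for CR) and PD tested before PR; the
baseline for both on-treatment responses is the pre-treatment MRI.

The **shrinkage-pattern proxy** classifies a partial responder as
*dendritic* when the follow-up mask has more 26-connected components
than baseline (fragmentation) or is not contained in the baseline mask
eroded by a 2 mm ball (uneven, boundary-hugging shrinkage), and
*concentric* otherwise. This is a computational proxy for a visual
call; the erosion radius is configuration, and the proxy is validated
only against constructed geometries (concentric spheres, fragmented
foci, crescents), not against reader judgments.

## Imaging predictors and grouping

Two per-timepoint predictors of pathological response are evaluated:

* `size = 0` — no residual enhancing lesion;
* `WI < 0 or size = 0` — the lesion has vanished **or** shows no washout
  at all in the delayed phase (strictly negative WI; WI exactly 0 does
  not qualify).

The size rule is strictly weaker than the combined rule (a property
test enforces this). For survival, patients split into three groups at a
timepoint: complete response on MRI (`cr_mri`), residual lesion with
fast washout (`rd_fast_washout`), residual lesion with any other curve
type (`rd_other`). "Residual" is *radiological* residual enhancing
lesion — a curve type only exists for enhancing lesions — which is one
of the genuinely open readings of the source material; the pathological
columns (RCB class, pCR) are kept independent inputs, with no
cross-constraint enforced between pCR and RCB class 0.

## Statistical conventions

* **Fisher's exact test** (2×2, two-sided) uses the
  sum-of-small-probabilities definition: the sum of hypergeometric
  probabilities not exceeding the observed table's (relative tolerance
  $10^{-7}$ for float ties). This is the definition in base R and in
  the clinical software generation the analyses mirror; the test suite
  cross-checks it against full enumeration for tables up to n = 40.
  Degenerate margins return p = 1 with a warning.
* **ICC** is ICC(2,1) — two-way random effects, absolute agreement,
  single rater — computed from the ANOVA mean squares. The agreement
  categories apply boundaries as printed, with exact boundary values in
  the lower-named category: < 0.50 poor, [0.50, 0.75] moderate,
  (0.75, 0.90] good, > 0.90 excellent. The form is a choice (the
  consistency ICC is a defensible alternative); absolute agreement is
  the stricter and more common reporting choice for measurement
  agreement.
* **Spearman correlation** is the Pearson correlation of mid-ranks with
  the large-sample t approximation for p (exact permutation p-values
  are out of scope); constant input is undefined, not 0.
* **t-tests** are pooled-variance Student by default (`var_equal =
  FALSE` gives Welch); zero pooled variance is undefined, signalled
  with a warning.
* **Survival**: Kaplan–Meier product-limit estimation (censoring at an
  event time processed after the events), K-group log-rank with
  $\chi^2_{K-1}$ reference, and Cox partial likelihood with **Efron**
  tie handling (Breslow via argument) — ties are expected with coarse
  follow-up granularity, and Efron is the more accurate approximation.
  Wald 95 % CIs as $\exp(\hat\beta \pm 1.96\,SE)$. Complete separation
  (all events in one group — which genuinely occurs when a group has
  0/21 events) is reported as non-convergence rather than a finite HR.
  Five-year survival is read off the KM curve at the largest event time
  ≤ 5 years.
* Reports round percentages to 1 decimal and p-values to 4 decimals;
  all internal computation is full precision.

## Synthetic data: what it does and does not emulate

`simulate_phantom()` builds three-phase volumes from kinetic *templates*
(`si_pre`, enhancement ratio %, WI %): a non-enhancing tissue
background, a lesion sphere, and optional disjoint spherical subregions
such as a planted fast-washout focus. Gaussian noise is added per phase
under counter-based child seeds (one master seed fans out; adding a
generator never perturbs existing streams). Because ROI means of
constant templates are exact, a noise-free phantom whose top-WI region
can host a disc is recovered *exactly* by the search — this, plus
equality with a brute-force oracle on random phantoms, is the core
image-domain validation. The phantoms deliberately omit MRI physics:
no Rician bias, coil profiles, motion, or partial-volume blur.

`simulate_cohort()` draws per-patient tables: RCB class with
probabilities (0.324, 0.230, 0.365, 0.081) and pCR ≡ RCB 0; RCB index
within the class bands (cut-points 1.36, 3.28); lesion morphology
probabilities (0.743, 0.108, 0.149); a latent "aggressive" profile in
35 % of residual-disease patients that drives persistently high WI and
fast-washout ratios; truncated-normal WI per timepoint (pCR centred
near 0 and negative by mid-treatment, aggressive residual disease
strictly positive post-treatment — read qualitatively from the group
separation such cohorts show; these are *illustrative configuration,
not estimates*); lesion sizes shrinking by group with size-0
probabilities at mid/post chosen to match the size-only predictor's
sensitivity; and exponential DDFS with hazards 0.003 / 0.07 / 0.007 per
year for `cr_mri` / `rd_fast_washout` / `rd_other` — a planted hazard
ratio of 0.10 between residual disease without and with fast washout,
with implied five-year survival of about 97 % and 70 % in the two
residual-disease groups — under uniform censoring on (0.67, 12.5)
years, the observation window such a cohort spans. Curve types are
*derived* from the sampled (ratio, WI) through the real classifier, so
the generator cannot drift from the classification rule.

What passing tests on this cohort show: the pipeline's statistics
recover the quantities the generator planted, at the planted effect
sizes. What they do not show: that real lesions obey truncated-normal
WI distributions, that real DDFS is exponential, or anything about
scanner- or protocol-level variability.

`reference_fixtures()` bundles six 2×2 stratified count tables reported
for the motivating cohort and six *reconstructed* confusion matrices. The reconstructions
were derived by hand so that each reproduces all five reported
percentages of its diagnostic-performance row simultaneously at
one-decimal rounding; the suite re-verifies that arithmetic. They are
labelled reconstructed because the underlying per-patient data are not
published; a different matrix reproducing the same five rounded
percentages cannot be fully excluded, but the stated one is consistent
with the per-analysis sample sizes.

## Validation problem sizes

The suite validates: ROI search ≡ brute force on 100 random phantoms up
to 26 voxels per axis (with and without noise, isotropic and
anisotropic); Fisher ≡ enumeration for random tables to n = 40; KM
against a hand-worked product-limit table; Cox calibration at n = 2000
(point recovery of log HR 0.10 within 3 SE), Wald CI coverage over 200
cohorts of n = 400 at a ~40 % event rate, and log-rank type-I error
over 10⁴ null replicates of n = 100; cohort marginals at n = 10⁵.
These sizes keep the full suite under a minute while leaving
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Masks are inputs; the package does not segment lesions, register
  phases or timepoints, or handle oblique grids.
* Size and kinetics use one mask per timepoint, whereas practice may
  measure size on a separate high-resolution contrast sequence.
* The shrinkage-pattern proxy approximates a visual judgement.
* Multivariate Cox, competing risks and multiple-testing correction are
  out of scope (the source analyses applied none).
* The exhaustive ROI search is a superset of any manual placement:
  reported maxima can exceed what readers placing a handful of ROIs
  would find, especially under noise (a max-over-placements is biased
  upward; the phantom tests quantify this on synthetic data).
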