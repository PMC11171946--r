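---
title: "Dynamic perviousness: model, phantom, and synthetic-cohort methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic perviousness: model, phantom, and synthetic-cohort methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynperv)
```

## The biomarker

Thrombus perviousness measures how much iodinated contrast penetrates an
occlusive clot between CT acquisitions, and is thought to reflect the clot's
histological density and therefore its behaviour under mechanical
thrombectomy. The *standard* perviousness (SP) biomarker is a single number:
the thrombus attenuation increase (TAI) from non-contrast CT (NCCT) to
arterial-phase CT angiography (CTA),

$$\mathrm{SP} = \bar{H}_{\mathrm{CTA}} - \bar{H}_{\mathrm{NCCT}},$$

where $\bar{H}$ is the mean clot density in Hounsfield units (HU), averaged
over three 1 mm regions of interest (ROIs) placed along the clot. SP ignores
everything that happens after the arterial phase: clots that take up contrast
slowly, and clots that release it quickly, are indistinguishable.

*Dynamic* perviousness adds a late venous-phase acquisition (CTV) and works
with the three pairwise density changes

$$\Delta_{NA} = \bar{H}_{\mathrm{CTA}} - \bar{H}_{\mathrm{NCCT}}, \qquad
  \Delta_{NV} = \bar{H}_{\mathrm{CTV}} - \bar{H}_{\mathrm{NCCT}}, \qquad
  \Delta_{AV} = \bar{H}_{\mathrm{CTV}} - \bar{H}_{\mathrm{CTA}},$$

which satisfy $\Delta_{NV} = \Delta_{NA} + \Delta_{AV}$ identically. With an
enhancement threshold $\tau$ (default 5 HU) the enhancement curve falls into
one of four patterns:

| pattern | meaning | rule |
|---|---|---|
| `C_NE` | no enhancement | $\Delta_{NA} \le \tau$ and $\Delta_{NV} \le \tau$ |
| `C_LE` | late enhancement | $\Delta_{NA} \le \tau$ and $\Delta_{NV} > \tau$ |
| `C_W`  | early enhancement, washout | $\Delta_{NA} > \tau$ and $\Delta_{AV} \le -\tau$ |
| `C_NW` | early enhancement, no washout | $\Delta_{NA} > \tau$ and $\Delta_{AV} > -\tau$ |

### Boundary conventions

The verbal definitions of the four patterns ("maximum increase of 5 HU",
"minimum decrease of 5 HU") overlap at exactly 5 HU, so the package fixes
inclusive boundaries on the non-enhancing and washout sides:
$\Delta_{NA} = \tau$ is *not* early enhancement, and $\Delta_{AV} = -\tau$
*is* washout. With these conventions the four rules form a true partition of
the $(\Delta_{NA}, \Delta_{AV})$ plane -- exactly one rule fires for every
input, which the test suite asserts over $10^5$ random delta pairs.

Two further choices were genuinely open:

* **`C_NE`'s "no enhancement over all phases"** is interpreted as constraints
  on the two NCCT-referenced deltas only. A clot with
  $\Delta_{NA} \le \tau$, $\Delta_{NV} \le \tau$ but a CTA$\to$CTV rise
  greater than $\tau$ is still `C_NE`: the late-enhancement split is defined
  purely in NCCT-referenced terms, and any other reading would break the
  partition property.
* **No rounding before comparison.** Densities and deltas are compared as
  floating point; display precision never influences the category.

`classify_dynamic()` exposes $\tau$ for sensitivity analysis. Raising it
collapses categories into `C_NE` (at $\tau = 50$ HU most clots are
"non-enhancing"), which the pipeline tests exploit as a sanity check.

## The digital phantom

The measurement procedure -- three 1 mm ROIs placed along the clot, averaged
per phase -- is emulated on synthetic volumes by `simulate_phantom()`. The
phantom is a brain-density background (35 HU) containing a contrast-filled
vessel along the x axis and a clot segment of configurable length (>= 3 mm,
the shortest clot the procedure supports) and radius. Clot voxels take the
requested per-phase HU plus optional white Gaussian noise; the patent lumen
takes phase-typical contrast values (about 45/350/200 HU) so that
misplacement of an ROI is immediately visible in the numbers.

Conventions, chosen for lack of any stated convention in clinical PACS
measurements: axis-aligned grids with the world origin at the volume corner,
voxel centres at $(i - \tfrac12)\,s$ for spacing $s$, sphere membership by
voxel centre, and 3D spherical ROIs (the clinical description "a size of
1 mm" does not say whether the ROIs were 2D circles on a reformatted plane;
spheres are the natural 3D reading). Default spacing is 0.5 mm isotropic,
finer than the 0.8 mm voxel-quality bar the clinical protocol enforces.

All three phases are generated on one grid, which stands in for the
proprietary 3D co-registration step of the clinical workflow; misalignment
can be injected explicitly as an integer-voxel shift of the CTA/CTV volumes.

`place_rois()` finds the clot's principal axis, measures the spanned length
(voxel-centre span plus one voxel, so a 3 mm clot measures 3 mm), and places
ROI centres at fractions $(i - \tfrac12)/n$ of that length -- the midpoints
of the proximal, middle, and distal thirds for $n = 3$. Centres are local
centroids of nearby clot voxels and are snapped to the nearest clot voxel if
a bend pushes the centroid outside the mask, so centres always lie inside
the clot. A clot shorter than $n$ ROI diameters raises a placement error; a
3 mm clot exactly fits three 1 mm ROIs. `mean_roi_density()` averages voxels
within each sphere and then averages the ROI means (not the pooled voxels),
matching the manual workflow.

On noiseless phantoms the round trip *measure $\to$ TAI $\to$ classify* is
exact for each published group-mean triplet. At a realistic 5 HU noise level
the three-ROI average pools roughly 21 voxels per phase, giving a standard
error near 1 HU per phase; triplets at least 10 HU from every decision
boundary essentially never misclassify (the Monte-Carlo test over 500 seeded
phantoms requires < 5% and observes ~0%).

## The synthetic cohort

No patient-level data are released with the study this package
operationalises, so every statistical stage is verified against a generator
whose defaults *are* the published group summaries: four enhancement groups
of sizes 49/22/37/29 (`C_NE`/`C_NW`/`C_W`/`C_LE`), per-group per-phase
density means and SDs, recanalization probabilities 39/49, 15/22, 29/37,
26/29, per-group mean pass counts 2.5/2.7/2.0/2.6, admission NIHSS means
13.5/17.0/12.2/13.6, and the observed missingness totals (26 deaths before
discharge, 35 additional patients without 3-month mRS, 10 without an
intervention, leaving the complete-case denominators 111 and 76 the clinical
models see).

Design of the joint distribution, where the publication gives only
marginals:

* **Densities** are drawn independently Gaussian per phase within group --
  no covariances are published -- and rejection-sampled until the classifier
  reproduces the intended label. The stored category is therefore exact by
  construction; the price is that *conditional* group means drift from the
  nominal marginal means (conditioning on the category truncates the
  Gaussians). Tests that need exact means use near-degenerate SDs instead.
  A category unreachable from its mean/SD configuration raises a
  configuration error after a bounded number of rejection rounds.
* **Pass counts** are $1 + \mathrm{Poisson}(m - 1)$ capped at 9, supported
  on the observed 1..9 range. The capped-mean ratio, computed by direct
  summation, is the closed-form truth for Poisson-recovery tests.
* **Discharge NIHSS** is admission NIHSS plus a group shift plus Gaussian
  noise (SD 4), rounded and clamped to 0-42; **3-month mRS** is admission
  mRS (Gaussian around 4.5, SD 1.2 -- severe strokes at presentation) plus
  an overall -0.6 shift plus a group shift plus noise (SD 1.2), clamped to
  0-6. This makes the baseline-adjusted linear models well-specified up to
  clamping, which at these settings affects a few percent of patients and
  biases group contrasts by well under one Monte-Carlo standard error. The
  default group shifts are the published point estimates
  (-1.24/0/-1.17/-3.05 for NIHSS, -0.15/0/-0.85/-1.30 for mRS, reference
  `C_NW`), so recovery studies exercise effect sizes of the magnitude the
  study reports -- the package recovers *its own injected truth*; it does
  not claim to reproduce the patient-level coefficients, which are not
  reproducible without the unreleased data.
* **Missingness** is assigned uniformly at random within the stated totals
  (only totals are published). Deaths lose both discharge NIHSS and 3-month
  mRS; the additional mRS losses are drawn from survivors.
* **One global seed** drives every draw through R's single generator
  stream, so cohorts are bytewise reproducible per seed.

One deliberate infidelity: admission NIHSS is generated per-group Gaussian
from the published group means/SDs, which cannot simultaneously reproduce
the published severity-band proportions (the real NIHSS distribution is
non-normal, median 15 with IQR 9-18). The per-group calibration was kept
because the regression stages condition on it; the severity banding itself
(minor 0-4, moderate 5-15, moderate-severe 16-20, severe 21+ -- the
non-overlapping convention, where the running text of the source study is
internally inconsistent) is tested as a partition of 0-42. Time metrics,
thrombolysis co-treatment, and scanner mix are not modelled.

## The outcome models

`dp_analysis()` fits, with `C_NW` (early enhancement without washout) as the
default reference:

* **Logistic** regression of technical success -- defined as a TICI grade of
  2c or 3 -- on the category, plain and optionally clot-length-adjusted.
  Exponentiated coefficients are odds ratios; with a single categorical
  predictor they equal the 2x2 cross-product ratios
  $\mathrm{OR} = (a d)/(b c)$, and `odds_ratio_2x2()` is kept as the
  independent closed-form oracle (agreement to $10^{-6}$ relative tolerance
  is a standing test). On the published success counts the model yields ORs
  1.82 (`C_NE`), 1.69 (`C_W`), and 4.04 (`C_LE`).
* **Logistic** regression of success on the *continuous* SP deltas
  ($\Delta_{NA}$, $\Delta_{NV}$), the comparator analysis; per-HU odds
  ratios.
* **Linear** regression of discharge NIHSS (and of 3-month mRS, treated as
  numeric -- the source analysis reports betas on mRS, and ordinal
  alternatives are out of scope) on the category, adjusting for the
  admission score. Complete-case, mirroring clinical follow-up attrition.
* **Poisson** regression of pass counts on the category, excluding patients
  without an intervention; unadjusted (no covariate is stated for this
  model), so rate ratios equal ratios of group sample means -- the second
  oracle equivalence.

Interval convention: Wald on the link scale by default (t-based for the
linear model), with profile-likelihood optional for the logistic fits. The
published intervals (e.g. 0.97-21.02 around an OR of 4.04) are not Wald and
their method is unstated, so only point estimates are treated as
reproducible; the Wald choice is validated instead by empirical coverage --
over 500 simulated cohorts at 10x the study size the 95% interval for the
`C_LE` odds ratio covers the true value 93-97% of the time. Degenerate
inputs are diagnosed, not smoothed over: complete separation errors name
the offending category, zero 2x2 cells are reported as explicitly infinite
or zero odds ratios (a Haldane-Anscombe 0.5 correction is available behind
a flag), constant predictors error, and categories with no observed
outcomes are dropped with a warning. p-values are two-sided Wald tests,
rounded to two significant figures only at print time.

## Problem sizes and reproducibility

The verification suite works at the study's own sizes: 137-patient cohorts
for pipeline checks, 10x (1370 patients) for effect recovery with 200
seeded replicates for the linear and Poisson stages, 500 replicates for
interval coverage, $10^5$ random delta pairs for the partition property,
and 500 noisy phantoms for classification robustness. These sizes put
Monte-Carlo noise well below the effects being checked while keeping the
default test run inside a couple of minutes on one CPU.

`run_pipeline()` chains simulate $\to$ classify $\to$ analyze $\to$ report
and writes CSVs and a markdown report with no timestamps, so a fixed seed
and configuration reproduce byte-identical outputs; the seed is recorded in
the report header.

## Known limitations

The phantom has no beam hardening, partial-volume blur, or deformable
misregistration, and its noise is white Gaussian rather than CT-textured;
passing phantom tests demonstrates correctness of the measurement geometry
and averaging, not robustness to scanner physics. The cohort generator's
independence assumptions (densities across phases within group, outcomes
conditionally independent given group) are conveniences, not claims about
stroke biology; parameter-recovery results certify the estimation
machinery, not clinical effect sizes. Pass counts are equidispersed by
construction while the published SDs suggest overdispersion, so
Poisson-model standard errors on real data should be read with that in
mind.
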