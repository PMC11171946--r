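# dynperv

Dynamic perviousness analysis of acute-ischemic-stroke thrombi from
three-phase CT.

## What this is for

When a large cerebral vessel is occluded, pre-treatment CT can probe the
clot itself: contrast material penetrates a permeable ("pervious") thrombus
and raises its measured density. The classical biomarker, **standard
perviousness (SP)**, is the thrombus attenuation increase (TAI) between
non-contrast CT (NCCT) and arterial-phase CT angiography (CTA),

    SP = H(CTA) − H(NCCT)          [HU, mean clot density]

and has produced contradictory outcome associations — partly because a
single early time point misses slow uptake and fast washout. **Dynamic
perviousness (DP)** adds a late venous-phase acquisition (CTV) and
classifies the enhancement *curve*, using all three pairwise changes
Δ_NA, Δ_NV, Δ_AV (with Δ_NV = Δ_NA + Δ_AV) and a 5 HU threshold τ:

| category | pattern | rule |
|---|---|---|
| `C_NE` | no enhancement              | Δ_NA ≤ τ and Δ_NV ≤ τ |
| `C_LE` | late enhancement            | Δ_NA ≤ τ and Δ_NV > τ |
| `C_W`  | early enhancement, washout  | Δ_NA > τ and Δ_AV ≤ −τ |
| `C_NW` | early enhancement, no washout | Δ_NA > τ and Δ_AV > −τ |

The four rules partition the delta plane. The category is then related to
mechanical-thrombectomy outcomes with conventional models (reference
`C_NW`): logistic regression for technical success (TICI 2c/3), linear
regression for discharge NIHSS and 3-month mRS adjusting for the admission
score, and Poisson regression for the number of retrieval passes.

The package is aimed at neuroimaging/stroke researchers who want to apply
or stress-test the DP classification: it bundles the classifier, a digital
three-phase CT phantom with the three-1-mm-ROI measurement procedure, a
synthetic cohort generator calibrated to the published group summaries, the
regression stages with closed-form oracles, an auditable
inclusion/exclusion flow, and a seed-reproducible end-to-end pipeline.

## Worked example

```r
library(dynperv)

# TAI deltas for the cohort-mean densities (NCCT, CTA, CTV)
d <- compute_tai(64.4, 74.4, 71.2)
d
#>   delta_na delta_nv delta_av
#> 1       10      6.8     -3.2
classify_dynamic(d)
#> [1] C_NW
#> Levels: C_NE C_NW C_W C_LE

# a synthetic 137-patient cohort and the full outcome analysis
co <- simulate_cohort(seed = 42)
fit <- dp_analysis(co)
fit
#> Dynamic perviousness outcome analysis (reference: C_NW, n = 137)
#>
#> logistic
#>  term estimate ci_low ci_high p_value
#>  C_NE     1.76  0.595    5.22   0.310
#>   C_W     1.35  0.441    4.13   0.600
#>  C_LE     4.95  1.130   21.70   0.034
#> ...
#> linear (nihss_discharge)
#>  term estimate ci_low ci_high p_value
#>  C_NE   -0.215  -2.49    2.06  0.8500
#>   C_W   -0.191  -2.60    2.22  0.8800
#>  C_LE   -3.930  -6.40   -1.45  0.0021
#> ...
```

Read: in this simulated replicate, late-enhancing clots (`C_LE`) have about
5-fold odds of complete recanalization versus early-enhancing clots without
washout (`C_NW`), and leave discharge NIHSS about 4 points lower at equal
admission severity — the qualitative pattern the generator injects, with
sampling noise at n = 137.

On the *published* success counts (39/49, 15/22, 29/37, 26/29) the same
logistic stage returns odds ratios 1.82 (`C_NE`), 1.69 (`C_W`) and 4.04
(`C_LE`), identical to the 2×2 cross-product oracle.

Phantom-based measurement, for testing the ROI geometry end to end:

```r
ph   <- simulate_phantom(c(62.5, 73.1, 78.2), clot_length = 18, noise_sd = 5, seed = 1)
rois <- place_rois(ph, n = 3, diameter = 1)       # proximal/middle/distal thirds
mean_roi_density(ph, rois)                        # -> ncct_hu, cta_hu, ctv_hu
```

An end-to-end run writing `cohort.csv`, `results.csv` and `report.md`
(byte-identical across runs of the same seed):

```r
run_pipeline("results/run1", seed = 7)
```

A thin command-line wrapper over these functions is in
`inst/scripts/dynperv.R` (subcommands `simulate`, `classify`, `measure`,
`analyze`, `flow`, `run`).

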