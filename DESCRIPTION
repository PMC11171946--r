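Package: dynperv
Title: Dynamic Perviousness Analysis of Stroke Thrombi from Three-Phase CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the dynamic perviousness of occlusive
    thrombi in acute ischemic stroke from three-phase computed tomography
    (non-contrast CT, arterial-phase CT angiography, and late venous-phase
    CT). Computes thrombus attenuation increase (TAI) between phases,
    classifies clots into four contrast-enhancement patterns (no enhancement,
    late enhancement, early enhancement with washout, early enhancement
    without washout), and relates the pattern to mechanical thrombectomy
    outcomes via logistic, linear, and Poisson regression with Wald
    intervals. Includes a digital three-phase CT phantom with 1 mm
    region-of-interest sampling along the clot, a synthetic patient cohort
    generator calibrated to published group summaries for end-to-end
    verification without patient data, an auditable inclusion/exclusion flow,
    and a reproducible simulate-measure-classify-analyze pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
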