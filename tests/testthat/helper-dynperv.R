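# Published per-group column means (NCCT, CTA, CTV) and the group each
# triplet must classify into; used across classifier, phantom, and
# acceptance tests.
table2_triplets <- function() {
  data.frame(
    group = c("C_NE", "C_NW", "C_W", "C_LE"),
    ncct_hu = c(68.6, 62.5, 61.3, 62.5),
    cta_hu = c(67.0, 73.1, 95.3, 61.4),
    ctv_hu = c(68.7, 78.2, 68.5, 79.8),
    stringsAsFactors = FALSE
  )
}

# Published study-flow exclusion counts, applied to 475 screened patients.
exclusion_steps <- function() {
  c("unsuitable thrombus" = 84,
    "MRI instead of CT" = 54,
    "external imaging not stored" = 81,
    "no late venous phase" = 46,
    "no unenhanced series" = 9,
    "motion artefact or low resolution" = 43,
    "no consent" = 21)
}

# Published recanalization successes / group sizes per category.
recan_counts <- function() {
  data.frame(group = c("C_NE", "C_NW", "C_W", "C_LE"),
             success = c(39, 15, 29, 26),
             n = c(49, 22, 37, 29),
             stringsAsFactors = FALSE)
}

# Expand success counts into a patient-level frame for the logistic fit.
cohort_from_counts <- function(counts = recan_counts()) {
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    data.frame(
      dp_category = counts$group[i],
      success = rep(c(TRUE, FALSE),
                    c(counts$success[i], counts$n[i] - counts$success[i])),
      stringsAsFactors = FALSE
    )
  }))
}

# Expected mean of the generator's pass-count model, 1 + min(Pois(m - 1), 8),
# by direct summation: the closed-form oracle for Poisson rate-ratio truth.
capped_passes_mean <- function(m, cap = 9) {
  k <- 0:200
  1 + sum(pmin(k, cap - 1) * stats::dpois(k, m - 1))
}
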