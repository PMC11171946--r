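#' Parameters for the synthetic thrombectomy cohort
#'
#' Returns the full parameter set of the cohort generator, calibrated by
#' default to the published per-group summaries of a 137-patient
#' three-phase-CT thrombectomy cohort: four enhancement groups of sizes
#' 49/22/37/29 (C_NE/C_NW/C_W/C_LE), per-group per-phase clot density means
#' and SDs, recanalization probabilities 39/49, 15/22, 29/37, 26/29,
#' per-group retrieval-pass means, admission NIHSS distributions, and the
#' observed missingness totals (26 deaths before discharge, 35 additional
#' patients without 3-month mRS, 10 without an intervention). Any component
#' can be overridden through `...`.
#'
#' Group effects on the clinical outcomes are the generator's ground truth
#' for parameter-recovery studies: discharge NIHSS is admission NIHSS plus a
#' group shift plus Gaussian noise (clamped to 0-42 and rounded), 3-month
#' mRS is admission mRS plus an overall shift plus a group shift plus noise
#' (clamped to 0-6), and pass counts are `1 + Poisson(mean - 1)` capped at
#' 9 passes.
#'
#' @param ... Named overrides of any default component.
#' @return A list of class `cohort_params`.
#' @examples
#' p <- cohort_params(group_sizes = c(10, 10, 10, 10))
#' p$recan_prob
#' @export
cohort_params <- function(...) {
  g <- DP_LEVELS   # C_NE, C_NW, C_W, C_LE
  p <- list(
    group_labels = g,
    group_sizes = stats::setNames(c(49, 22, 37, 29), g),
    # per-group per-phase clot density, HU
    phase_mu = matrix(c(68.6, 67.0, 68.7,
                        62.5, 73.1, 78.2,
                        61.3, 95.3, 68.5,
                        62.5, 61.4, 79.8),
                      nrow = 4, byrow = TRUE,
                      dimnames = list(g, c("ncct", "cta", "ctv"))),
    phase_sd = matrix(c(8.1, 8.7, 8.2,
                        9.6, 9.8, 14.6,
                        10.8, 31.1, 13.4,
                        7.9, 8.1, 16.6),
                      nrow = 4, byrow = TRUE,
                      dimnames = list(g, c("ncct", "cta", "ctv"))),
    recan_prob = stats::setNames(c(39 / 49, 15 / 22, 29 / 37, 26 / 29), g),
    passes_mean = stats::setNames(c(2.5, 2.7, 2.0, 2.6), g),
    passes_cap = 9,
    clot_len_mu = stats::setNames(c(18.9, 20.2, 14.7, 19.9), g),
    clot_len_sd = stats::setNames(c(9.4, 11.4, 8.1, 13.0), g),
    clot_len_range = c(3, 61),
    age_mu = stats::setNames(c(70.2, 78.0, 71.5, 75.5), g),
    age_sd = stats::setNames(c(15.9, 12.3, 13.8, 12.1), g),
    female_prop = 0.41,
    site_probs = c(ICA = 43, M1 = 69, M2 = 19, BA = 6) / 137,
    nihss_admit_mu = stats::setNames(c(13.5, 17.0, 12.2, 13.6), g),
    nihss_admit_sd = stats::setNames(c(6.9, 6.9, 6.3, 5.5), g),
    # true group shifts (reference C_NW) driving the outcome models
    nihss_effect = stats::setNames(c(-1.24, 0, -1.17, -3.05), g),
    nihss_resid_sd = 4,
    mrs_admit_mu = 4.5,
    mrs_admit_sd = 1.2,
    mrs_shift = -0.6,
    mrs_effect = stats::setNames(c(-0.15, 0, -0.85, -1.30), g),
    mrs_resid_sd = 1.2,
    n_deaths = 26,
    n_missing_mrs = 35,
    n_no_intervention = 10,
    tau = 5,
    max_reject_rounds = 1000
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown cohort parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  if (any(p$recan_prob < 0 | p$recan_prob > 1)) {
    stop("'recan_prob' must lie in [0, 1]", call. = FALSE)
  }
  if (any(p$group_sizes < 0)) stop("group sizes must be >= 0", call. = FALSE)
  if (any(p$phase_sd <= 0)) stop("phase SDs must be > 0", call. = FALSE)
  class(p) <- "cohort_params"
  p
}

# rejection-sample n density triplets from independent per-phase Gaussians,
# conditioned on classifying into `label`; vectorised over patients
.draw_group_densities <- function(n, mu, sd, label, tau, max_rounds) {
  out <- matrix(NA_real_, n, 3)
  need <- seq_len(n)
  rounds <- 0L
  while (length(need) && rounds < max_rounds) {
    m <- length(need)
    x <- cbind(stats::rnorm(m, mu[1], sd[1]),
               stats::rnorm(m, mu[2], sd[2]),
               stats::rnorm(m, mu[3], sd[3]))
    d <- compute_tai(x[, 1], x[, 2], x[, 3])
    ok <- classify_dynamic(d, tau = tau) == label
    if (any(ok)) {
      out[need[ok], ] <- x[ok, , drop = FALSE]
      need <- need[!ok]
    }
    rounds <- rounds + 1L
  }
  if (length(need)) {
    stop("configuration error: category ", label,
         " unreachable under the supplied density means/SDs (rejection ",
         "sampling exhausted after ", max_rounds, " rounds)", call. = FALSE)
  }
  out
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a synthetic thrombectomy cohort
#'
#' Draws a patient-level cohort with the joint structure the downstream
#' analysis assumes. Per enhancement group, phase densities are drawn from
#' independent Gaussians (the published tables give only marginal means and
#' SDs) and rejection-sampled until [classify_dynamic()] reproduces the
#' intended group label, so the stored `dp_category` is exact by
#' construction. Recanalization success is Bernoulli per group (success
#' means a TICI grade of 2c or 3), pass counts are shifted capped Poisson,
#' and discharge NIHSS / 3-month mRS follow baseline-plus-group-shift linear
#' models, making the baseline-adjusted regressions of [dp_analysis()]
#' well-specified. Deaths before discharge, missing 3-month mRS, and
#' patients without an intervention are assigned uniformly at random in the
#' configured totals.
#'
#' @param params A [cohort_params()] list.
#' @param seed Optional integer seed; one global stream drives every draw,
#'   so equal seeds give identical cohorts.
#' @param size_factor Positive multiplier applied to group sizes and
#'   missingness totals (e.g. 10 for parameter-recovery studies).
#'
#' @return A `data.frame` with one row per patient: `patient_id`, `age`,
#'   `sex`, `occlusion_site`, `clot_length`, the three phase densities, TAI
#'   deltas, `sp_tai`, `dp_category`, `tici`, `success`, `n_passes` (NA if
#'   no intervention), `nihss_admit`, `nihss_discharge` (NA if deceased),
#'   `mrs_admit`, `mrs_3mo` (NA if deceased or lost to follow-up).
#'
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' table(cohort$dp_category)
#' @export
simulate_cohort <- function(params = cohort_params(), seed = NULL,
                            size_factor = 1) {
  stopifnot(inherits(params, "cohort_params"), size_factor > 0)
  if (!is.null(seed)) set.seed(seed)
  g <- params$group_labels
  sizes <- round(params$group_sizes * size_factor)
  n <- sum(sizes)

  dens <- do.call(rbind, lapply(g, function(lab) {
    .draw_group_densities(sizes[[lab]], params$phase_mu[lab, ],
                          params$phase_sd[lab, ], lab, params$tau,
                          params$max_reject_rounds)
  }))
  grp <- factor(rep(g, sizes), levels = DP_LEVELS)

  d <- compute_tai(dens[, 1], dens[, 2], dens[, 3])
  stopifnot(all(classify_dynamic(d, tau = params$tau) == grp))

  clot_length <- .clamp(
    stats::rnorm(n, params$clot_len_mu[grp], params$clot_len_sd[grp]),
    params$clot_len_range[1], params$clot_len_range[2])
  age <- round(.clamp(stats::rnorm(n, params$age_mu[grp],
                                   params$age_sd[grp]), 17, 99))
  sex <- ifelse(stats::runif(n) < params$female_prop, "F", "M")
  site <- sample(names(params$site_probs), n, replace = TRUE,
                 prob = params$site_probs)

  success <- stats::rbinom(n, 1, params$recan_prob[grp]) == 1
  tici <- ifelse(success,
                 sample(c("2c", "3"), n, replace = TRUE, prob = c(0.4, 0.6)),
                 sample(c("0", "1", "2a", "2b"), n, replace = TRUE,
                        prob = c(0.1, 0.1, 0.3, 0.5)))
  n_passes <- 1L + pmin(stats::rpois(n, params$passes_mean[grp] - 1),
                        params$passes_cap - 1L)

  nihss_admit <- round(.clamp(
    stats::rnorm(n, params$nihss_admit_mu[grp], params$nihss_admit_sd[grp]),
    0, 42))
  nihss_discharge <- round(.clamp(
    nihss_admit + params$nihss_effect[grp] +
      stats::rnorm(n, 0, params$nihss_resid_sd), 0, 42))
  mrs_admit <- round(.clamp(
    stats::rnorm(n, params$mrs_admit_mu, params$mrs_admit_sd), 0, 6))
  mrs_3mo <- round(.clamp(
    mrs_admit + params$mrs_shift + params$mrs_effect[grp] +
      stats::rnorm(n, 0, params$mrs_resid_sd), 0, 6))

  # missingness: deaths lose discharge NIHSS and 3-month mRS; a further set
  # is lost to mRS follow-up; some patients never needed an intervention
  n_deaths <- min(round(params$n_deaths * size_factor), n)
  n_miss_mrs <- min(round(params$n_missing_mrs * size_factor), n - n_deaths)
  n_no_int <- min(round(params$n_no_intervention * size_factor), n)
  deceased <- sample.int(n, n_deaths)
  lost_mrs <- sample(setdiff(seq_len(n), deceased), n_miss_mrs)
  no_int <- sample.int(n, n_no_int)
  nihss_discharge[deceased] <- NA
  mrs_3mo[c(deceased, lost_mrs)] <- NA
  n_passes[no_int] <- NA

  out <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = age, sex = sex, occlusion_site = site,
    clot_length = clot_length,
    ncct_hu = dens[, 1], cta_hu = dens[, 2], ctv_hu = dens[, 3],
    delta_na = d$delta_na, delta_nv = d$delta_nv, delta_av = d$delta_av,
    sp_tai = d$delta_na,
    dp_category = grp,
    tici = tici, success = success, n_passes = n_passes,
    nihss_admit = nihss_admit, nihss_discharge = nihss_discharge,
    mrs_admit = mrs_admit, mrs_3mo = mrs_3mo,
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- params
  out
}

.mean_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_)
}

#' Per-group summary table of a cohort
#'
#' Regenerates the per-enhancement-group summary layout used for reporting:
#' group size, mean (SD) of clot length, the three phase densities and
#' admission NIHSS, recanalization successes N (%), mean (SD) passes, and
#' mean (SD) 3-month mRS. Empty groups are reported with N = 0 and absent
#' statistics; single-patient groups report an absent SD.
#'
#' @param cohort A cohort `data.frame` with a `dp_category` factor (from
#'   [simulate_cohort()] or [classify_cohort()]).
#' @return A `data.frame` of class `dp_truth_table`, one column per group
#'   plus an `overall` column, one row per statistic.
#' @examples
#' truth_table(simulate_cohort(seed = 1))
#' @export
truth_table <- function(cohort) {
  if (!is.data.frame(cohort) || !nrow(cohort)) {
    stop("'cohort' must be a non-empty data frame", call. = FALSE)
  }
  if (!"dp_category" %in% names(cohort)) {
    stop("'cohort' lacks a 'dp_category' column; run classify_cohort() first",
         call. = FALSE)
  }
  grp <- factor(cohort$dp_category, levels = DP_LEVELS)
  cols <- c("overall", DP_LEVELS)
  one <- function(sub) {
    n <- nrow(sub)
    ms <- function(v) .mean_sd(if (n) sub[[v]] else numeric(0))
    suc <- if (n) sum(sub$success, na.rm = TRUE) else NA_integer_
    c(n = n,
      clot_length = ms("clot_length"),
      ncct = ms("ncct_hu"), cta = ms("cta_hu"), ctv = ms("ctv_hu"),
      nihss_admit = ms("nihss_admit"),
      success_n = suc,
      success_pct = if (n) 100 * suc / n else NA_real_,
      passes = ms("n_passes"),
      mrs_3mo = ms("mrs_3mo"))
  }
  stats_list <- c(list(overall = one(cohort)),
                  lapply(DP_LEVELS, function(lv) one(cohort[grp == lv, ,
                                                            drop = FALSE])))
  tab <- do.call(cbind, stats_list)
  colnames(tab) <- cols
  out <- as.data.frame(tab)
  class(out) <- c("dp_truth_table", "data.frame")
  out
}

#' @export
print.dp_truth_table <- function(x, digits = 1, ...) {
  fmt <- function(m, s) {
    ifelse(is.na(m), "-",
           paste0(format(round(m, digits), trim = TRUE), " (",
                  ifelse(is.na(s), "-", format(round(s, digits),
                                               trim = TRUE)), ")"))
  }
  rows <- rbind(
    N = format(unlist(x["n", ])),
    `Clot length mm, mean (SD)` = fmt(unlist(x["clot_length.mean", ]),
                                      unlist(x["clot_length.sd", ])),
    `NCCT HU, mean (SD)` = fmt(unlist(x["ncct.mean", ]),
                               unlist(x["ncct.sd", ])),
    `CTA HU, mean (SD)` = fmt(unlist(x["cta.mean", ]),
                              unlist(x["cta.sd", ])),
    `CTV HU, mean (SD)` = fmt(unlist(x["ctv.mean", ]),
                              unlist(x["ctv.sd", ])),
    `NIHSS admission, mean (SD)` = fmt(unlist(x["nihss_admit.mean", ]),
                                       unlist(x["nihss_admit.sd", ])),
    `Recanalization success N (%)` = ifelse(
      is.na(unlist(x["success_n", ])), "-",
      paste0(unlist(x["success_n", ]), " (",
             round(unlist(x["success_pct", ]), 1), ")")),
    `Passes, mean (SD)` = fmt(unlist(x["passes.mean", ]),
                              unlist(x["passes.sd", ])),
    `mRS 3 months, mean (SD)` = fmt(unlist(x["mrs_3mo.mean", ]),
                                    unlist(x["mrs_3mo.sd", ]))
  )
  colnames(rows) <- colnames(x)
  print(rows, quote = FALSE, right = TRUE)
  invisible(x)
}
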