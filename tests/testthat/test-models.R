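test_that("2x2 odds ratios reproduce the published group contrasts", {
  # successes/failures vs the reference group's 15/7
  expect_equal(round(odds_ratio_2x2(26, 3, 15, 7)$estimate, 2), 4.04)
  expect_equal(round(odds_ratio_2x2(39, 10, 15, 7)$estimate, 2), 1.82)
  expect_equal(round(odds_ratio_2x2(29, 8, 15, 7)$estimate, 2), 1.69)
  # Wald p-values on the log scale
  expect_equal(round(odds_ratio_2x2(26, 3, 15, 7)$p_value, 3), 0.067)
})

test_that("odds ratio obeys symmetry and interval ordering", {
  r <- odds_ratio_2x2(8, 8, 8, 8)
  expect_equal(r$estimate, 1)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
  r2 <- odds_ratio_2x2(20, 5, 10, 10)
  expect_true(r2$ci_low <= r2$estimate && r2$estimate <= r2$ci_high)
})

test_that("zero cells are reported explicitly, not silently corrected", {
  r <- odds_ratio_2x2(10, 0, 5, 5)
  expect_equal(r$estimate, Inf)
  expect_true(is.na(r$ci_low))
  expect_match(r$note, "zero cell")
  r0 <- odds_ratio_2x2(0, 10, 5, 5)
  expect_equal(r0$estimate, 0)
  # the Haldane-Anscombe correction gives a finite estimate on demand
  rc <- odds_ratio_2x2(10, 0, 5, 5, correction = TRUE)
  expect_true(is.finite(rc$estimate))
  expect_equal(rc$estimate, (10.5 * 5.5) / (0.5 * 5.5))
})

test_that("cell counts are validated", {
  expect_error(odds_ratio_2x2(-1, 2, 3, 4), "non-negative integers")
  expect_error(odds_ratio_2x2(1.5, 2, 3, 4), "non-negative integers")
})

test_that("unadjusted categorical logistic fit equals the 2x2 oracle", {
  co <- cohort_from_counts()
  fit <- fit_recanalization_logistic(co, reference = "C_NW")
  counts <- recan_counts()
  ref <- counts[counts$group == "C_NW", ]
  for (g in setdiff(counts$group, "C_NW")) {
    row <- counts[counts$group == g, ]
    oracle <- odds_ratio_2x2(row$success, row$n - row$success,
                             ref$success, ref$n - ref$success)
    est <- fit$estimate[fit$term == g]
    expect_equal(est, oracle$estimate, tolerance = 1e-6)
  }
  # and reproduces the published ORs at two decimals
  expect_equal(round(fit$estimate[fit$term == "C_NE"], 2), 1.82)
  expect_equal(round(fit$estimate[fit$term == "C_W"], 2), 1.69)
  expect_equal(round(fit$estimate[fit$term == "C_LE"], 2), 4.04)
})

test_that("oracle equivalence holds on simulated cohorts too", {
  for (s in 1:3) {
    co <- simulate_cohort(seed = 300 + s)
    fit <- fit_recanalization_logistic(co)
    tab <- table(co$dp_category, co$success)
    for (g in setdiff(DP_LEVELS, "C_NW")) {
      oracle <- odds_ratio_2x2(tab[g, "TRUE"], tab[g, "FALSE"],
                               tab["C_NW", "TRUE"], tab["C_NW", "FALSE"])
      expect_equal(fit$estimate[fit$term == g], oracle$estimate,
                   tolerance = 1e-6)
    }
  }
})

test_that("relabeling the reference permutes but preserves pairwise ORs", {
  co <- simulate_cohort(seed = 31)
  f_nw <- fit_recanalization_logistic(co, reference = "C_NW")
  f_ne <- fit_recanalization_logistic(co, reference = "C_NE")
  # OR_{C_LE vs C_W} must be identical from either parameterization
  a <- f_nw$estimate[f_nw$term == "C_LE"] /
    f_nw$estimate[f_nw$term == "C_W"]
  b <- f_ne$estimate[f_ne$term == "C_LE"] /
    f_ne$estimate[f_ne$term == "C_W"]
  expect_equal(a, b, tolerance = 1e-8)
  # and switching reference inverts the contrast
  expect_equal(f_ne$estimate[f_ne$term == "C_NW"],
               1 / f_nw$estimate[f_nw$term == "C_NE"], tolerance = 1e-8)
})

test_that("clot-length adjustment keeps the category terms interpretable", {
  co <- simulate_cohort(seed = 32)
  fit <- fit_recanalization_logistic(co, adjust_clot_length = TRUE)
  expect_setequal(fit$term, c("C_NE", "C_W", "C_LE", "clot_length"))
  expect_true(all(fit$estimate > 0))
})

test_that("logistic fit diagnoses separation and degenerate input", {
  co <- simulate_cohort(seed = 33)
  co$success[co$dp_category == "C_LE"] <- TRUE
  expect_error(fit_recanalization_logistic(co),
               "complete separation: category C_LE")
  one_cat <- data.frame(dp_category = rep("C_NW", 20),
                        success = rep(c(TRUE, FALSE), 10))
  expect_error(fit_recanalization_logistic(one_cat), ">= 2 categories")
})

test_that("continuous SP model is null when deltas carry no signal", {
  set.seed(44)
  n <- 6000
  co <- data.frame(delta_na = rnorm(n, 10, 15),
                   delta_nv = rnorm(n, 8, 12),
                   success = runif(n) < 0.7)
  fit <- fit_sp_logistic(co)
  expect_equal(fit$estimate[fit$term == "delta_na"], 1, tolerance = 0.01)
  expect_equal(fit$estimate[fit$term == "delta_nv"], 1, tolerance = 0.01)
})

test_that("continuous SP model recovers an injected per-HU log-odds slope", {
  set.seed(45)
  n <- 5000
  delta_na <- rnorm(n, 10, 15)
  delta_nv <- rnorm(n, 8, 12)
  eta <- -0.2 + 0.05 * delta_na
  co <- data.frame(delta_na = delta_na, delta_nv = delta_nv,
                   success = runif(n) < plogis(eta))
  fit <- fit_sp_logistic(co)
  est <- log(fit$estimate[fit$term == "delta_na"])
  se <- (log(fit$ci_high) - log(fit$ci_low))[fit$term == "delta_na"] /
    (2 * qnorm(0.975))
  expect_lt(abs(est - 0.05), 3 * se)
})

test_that("constant SP predictor raises an error", {
  co <- data.frame(delta_na = rep(2, 50), delta_nv = rnorm(50),
                   success = runif(50) < 0.5)
  expect_error(fit_sp_logistic(co), "zero variance")
})

test_that("linear model betas vanish when outcome equals baseline", {
  co <- simulate_cohort(seed = 51)
  co$nihss_discharge <- co$nihss_admit
  # a perfect fit makes lm grumble about unreliable summaries; expected here
  fit <- suppressWarnings(fit_outcome_linear(co, "nihss_discharge"))
  expect_true(all(abs(fit$estimate) < 1e-10))
})

test_that("linear model drops outcome-free categories and errors when no
           contrast remains", {
  co <- simulate_cohort(seed = 52)
  co$nihss_discharge[co$dp_category == "C_W"] <- NA
  expect_warning(fit <- fit_outcome_linear(co, "nihss_discharge"),
                 "C_W")
  expect_false("C_W" %in% fit$term)

  co2 <- simulate_cohort(seed = 53)
  co2$nihss_discharge[co2$dp_category != "C_NW"] <- NA
  expect_error(suppressWarnings(fit_outcome_linear(co2, "nihss_discharge")),
               "no contrast estimable")
})

test_that("mRS linear model uses the admission mRS as baseline", {
  co <- simulate_cohort(seed = 54)
  fit <- fit_outcome_linear(co, "mrs_3mo")
  expect_equal(unique(fit$model), "linear (mrs_3mo)")
  base_coef <- stats::coef(attr(fit, "fit"))[["base"]]
  expect_gt(base_coef, 0)   # follow-up disability tracks admission mRS
})

test_that("unadjusted Poisson rate ratios equal group sample-mean ratios", {
  co <- simulate_cohort(seed = 61)
  fit <- fit_passes_poisson(co)
  means <- tapply(co$n_passes, co$dp_category, mean, na.rm = TRUE)
  for (g in setdiff(DP_LEVELS, "C_NW")) {
    expect_equal(fit$estimate[fit$term == g],
                 unname(means[g] / means["C_NW"]), tolerance = 1e-6)
  }
})

test_that("Poisson rate ratios are near one for equal group means", {
  p <- cohort_params(passes_mean = stats::setNames(rep(2.4, 4), DP_LEVELS),
                     group_sizes = stats::setNames(rep(4000, 4), DP_LEVELS),
                     n_deaths = 0, n_missing_mrs = 0, n_no_intervention = 0)
  co <- simulate_cohort(p, seed = 62)
  fit <- fit_passes_poisson(co)
  expect_true(all(abs(fit$estimate - 1) < 0.05))
})

test_that("Poisson fit excludes untreated patients and validates counts", {
  co <- simulate_cohort(seed = 63)
  n_treated <- sum(!is.na(co$n_passes))
  fit <- fit_passes_poisson(co)
  expect_equal(stats::nobs(attr(fit, "fit")), n_treated)

  co$n_passes[co$dp_category == "C_LE"] <- NA
  expect_warning(fit2 <- fit_passes_poisson(co), "C_LE")
  expect_false("C_LE" %in% fit2$term)

  bad <- data.frame(dp_category = rep(c("C_NW", "C_NE"), each = 5),
                    n_passes = c(0, rep(2, 9)))
  expect_error(fit_passes_poisson(bad), ">= 1")
})

test_that("dp_analysis collects all families into one classed result", {
  co <- simulate_cohort(seed = 71)
  fit <- dp_analysis(co, adjust_clot_length = TRUE)
  expect_s3_class(fit, "dp_analysis")
  expect_setequal(unique(fit$model),
                  c("logistic", "logistic (length-adjusted)",
                    "logistic (continuous SP)", "linear (nihss_discharge)",
                    "linear (mrs_3mo)", "poisson (passes)"))
  expect_true(all(fit$ci_low <= fit$estimate & fit$estimate <= fit$ci_high))
  cf <- coef(fit)
  expect_named(cf)
  expect_equal(unname(cf["logistic: C_LE"]),
               fit$estimate[fit$model == "logistic" & fit$term == "C_LE"])
  expect_output(print(fit), "reference: C_NW")
  expect_output(summary(fit), "Cohort size: 137")
})

test_that("profile-likelihood intervals are available and bracket the OR", {
  co <- cohort_from_counts()
  fit <- fit_recanalization_logistic(co, ci_method = "profile")
  cle <- fit[fit$term == "C_LE", ]
  expect_true(cle$ci_low < cle$estimate && cle$estimate < cle$ci_high)
  # profile interval differs from Wald for these small cells
  wald <- fit_recanalization_logistic(co)
  expect_false(isTRUE(all.equal(cle$ci_high,
                                wald$ci_high[wald$term == "C_LE"])))
})
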