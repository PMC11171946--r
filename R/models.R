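.dp_result <- function(term, estimate, ci_low, ci_high, p_value, model,
                       reference = NA_character_, note = NA_character_) {
  out <- data.frame(term = term, estimate = estimate, ci_low = ci_low,
                    ci_high = ci_high, p_value = p_value, model = model,
                    reference = reference, note = note,
                    stringsAsFactors = FALSE)
  class(out) <- c("dp_result", "data.frame")
  out
}

#' @export
print.dp_result <- function(x, digits = 3, ...) {
  y <- x
  for (v in c("estimate", "ci_low", "ci_high")) {
    y[[v]] <- signif(y[[v]], digits)
  }
  y$p_value <- signif(y$p_value, 2)   # two significant figures at report time
  if (all(is.na(y$note))) y$note <- NULL
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Odds ratio from a 2x2 contingency table
#'
#' Closed-form cross-product odds ratio for successes/failures in an exposed
#' versus a reference group, with a Wald confidence interval on the log
#' scale (`SE = sqrt(1/a + 1/b + 1/c + 1/d)`) and a two-sided Wald p-value.
#' This is the brute-force oracle for the unadjusted categorical logistic
#' model: with a single categorical predictor the two agree exactly.
#'
#' A zero off-diagonal cell makes the odds ratio infinite (or zero); that
#' condition is reported explicitly in the result's `note` with `Inf`/`0`
#' estimates and absent interval, unless `correction = TRUE`, in which case
#' 0.5 is added to every cell (Haldane-Anscombe) before estimation.
#'
#' @param a,b Successes and failures in the exposed group.
#' @param c,d Successes and failures in the reference group.
#' @param correction Apply the Haldane-Anscombe 0.5 continuity correction.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row `dp_result` data frame: `term`, `estimate` (OR),
#'   `ci_low`, `ci_high`, `p_value`, `model`, `note`.
#' @examples
#' odds_ratio_2x2(26, 3, 15, 7)   # OR 4.04
#' odds_ratio_2x2(39, 10, 15, 7)  # OR 1.82
#' @export
odds_ratio_2x2 <- function(a, b, c, d, correction = FALSE,
                           conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(abs(cells - round(cells)) > 1e-8)) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (any(cells == 0)) {
    if (correction) {
      cells <- cells + 0.5
    } else {
      est <- if (cells[["b"]] == 0 || cells[["c"]] == 0) Inf else 0
      return(.dp_result("exposed vs reference", est, NA_real_, NA_real_,
                        NA_real_, "odds_ratio_2x2",
                        note = "zero cell: odds ratio degenerate; use correction = TRUE"))
    }
  }
  or <- (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(log(or)) / se)
  .dp_result("exposed vs reference", unname(or),
             unname(exp(log(or) - z * se)), unname(exp(log(or) + z * se)),
             unname(p), "odds_ratio_2x2")
}

.require_cols <- function(cohort, cols, fn) {
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) {
    stop(fn, ": cohort lacks column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

.category_factor <- function(cohort, reference) {
  if (!reference %in% DP_LEVELS) {
    stop("'reference' must be one of ", paste(DP_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  stats::relevel(factor(cohort$dp_category, levels = DP_LEVELS),
                 ref = reference)
}

# Wald CIs and p-values for glm coefficients on the link scale
.glm_wald <- function(fit, terms, conf_level, exponentiate, model, reference,
                      ci_method = "wald") {
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- sm[terms, "Estimate"]
  se <- sm[terms, "Std. Error"]
  if (ci_method == "profile") {
    ci <- suppressMessages(
      stats::confint(fit, parm = terms, level = conf_level))
    if (length(terms) == 1L) ci <- matrix(ci, nrow = 1)
    lo <- ci[, 1]; hi <- ci[, 2]
  } else {
    lo <- est - z * se
    hi <- est + z * se
  }
  pcol <- grep("^Pr\\(", colnames(sm))
  p <- sm[terms, pcol]
  tf <- if (exponentiate) exp else identity
  .dp_result(terms, unname(tf(est)), unname(tf(lo)), unname(tf(hi)),
             unname(p), model, reference)
}

#' Logistic regression of recanalization success on enhancement pattern
#'
#' Fits a maximum-likelihood logistic model of technical success (TICI 2c or
#' 3) on the dynamic perviousness category, with a configurable reference
#' level (default `C_NW`, early enhancement without washout) and optional
#' adjustment for clot length. Exponentiated coefficients are returned as
#' odds ratios; without the covariate these equal the 2x2 cross-product
#' ratios of [odds_ratio_2x2()] exactly.
#'
#' @param cohort Data frame with `dp_category` and logical/0-1 `success`
#'   (plus `clot_length` when adjusting).
#' @param reference Reference category label.
#' @param adjust_clot_length Also include clot length (mm) as a covariate.
#' @param conf_level Confidence level.
#' @param ci_method `"wald"` (default, on the log-odds scale) or
#'   `"profile"` (likelihood profile).
#' @return A `dp_result` data frame, one row per non-reference category
#'   (plus the length term when adjusted). Estimates are odds ratios.
#' @examples
#' co <- simulate_cohort(seed = 1)
#' fit_recanalization_logistic(co)
#' @export
fit_recanalization_logistic <- function(cohort, reference = "C_NW",
                                        adjust_clot_length = FALSE,
                                        conf_level = 0.95,
                                        ci_method = c("wald", "profile")) {
  ci_method <- match.arg(ci_method)
  .require_cols(cohort, c("dp_category", "success"),
                "fit_recanalization_logistic")
  keep <- !is.na(cohort$success) & !is.na(cohort$dp_category)
  if (adjust_clot_length) {
    .require_cols(cohort, "clot_length", "fit_recanalization_logistic")
    keep <- keep & !is.na(cohort$clot_length)
  }
  cohort <- cohort[keep, , drop = FALSE]
  grp <- .category_factor(cohort, reference)
  grp <- droplevels(grp)
  if (nlevels(grp) < 2) {
    stop("need >= 2 categories with observed outcomes", call. = FALSE)
  }
  tab <- table(grp, factor(as.logical(cohort$success), c(FALSE, TRUE)))
  degenerate <- rownames(tab)[tab[, 1] == 0 | tab[, 2] == 0]
  if (length(degenerate)) {
    stop("complete separation: category ", paste(degenerate, collapse = ", "),
         " has all-success or all-failure outcomes", call. = FALSE)
  }
  dat <- data.frame(success = as.logical(cohort$success), grp = grp)
  form <- success ~ grp
  if (adjust_clot_length) {
    dat$clot_length <- cohort$clot_length
    form <- success ~ grp + clot_length
  }
  fit <- stats::glm(form, family = stats::binomial(), data = dat)
  terms <- setdiff(names(stats::coef(fit)), "(Intercept)")
  res <- .glm_wald(fit, terms, conf_level, exponentiate = TRUE,
                   model = if (adjust_clot_length) "logistic (length-adjusted)"
                           else "logistic",
                   reference = reference, ci_method = ci_method)
  res$term <- sub("^grp", "", res$term)
  attr(res, "fit") <- fit
  res
}

#' Logistic regression of success on continuous standard perviousness
#'
#' The comparator analysis: technical success regressed on the continuous
#' NCCT-to-CTA attenuation increase (`delta_na`, standard perviousness) and
#' the NCCT-to-CTV increase (`delta_nv`), without enhancement groups.
#' Exponentiated coefficients are per-HU odds ratios.
#'
#' @param cohort Data frame with `success` and the delta columns (computed
#'   from the phase densities when absent).
#' @param predictors Delta columns to include (default both).
#' @inheritParams fit_recanalization_logistic
#' @return A `dp_result` data frame with one per-HU odds ratio per
#'   predictor.
#' @export
fit_sp_logistic <- function(cohort, predictors = c("delta_na", "delta_nv"),
                            conf_level = 0.95) {
  .require_cols(cohort, "success", "fit_sp_logistic")
  if (!all(predictors %in% names(cohort))) {
    cohort <- classify_cohort(cohort)
  }
  keep <- stats::complete.cases(cohort[, c("success", predictors)])
  cohort <- cohort[keep, , drop = FALSE]
  for (v in predictors) {
    if (stats::sd(cohort[[v]]) == 0) {
      stop("predictor '", v, "' has zero variance", call. = FALSE)
    }
  }
  dat <- cohort[, c("success", predictors)]
  dat$success <- as.logical(dat$success)
  fit <- stats::glm(stats::reformulate(predictors, "success"),
                    family = stats::binomial(), data = dat)
  res <- .glm_wald(fit, predictors, conf_level, exponentiate = TRUE,
                   model = "logistic (continuous SP)", reference = NA)
  attr(res, "fit") <- fit
  res
}

#' Baseline-adjusted linear model for clinical outcomes
#'
#' Ordinary least squares of an outcome score (discharge NIHSS or 3-month
#' mRS, treated as numeric) on the enhancement category, adjusting for the
#' corresponding admission score. Complete-case: rows with a missing outcome
#' or baseline are dropped, matching the shrinking denominators of clinical
#' follow-up; categories left with no observed outcome are dropped with a
#' warning.
#'
#' @param cohort Cohort data frame.
#' @param outcome `"nihss_discharge"` or `"mrs_3mo"`.
#' @param baseline Baseline covariate column; defaults to `nihss_admit` or
#'   `mrs_admit` to match the outcome.
#' @inheritParams fit_recanalization_logistic
#' @return A `dp_result` data frame of betas (score points vs the reference
#'   category) with t-based 95% intervals.
#' @examples
#' co <- simulate_cohort(seed = 1)
#' fit_outcome_linear(co, "nihss_discharge")
#' @export
fit_outcome_linear <- function(cohort,
                               outcome = c("nihss_discharge", "mrs_3mo"),
                               baseline = NULL, reference = "C_NW",
                               conf_level = 0.95) {
  outcome <- match.arg(outcome)
  if (is.null(baseline)) {
    baseline <- if (outcome == "nihss_discharge") "nihss_admit"
                else "mrs_admit"
  }
  .require_cols(cohort, c("dp_category", outcome, baseline),
                "fit_outcome_linear")
  keep <- !is.na(cohort[[outcome]]) & !is.na(cohort[[baseline]]) &
    !is.na(cohort$dp_category)
  dropped <- setdiff(unique(as.character(cohort$dp_category)),
                     unique(as.character(cohort$dp_category[keep])))
  if (length(dropped)) {
    warning("category ", paste(dropped, collapse = ", "),
            " has no observed outcomes and was dropped", call. = FALSE)
  }
  cohort <- cohort[keep, , drop = FALSE]
  grp <- droplevels(.category_factor(cohort, reference))
  if (nlevels(grp) < 2) {
    stop("no contrast estimable: fewer than two categories with observed ",
         "outcomes", call. = FALSE)
  }
  dat <- data.frame(y = cohort[[outcome]], base = cohort[[baseline]],
                    grp = grp)
  fit <- stats::lm(y ~ base + grp, data = dat)
  sm <- summary(fit)$coefficients
  terms <- grep("^grp", rownames(sm), value = TRUE)
  ci <- stats::confint(fit, parm = terms, level = conf_level)
  if (length(terms) == 1L) ci <- matrix(ci, nrow = 1)
  res <- .dp_result(sub("^grp", "", terms), unname(sm[terms, "Estimate"]),
                    unname(ci[, 1]), unname(ci[, 2]),
                    unname(sm[terms, "Pr(>|t|)"]),
                    paste0("linear (", outcome, ")"), reference)
  attr(res, "fit") <- fit
  res
}

#' Poisson regression of retrieval passes on enhancement pattern
#'
#' Log-linear Poisson model of the number of thrombectomy passes on the
#' enhancement category; exponentiated coefficients are rate ratios versus
#' the reference. Patients without an intervention (missing pass count) are
#' excluded; categories left empty are dropped with a warning. Unadjusted,
#' so the fitted rate ratios equal the ratios of group sample means.
#'
#' @param cohort Cohort data frame with `dp_category` and `n_passes`.
#' @inheritParams fit_recanalization_logistic
#' @return A `dp_result` data frame of rate ratios with Wald intervals.
#' @examples
#' co <- simulate_cohort(seed = 1)
#' fit_passes_poisson(co)
#' @export
fit_passes_poisson <- function(cohort, reference = "C_NW",
                               conf_level = 0.95) {
  .require_cols(cohort, c("dp_category", "n_passes"), "fit_passes_poisson")
  keep <- !is.na(cohort$n_passes) & !is.na(cohort$dp_category)
  dropped <- setdiff(unique(as.character(cohort$dp_category)),
                     unique(as.character(cohort$dp_category[keep])))
  if (length(dropped)) {
    warning("category ", paste(dropped, collapse = ", "),
            " has no patients with an intervention and was dropped",
            call. = FALSE)
  }
  cohort <- cohort[keep, , drop = FALSE]
  if (any(cohort$n_passes < 1)) {
    stop("pass counts must be >= 1 for treated patients", call. = FALSE)
  }
  grp <- droplevels(.category_factor(cohort, reference))
  if (nlevels(grp) < 2) {
    stop("no contrast estimable: fewer than two categories with pass counts",
         call. = FALSE)
  }
  dat <- data.frame(passes = cohort$n_passes, grp = grp)
  fit <- stats::glm(passes ~ grp, family = stats::poisson(), data = dat)
  terms <- grep("^grp", names(stats::coef(fit)), value = TRUE)
  res <- .glm_wald(fit, terms, conf_level, exponentiate = TRUE,
                   model = "poisson (passes)", reference = reference)
  res$term <- sub("^grp", "", res$term)
  attr(res, "fit") <- fit
  res
}

#' Fit the full dynamic-perviousness outcome analysis
#'
#' The central modelling entry point: runs the selected regression families
#' on a classified cohort -- logistic for recanalization success (plain and
#' clot-length-adjusted), the continuous standard-perviousness comparator,
#' baseline-adjusted linear models for discharge NIHSS and 3-month mRS, and
#' Poisson for pass counts -- and collects the per-term estimates into one
#' tidy frame.
#'
#' @param cohort A classified cohort data frame ([simulate_cohort()] output,
#'   or any frame run through [classify_cohort()] with outcome columns).
#' @param models Subset of `c("logistic", "sp", "linear", "poisson")`.
#' @param reference Reference enhancement category (default `C_NW`).
#' @param adjust_clot_length Also fit the length-adjusted logistic model.
#' @param conf_level Confidence level for all intervals.
#' @return An object of class `dp_analysis`: a data frame of results
#'   (columns `term`, `estimate`, `ci_low`, `ci_high`, `p_value`, `model`,
#'   `reference`) with the fitted model objects in attribute `"fits"`.
#'   `print()` formats it; `summary()` adds cohort counts; `coef()` returns
#'   the named estimates.
#' @examples
#' co <- simulate_cohort(seed = 1)
#' fit <- dp_analysis(co)
#' fit
#' coef(fit)
#' @export
dp_analysis <- function(cohort,
                        models = c("logistic", "sp", "linear", "poisson"),
                        reference = "C_NW", adjust_clot_length = FALSE,
                        conf_level = 0.95) {
  models <- match.arg(models, several.ok = TRUE)
  parts <- list()
  fits <- list()
  if ("logistic" %in% models) {
    r <- fit_recanalization_logistic(cohort, reference,
                                     conf_level = conf_level)
    fits$logistic <- attr(r, "fit")
    parts <- c(parts, list(r))
    if (adjust_clot_length) {
      r2 <- fit_recanalization_logistic(cohort, reference,
                                        adjust_clot_length = TRUE,
                                        conf_level = conf_level)
      fits$logistic_adjusted <- attr(r2, "fit")
      parts <- c(parts, list(r2))
    }
  }
  if ("sp" %in% models) {
    r <- fit_sp_logistic(cohort, conf_level = conf_level)
    fits$sp <- attr(r, "fit")
    parts <- c(parts, list(r))
  }
  if ("linear" %in% models) {
    for (oc in c("nihss_discharge", "mrs_3mo")) {
      if (oc %in% names(cohort)) {
        r <- fit_outcome_linear(cohort, oc, reference = reference,
                                conf_level = conf_level)
        fits[[oc]] <- attr(r, "fit")
        parts <- c(parts, list(r))
      }
    }
  }
  if ("poisson" %in% models && "n_passes" %in% names(cohort)) {
    r <- fit_passes_poisson(cohort, reference, conf_level = conf_level)
    fits$poisson <- attr(r, "fit")
    parts <- c(parts, list(r))
  }
  out <- do.call(rbind, parts)
  attr(out, "fits") <- fits
  attr(out, "n") <- nrow(cohort)
  attr(out, "reference") <- reference
  class(out) <- c("dp_analysis", "dp_result", "data.frame")
  out
}

#' @export
print.dp_analysis <- function(x, digits = 3, ...) {
  cat("Dynamic perviousness outcome analysis (reference: ",
      attr(x, "reference"), ", n = ", attr(x, "n"), ")\n\n", sep = "")
  for (m in unique(x$model)) {
    cat(m, "\n")
    sub <- x[x$model == m, c("term", "estimate", "ci_low", "ci_high",
                             "p_value")]
    sub$estimate <- signif(sub$estimate, digits)
    sub$ci_low <- signif(sub$ci_low, digits)
    sub$ci_high <- signif(sub$ci_high, digits)
    sub$p_value <- signif(sub$p_value, 2)
    print.data.frame(sub, row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.dp_analysis <- function(object, ...) {
  cat("Cohort size:", attr(object, "n"), "patients; reference category:",
      attr(object, "reference"), "\n")
  print(object, ...)
  invisible(object)
}

#' @export
coef.dp_analysis <- function(object, ...) {
  stats::setNames(object$estimate, paste(object$model, object$term, sep = ": "))
}
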