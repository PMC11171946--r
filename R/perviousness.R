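#' dynperv: dynamic perviousness of stroke thrombi from three-phase CT
#'
#' Quantifies how much iodinated contrast an occlusive thrombus takes up
#' between the three acquisitions of a stroke CT protocol -- non-contrast CT
#' (NCCT), arterial-phase CT angiography (CTA), and a late venous phase (CTV)
#' -- and classifies the time-resolved enhancement curve into one of four
#' perviousness patterns. The pattern, rather than the single NCCT-to-CTA
#' attenuation increase used by standard perviousness, is then related to
#' mechanical thrombectomy outcomes (recanalization success, retrieval passes,
#' NIHSS and mRS scores) through conventional regression models.
#'
#' The main entry points are [compute_tai()] and [classify_dynamic()] for the
#' imaging biomarker, [simulate_phantom()] / [place_rois()] /
#' [mean_roi_density()] for the digital measurement phantom,
#' [simulate_cohort()] for synthetic cohorts, [dp_analysis()] for the outcome
#' models, [apply_exclusions()] for cohort accounting, and [run_pipeline()]
#' for the end-to-end reproducible run.
#'
#' @keywords internal
"_PACKAGE"

#' Dynamic perviousness category labels
#'
#' The four contrast-enhancement patterns, in the column order used for
#' reporting: `C_NE` (no enhancement), `C_NW` (early enhancement without
#' washout), `C_W` (early enhancement with washout), `C_LE` (late
#' enhancement).
#'
#' @format Character vector of length 4.
#' @export
DP_LEVELS <- c("C_NE", "C_NW", "C_W", "C_LE")

# Plausible clot density range in HU; values outside trigger a warning only,
# since contrast-laden clots occasionally exceed textbook ranges.
.HU_RANGE <- c(-100, 300)

.check_hu <- function(x, name) {
  if (!is.numeric(x)) {
    stop("'", name, "' must be numeric", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("'", name, "' contains non-finite values", call. = FALSE)
  }
  if (any(x < .HU_RANGE[1] | x > .HU_RANGE[2])) {
    warning("'", name, "' has values outside the plausible clot range of ",
            .HU_RANGE[1], "..", .HU_RANGE[2], " HU", call. = FALSE)
  }
  invisible(x)
}

.check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("'tau' must be a single positive number (HU)", call. = FALSE)
  }
  tau
}

#' Thrombus attenuation increase (TAI) between the three CT phases
#'
#' Computes the three pairwise density changes of the mean clot density
#' across the acquisition phases: NCCT to CTA (`delta_na`), NCCT to CTV
#' (`delta_nv`), and CTA to CTV (`delta_av`). By construction
#' `delta_nv == delta_na + delta_av` exactly.
#'
#' @param ncct_hu,cta_hu,ctv_hu Numeric vectors of mean clot density in
#'   Hounsfield units on the non-contrast, arterial-phase, and late
#'   venous-phase scans. Must be finite and of equal length; values outside
#'   -100..300 HU raise a warning.
#'
#' @return A `data.frame` with columns `delta_na`, `delta_nv`, `delta_av`
#'   (HU), one row per input clot.
#'
#' @examples
#' compute_tai(64.4, 74.4, 71.2)   # overall cohort means
#' compute_tai(62.5, 61.4, 79.8)   # a late-enhancing clot
#' @seealso [classify_dynamic()], [standard_perviousness()]
#' @export
compute_tai <- function(ncct_hu, cta_hu, ctv_hu) {
  .check_hu(ncct_hu, "ncct_hu")
  .check_hu(cta_hu, "cta_hu")
  .check_hu(ctv_hu, "ctv_hu")
  n <- unique(c(length(ncct_hu), length(cta_hu), length(ctv_hu)))
  if (length(n) != 1L) {
    stop("phase density vectors must have equal length", call. = FALSE)
  }
  data.frame(
    delta_na = cta_hu - ncct_hu,
    delta_nv = ctv_hu - ncct_hu,
    delta_av = ctv_hu - cta_hu
  )
}

#' Standard (two-point) perviousness
#'
#' The classical thrombus attenuation increase using only two time points:
#' mean clot density on CTA minus mean clot density on NCCT. The venous phase
#' is ignored; this is the comparator biomarker against which the dynamic
#' classification is evaluated.
#'
#' @inheritParams compute_tai
#' @return Numeric vector of HU changes (CTA minus NCCT).
#' @examples
#' standard_perviousness(64.4, 74.4)  # 10 HU
#' @export
standard_perviousness <- function(ncct_hu, cta_hu) {
  .check_hu(ncct_hu, "ncct_hu")
  .check_hu(cta_hu, "cta_hu")
  cta_hu - ncct_hu
}

#' Classify the dynamic perviousness pattern
#'
#' Assigns each clot to one of four enhancement patterns from its TAI deltas,
#' using an enhancement threshold `tau` (default 5 HU):
#'
#' * `C_NE` -- no enhancement: `delta_na <= tau` and `delta_nv <= tau`
#'   (at most `tau` HU increase over both NCCT-referenced phases);
#' * `C_LE` -- late enhancement: `delta_na <= tau` and `delta_nv > tau`;
#' * `C_W`  -- early enhancement with washout: `delta_na > tau` and
#'   `delta_av <= -tau` (at least `tau` HU drop from CTA to CTV);
#' * `C_NW` -- early enhancement without washout: `delta_na > tau` and
#'   `delta_av > -tau`.
#'
#' The four rules partition the `(delta_na, delta_av)` plane: exactly one
#' fires for every input. Boundaries are inclusive on the non-enhancing and
#' washout sides (`delta_na = tau` is not early enhancement; `delta_av =
#' -tau` is washout). Densities are compared as floating point without
#' rounding.
#'
#' @param deltas Either a `data.frame` as returned by [compute_tai()]
#'   (columns `delta_na`, `delta_nv`, and optionally `delta_av`), or a
#'   numeric vector of `delta_na` values when `delta_nv` is supplied
#'   separately.
#' @param delta_nv Numeric vector of NCCT-to-CTV changes, when `deltas` is
#'   given as a plain `delta_na` vector.
#' @param delta_av Numeric vector of CTA-to-CTV changes; defaults to
#'   `delta_nv - delta_na`.
#' @param tau Enhancement threshold in HU, a single positive number
#'   (default 5). Exposed for sensitivity analysis.
#'
#' @return A factor with levels `c("C_NE", "C_NW", "C_W", "C_LE")`.
#'
#' @examples
#' classify_dynamic(compute_tai(62.5, 73.1, 78.2))  # C_NW
#' classify_dynamic(10.6, 15.7)                     # C_NW again
#' classify_dynamic(34, 7.2, -26.8)                 # washout
#' @export
classify_dynamic <- function(deltas, delta_nv = NULL, delta_av = NULL,
                             tau = 5) {
  .check_tau(tau)
  if (is.data.frame(deltas)) {
    if (!all(c("delta_na", "delta_nv") %in% names(deltas))) {
      stop("'deltas' must have columns 'delta_na' and 'delta_nv'",
           call. = FALSE)
    }
    delta_na <- deltas$delta_na
    delta_av <- if ("delta_av" %in% names(deltas)) deltas$delta_av else NULL
    delta_nv <- deltas$delta_nv
  } else {
    delta_na <- deltas
    if (is.null(delta_nv)) {
      stop("supply 'delta_nv' when 'deltas' is not a data frame",
           call. = FALSE)
    }
  }
  if (is.null(delta_av)) delta_av <- delta_nv - delta_na
  for (v in list(delta_na, delta_nv, delta_av)) {
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("TAI deltas must be finite numerics", call. = FALSE)
    }
  }
  early <- delta_na > tau
  lab <- ifelse(!early,
                ifelse(delta_nv <= tau, "C_NE", "C_LE"),
                ifelse(delta_av <= -tau, "C_W", "C_NW"))
  factor(lab, levels = DP_LEVELS)
}

#' Classify every clot in a density table
#'
#' Convenience wrapper for tabular input (the CSV schema of the pipeline):
#' takes a data frame with per-patient phase densities, appends the TAI
#' deltas, the standard perviousness value, and the dynamic perviousness
#' category.
#'
#' @param x A `data.frame` with numeric columns `ncct_hu`, `cta_hu`,
#'   `ctv_hu`; other columns (e.g. `patient_id`) pass through untouched.
#' @inheritParams classify_dynamic
#'
#' @return `x` with added columns `delta_na`, `delta_nv`, `delta_av`,
#'   `sp_tai`, and factor `dp_category`.
#'
#' @examples
#' df <- data.frame(patient_id = 1:2,
#'                  ncct_hu = c(68.6, 62.5),
#'                  cta_hu  = c(67.0, 61.4),
#'                  ctv_hu  = c(68.7, 79.8))
#' classify_cohort(df)
#' @export
classify_cohort <- function(x, tau = 5) {
  if (!is.data.frame(x)) stop("'x' must be a data frame", call. = FALSE)
  need <- c("ncct_hu", "cta_hu", "ctv_hu")
  if (!all(need %in% names(x))) {
    stop("'x' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d <- compute_tai(x$ncct_hu, x$cta_hu, x$ctv_hu)
  x$delta_na <- d$delta_na
  x$delta_nv <- d$delta_nv
  x$delta_av <- d$delta_av
  x$sp_tai <- d$delta_na
  x$dp_category <- classify_dynamic(d, tau = tau)
  x
}
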