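#' Apply an ordered inclusion/exclusion flow to a starting count
#'
#' Implements the study-flowchart arithmetic as an auditable chain: each
#' step removes a stated number of patients for a stated reason, and the
#' audit trail records the running total after every step. The final count
#' is order-invariant; the audit trail is not.
#'
#' @param n_initial Starting number of patients (non-negative integer).
#' @param steps Either a named numeric vector (`names` = reasons, values =
#'   counts removed) or a `data.frame` with columns `label` and
#'   `n_removed`. Labels must be unique and counts non-negative.
#'
#' @return An object of class `exclusion_audit`: a list with `n_initial`,
#'   `n_final`, and `audit` (a data frame with `step`, `label`,
#'   `n_removed`, `n_remaining`).
#'
#' @examples
#' apply_exclusions(475, c(
#'   "unsuitable thrombus (calcified/distal/extracranial)" = 84,
#'   "MRI instead of CT" = 54,
#'   "external imaging, not stored" = 81,
#'   "no late venous phase" = 46,
#'   "no unenhanced series" = 9,
#'   "motion artefact or voxels > 0.8 mm" = 43,
#'   "no consent" = 21))
#' @export
apply_exclusions <- function(n_initial, steps) {
  if (!is.numeric(n_initial) || length(n_initial) != 1L || n_initial < 0 ||
      n_initial != round(n_initial)) {
    stop("'n_initial' must be a single non-negative integer", call. = FALSE)
  }
  if (is.data.frame(steps)) {
    if (!all(c("label", "n_removed") %in% names(steps))) {
      stop("'steps' data frame needs columns 'label' and 'n_removed'",
           call. = FALSE)
    }
    labels <- as.character(steps$label)
    removed <- steps$n_removed
  } else {
    removed <- as.numeric(steps)
    labels <- names(steps)
    if (is.null(labels) && length(steps)) {
      labels <- paste("step", seq_along(steps))
    }
  }
  if (anyDuplicated(labels)) {
    stop("exclusion step labels must be unique", call. = FALSE)
  }
  if (any(removed < 0) || any(removed != round(removed))) {
    stop("'n_removed' must be non-negative integers", call. = FALSE)
  }
  running <- n_initial - cumsum(c(0, removed))[-1]
  if (length(removed) && any(running < 0)) {
    bad <- which(running < 0)[1]
    stop("consistency error at step ", bad, " ('", labels[bad],
         "'): running total would drop to ", running[bad], call. = FALSE)
  }
  audit <- data.frame(step = seq_along(removed),
                      label = labels,
                      n_removed = removed,
                      n_remaining = if (length(removed)) running
                                    else integer(0),
                      stringsAsFactors = FALSE)
  structure(list(n_initial = n_initial,
                 n_final = if (length(removed)) utils::tail(running, 1)
                           else n_initial,
                 audit = audit),
            class = "exclusion_audit")
}

#' @export
print.exclusion_audit <- function(x, ...) {
  cat("Inclusion/exclusion flow:", x$n_initial, "->", x$n_final,
      "patients\n")
  if (nrow(x$audit)) print.data.frame(x$audit, row.names = FALSE)
  invisible(x)
}

#' Predicate-based exclusion flow over a patient table
#'
#' Simulation-mode counterpart of [apply_exclusions()]: instead of published
#' counts, each step is a keep-predicate evaluated on the rows of a cohort
#' data frame, applied in order, with the same audit structure.
#'
#' @param cohort A data frame of patients.
#' @param predicates Named list of functions; each takes the current data
#'   frame and returns a logical keep-vector of its row count.
#' @return A list with the filtered `cohort` and an `exclusion_audit`.
#' @examples
#' co <- simulate_cohort(seed = 1)
#' flow <- apply_exclusion_predicates(co, list(
#'   "clot shorter than 5 mm" = function(d) d$clot_length >= 5))
#' flow$audit
#' @export
apply_exclusion_predicates <- function(cohort, predicates) {
  stopifnot(is.data.frame(cohort), is.list(predicates))
  if (is.null(names(predicates)) || anyDuplicated(names(predicates))) {
    stop("'predicates' must be a uniquely named list", call. = FALSE)
  }
  n0 <- nrow(cohort)
  removed <- integer(length(predicates))
  for (i in seq_along(predicates)) {
    keep <- predicates[[i]](cohort)
    if (!is.logical(keep) || length(keep) != nrow(cohort)) {
      stop("predicate '", names(predicates)[i],
           "' did not return one logical per row", call. = FALSE)
    }
    keep[is.na(keep)] <- FALSE
    removed[i] <- sum(!keep)
    cohort <- cohort[keep, , drop = FALSE]
  }
  audit <- apply_exclusions(n0, stats::setNames(removed, names(predicates)))
  list(cohort = cohort, audit = audit)
}
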