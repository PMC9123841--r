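#' Missing-value policies
#'
#' Label-free proteomics leaves many cells unquantified, and different
#' pipeline stages handle them differently. A `missing_policy` names one of
#' the four substitution rules used throughout the package:
#'
#' * `"keep"` — leave missing values as `NA` (descriptive summaries).
#' * `"zero"` — substitute 0 (SVM features, entropy ratios, within-fraction
#'   t-tests): an unquantified fraction is treated as holding none of the
#'   protein's signal.
#' * `"protein_min"` — substitute the minimum observed LFQ of that protein
#'   across all samples (PCA, heatmaps, ANOVA/Tukey), a conservative
#'   detection-floor imputation.
#' * `"epsilon"` — substitute a tiny positive constant (default `1e-10`),
#'   used before entropy calculations so that `0 * log2(0)` terms are
#'   defined.
#'
#' @param method One of `"keep"`, `"zero"`, `"protein_min"`, `"epsilon"`.
#' @param epsilon Positive constant for the `"epsilon"` method and as the
#'   fallback when `"protein_min"` meets a protein with no observed value.
#' @return A `missing_policy` object.
#' @export
missing_policy <- function(method = c("keep", "zero", "protein_min", "epsilon"),
                           epsilon = 1e-10) {
  method <- match.arg(method)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort("epsilon must be a single strictly positive number.",
          class = "organellar_validation_error")
  }
  structure(list(method = method, epsilon = epsilon), class = "missing_policy")
}

#' @export
print.missing_policy <- function(x, ...) {
  cat("<missing_policy> ", x$method,
      if (x$method == "epsilon") paste0(" (", format(x$epsilon), ")"), "\n",
      sep = "")
  invisible(x)
}

as_missing_policy <- function(policy) {
  if (inherits(policy, "missing_policy")) return(policy)
  if (is.character(policy) && length(policy) == 1) return(missing_policy(policy))
  abort("policy must be a missing_policy or a policy name.",
        class = "organellar_validation_error")
}

#' Substitute missing intensities under a policy
#'
#' Returns a copy of the LFQ table with every missing cell replaced
#' according to the policy; observed cells are never altered. Under
#' `"protein_min"`, a protein with no observed value at all falls back to
#' the epsilon constant with a warning.
#'
#' @param x An `lfq_tbl`.
#' @param policy A [missing_policy()] (or its name).
#' @return An `lfq_tbl` of identical shape.
#' @export
apply_missing_policy <- function(x, policy) {
  stopifnot(is_lfq_tbl(x))
  policy <- as_missing_policy(policy)
  if (policy$method == "keep") return(x)
  samples <- lfq_samples(x)
  m <- lfq_matrix(x)
  na <- is.na(m)
  if (policy$method == "zero") {
    m[na] <- 0
  } else if (policy$method == "epsilon") {
    m[na] <- policy$epsilon
  } else { # protein_min
    mins <- apply(m, 1, function(r) if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
    none <- is.na(mins)
    if (any(none)) {
      warn(paste0(sum(none), " protein(s) with no observed value; ",
                  "epsilon fallback used for protein_min."))
      mins[none] <- policy$epsilon
    }
    fill <- matrix(mins, nrow = nrow(m), ncol = ncol(m))
    m[na] <- fill[na]
  }
  for (j in seq_along(samples)) x[[samples[j]]] <- m[, j]
  attr(x, "missing_policy") <- policy$method
  x
}

#' Filter proteins by unique-peptide support
#'
#' Retains proteins identified by at least `min_peptides` unique peptides
#' (quality-control filter; the study required two).
#'
#' @param x An `lfq_tbl`.
#' @param min_peptides Minimum unique-peptide count (default 2).
#' @return The filtered `lfq_tbl`; sample set unchanged.
#' @export
filter_unique_peptides <- function(x, min_peptides = 2) {
  stopifnot(is_lfq_tbl(x), min_peptides >= 1)
  keep <- x$unique_peptides >= min_peptides
  if (!any(keep)) warn("No proteins survive the unique-peptide filter.")
  x[keep, ]
}

#' Filter proteins by missing-value count
#'
#' Retains proteins whose number of missing cells does not exceed
#' `max_missing`. The default `"auto"` sets the bound to
#' `n_subjects * (n_fractions - 1)`, so a protein quantified in all
#' replicates of exactly one fraction — appropriately undetected elsewhere —
#' survives (60 of 70 cells for 10 subjects and 7 fractions). Alternatively,
#' `max_missing_frac` gives the proportional reading: proteins with more
#' than that fraction of missing cells are excluded.
#'
#' @param x An `lfq_tbl`.
#' @param design A `study_design` matching `x`.
#' @param max_missing Integer bound on missing cells per protein, or
#'   `"auto"`.
#' @param max_missing_frac If non-`NULL`, overrides `max_missing` with
#'   `floor(max_missing_frac * n_samples)` (e.g. `0.6` excludes proteins
#'   with over 60\% missing values).
#' @return The filtered `lfq_tbl`.
#' @export
filter_missingness <- function(x, design, max_missing = "auto",
                               max_missing_frac = NULL) {
  stopifnot(is_lfq_tbl(x), is_study_design(design))
  check_design_match(x, design)
  n_samples <- length(lfq_samples(x))
  if (!is.null(max_missing_frac)) {
    stopifnot(max_missing_frac > 0, max_missing_frac < 1)
    max_missing <- floor(max_missing_frac * n_samples)
  } else if (identical(max_missing, "auto")) {
    n_subjects <- dplyr::n_distinct(design$subject_id)
    max_missing <- n_subjects * (n_fractions(design) - 1L)
  }
  max_missing <- as.integer(max_missing)
  if (max_missing >= n_samples) {
    abort("max_missing must be smaller than the number of samples.",
          class = "organellar_validation_error")
  }
  n_missing <- rowSums(is.na(lfq_matrix(x)))
  keep <- n_missing <= max_missing
  if (!any(keep)) warn("No proteins survive the missingness filter.")
  x[keep, ]
}
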