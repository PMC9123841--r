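#' Study designs for fractionation experiments
#'
#' A `study_design` maps each sample to a subject, a centrifugation fraction
#' (1..F) and a diagnosis group (`CONTROL` or `CASE`), with optional
#' per-subject covariates (`age` in years, `pmi` post-mortem interval in
#' hours, `sex`). Validation enforces a complete subjects-by-fractions grid:
#' every subject contributes exactly one sample per fraction.
#'
#' @param x A data frame with columns `sample_id`, `subject_id`, `fraction`,
#'   `diagnosis` and optionally `age`, `pmi`, `sex`.
#' @param n_fractions Number of fractions F; by default inferred as
#'   `max(fraction)`.
#' @return A validated `study_design` tibble with attribute `n_fractions`.
#' @export
as_study_design <- function(x, n_fractions = NULL) {
  x <- tibble::as_tibble(x)
  needed <- c("sample_id", "subject_id", "fraction", "diagnosis")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("study_design is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "organellar_format_error")
  }
  x$sample_id <- as.character(x$sample_id)
  x$subject_id <- as.character(x$subject_id)
  x$fraction <- as.integer(x$fraction)
  x$diagnosis <- toupper(as.character(x$diagnosis))
  if (anyDuplicated(x$sample_id)) {
    abort("Duplicate sample ids in study design.",
          class = "organellar_validation_error")
  }
  if (!all(x$diagnosis %in% c("CONTROL", "CASE"))) {
    abort("diagnosis must be CONTROL or CASE.",
          class = "organellar_validation_error")
  }
  n_fractions <- n_fractions %||% max(x$fraction)
  if (any(x$fraction < 1L) || any(x$fraction > n_fractions)) {
    abort(paste0("fraction values must lie in 1..", n_fractions, "."),
          class = "organellar_validation_error")
  }
  grid <- table(x$subject_id, x$fraction)
  if (ncol(grid) != n_fractions || any(grid != 1L)) {
    abort("Incomplete design: every (subject, fraction) pair must appear exactly once.",
          class = "organellar_validation_error")
  }
  per_subj <- unique(x[, c("subject_id", "diagnosis")])
  if (anyDuplicated(per_subj$subject_id)) {
    abort("A subject is listed under two diagnosis groups.",
          class = "organellar_validation_error")
  }
  attr(x, "n_fractions") <- as.integer(n_fractions)
  class(x) <- c("study_design", class(tibble::tibble()))
  x
}

#' @rdname as_study_design
#' @export
is_study_design <- function(x) inherits(x, "study_design")

#' Number of fractions in a design
#' @param design A `study_design`.
#' @export
n_fractions <- function(design) attr(design, "n_fractions")

#' Read a sample-metadata table
#'
#' Expects a TSV with columns `sample_id, subject_id, fraction, diagnosis`
#' and optionally `age, pmi, sex`.
#'
#' @param path Path to a tab-separated metadata file.
#' @inheritParams as_study_design
#' @export
read_study_design <- function(path, n_fractions = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "organellar_io_error")
  }
  as_study_design(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
                  n_fractions = n_fractions)
}

#' Check that an LFQ table and a design describe the same samples
#' @param x An `lfq_tbl`.
#' @param design A `study_design`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_design_match <- function(x, design) {
  s1 <- sort(lfq_samples(x))
  s2 <- sort(design$sample_id)
  if (!identical(s1, s2)) {
    abort("Samples in the LFQ table and the study design differ.",
          class = "organellar_validation_error")
  }
  invisible(TRUE)
}

#' Cohort summary statistics
#'
#' Per-group and overall mean, SD, median, min and max for each numeric
#' subject-level covariate, in the layout of a clinical demographics table.
#' The overall row is computed from the subject-level values, so its mean is
#' the size-weighted mean of the group means and its SD is the combined-sample
#' SD (the two-group pooling identity; see [pool_moments()]).
#'
#' @param design A `study_design` carrying covariate columns.
#' @param covariates Covariate column names to summarize (default: the
#'   numeric ones among `age` and `pmi` that are present).
#' @param digits Decimal places for the `*_display` columns (rounded half
#'   away from zero); full precision is kept in the plain columns.
#' @return A tibble with one row per (covariate, group) where group is
#'   `CASE`, `CONTROL` or `Overall`.
#' @export
summarize_cohort <- function(design, covariates = c("age", "pmi"), digits = 2) {
  stopifnot(is_study_design(design))
  subj <- dplyr::distinct(
    tibble::as_tibble(design)[, c("subject_id", "diagnosis",
                                  intersect(covariates, names(design)))],
    .data$subject_id, .keep_all = TRUE
  )
  keep <- character()
  for (cv in covariates) {
    if (!cv %in% names(subj) || !is.numeric(subj[[cv]]) || anyNA(subj[[cv]])) {
      warn(paste0("Covariate '", cv, "' missing or incomplete; omitted from summary."))
    } else {
      keep <- c(keep, cv)
    }
  }
  if (length(keep) == 0) {
    abort("No usable covariates to summarize.", class = "organellar_validation_error")
  }
  one <- function(v, group, cv) {
    tibble::tibble(
      covariate = cv, group = group, n = length(v),
      mean = mean(v), sd = sd(v), median = median(v),
      min = min(v), max = max(v)
    )
  }
  out <- purrr::map_dfr(keep, function(cv) {
    dplyr::bind_rows(
      purrr::map_dfr(split(subj, subj$diagnosis),
                     function(g) one(g[[cv]], g$diagnosis[1], cv)),
      one(subj[[cv]], "Overall", cv)
    )
  })
  for (col in c("mean", "sd", "median", "min", "max")) {
    out[[paste0(col, "_display")]] <- round_half_up(out[[col]], digits)
  }
  out
}

#' Pool group-level moments into overall moments
#'
#' Combines per-group sample sizes, means and sample SDs into the mean and
#' sample SD of the concatenated sample, using the exact pooling identity
#' \eqn{(N-1) s^2 = \sum_g [(n_g-1) s_g^2 + n_g (m_g - m)^2]}. Used to
#' reproduce the "Overall" column of a demographics table from its printed
#' group summaries.
#'
#' @param n Vector of group sizes.
#' @param mean Vector of group means.
#' @param sd Vector of group sample SDs.
#' @return A one-row tibble with `n`, `mean`, `sd`.
#' @export
pool_moments <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd), all(n >= 1))
  N <- sum(n)
  m <- sum(n * mean) / N
  ss <- sum((n - 1) * sd^2 + n * (mean - m)^2)
  tibble::tibble(n = N, mean = m, sd = sqrt(ss / (N - 1)))
}

# round half away from zero (display convention for demographic tables;
# base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
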