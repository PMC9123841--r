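#' Per-subject proportional fraction profiles
#'
#' Converts LFQ intensities to the proportion of each protein's total signal
#' found in each fraction, separately for every subject:
#' `ratio(s, p, f) = LFQ(s, p, f) / sum_f LFQ(s, p, f)`. The resulting
#' 7-part composition is the unit of all downstream localization analysis —
#' it removes between-sample abundance scale, so a profile depends only on
#' how the protein partitions across the gradient.
#'
#' The missing policy is applied to the intensities *before* the ratios are
#' formed. Under `"keep"`, unobserved cells stay `NA` and the observed
#' ratios of a profile still sum to 1; under `"zero"` they contribute
#' nothing; under `"epsilon"` they receive a vanishing share (the convention
#' used ahead of entropy calculations). When a protein has no usable signal
#' in any fraction for a subject, the profile is flagged `all_missing` and
#' its ratios are `NA`.
#'
#' @param x An `lfq_tbl` (filtered and validated).
#' @param design A `study_design` matching `x`.
#' @param policy A [missing_policy()]; default `"zero"`.
#' @return A `profile_tbl`: a long tibble with columns `protein_id`,
#'   `subject_id`, `diagnosis`, `fraction`, `ratio`, `all_missing`, carrying
#'   attributes `n_fractions` and `missing_policy`. Every non-`all_missing`
#'   profile's ratios sum to 1 within 1e-9.
#' @export
to_proportions <- function(x, design, policy = missing_policy("zero")) {
  stopifnot(is_lfq_tbl(x), is_study_design(design))
  check_design_match(x, design)
  policy <- as_missing_policy(policy)
  x <- apply_missing_policy(x, policy)
  m <- lfq_matrix(x)
  f <- n_fractions(design)
  subjects <- unique(design$subject_id)
  out <- purrr::map_dfr(subjects, function(s) {
    rows <- design[design$subject_id == s, ]
    rows <- rows[order(rows$fraction), ]
    sub <- m[, rows$sample_id, drop = FALSE]
    denom <- rowSums(sub, na.rm = TRUE)
    all_miss <- denom == 0 | rowSums(!is.na(sub)) == 0
    ratio <- sub / denom
    ratio[all_miss, ] <- NA_real_
    tibble::tibble(
      protein_id = rep(rownames(m), f),
      subject_id = s,
      diagnosis = rows$diagnosis[1],
      fraction = rep(seq_len(f), each = nrow(m)),
      ratio = as.vector(ratio),
      all_missing = rep(all_miss, f)
    )
  })
  attr(out, "n_fractions") <- f
  attr(out, "missing_policy") <- policy$method
  class(out) <- c("profile_tbl", class(tibble::tibble()))
  out
}

#' @rdname to_proportions
#' @export
is_profile_tbl <- function(x) inherits(x, "profile_tbl")

#' Mean marker profiles per organelle
#'
#' The average proportional distribution profile of each organelle's marker
#' set: the arithmetic mean of the member ratio vectors over all
#' (subject, marker) observations jointly, skipping `all_missing` profiles.
#' Because each contributing profile is a composition on the same support,
#' every mean vector again sums to 1.
#'
#' @param profiles A `profile_tbl`.
#' @param catalog A `marker_catalog`.
#' @return A `marker_profiles` tibble: `organelle`, `fraction`,
#'   `mean_ratio`, `n_markers` (distinct marker proteins present), `n_obs`
#'   (subject-by-marker observations averaged).
#' @export
marker_mean_profiles <- function(profiles, catalog) {
  stopifnot(is_profile_tbl(profiles), is_marker_catalog(catalog))
  joined <- dplyr::inner_join(
    tibble::as_tibble(profiles)[!profiles$all_missing, ],
    tibble::as_tibble(catalog)[, c("protein_id", "organelle")],
    by = "protein_id"
  )
  absent <- setdiff(unique(catalog$organelle), unique(joined$organelle))
  if (length(absent) > 0) {
    warn(paste0("No markers present in the profiles for class(es): ",
                paste(absent, collapse = ", "), "; omitted."))
  }
  if (nrow(joined) == 0) {
    abort("No marker profiles available.", class = "organellar_validation_error")
  }
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$organelle, .data$fraction),
    mean_ratio = mean(.data$ratio),
    n_markers = dplyr::n_distinct(.data$protein_id),
    n_obs = dplyr::n(),
    .groups = "drop"
  )
  class(out) <- c("marker_profiles", class(tibble::tibble()))
  out
}

#' Profile reproducibility across subjects (RMSE)
#'
#' For each protein, how much a subject's fraction profile deviates from the
#' cross-subject mean profile: the per-subject root-mean-square deviation
#' over fractions, averaged over subjects (`pooled = FALSE`, default), or a
#' single RMSE pooled over all subject-by-fraction deviations
#' (`pooled = TRUE`). A value of 0.05 means the ratio in a typical fraction
#' varies by about 5 percentage points around the consensus pattern.
#'
#' @param profiles A `profile_tbl`.
#' @param subjects Optional subject ids to restrict to (e.g. controls only).
#' @param pooled Pool deviations before taking the root (default `FALSE`).
#' @return A tibble with `protein_id`, `n_subjects`, `rmse`. Proteins with
#'   fewer than two usable subjects get `NA` with a warning.
#' @export
profile_rmse <- function(profiles, subjects = NULL, pooled = FALSE) {
  stopifnot(is_profile_tbl(profiles))
  tb <- tibble::as_tibble(profiles)[!profiles$all_missing, ]
  if (!is.null(subjects)) tb <- tb[tb$subject_id %in% subjects, ]
  f <- attr(profiles, "n_fractions")
  one <- function(g) {
    w <- tidyr::pivot_wider(g[, c("subject_id", "fraction", "ratio")],
                            names_from = "fraction", values_from = "ratio")
    m <- as.matrix(w[, -1, drop = FALSE])
    n_subj <- nrow(m)
    if (n_subj < 2) {
      return(tibble::tibble(protein_id = g$protein_id[1],
                            n_subjects = n_subj, rmse = NA_real_))
    }
    dev2 <- sweep(m, 2, colMeans(m))^2
    rmse <- if (pooled) sqrt(mean(dev2)) else mean(sqrt(rowMeans(dev2)))
    tibble::tibble(protein_id = g$protein_id[1], n_subjects = n_subj, rmse = rmse)
  }
  out <- purrr::map_dfr(split(tb, tb$protein_id), one)
  if (any(is.na(out$rmse))) {
    warn(paste0(sum(is.na(out$rmse)),
                " protein(s) with fewer than 2 usable subjects: RMSE undefined."))
  }
  out[order(out$protein_id), ]
}

#' Whole-tissue signal: summed LFQ across fractions
#'
#' The per-(protein, subject) total of LFQ intensities over all fractions
#' (missing cells as zero by default). Because the serial fractions jointly
#' partition the homogenate, this total approximates the protein's
#' whole-tissue abundance in that subject and supports the check that a
#' localization shift is not merely an abundance change.
#'
#' @param x An `lfq_tbl`.
#' @param design A `study_design` matching `x`.
#' @param policy A [missing_policy()]; default `"zero"`.
#' @return A tibble `protein_id`, `subject_id`, `diagnosis`, `total_lfq`.
#' @export
summed_lfq <- function(x, design, policy = missing_policy("zero")) {
  stopifnot(is_lfq_tbl(x), is_study_design(design))
  check_design_match(x, design)
  x <- apply_missing_policy(x, as_missing_policy(policy))
  m <- lfq_matrix(x)
  subjects <- unique(design$subject_id)
  purrr::map_dfr(subjects, function(s) {
    rows <- design[design$subject_id == s, ]
    tot <- unname(rowSums(m[, rows$sample_id, drop = FALSE], na.rm = TRUE))
    tibble::tibble(protein_id = rownames(m), subject_id = s,
                   diagnosis = rows$diagnosis[1], total_lfq = tot)
  })
}
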