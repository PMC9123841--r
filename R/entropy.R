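#' Normalized Shannon entropy of a fraction profile
#'
#' Measures how evenly a protein's signal spreads across the n fractions:
#' `entropy = -sum(ratio * log2(ratio)) / log2(n)`, so 1 means perfectly
#' uniform (maximally disordered) and values near 0 mean the protein is
#' confined to a single fraction (highly ordered). Missing and exactly-zero
#' ratios are replaced by a tiny positive epsilon (default `1e-10`) and the
#' vector renormalized to sum 1, so every term is defined and a one-hot
#' profile scores essentially 0.
#'
#' @param ratios Numeric vector of F >= 2 non-negative fraction ratios
#'   (`NA` allowed; treated as epsilon).
#' @param epsilon Positive substitution constant for missing/zero entries.
#' @return A single value in `[0, 1]`.
#' @export
shannon_entropy <- function(ratios, epsilon = 1e-10) {
  if (length(ratios) < 2) {
    abort("Entropy needs at least two fractions.",
          class = "organellar_validation_error")
  }
  if (any(ratios < 0, na.rm = TRUE)) {
    abort("Ratios must be non-negative.", class = "organellar_validation_error")
  }
  ratios[is.na(ratios) | ratios == 0] <- epsilon
  r <- ratios / sum(ratios)
  -sum(r * log2(r)) / log2(length(r))
}

# row-wise entropy over a profiles-by-fractions matrix (same convention)
entropy_rows <- function(m, epsilon = 1e-10) {
  m[is.na(m) | m == 0] <- epsilon
  m <- m / rowSums(m)
  -rowSums(m * log2(m)) / log2(ncol(m))
}

#' Entropy table and global delta entropy
#'
#' Computes the normalized Shannon entropy of every (protein, subject)
#' profile, then per protein the mean entropy in each diagnosis group and
#' the *global delta entropy*: mean entropy of control subjects minus mean
#' entropy of case subjects. A large positive delta means the protein is
#' more ordered (more fraction-confined) in disease; a large magnitude in
#' either direction suggests re-localization.
#'
#' Profiles are expected from epsilon-policy proportions (see
#' [to_proportions()] with `missing_policy("epsilon")`), mirroring the
#' convention that unquantified intensities enter the composition as 1e-10
#' before renormalization.
#'
#' @param profiles A `profile_tbl`.
#' @param epsilon Substitution constant passed to the entropy evaluation.
#' @return An `entropy_tbl`: one row per protein with `mean_entropy_control`,
#'   `mean_entropy_case`, `delta_entropy`, `n_control`, `n_case` and a
#'   `delta_defined` flag (false when a protein has no usable profile in an
#'   entire group). The per-(protein, subject) entropies are available via
#'   [entropy_by_subject()].
#' @export
entropy_table <- function(profiles, epsilon = 1e-10) {
  stopifnot(is_profile_tbl(profiles))
  tb <- tibble::as_tibble(profiles)[!profiles$all_missing, ]
  w <- tidyr::pivot_wider(tb[, c("protein_id", "subject_id", "diagnosis",
                                 "fraction", "ratio")],
                          names_from = "fraction", values_from = "ratio")
  ent <- entropy_rows(as.matrix(w[, -(1:3), drop = FALSE]), epsilon = epsilon)
  by_subject <- tibble::tibble(
    protein_id = w$protein_id, subject_id = w$subject_id,
    diagnosis = w$diagnosis, entropy = ent
  )
  out <- dplyr::summarise(
    dplyr::group_by(by_subject, .data$protein_id),
    mean_entropy_control = mean(.data$entropy[.data$diagnosis == "CONTROL"]),
    mean_entropy_case = mean(.data$entropy[.data$diagnosis == "CASE"]),
    n_control = sum(.data$diagnosis == "CONTROL"),
    n_case = sum(.data$diagnosis == "CASE"),
    .groups = "drop"
  )
  out$delta_entropy <- out$mean_entropy_control - out$mean_entropy_case
  out$delta_defined <- out$n_control > 0 & out$n_case > 0
  if (any(!out$delta_defined)) {
    warn(paste0(sum(!out$delta_defined),
                " protein(s) absent for an entire group: delta entropy undefined."))
  }
  attr(out, "by_subject") <- by_subject
  attr(out, "epsilon") <- epsilon
  class(out) <- c("entropy_tbl", class(tibble::tibble()))
  out
}

#' Per-(protein, subject) entropies behind an `entropy_tbl`
#' @param x An `entropy_tbl`.
#' @export
entropy_by_subject <- function(x) {
  stopifnot(inherits(x, "entropy_tbl"))
  attr(x, "by_subject")
}
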