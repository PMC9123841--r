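#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]) with
#' input validation; missing p-values are propagated as missing and the
#' family size is the number of observed p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, same length and order; `adjusted >= raw`,
#'   capped at 1.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].", class = "organellar_validation_error")
  }
  out <- rep(NA_real_, length(p))
  obs <- !is.na(p)
  out[obs] <- p.adjust(p[obs], method = "BH")
  out
}

# vectorised two-sample Student t (pooled variance) across matrix rows:
# x, y are proteins-by-subjects matrices for the two groups. NA cells are
# dropped per row. Returns mean1, mean2, t, df, p. Degenerate rows (zero
# pooled variance) get t = 0, p = 1 when the means agree, else +-Inf, p = 0.
row_student_t <- function(x, y) {
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
  ss1 <- rowSums((x - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((y - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  zero_var <- is.finite(df) & df > 0 & sp2 == 0
  eq <- zero_var & (m1 == m2)
  t[eq] <- 0; p[eq] <- 1
  ne <- zero_var & (m1 != m2)
  t[ne] <- sign(m1[ne] - m2[ne]) * Inf; p[ne] <- 0
  bad <- n1 < 2 | n2 < 2
  t[bad] <- NA_real_; p[bad] <- NA_real_; df[bad] <- NA_real_
  list(mean1 = m1, mean2 = m2, t = t, df = df, p = p)
}

#' Within-fraction group tests of proportional ratios
#'
#' For every (protein, fraction), a two-sample Student's t-test (pooled
#' variance by default) of the proportional ratios between control and case
#' subjects, identifying the fraction in which a protein's distribution
#' differs between groups. The t statistic is signed control minus case.
#' P-values are Benjamini-Hochberg adjusted, by default jointly over the
#' whole protein-by-fraction family (`family = "per_fraction"` adjusts
#' within each fraction instead).
#'
#' Ratios are expected from zero-policy proportions (unquantified cells
#' contribute no signal). Subjects whose whole profile is missing for a
#' protein are excluded from that protein's tests.
#'
#' @param profiles A `profile_tbl`.
#' @param family `"global"` (default) or `"per_fraction"` BH family.
#' @param var_equal Pooled-variance Student's t (default `TRUE`); `FALSE`
#'   gives Welch's t.
#' @return A tibble `protein_id`, `fraction`, `mean_control`, `mean_case`,
#'   `n_control`, `n_case`, `t`, `df`, `p`, `p_adj`.
#' @export
within_fraction_tests <- function(profiles, family = c("global", "per_fraction"),
                                  var_equal = TRUE) {
  stopifnot(is_profile_tbl(profiles))
  family <- match.arg(family)
  tb <- tibble::as_tibble(profiles)[!profiles$all_missing, ]
  nf <- attr(profiles, "n_fractions")
  subjects <- unique(tb[, c("subject_id", "diagnosis")])
  ctrl <- subjects$subject_id[subjects$diagnosis == "CONTROL"]
  case <- subjects$subject_id[subjects$diagnosis == "CASE"]
  if (length(ctrl) < 2 || length(case) < 2) {
    abort("Need at least two subjects per group.",
          class = "organellar_validation_error")
  }
  out <- purrr::map_dfr(seq_len(nf), function(f) {
    ft <- tb[tb$fraction == f, ]
    w <- tidyr::pivot_wider(ft[, c("protein_id", "subject_id", "ratio")],
                            names_from = "subject_id", values_from = "ratio")
    prot <- w$protein_id
    mcols <- function(ids) {
      m <- as.matrix(w[, intersect(ids, names(w)), drop = FALSE])
      m
    }
    res <- if (var_equal) {
      row_student_t(mcols(ctrl), mcols(case))
    } else {
      row_welch_t(mcols(ctrl), mcols(case))
    }
    tibble::tibble(protein_id = prot, fraction = f,
                   mean_control = res$mean1, mean_case = res$mean2,
                   n_control = rowSums(!is.na(mcols(ctrl))),
                   n_case = rowSums(!is.na(mcols(case))),
                   t = res$t, df = res$df, p = res$p)
  })
  if (family == "global") {
    out$p_adj <- benjamini_hochberg(out$p)
  } else {
    out <- dplyr::mutate(dplyr::group_by(out, .data$fraction),
                         p_adj = benjamini_hochberg(.data$p))
    out <- dplyr::ungroup(out)
  }
  attr(out, "family") <- family
  out[order(out$protein_id, out$fraction), ]
}

# Welch variant (unpooled variance, Satterthwaite df)
row_welch_t <- function(x, y) {
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
  v1 <- rowSums((x - m1)^2, na.rm = TRUE) / (n1 - 1)
  v2 <- rowSums((y - m2)^2, na.rm = TRUE) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  zero <- se2 == 0
  eq <- zero & m1 == m2; t[eq] <- 0; p[eq] <- 1; df[eq] <- n1[eq] + n2[eq] - 2
  ne <- zero & m1 != m2; t[ne] <- sign(m1[ne] - m2[ne]) * Inf; p[ne] <- 0
  bad <- n1 < 2 | n2 < 2
  t[bad] <- NA_real_; p[bad] <- NA_real_; df[bad] <- NA_real_
  list(mean1 = m1, mean2 = m2, t = t, df = df, p = p)
}

#' Per-protein ANOVA across fractions with Tukey post hoc
#'
#' One-way ANOVA of log2 policy-imputed LFQ against centrifugation fraction,
#' per protein, identifying proteins whose abundance differs between
#' fractions (i.e. proteins that actually partition on the gradient).
#' P-values are BH-adjusted across proteins; for the significant proteins,
#' Tukey's honest significant difference gives the pairwise fraction
#' contrasts, and their significant counts per fraction pair summarize which
#' fractions drive the separation.
#'
#' @param x An `lfq_tbl`.
#' @param design A `study_design` matching `x`.
#' @param policy Missing-value policy; default `"protein_min"`.
#' @param transform `"log2"` (default) or `"none"`.
#' @param alpha BH-adjusted significance level gating the Tukey step.
#' @param tukey Run the Tukey step (default `TRUE`).
#' @return A `fraction_anova` object: list with `anova` (per-protein `F`,
#'   `df1`, `df2`, `p`, `p_adj`), `tukey` (per significant protein and
#'   fraction pair: `diff`, `lwr`, `upr`, `p_tukey`) and `pair_counts`
#'   (significant Tukey contrasts per fraction pair). Has a [tidy()] method.
#' @export
fraction_anova <- function(x, design, policy = missing_policy("protein_min"),
                           transform = c("log2", "none"), alpha = 0.05,
                           tukey = TRUE) {
  stopifnot(is_lfq_tbl(x), is_study_design(design))
  check_design_match(x, design)
  transform <- match.arg(transform)
  x <- apply_missing_policy(x, as_missing_policy(policy))
  m <- lfq_matrix(x)
  if (transform == "log2") {
    if (any(m <= 0, na.rm = TRUE)) {
      abort("log2 transform requires strictly positive imputed intensities.",
            class = "organellar_validation_error")
    }
    m <- log2(m)
  }
  frac <- factor(design$fraction[match(colnames(m), design$sample_id)])
  if (min(table(frac)) < 2) {
    abort("Need at least two replicates per fraction.",
          class = "organellar_validation_error")
  }
  n <- nrow(m)
  fits <- vector("list", n)
  Fv <- df1 <- df2 <- pv <- rep(NA_real_, n)
  skipped <- rep(FALSE, n)
  for (i in seq_len(n)) {
    yv <- m[i, ]
    ok <- !is.na(yv)
    if (dplyr::n_distinct(frac[ok]) < 2 || sum(ok) < 3) {
      skipped[i] <- TRUE
      next
    }
    dat <- data.frame(y = yv[ok], fraction = frac[ok])
    if (var(dat$y) == 0) { # constant response: no fraction effect
      Fv[i] <- 0; pv[i] <- 1
      df1[i] <- nlevels(droplevels(dat$fraction)) - 1
      df2[i] <- nrow(dat) - nlevels(droplevels(dat$fraction))
      next
    }
    fit <- aov(y ~ fraction, data = dat)
    fits[[i]] <- fit
    s <- summary(fit)[[1]]
    Fv[i] <- s[["F value"]][1]; pv[i] <- s[["Pr(>F)"]][1]
    df1[i] <- s[["Df"]][1]; df2[i] <- s[["Df"]][2]
    if (!is.finite(Fv[i])) { Fv[i] <- 0; pv[i] <- 1 } # constant response
  }
  res <- tibble::tibble(protein_id = rownames(m), F = Fv, df1 = df1,
                        df2 = df2, p = pv, skipped = skipped)
  if (any(res$skipped)) {
    warn(paste0(sum(res$skipped), " protein(s) with fewer than 2 fractions of data skipped."))
  }
  res$p_adj <- benjamini_hochberg(res$p)
  tukey_tbl <- tibble::tibble(protein_id = character(), contrast = character(),
                              diff = numeric(), lwr = numeric(),
                              upr = numeric(), p_tukey = numeric())
  if (tukey) {
    sig <- which(!is.na(res$p_adj) & res$p_adj < alpha)
    tukey_tbl <- purrr::map_dfr(sig, function(i) {
      tk <- TukeyHSD(fits[[i]])[[1]]
      tibble::tibble(protein_id = res$protein_id[i], contrast = rownames(tk),
                     diff = tk[, "diff"], lwr = tk[, "lwr"],
                     upr = tk[, "upr"], p_tukey = tk[, "p adj"])
    })
  }
  pair_counts <- if (nrow(tukey_tbl) > 0) {
    dplyr::summarise(dplyr::group_by(tukey_tbl, .data$contrast),
                     n_significant = sum(.data$p_tukey < alpha),
                     .groups = "drop")
  } else {
    tibble::tibble(contrast = character(), n_significant = integer())
  }
  structure(list(anova = res[, c("protein_id", "F", "df1", "df2", "p", "p_adj")],
                 tukey = tukey_tbl, pair_counts = pair_counts,
                 alpha = alpha, policy = as_missing_policy(policy)$method),
            class = "fraction_anova")
}

#' @export
tidy.fraction_anova <- function(x, ...) x$anova

#' @export
glance.fraction_anova <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$anova),
    n_significant = sum(x$anova$p_adj < x$alpha, na.rm = TRUE),
    alpha = x$alpha,
    policy = x$policy
  )
}

#' @export
print.fraction_anova <- function(x, ...) {
  g <- glance(x)
  cat("<fraction_anova> ", g$n_proteins, " proteins, ", g$n_significant,
      " significant at BH-adjusted p < ", g$alpha, "\n", sep = "")
  invisible(x)
}

#' Rank re-localization candidates
#'
#' Orders proteins by the magnitude of their global delta entropy (largest
#' distribution change between groups first) and annotates each with the
#' fractions in which the within-fraction test is significant at the given
#' BH-adjusted level. Proteins significant in at least one fraction are the
#' discovery set.
#'
#' @param entropy An `entropy_tbl` from [entropy_table()].
#' @param tests A within-fraction test table from [within_fraction_tests()].
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return A tibble ordered by `abs(delta_entropy)` descending (protein id
#'   breaking ties): `rank`, `protein_id`, `delta_entropy`,
#'   `mean_entropy_control`, `mean_entropy_case`, `significant_fractions`
#'   (comma-separated), `n_significant`, `any_significant`.
#' @export
rank_candidates <- function(entropy, tests, alpha = 0.05) {
  stopifnot(inherits(entropy, "entropy_tbl"))
  sig <- dplyr::summarise(
    dplyr::group_by(tests, .data$protein_id),
    significant_fractions = paste(.data$fraction[!is.na(.data$p_adj) &
                                                   .data$p_adj < alpha],
                                  collapse = ","),
    n_significant = sum(.data$p_adj < alpha, na.rm = TRUE),
    .groups = "drop"
  )
  ent_tb <- tibble::tibble(
    protein_id = entropy$protein_id,
    delta_entropy = entropy$delta_entropy,
    mean_entropy_control = entropy$mean_entropy_control,
    mean_entropy_case = entropy$mean_entropy_case
  )
  out <- dplyr::left_join(ent_tb, sig, by = "protein_id")
  out$n_significant[is.na(out$n_significant)] <- 0L
  out$significant_fractions[is.na(out$significant_fractions)] <- ""
  out$any_significant <- out$n_significant > 0
  out <- out[order(-abs(out$delta_entropy), out$protein_id), ]
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "protein_id", "delta_entropy", "mean_entropy_control",
          "mean_entropy_case", "significant_fractions", "n_significant",
          "any_significant")]
}
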