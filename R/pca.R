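#' Principal component analysis of an LFQ table
#'
#' Centred (not variance-scaled by default) PCA of log2 policy-imputed LFQ
#' values, in one of two orientations:
#'
#' * `"samples"` — observations are the samples, variables the proteins:
#'   shows how samples cluster by centrifugation fraction.
#' * `"proteins"` — observations are the proteins, variables the samples:
#'   the organelle marker map, on which marker classes separate along the
#'   leading components.
#'
#' @param x An `lfq_tbl`.
#' @param design Optional `study_design`; when supplied, sample scores are
#'   annotated with subject, fraction and diagnosis.
#' @param orientation `"samples"` or `"proteins"`.
#' @param transform `"log2"` (default) or `"none"`. log2 requires strictly
#'   positive values after imputation.
#' @param policy Missing-value policy; default `"protein_min"`, which must
#'   resolve every missing cell.
#' @param center,scale. Passed to [stats::prcomp()]; defaults centre-only.
#' @return An `lfq_pca` object wrapping the `prcomp` fit, with [tidy()],
#'   [glance()], [pca_variance()] and [autoplot()] methods.
#' @export
run_pca <- function(x, design = NULL,
                    orientation = c("samples", "proteins"),
                    transform = c("log2", "none"),
                    policy = missing_policy("protein_min"),
                    center = TRUE, scale. = FALSE) {
  stopifnot(is_lfq_tbl(x))
  orientation <- match.arg(orientation)
  transform <- match.arg(transform)
  if (!is.null(design)) check_design_match(x, design)
  x <- apply_missing_policy(x, as_missing_policy(policy))
  m <- lfq_matrix(x)
  if (anyNA(m)) {
    abort("PCA requires a policy that resolves all missing values.",
          class = "organellar_validation_error")
  }
  if (transform == "log2") {
    if (any(m <= 0)) {
      abort("log2 transform requires strictly positive imputed intensities.",
            class = "organellar_validation_error")
    }
    m <- log2(m)
  }
  obs <- if (orientation == "samples") t(m) else m
  v <- apply(obs, 2, var)
  if (any(v == 0)) {
    warn(paste0(sum(v == 0), " zero-variance variable(s) dropped before PCA."))
    obs <- obs[, v > 0, drop = FALSE]
  }
  fit <- prcomp(obs, center = center, scale. = scale.)
  structure(
    list(prcomp = fit, orientation = orientation, transform = transform,
         labels = rownames(obs), design = design),
    class = "lfq_pca"
  )
}

#' Variance decomposition of an `lfq_pca`
#' @param x An `lfq_pca`.
#' @return A tibble with `component`, `variance`, `prop_variance`,
#'   `cum_variance`.
#' @export
pca_variance <- function(x) {
  stopifnot(inherits(x, "lfq_pca"))
  v <- x$prcomp$sdev^2
  tibble::tibble(
    component = seq_along(v),
    variance = v,
    prop_variance = v / sum(v),
    cum_variance = cumsum(v) / sum(v)
  )
}

#' @export
tidy.lfq_pca <- function(x, n_components = 5, ...) {
  k <- min(n_components, ncol(x$prcomp$x))
  scores <- tibble::as_tibble(x$prcomp$x[, seq_len(k), drop = FALSE])
  id_col <- if (x$orientation == "samples") "sample_id" else "protein_id"
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := x$labels), scores)
  if (x$orientation == "samples" && !is.null(x$design)) {
    out <- dplyr::left_join(out, tibble::as_tibble(x$design), by = "sample_id")
  }
  out
}

#' @export
glance.lfq_pca <- function(x, ...) {
  pv <- pca_variance(x)
  tibble::tibble(
    orientation = x$orientation,
    n_obs = nrow(x$prcomp$x),
    n_components = nrow(pv),
    pc1_prop = pv$prop_variance[1],
    pc2_prop = if (nrow(pv) >= 2) pv$prop_variance[2] else NA_real_
  )
}

#' @export
print.lfq_pca <- function(x, ...) {
  pv <- pca_variance(x)
  cat("<lfq_pca> orientation=", x$orientation,
      ", ", nrow(x$prcomp$x), " observations, PC1 ",
      sprintf("%.1f%%", 100 * pv$prop_variance[1]), " of variance\n", sep = "")
  invisible(x)
}

#' @export
autoplot.lfq_pca <- function(object, components = c(1, 2), markers = NULL, ...) {
  sc <- tidy(object, n_components = max(components))
  pcs <- paste0("PC", components)
  pv <- pca_variance(object)
  labs_xy <- sprintf("%s (%.1f%%)", pcs, 100 * pv$prop_variance[components])
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]]))
  if (object$orientation == "samples" && "fraction" %in% names(sc)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fraction),
                                              shape = .data$diagnosis), size = 2) +
      ggplot2::labs(colour = "Fraction", shape = "Diagnosis")
  } else if (!is.null(markers)) {
    sc <- dplyr::inner_join(sc, tibble::as_tibble(markers)[, c("protein_id", "organelle")],
                            by = "protein_id")
    p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
                                          colour = .data$organelle)) +
      ggplot2::geom_point(size = 1.5, alpha = 0.8) +
      ggplot2::labs(colour = "Organelle")
  } else {
    p <- p + ggplot2::geom_point(size = 1, alpha = 0.6)
  }
  p + ggplot2::labs(x = labs_xy[1], y = labs_xy[2]) + ggplot2::theme_minimal()
}

#' Line plot of mean marker profiles
#' @param object A `marker_profiles` tibble from [marker_mean_profiles()].
#' @param ... Unused.
#' @export
autoplot.marker_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction, y = .data$mean_ratio,
                                       colour = .data$organelle)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_x_continuous(breaks = unique(object$fraction)) +
    ggplot2::labs(x = "Fraction", y = "Mean proportion of total LFQ",
                  colour = "Organelle") +
    ggplot2::theme_minimal()
}

#' Boxplot of a protein's fraction profile by diagnosis group
#'
#' The per-fraction distribution of proportional ratios across subjects,
#' split by diagnosis — the standard view for inspecting a candidate
#' re-localization event.
#'
#' @param profiles A `profile_tbl`.
#' @param protein A protein id present in `profiles`.
#' @export
plot_protein_profile <- function(profiles, protein) {
  stopifnot(is_profile_tbl(profiles))
  tb <- tibble::as_tibble(profiles)
  tb <- tb[tb$protein_id == protein & !tb$all_missing, ]
  if (nrow(tb) == 0) {
    abort(paste0("No usable profiles for protein '", protein, "'."),
          class = "organellar_validation_error")
  }
  ggplot2::ggplot(tb, ggplot2::aes(x = factor(.data$fraction), y = .data$ratio,
                                   fill = .data$diagnosis)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(jitter.width = 0.1),
                        size = 1) +
    ggplot2::labs(title = protein, x = "Fraction",
                  y = "Proportion of total LFQ", fill = "Group") +
    ggplot2::theme_minimal()
}
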