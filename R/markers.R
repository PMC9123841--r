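#' Organelle marker catalogs
#'
#' A `marker_catalog` maps protein ids to a single organelle class each.
#' Classes with fewer members than the SVM down-sampling size cannot form a
#' balanced training class and are flagged untrainable (in the study this
#' excluded e.g. the Golgi apparatus).
#'
#' @param x A data frame with columns `protein_id` and `organelle`.
#' @param n_per_class Down-sampling size used to flag trainable classes
#'   (default 35).
#' @return A validated `marker_catalog` tibble with a logical `trainable`
#'   column and attribute `n_per_class`.
#' @export
as_marker_catalog <- function(x, n_per_class = 35) {
  x <- tibble::as_tibble(x)
  if (!all(c("protein_id", "organelle") %in% names(x))) {
    abort("marker_catalog needs columns protein_id and organelle.",
          class = "organellar_format_error")
  }
  x$protein_id <- as.character(x$protein_id)
  x$organelle <- as.character(x$organelle)
  if (anyDuplicated(x$protein_id)) {
    dup <- unique(x$protein_id[duplicated(x$protein_id)])
    abort(paste0("Marker(s) listed under more than one class: ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "organellar_validation_error")
  }
  sizes <- table(x$organelle)
  x$trainable <- as.vector(sizes[x$organelle] >= n_per_class)
  small <- names(sizes)[sizes < n_per_class]
  if (length(small) > 0) {
    warn(paste0("Class(es) below the down-sampling size (", n_per_class,
                ") flagged untrainable: ", paste(small, collapse = ", ")))
  }
  x <- x[, c("protein_id", "organelle", "trainable")]
  attr(x, "n_per_class") <- as.integer(n_per_class)
  class(x) <- c("marker_catalog", class(tibble::tibble()))
  x
}

#' @rdname as_marker_catalog
#' @export
is_marker_catalog <- function(x) inherits(x, "marker_catalog")

#' Read a two-column organelle marker table
#'
#' @param path Path to a TSV with columns `protein_id` and `organelle`.
#' @inheritParams as_marker_catalog
#' @export
read_marker_catalog <- function(path, n_per_class = 35) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "organellar_io_error")
  }
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_marker_catalog(tb, n_per_class = n_per_class)
}

#' Class sizes of a marker catalog
#' @param catalog A `marker_catalog`.
#' @return A tibble with `organelle`, `n`, `trainable`.
#' @export
marker_class_sizes <- function(catalog) {
  stopifnot(is_marker_catalog(catalog))
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(catalog), .data$organelle),
                   n = dplyr::n(), trainable = .data$trainable[1],
                   .groups = "drop")
}

#' Down-sample markers to balanced class sizes
#'
#' Randomly selects exactly `n_per_class` markers per trainable class,
#' without replacement, so SVM training classes are balanced. Classes with
#' fewer members are excluded with a warning. Deterministic for a given
#' `seed`.
#'
#' @param catalog A `marker_catalog`.
#' @param n_per_class Markers retained per class (default 35).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `marker_catalog` with `n_per_class` members in every class.
#' @export
downsample_markers <- function(catalog, n_per_class = 35, seed = NULL) {
  stopifnot(is_marker_catalog(catalog))
  draw <- function() {
    parts <- split(tibble::as_tibble(catalog), catalog$organelle)
    kept <- purrr::map(parts, function(p) {
      if (nrow(p) < n_per_class) return(NULL)
      p[sample.int(nrow(p), n_per_class), ]
    })
    dropped <- names(parts)[purrr::map_lgl(kept, is.null)]
    if (length(dropped) > 0) {
      warn(paste0("Class(es) with fewer than ", n_per_class,
                  " markers excluded from training: ",
                  paste(dropped, collapse = ", ")))
    }
    dplyr::bind_rows(kept)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (nrow(out) == 0) {
    abort("No class has enough markers to train on.",
          class = "organellar_validation_error")
  }
  out <- out[order(out$organelle, out$protein_id), ]
  as_marker_catalog(out[, c("protein_id", "organelle")], n_per_class = n_per_class)
}
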