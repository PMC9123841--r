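#' LFQ protein quantification tables
#'
#' An `lfq_tbl` is a tibble holding one row per protein group: the columns
#' `protein_id`, `gene_symbol` and `unique_peptides`, followed by one numeric
#' intensity column per sample. Missing quantifications are stored as `NA`;
#' by MaxQuant convention a literal `0` in an input file means "not
#' quantified" and is converted to `NA` at load time.
#'
#' @param x A data frame with the columns described above.
#' @return A validated `lfq_tbl`.
#' @export
as_lfq_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  meta <- c("protein_id", "gene_symbol", "unique_peptides")
  missing_cols <- setdiff(meta, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("lfq_tbl is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "organellar_format_error")
  }
  samples <- setdiff(names(x), meta)
  if (length(samples) == 0) {
    abort("lfq_tbl has no sample intensity columns.",
          class = "organellar_format_error")
  }
  if (anyDuplicated(x$protein_id)) {
    dup <- unique(x$protein_id[duplicated(x$protein_id)])
    abort(paste0("Duplicate protein id(s): ", paste(head(dup, 5), collapse = ", ")),
          class = "organellar_validation_error")
  }
  x$protein_id <- as.character(x$protein_id)
  x$gene_symbol <- as.character(x$gene_symbol)
  x$unique_peptides <- as.integer(x$unique_peptides)
  if (any(is.na(x$unique_peptides)) || any(x$unique_peptides < 0)) {
    abort("unique_peptides must be non-negative integers.",
          class = "organellar_validation_error")
  }
  for (s in samples) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort(paste0("Sample column '", s, "' is not numeric."),
            class = "organellar_format_error")
    }
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0("Negative intensity in sample column '", s, "'."),
            class = "organellar_validation_error")
    }
  }
  x <- x[, c(meta, samples)]
  class(x) <- c("lfq_tbl", class(tibble::tibble()))
  x
}

#' @rdname as_lfq_tbl
#' @export
is_lfq_tbl <- function(x) inherits(x, "lfq_tbl")

#' Sample ids of an LFQ table
#' @param x An `lfq_tbl`.
#' @return Character vector of sample column names.
#' @export
lfq_samples <- function(x) {
  setdiff(names(x), c("protein_id", "gene_symbol", "unique_peptides"))
}

#' Intensity matrix of an LFQ table
#'
#' @param x An `lfq_tbl`.
#' @return A numeric proteins-by-samples matrix with protein ids as row names.
#' @export
lfq_matrix <- function(x) {
  samples <- lfq_samples(x)
  m <- as.matrix(x[, samples, drop = FALSE])
  rownames(m) <- x$protein_id
  m
}

#' Read a MaxQuant-style protein quantification table
#'
#' Reads a wide tab-separated `proteinGroups.txt`-dialect table: a protein id
#' column, a gene symbol column, a unique-peptide count column and one LFQ
#' intensity column per sample, identified by a shared column-name prefix
#' which is stripped to obtain the sample id.
#'
#' @param path Path to a tab-separated file.
#' @param sample_prefix Prefix of the per-sample intensity columns
#'   (default `"LFQ intensity "`).
#' @param col_map Named list mapping the internal names `protein_id`,
#'   `gene_symbol`, `unique_peptides` to the column headers in the file.
#'   Defaults to the MaxQuant headers `"Protein IDs"`, `"Gene names"`,
#'   `"Unique peptides"`.
#' @param zero_as_missing Convert stored zeros to missing (`NA`) on load
#'   (MaxQuant writes 0 for "not quantified"). Default `TRUE`.
#' @return An [as_lfq_tbl()]-validated `lfq_tbl`, row order as in the file.
#' @export
read_lfq_table <- function(path,
                           sample_prefix = "LFQ intensity ",
                           col_map = list(protein_id = "Protein IDs",
                                          gene_symbol = "Gene names",
                                          unique_peptides = "Unique peptides"),
                           zero_as_missing = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "organellar_io_error")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (nm in c("protein_id", "gene_symbol", "unique_peptides")) {
    if (is.null(col_map[[nm]]) || !col_map[[nm]] %in% names(raw)) {
      abort(paste0("Input table lacks required column '", col_map[[nm]] %||% nm,
                   "' (maps to ", nm, ")."),
            class = "organellar_format_error")
    }
  }
  sample_cols <- names(raw)[startsWith(names(raw), sample_prefix)]
  if (length(sample_cols) == 0) {
    abort(paste0("No sample columns match the prefix '", sample_prefix, "'."),
          class = "organellar_format_error")
  }
  out <- tibble::tibble(
    protein_id = as.character(raw[[col_map$protein_id]]),
    gene_symbol = as.character(raw[[col_map$gene_symbol]]),
    unique_peptides = raw[[col_map$unique_peptides]]
  )
  for (sc in sample_cols) {
    v <- as.numeric(raw[[sc]])
    if (zero_as_missing) v[!is.na(v) & v == 0] <- NA_real_
    out[[substring(sc, nchar(sample_prefix) + 1L)]] <- v
  }
  as_lfq_tbl(out)
}

#' Write an LFQ table in the MaxQuant dialect
#'
#' Inverse of [read_lfq_table()]: missing values are written as 0, sample
#' columns regain the intensity prefix. Reading the file back with
#' [read_lfq_table()] reproduces the original table exactly as long as no
#' observed intensity equals 0.
#'
#' @param x An `lfq_tbl`.
#' @param path Output path.
#' @inheritParams read_lfq_table
#' @return `path`, invisibly.
#' @export
write_lfq_table <- function(x, path, sample_prefix = "LFQ intensity ") {
  stopifnot(is_lfq_tbl(x))
  samples <- lfq_samples(x)
  out <- tibble::tibble(
    "Protein IDs" = x$protein_id,
    "Gene names" = x$gene_symbol,
    "Unique peptides" = x$unique_peptides
  )
  for (s in samples) {
    v <- x[[s]]
    v[is.na(v)] <- 0
    out[[paste0(sample_prefix, s)]] <- v
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
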