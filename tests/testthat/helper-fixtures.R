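# in-code fixtures shared across test files

# tiny wide LFQ tibble: proteins x samples, NA for missing
toy_lfq <- function(values, protein_ids = NULL, sample_ids = NULL,
                    peptides = NULL) {
  m <- as.matrix(values)
  protein_ids <- protein_ids %||% paste0("P", seq_len(nrow(m)))
  sample_ids <- sample_ids %||% paste0("S", seq_len(ncol(m)))
  tb <- tibble::tibble(
    protein_id = protein_ids,
    gene_symbol = paste0("G", protein_ids),
    unique_peptides = peptides %||% rep(2L, nrow(m))
  )
  for (j in seq_len(ncol(m))) tb[[sample_ids[j]]] <- m[, j]
  as_lfq_tbl(tb)
}

# complete design for n_per_group subjects per group and f fractions;
# sample ids "<subject>_F<fraction>"
toy_design <- function(n_per_group = 5, f = 7, covariates = FALSE) {
  subj <- c(paste0("CTRL", seq_len(n_per_group)),
            paste0("CASE", seq_len(n_per_group)))
  diag <- rep(c("CONTROL", "CASE"), each = n_per_group)
  tb <- tidyr::expand_grid(subject_id = subj, fraction = seq_len(f))
  tb$sample_id <- paste0(tb$subject_id, "_F", tb$fraction)
  tb$diagnosis <- rep(diag, each = f)
  if (covariates) {
    cov <- tibble::tibble(subject_id = subj,
                          age = seq(85, by = 1, length.out = length(subj)),
                          pmi = seq(8, by = 1.5, length.out = length(subj)),
                          sex = rep(c("F", "M"), length.out = length(subj)))
    tb <- dplyr::left_join(tb, cov, by = "subject_id")
  }
  as_study_design(tb[, c("sample_id", setdiff(names(tb), "sample_id"))])
}

# single-subject design with f fractions
toy_design1 <- function(f = 7, subject = "S1", diagnosis = "CONTROL") {
  as_study_design(tibble::tibble(
    sample_id = paste0(subject, "_F", seq_len(f)),
    subject_id = subject, fraction = seq_len(f), diagnosis = diagnosis
  ))
}

# random positive LFQ matrix keyed to a design, with optional missingness
random_lfq <- function(design, n_proteins = 20, miss_frac = 0, seed = 1) {
  withr::with_seed(seed, {
    n_s <- nrow(design)
    m <- matrix(rlnorm(n_proteins * n_s, 14, 1), n_proteins, n_s)
    if (miss_frac > 0) m[runif(length(m)) < miss_frac] <- NA
    toy_lfq(m, sample_ids = design$sample_id)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
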