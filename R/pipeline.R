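#' Pipeline configuration
#'
#' Collects every input path and analysis constant used by
#' [run_pipeline()]. Defaults are the canonical settings: at least two
#' unique peptides per protein, the "auto" missingness bound (a protein
#' may survive on one fully observed fraction), 35 markers per class with
#' 10-fold cross-validation and a 10x10 tuning grid, consensus over 5
#' control subjects with a 4-of-5 HIGH bar, and BH-adjusted significance at
#' 0.05.
#'
#' @param lfq_path,metadata_path,markers_path Input file paths (see
#'   [read_lfq_table()], [read_study_design()], [read_marker_catalog()]).
#' @param out_dir Output directory for stage TSVs, the manifest and the
#'   summary.
#' @param min_peptides Unique-peptide filter threshold (default 2).
#' @param max_missing Missingness bound or `"auto"` (default).
#' @param n_per_class,cv_folds,n_tuning SVM settings (defaults 35, 10, 10).
#' @param n_control,high_threshold Consensus settings (defaults 5, 4).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param seed Master seed for down-sampling and cross-validation.
#' @param sample_prefix LFQ intensity column prefix in the input table.
#' @param run_svm Run the per-subject SVM stage (default `TRUE`; the
#'   entropy-based disease contrast is independent of it).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(lfq_path, metadata_path, markers_path, out_dir,
                            min_peptides = 2, max_missing = "auto",
                            n_per_class = 35, cv_folds = 10, n_tuning = 10,
                            n_control = 5, high_threshold = 4, alpha = 0.05,
                            seed = 1, sample_prefix = "LFQ intensity ",
                            run_svm = TRUE) {
  cfg <- list(lfq_path = lfq_path, metadata_path = metadata_path,
              markers_path = markers_path, out_dir = out_dir,
              min_peptides = min_peptides, max_missing = max_missing,
              n_per_class = n_per_class, cv_folds = cv_folds,
              n_tuning = n_tuning, n_control = n_control,
              high_threshold = high_threshold, alpha = alpha,
              seed = as.integer(seed), sample_prefix = sample_prefix,
              run_svm = isTRUE(run_svm))
  for (p in c("lfq_path", "metadata_path", "markers_path")) {
    if (!file.exists(cfg[[p]])) {
      abort(paste0(p, " does not exist: ", cfg[[p]]),
            class = "organellar_validation_error")
    }
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1 || cfg$min_peptides < 1 ||
      cfg$high_threshold > cfg$n_control) {
    abort("Pipeline thresholds out of range.",
          class = "organellar_validation_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

stage_log <- function(stage, msg) {
  inform(paste0("[", stage, "] ", msg))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", stage, "' failed: ", conditionMessage(e)),
          class = "organellar_pipeline_error", parent = e)
  })
}

#' Run the full fractionation-proteomics pipeline
#'
#' Executes the stages in the order of the analysis: ingest and filtering,
#' cohort summary, sample PCA, per-protein fraction ANOVA with Tukey post
#' hoc, marker mean profiles, per-subject SVM classification with consensus
#' confidence tiers and the covariate performance check, entropy and global
#' delta entropy, within-fraction t-tests, and the ranked candidate table.
#' Every stage writes a TSV into the output directory; a JSON manifest
#' records the package version, seed, configuration (and its hash) and
#' per-stage row counts, and `summary.txt` gives a human-readable account
#' (filter survivor counts, tier sizes, top candidates).
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  counts <- list()
  tsv <- function(x, name) {
    readr::write_tsv(tibble::as_tibble(x), out(name), progress = FALSE)
    counts[[name]] <<- nrow(x)
  }

  stage_log("ingest", paste0("reading ", config$lfq_path))
  lfq <- run_stage("ingest", read_lfq_table(config$lfq_path,
                                            sample_prefix = config$sample_prefix))
  design <- run_stage("ingest", read_study_design(config$metadata_path))
  markers <- run_stage("ingest",
                       read_marker_catalog(config$markers_path,
                                           n_per_class = config$n_per_class))
  n_input <- nrow(lfq)
  lfq <- run_stage("filter", {
    x <- filter_unique_peptides(lfq, config$min_peptides)
    filter_missingness(x, design, max_missing = config$max_missing)
  })
  stage_log("filter", paste0(n_input, " proteins in, ", nrow(lfq), " retained"))

  cohort <- run_stage("cohort", tryCatch(summarize_cohort(design),
                                         error = function(e) NULL))
  if (!is.null(cohort)) tsv(cohort, "cohort_summary.tsv")

  stage_log("pca", "sample-orientation PCA")
  pca <- run_stage("pca", run_pca(lfq, design, orientation = "samples"))
  tsv(tidy(pca), "pca_scores.tsv")
  tsv(pca_variance(pca), "pca_variance.tsv")

  stage_log("anova", "per-protein fraction ANOVA + Tukey")
  anova <- run_stage("anova", fraction_anova(lfq, design, alpha = config$alpha))
  tsv(tidy(anova), "anova.tsv")
  tsv(anova$tukey, "tukey.tsv")
  tsv(anova$pair_counts, "tukey_pair_counts.tsv")

  stage_log("profiles", "proportional profiles and marker means")
  prof_zero <- run_stage("profiles", to_proportions(lfq, design,
                                                    missing_policy("zero")))
  tsv(prof_zero[!prof_zero$all_missing, ], "profiles.tsv")
  mmp <- run_stage("profiles", marker_mean_profiles(prof_zero, markers))
  tsv(mmp, "marker_mean_profiles.tsv")

  consensus <- NULL
  if (config$run_svm) {
    stage_log("svm", paste0("training per-subject SVMs (seed ", config$seed, ")"))
    cls <- run_stage("svm", classify_all_subjects(
      lfq, design, markers, n_per_class = config$n_per_class,
      cv_folds = config$cv_folds, n_tuning = config$n_tuning,
      seed = config$seed))
    tsv(cls$assignments, "assignments.tsv")
    tsv(cls$performance, "svm_performance.tsv")
    consensus <- run_stage("svm", consensus_confidence(
      cls, design, n_control = config$n_control,
      high_threshold = config$high_threshold))
    tsv(consensus, "consensus.tsv")
    covar <- run_stage("svm", tryCatch(performance_covariate_check(cls, design),
                                       error = function(e) NULL))
    if (!is.null(covar)) tsv(covar, "svm_covariate_check.tsv")
  }

  stage_log("entropy", "normalized entropy and delta entropy")
  prof_eps <- run_stage("entropy", to_proportions(lfq, design,
                                                  missing_policy("epsilon")))
  ent <- run_stage("entropy", entropy_table(prof_eps))
  tsv(entropy_by_subject(ent), "entropy_by_subject.tsv")
  tsv(ent, "delta_entropy.tsv")

  stage_log("tests", "within-fraction t-tests")
  tests <- run_stage("tests", within_fraction_tests(prof_zero))
  tsv(tests, "within_fraction_tests.tsv")

  ranked <- run_stage("rank", rank_candidates(ent, tests, alpha = config$alpha))
  tsv(ranked, "candidates.tsv")

  totals <- run_stage("summed", summed_lfq(lfq, design))
  tsv(totals, "summed_lfq.tsv")

  manifest <- list(
    package = "organellar",
    version = as.character(utils::packageVersion("organellar")),
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    n_proteins_input = n_input,
    n_proteins_retained = nrow(lfq),
    files = names(counts),
    row_counts = counts,
    tier_counts = if (!is.null(consensus)) as.list(table(consensus$tier)),
    n_candidates = sum(ranked$any_significant),
    completed = TRUE
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  sm <- c(
    "organellar pipeline summary",
    paste0("proteins in input: ", n_input),
    paste0("proteins after filters (>=", config$min_peptides,
           " unique peptides, missingness <= ",
           ifelse(identical(config$max_missing, "auto"), "auto", config$max_missing),
           "): ", nrow(lfq)),
    paste0("ANOVA-significant proteins (BH p < ", config$alpha, "): ",
           glance(anova)$n_significant),
    if (!is.null(consensus)) paste0(
      "consensus tiers: HIGH=", sum(consensus$tier == "HIGH", na.rm = TRUE),
      " MEDIUM=", sum(consensus$tier == "MEDIUM", na.rm = TRUE),
      " LOW=", sum(consensus$tier == "LOW", na.rm = TRUE)),
    paste0("proteins significant in >=1 fraction: ", sum(ranked$any_significant)),
    "top candidates by |delta entropy|:",
    utils::capture.output(print(head(ranked, 10)))
  )
  writeLines(sm, out("summary.txt"))
  invisible(manifest)
}
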