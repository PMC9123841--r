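#' Simulation configuration
#'
#' Parameters of the synthetic fractionation-proteomics generator. The
#' defaults emulate the study conditions the pipeline was designed for:
#' 7 centrifugation fractions, 8 organelle classes with 40 markers each,
#' two diagnosis groups of 5 subjects, lognormal protein abundance spanning
#' several orders of magnitude, Dirichlet compositional noise around the
#' class archetype profiles (per-fraction SD about 0.03, matching a
#' profile RMSE on the 0.05 scale), intensity-dependent (missing not at
#' random) dropout, and a minority of non-marker proteins whose profile is
#' mixed toward a different organelle's archetype in the case group.
#'
#' @param n_fractions Number of fractions (default 7).
#' @param n_classes Number of organelle classes (default 8; up to 8 named
#'   classes are available at 7 fractions).
#' @param n_markers_per_class Markers per class (default 40).
#' @param n_nonmarkers Non-marker proteins (default 1680, for 2000 proteins
#'   in total at the defaults).
#' @param subjects_per_group Subjects per diagnosis group (default 5).
#' @param abundance_meanlog,abundance_sdlog Natural-log mean/SD of protein
#'   abundance (defaults 16 and 1.2: median LFQ near 9e6, spanning roughly
#'   three orders of magnitude for the robustly quantified proteins the
#'   cohort emulates).
#' @param profile_concentration Dirichlet concentration for per-protein
#'   deviation from the class archetype (default 100, per-fraction SD
#'   about 0.03-0.04).
#' @param subject_concentration Dirichlet concentration for per-subject
#'   deviation from the protein's group profile (default 700; together
#'   with the measurement noise this puts the per-subject profile RMSE on
#'   the 0.03-0.05 scale).
#' @param subject_scale_sdlog Lognormal SD of the per-(subject, protein)
#'   loading scale (default 0.3).
#' @param noise_sdlog Lognormal SD of per-cell measurement noise
#'   (default 0.08).
#' @param miss_model `"mnar"` (logistic in log10 intensity, default),
#'   `"mcar"` (uniform), or `"none"`.
#' @param miss_intercept,miss_slope MNAR logistic coefficients:
#'   `P(missing) = plogis(miss_intercept + miss_slope * log10(intensity))`
#'   (defaults 1.2 and -0.7, about 5\% dropout concentrated in low
#'   intensities).
#' @param miss_rate MCAR dropout rate (default 0.1).
#' @param n_effect Number of planted re-localization proteins (default 50).
#' @param effect_lambda Mixing weight toward the target archetype in the
#'   case group, in `[0, 1]` (default 0.6).
#' @param effect_target `"random"` (default) draws the target archetype
#'   uniformly among the distinguishable classes; `"max_contrast"` picks
#'   the one with the largest entropy contrast to the source, emulating a
#'   clear spread-to-concentrated re-localization exemplar.
#' @param archetype_width Peak width of generically generated archetypes
#'   (only used when `n_classes` differs from 8; 0 gives one-hot profiles).
#' @param seed Integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_fractions = 7, n_classes = 8,
                       n_markers_per_class = 40, n_nonmarkers = 1680,
                       subjects_per_group = 5,
                       abundance_meanlog = 16, abundance_sdlog = 1.2,
                       profile_concentration = 100,
                       subject_concentration = 700,
                       subject_scale_sdlog = 0.3, noise_sdlog = 0.08,
                       miss_model = c("mnar", "mcar", "none"),
                       miss_intercept = 1.2, miss_slope = -0.7,
                       miss_rate = 0.1,
                       n_effect = 50, effect_lambda = 0.6,
                       effect_target = c("random", "max_contrast"),
                       archetype_width = 0.8, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    abort("A single integer seed is mandatory.",
          class = "organellar_validation_error")
  }
  miss_model <- match.arg(miss_model)
  effect_target <- match.arg(effect_target)
  cfg <- list(n_fractions = as.integer(n_fractions),
              n_classes = as.integer(n_classes),
              n_markers_per_class = as.integer(n_markers_per_class),
              n_nonmarkers = as.integer(n_nonmarkers),
              subjects_per_group = as.integer(subjects_per_group),
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              profile_concentration = profile_concentration,
              subject_concentration = subject_concentration,
              subject_scale_sdlog = subject_scale_sdlog,
              noise_sdlog = noise_sdlog, miss_model = miss_model,
              miss_intercept = miss_intercept, miss_slope = miss_slope,
              miss_rate = miss_rate, n_effect = as.integer(n_effect),
              effect_lambda = effect_lambda, effect_target = effect_target,
              archetype_width = archetype_width, seed = as.integer(seed))
  with(cfg, {
    if (n_fractions < 2 || n_classes < 2 || n_markers_per_class < 1 ||
        subjects_per_group < 1 || n_nonmarkers < 0) {
      abort("All counts must be positive (n_nonmarkers may be 0).",
            class = "organellar_validation_error")
    }
    if (effect_lambda < 0 || effect_lambda > 1) {
      abort("effect_lambda must lie in [0, 1].",
            class = "organellar_validation_error")
    }
    if (n_effect > n_nonmarkers) {
      abort("n_effect cannot exceed n_nonmarkers (effects are non-markers).",
            class = "organellar_validation_error")
    }
  })
  structure(cfg, class = "sim_config")
}

# curated archetypes for the 7-fraction, 8-class default: shapes emulate a
# serial centrifugation gradient (nucleus pelleting first, cytosol in the
# final supernatant, post-synapse co-sedimenting with mitochondria)
canonical_archetypes <- function() {
  a <- rbind(
    nucleus         = c(0.55, 0.18, 0.10, 0.06, 0.04, 0.04, 0.03),
    mitochondria    = c(0.05, 0.10, 0.30, 0.30, 0.12, 0.08, 0.05),
    postsynapse     = c(0.06, 0.11, 0.28, 0.28, 0.13, 0.09, 0.05),
    er              = c(0.08, 0.32, 0.24, 0.14, 0.12, 0.06, 0.04),
    plasma_membrane = c(0.10, 0.14, 0.12, 0.10, 0.32, 0.14, 0.08),
    presynapse      = c(0.05, 0.09, 0.08, 0.14, 0.22, 0.30, 0.12),
    cytoskeleton    = c(0.22, 0.16, 0.10, 0.08, 0.07, 0.12, 0.25),
    cytosol         = c(0.02, 0.03, 0.04, 0.05, 0.06, 0.10, 0.70)
  )
  colnames(a) <- paste0("F", 1:7)
  a
}

#' Organelle archetype profiles
#'
#' The per-class ground-truth compositions over fractions that the generator
#' perturbs. With the default 8 classes at 7 fractions, a curated set of
#' named organelle shapes is used; pairwise total-variation distances are at
#' least 0.2 for all class pairs except the designated co-segregating pair
#' (post-synapse vs mitochondria, distance at most 0.1), emulating organelles
#' whose sedimentation patterns are nearly indistinguishable. For other
#' class counts, peaks are spread evenly across the gradient with Gaussian
#' width `archetype_width` (0 gives maximally separated one-hot profiles).
#'
#' @param config A [sim_config()].
#' @return A classes-by-fractions matrix of compositions (rows sum to 1)
#'   with attribute `coseg_pair` naming the designated co-segregating pair
#'   (or `NULL` when none exists).
#' @export
make_archetypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  f <- config$n_fractions
  k <- config$n_classes
  if (f == 7 && k == 8) {
    arch <- canonical_archetypes()
    coseg <- c("mitochondria", "postsynapse")
  } else {
    peaks <- seq(1, f, length.out = k)
    w <- config$archetype_width
    arch <- t(vapply(peaks, function(mu) {
      v <- if (w == 0) as.numeric(seq_len(f) == round(mu)) else
        exp(-((seq_len(f) - mu)^2) / (2 * w^2))
      v / sum(v)
    }, numeric(f)))
    rownames(arch) <- paste0("class", seq_len(k))
    colnames(arch) <- paste0("F", seq_len(f))
    coseg <- NULL
  }
  tv <- archetype_distances(arch)
  lower <- tv[lower.tri(tv)]
  if (!is.null(coseg)) {
    is_pair <- outer(rownames(tv) %in% coseg, colnames(tv) %in% coseg, "&")
    pair_tv <- tv[coseg[1], coseg[2]]
    others <- tv[lower.tri(tv) & !is_pair]
    if (pair_tv > 0.1 || any(others < 0.2)) {
      abort("Archetype separation constraints violated.",
            class = "organellar_validation_error")
    }
  } else if (any(lower < 0.05)) {
    abort(paste0("Archetypes are not separable (min pairwise distance ",
                 signif(min(lower), 2), "); reduce n_classes or archetype_width."),
          class = "organellar_validation_error")
  }
  attr(arch, "coseg_pair") <- coseg
  arch
}

#' Pairwise total-variation distances between archetype profiles
#' @param arch A classes-by-fractions composition matrix.
#' @return A symmetric classes-by-classes distance matrix
#'   (`0.5 * sum |a - b|`).
#' @export
archetype_distances <- function(arch) {
  k <- nrow(arch)
  tv <- matrix(0, k, k, dimnames = list(rownames(arch), rownames(arch)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    tv[i, j] <- 0.5 * sum(abs(arch[i, ] - arch[j, ]))
  }
  tv
}

# Dirichlet sampling via gamma variates; rows of alpha give one draw each
rdirichlet_rows <- function(alpha) {
  g <- matrix(rgamma(length(alpha), shape = alpha), nrow = nrow(alpha))
  g / rowSums(g)
}

#' Simulate a fractionation-proteomics dataset with known ground truth
#'
#' Generates an LFQ table, study design, marker catalog and truth table
#' under the model: each protein belongs to an organelle class and its true
#' profile is a Dirichlet perturbation of the class archetype; each
#' subject's realized profile is a further Dirichlet perturbation;
#' `LFQ(s, p, f) = abundance(p) * scale(s, p) * profile(s, p, f) * noise`,
#' with lognormal abundance, subject loading and measurement noise. Planted
#' effect proteins (non-markers) use, in the case group, the mixture
#' `(1 - lambda) * own profile + lambda * target archetype`, so their
#' distribution — not their whole-tissue abundance — changes with disease.
#' Missingness is drawn per cell, by default logistic in log10 intensity.
#'
#' @param config A [sim_config()]; the result is deterministic given the
#'   config (including its seed).
#' @return A `sim_dataset` list: `lfq` (`lfq_tbl`), `design`
#'   (`study_design` with age/pmi/sex covariates), `markers`
#'   (`marker_catalog`), `truth` (per protein: class, marker/effect flags,
#'   target class, per-group true entropies and true delta entropy),
#'   `archetypes`, and the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- make_archetypes(config)
  withr::with_seed(config$seed, simulate_dataset_impl(config, arch))
}

simulate_dataset_impl <- function(config, arch) {
  f <- config$n_fractions
  classes <- rownames(arch)
  n_marker <- config$n_classes * config$n_markers_per_class
  n_total <- n_marker + config$n_nonmarkers

  marker_class <- rep(classes, each = config$n_markers_per_class)
  marker_ids <- paste0("MK", formatC(seq_len(n_marker), width = 4, flag = "0"))
  nm_class <- if (config$n_nonmarkers > 0) {
    sample(classes, config$n_nonmarkers, replace = TRUE)
  } else character()
  nm_ids <- if (config$n_nonmarkers > 0) {
    paste0("NP", formatC(seq_len(config$n_nonmarkers), width = 5, flag = "0"))
  } else character()
  protein_id <- c(marker_ids, nm_ids)
  true_class <- c(marker_class, nm_class)
  is_marker <- c(rep(TRUE, n_marker), rep(FALSE, config$n_nonmarkers))

  # per-protein true (control-group) profile
  alpha <- arch[true_class, , drop = FALSE] * config$profile_concentration
  prof_control <- rdirichlet_rows(alpha)

  # planted effects: case-group profile mixed toward a different archetype
  is_effect <- rep(FALSE, n_total)
  target_class <- rep(NA_character_, n_total)
  prof_case <- prof_control
  if (config$n_effect > 0 && config$n_nonmarkers > 0) {
    eff_idx <- n_marker + sample.int(config$n_nonmarkers, config$n_effect)
    is_effect[eff_idx] <- TRUE
    tv <- archetype_distances(arch)
    for (i in eff_idx) {
      # target must be distinguishable on the gradient: a shift toward an
      # archetype that co-sediments with the source is not a plantable effect
      eligible <- classes[classes != true_class[i] & tv[true_class[i], ] >= 0.2]
      if (length(eligible) == 0) eligible <- setdiff(classes, true_class[i])
      target_class[i] <- if (config$effect_target == "max_contrast") {
        h <- entropy_rows(arch)
        eligible[which.max(abs(h[eligible] - h[true_class[i]]))]
      } else {
        sample(eligible, 1)
      }
      prof_case[i, ] <- (1 - config$effect_lambda) * prof_control[i, ] +
        config$effect_lambda * arch[target_class[i], ]
    }
  }

  abundance <- rlnorm(n_total, config$abundance_meanlog, config$abundance_sdlog)

  n_subj <- 2 * config$subjects_per_group
  subj_ids <- c(paste0("CTRL", seq_len(config$subjects_per_group)),
                paste0("CASE", seq_len(config$subjects_per_group)))
  diagnosis <- rep(c("CONTROL", "CASE"), each = config$subjects_per_group)

  lfq <- tibble::tibble(
    protein_id = protein_id,
    gene_symbol = paste0("G", protein_id),
    unique_peptides = 2L + stats::rpois(n_total, 8)
  )
  for (si in seq_len(n_subj)) {
    group_prof <- if (diagnosis[si] == "CONTROL") prof_control else prof_case
    subj_prof <- rdirichlet_rows(group_prof * config$subject_concentration)
    scale_sp <- rlnorm(n_total, 0, config$subject_scale_sdlog)
    noise <- matrix(rlnorm(n_total * f, 0, config$noise_sdlog), n_total, f)
    vals <- abundance * scale_sp * subj_prof * noise
    # the dropout uniforms are always drawn so the intensity stream is
    # identical across miss_model settings at a fixed seed (counterfactual
    # masking: "none" reveals exactly the cells the other models would hide)
    u <- matrix(runif(n_total * f), n_total, f)
    miss <- switch(config$miss_model,
      none = u < 0,
      mcar = u < config$miss_rate,
      mnar = u < plogis(config$miss_intercept +
                          config$miss_slope * log10(vals))
    )
    vals[miss] <- NA_real_
    for (fr in seq_len(f)) {
      lfq[[paste0(subj_ids[si], "_F", fr)]] <- vals[, fr]
    }
  }
  lfq <- as_lfq_tbl(lfq)

  design <- tibble::tibble(
    sample_id = as.vector(t(outer(subj_ids, seq_len(f),
                                  function(s, fr) paste0(s, "_F", fr)))),
    subject_id = rep(subj_ids, each = f),
    fraction = rep(seq_len(f), n_subj),
    diagnosis = rep(diagnosis, each = f)
  )
  covars <- tibble::tibble(
    subject_id = subj_ids,
    age = round(rnorm(n_subj, 90, 3), 1),
    pmi = round(rlnorm(n_subj, log(14), 0.35), 1),
    sex = sample(c("F", "M"), n_subj, replace = TRUE)
  )
  design <- as_study_design(dplyr::left_join(design, covars, by = "subject_id"))

  markers <- as_marker_catalog(
    tibble::tibble(protein_id = marker_ids, organelle = marker_class),
    n_per_class = min(35L, config$n_markers_per_class)
  )

  truth <- tibble::tibble(
    protein_id = protein_id, true_class = true_class,
    is_marker = is_marker, is_effect = is_effect,
    target_class = target_class,
    true_entropy_control = entropy_rows(prof_control),
    true_entropy_case = entropy_rows(prof_case)
  )
  truth$true_delta_entropy <- truth$true_entropy_control - truth$true_entropy_case

  structure(list(lfq = lfq, design = design, markers = markers,
                 truth = truth, archetypes = arch, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$lfq), " proteins x ",
      length(lfq_samples(x$lfq)), " samples (",
      sum(x$truth$is_marker), " markers, ", sum(x$truth$is_effect),
      " planted effects, seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset as ingest-format fixtures
#'
#' Emits `proteinGroups.tsv` (MaxQuant dialect), `metadata.tsv`,
#' `markers.tsv` and `truth.tsv` into a directory. Reading the first three
#' back with the ingest readers reproduces the in-memory dataset.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    lfq = file.path(dir, "proteinGroups.tsv"),
    design = file.path(dir, "metadata.tsv"),
    markers = file.path(dir, "markers.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_lfq_table(dataset$lfq, paths["lfq"])
  readr::write_tsv(tibble::as_tibble(dataset$design), paths["design"],
                   progress = FALSE)
  readr::write_tsv(tibble::as_tibble(dataset$markers)[, c("protein_id", "organelle")],
                   paths["markers"], progress = FALSE)
  readr::write_tsv(dataset$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
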