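#' Per-subject feature table for organelle classification
#'
#' Builds the feature matrix one subject's SVM is trained and scored on:
#' each protein's values across that subject's F fractions, derived from
#' zero-policy LFQ, then centred and scaled per fraction using statistics
#' fitted on the *training markers only* and applied unchanged to every
#' protein (so the classifier never peeks at non-marker distributions).
#'
#' By default the raw intensities are first converted to within-subject
#' proportional profiles (`values = "ratio"`), which carry the localization
#' signal free of per-protein abundance scale; `values = "lfq"` standardizes
#' the raw zero-imputed intensities instead.
#'
#' @param x An `lfq_tbl`.
#' @param design A `study_design` matching `x`.
#' @param subject Subject id to build features for.
#' @param training A `marker_catalog` holding the (down-sampled) training
#'   markers; the per-fraction centre/scale is fitted on these rows. With
#'   `scale_on = "all"` the scaler is fitted on all proteins instead.
#' @param values `"ratio"` (default) or `"lfq"`.
#' @param scale_on `"markers"` (default) or `"all"`.
#' @return A `subject_features` object: feature matrix (proteins x
#'   fractions), the scaling parameters, the training ids present, and the
#'   ids of proteins dropped for having no signal in this subject.
#' @export
build_features <- function(x, design, subject, training,
                           values = c("ratio", "lfq"),
                           scale_on = c("markers", "all")) {
  stopifnot(is_lfq_tbl(x), is_study_design(design), is_marker_catalog(training))
  values <- match.arg(values)
  scale_on <- match.arg(scale_on)
  check_design_match(x, design)
  rows <- design[design$subject_id == subject, ]
  if (nrow(rows) == 0) {
    abort(paste0("Unknown subject '", subject, "'."),
          class = "organellar_validation_error")
  }
  rows <- rows[order(rows$fraction), ]
  m <- lfq_matrix(apply_missing_policy(x, missing_policy("zero")))
  m <- m[, rows$sample_id, drop = FALSE]
  colnames(m) <- paste0("F", rows$fraction)
  dropped <- rownames(m)[rowSums(m) == 0]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (values == "ratio") m <- m / rowSums(m)
  train_ids <- intersect(training$protein_id, rownames(m))
  if (length(train_ids) == 0) {
    abort("No training markers present for this subject.",
          class = "organellar_validation_error")
  }
  fit_rows <- if (scale_on == "markers") m[train_ids, , drop = FALSE] else m
  centers <- colMeans(fit_rows)
  scales <- apply(fit_rows, 2, sd)
  if (any(scales == 0)) {
    warn(paste0("Zero-variance feature(s) ",
                paste(colnames(m)[scales == 0], collapse = ", "),
                ": centred but not rescaled."))
    scales[scales == 0] <- 1
  }
  feat <- sweep(sweep(m, 2, centers), 2, scales, "/")
  structure(list(subject_id = subject, features = feat,
                 centers = centers, scales = scales,
                 training_ids = train_ids, dropped = dropped,
                 values = values, scale_on = scale_on),
            class = "subject_features")
}

#' @export
print.subject_features <- function(x, ...) {
  cat("<subject_features> subject ", x$subject_id, ": ",
      nrow(x$features), " proteins x ", ncol(x$features), " fractions (",
      x$values, " values, scaler fitted on ", x$scale_on, ")\n", sep = "")
  invisible(x)
}

# stratified k-fold assignment: shuffles within class, then deals fold ids
# round-robin so every fold sees every class
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train one subject's organelle SVM
#'
#' Radial-basis-function SVM over the subject's marker features, with
#' hyperparameters chosen to maximize stratified 10-fold cross-validated
#' accuracy over a `n_tuning` x `n_tuning` grid: sigma (the RBF width,
#' libsvm's gamma) spans `2^-8 .. 2^1` times the median-pairwise-distance
#' heuristic value, and the cost C spans `2^-2 .. 2^7`. Ties prefer the
#' smaller C, then the smaller sigma. Training performance is summarized as
#' the percentage of held-out markers assigned to the correct organelle,
#' per class, at the selected hyperparameters.
#'
#' @param features A `subject_features` object.
#' @param markers A balanced `marker_catalog` (e.g. from
#'   [downsample_markers()]); classes must have equal sizes.
#' @param cv_folds Cross-validation folds (default 10).
#' @param n_tuning Grid levels per hyperparameter (default 10).
#' @param seed Integer seed controlling fold assignment; `NULL` uses the
#'   current RNG state.
#' @return A `subject_svm` object with the fitted model, chosen `sigma` and
#'   `C`, the full tuning grid, per-class CV performance (percent correct)
#'   and the training protein ids. Has [tidy()] and [glance()] methods.
#' @export
train_subject_svm <- function(features, markers, cv_folds = 10, n_tuning = 10,
                              seed = NULL) {
  stopifnot(inherits(features, "subject_features"), is_marker_catalog(markers))
  ids <- intersect(markers$protein_id, rownames(features$features))
  lab <- markers$organelle[match(ids, markers$protein_id)]
  if (dplyr::n_distinct(lab) < 2) {
    abort("Need at least two trainable classes.",
          class = "organellar_validation_error")
  }
  X <- features$features[ids, , drop = FALSE]
  y <- factor(lab)
  if (anyNA(X)) {
    abort("Features contain missing values; apply the zero policy first.",
          class = "organellar_validation_error")
  }
  d2 <- stats::dist(X)^2
  sigma0 <- 1 / stats::median(d2[d2 > 0])
  sigmas <- sigma0 * 2^seq(-8, 1, length.out = n_tuning)
  costs <- 2^seq(-2, 7, length.out = n_tuning)
  run <- function() {
    fold <- stratified_folds(y, cv_folds)
    grid <- tidyr::expand_grid(sigma = sigmas, C = costs)
    cv_pred <- function(sg, cc) {
      pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
      for (k in sort(unique(fold))) {
        tr <- fold != k
        fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                          gamma = sg, cost = cc, scale = FALSE)
        pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])
      }
      pred
    }
    grid$accuracy <- purrr::map2_dbl(grid$sigma, grid$C,
                                     function(sg, cc) mean(cv_pred(sg, cc) == y))
    best <- grid[order(-grid$accuracy, grid$C, grid$sigma), ][1, ]
    held_out <- cv_pred(best$sigma, best$C)
    perf <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(organelle = as.character(y),
                                     correct = held_out == y),
                      .data$organelle),
      pct_correct = 100 * mean(.data$correct), n = dplyr::n(),
      .groups = "drop"
    )
    final <- e1071::svm(X, y, kernel = "radial", gamma = best$sigma,
                        cost = best$C, scale = FALSE)
    list(grid = grid, best = best, perf = perf, final = final)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(subject_id = features$subject_id, model = res$final,
                 sigma = res$best$sigma, C = res$best$C,
                 cv_accuracy = res$best$accuracy, grid = res$grid,
                 performance = res$perf, classes = levels(y),
                 training_ids = ids, cv_folds = cv_folds,
                 n_tuning = n_tuning, seed = seed),
            class = "subject_svm")
}

#' @export
tidy.subject_svm <- function(x, ...) {
  dplyr::mutate(x$performance, subject_id = x$subject_id, .before = 1)
}

#' @export
glance.subject_svm <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, sigma = x$sigma, C = x$C,
                 cv_accuracy = x$cv_accuracy,
                 mean_pct_correct = mean(x$performance$pct_correct),
                 n_classes = length(x$classes),
                 n_train = length(x$training_ids))
}

#' @export
print.subject_svm <- function(x, ...) {
  cat("<subject_svm> subject ", x$subject_id, ": ", length(x$classes),
      " classes, CV accuracy ", sprintf("%.1f%%", 100 * x$cv_accuracy),
      " (sigma=", signif(x$sigma, 3), ", C=", signif(x$C, 3), ")\n", sep = "")
  invisible(x)
}

#' Classify the proteins outside the training set
#'
#' Predicts an organelle for every protein in the subject's feature table
#' that was not used to train the model (held-out markers are scored like
#' any other non-training protein).
#'
#' @param model A `subject_svm`.
#' @param features The `subject_features` the model was trained on.
#' @param training_ids Protein ids to exclude (default: the model's).
#' @return A tibble `protein_id`, `subject_id`, `organelle`.
#' @export
classify_nonmarkers <- function(model, features, training_ids = model$training_ids) {
  stopifnot(inherits(model, "subject_svm"), inherits(features, "subject_features"))
  if (!identical(model$subject_id, features$subject_id)) {
    abort("Model and features belong to different subjects.",
          class = "organellar_validation_error")
  }
  X <- features$features
  if (anyNA(X)) {
    abort("Features contain missing values; apply the zero policy first.",
          class = "organellar_validation_error")
  }
  keep <- setdiff(rownames(X), training_ids)
  X <- X[keep, , drop = FALSE]
  pred <- predict(model$model, X)
  tibble::tibble(protein_id = keep, subject_id = features$subject_id,
                 organelle = as.character(pred))
}

#' Run the per-subject SVM classification for every subject
#'
#' For each subject: draw a fresh balanced down-sample of the markers usable
#' in that subject, build the subject's feature table, tune and train the
#' RBF-SVM, and classify all non-training proteins. The master seed expands
#' to independent per-subject streams, so one subject's results do not
#' depend on the processing order of the others.
#'
#' @param x An `lfq_tbl`.
#' @param design A `study_design`.
#' @param catalog A `marker_catalog`.
#' @param n_per_class Markers per class after down-sampling (default 35).
#' @param cv_folds,n_tuning Passed to [train_subject_svm()].
#' @param seed Master integer seed.
#' @param values,scale_on Passed to [build_features()].
#' @return An `organelle_assignments` object: `assignments` tibble
#'   (`protein_id`, `subject_id`, `organelle`), `performance` tibble
#'   (per subject and class), `models` (list of `subject_svm`), and
#'   `training` (per-subject training catalogs).
#' @export
classify_all_subjects <- function(x, design, catalog, n_per_class = 35,
                                  cv_folds = 10, n_tuning = 10, seed = 1,
                                  values = "ratio", scale_on = "markers") {
  stopifnot(is_lfq_tbl(x), is_study_design(design), is_marker_catalog(catalog))
  subjects <- unique(design$subject_id)
  models <- list(); training <- list()
  assignments <- list(); performance <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    s_seed <- seed + i
    feat_all <- build_features(x, design, s,
                               training = catalog, values = values,
                               scale_on = "all")
    usable <- catalog[catalog$protein_id %in% rownames(feat_all$features), ]
    usable <- as_marker_catalog(tibble::as_tibble(usable)[, c("protein_id", "organelle")],
                                n_per_class = n_per_class)
    train_cat <- downsample_markers(usable, n_per_class = n_per_class,
                                    seed = s_seed)
    feat <- build_features(x, design, s, training = train_cat,
                           values = values, scale_on = scale_on)
    mod <- train_subject_svm(feat, train_cat, cv_folds = cv_folds,
                             n_tuning = n_tuning, seed = s_seed)
    models[[s]] <- mod
    training[[s]] <- train_cat
    assignments[[s]] <- classify_nonmarkers(mod, feat)
    performance[[s]] <- tidy(mod)
  }
  structure(list(assignments = dplyr::bind_rows(assignments),
                 performance = dplyr::bind_rows(performance),
                 models = models, training = training,
                 n_per_class = n_per_class, seed = seed),
            class = "organelle_assignments")
}

#' @export
print.organelle_assignments <- function(x, ...) {
  cat("<organelle_assignments> ", dplyr::n_distinct(x$assignments$protein_id),
      " proteins across ", length(x$models), " subjects\n", sep = "")
  invisible(x)
}

# tier rule for one protein's label multiset: HIGH if the modal label covers
# at least high_threshold of n_expected subjects (rescaled proportionally if
# some labels are unavailable); LOW if all labels are distinct or no unique
# modal label exists; MEDIUM otherwise.
label_tier <- function(labels, n_expected, high_threshold) {
  n <- length(labels)
  if (n < 2) return(list(tier = NA_character_, dominant = NA_character_,
                         rescaled = NA))
  counts <- sort(table(labels), decreasing = TRUE)
  need <- ceiling(high_threshold / n_expected * n)
  rescaled <- n != n_expected
  if (counts[1] >= need) {
    return(list(tier = "HIGH", dominant = names(counts)[1], rescaled = rescaled))
  }
  if (length(counts) == n) { # all distinct
    return(list(tier = "LOW", dominant = NA_character_, rescaled = rescaled))
  }
  if (sum(counts == counts[1]) > 1) { # tied mode: no dominant assignment
    return(list(tier = "LOW", dominant = NA_character_, rescaled = rescaled))
  }
  list(tier = "MEDIUM", dominant = names(counts)[1], rescaled = rescaled)
}

#' Cross-subject consensus confidence tiers
#'
#' Summarizes the per-subject organelle assignments of each protein over the
#' control subjects into a confidence tier: `HIGH` if at least
#' `high_threshold` of `n_control` subjects agree (4 of 5 by default),
#' `LOW` if every subject gave a different organelle or no single organelle
#' dominates (tied modes), and `MEDIUM` when a unique dominant assignment
#' exists short of the HIGH bar. Proteins lacking a label in some subjects
#' are tiered on the available labels with the HIGH bar rescaled
#' proportionally and flagged.
#'
#' @param assignments An `organelle_assignments` object or a tibble with
#'   `protein_id`, `subject_id`, `organelle`.
#' @param design A `study_design` (identifies the control subjects).
#' @param n_control Expected number of consensus subjects (default 5).
#' @param high_threshold Agreeing subjects required for HIGH (default 4).
#' @param subjects `"control"` (default) or `"all"`.
#' @return A tibble `protein_id`, `tier`, `dominant_organelle`, `n_labels`,
#'   `rescaled`.
#' @export
consensus_confidence <- function(assignments, design, n_control = 5,
                                 high_threshold = 4,
                                 subjects = c("control", "all")) {
  subjects <- match.arg(subjects)
  if (inherits(assignments, "organelle_assignments")) {
    assignments <- assignments$assignments
  }
  stopifnot(is_study_design(design))
  keep_subj <- if (subjects == "control") {
    unique(design$subject_id[design$diagnosis == "CONTROL"])
  } else {
    unique(design$subject_id)
  }
  n_expected <- if (subjects == "control") n_control else length(keep_subj)
  tb <- assignments[assignments$subject_id %in% keep_subj, ]
  out <- purrr::map_dfr(split(tb$organelle, tb$protein_id), function(labs) {
    r <- label_tier(labs, n_expected, high_threshold)
    tibble::tibble(tier = r$tier, dominant_organelle = r$dominant,
                   n_labels = length(labs), rescaled = r$rescaled)
  }, .id = "protein_id")
  out$tier <- factor(out$tier, levels = c("HIGH", "MEDIUM", "LOW"))
  out[order(out$protein_id), ]
}

#' Does classifier performance depend on diagnosis or PMI?
#'
#' Ordinary least squares of each subject's mean training performance
#' (mean per-class percent correct) on diagnosis group and post-mortem
#' interval. Non-significant coefficients support that classification
#' quality is comparable across groups and unaffected by PMI.
#'
#' @param assignments An `organelle_assignments` object, or a tibble with
#'   `subject_id` and `pct_correct` per class.
#' @param design A `study_design` with a `pmi` covariate (diagnosis always
#'   used; PMI dropped with a warning if absent).
#' @return A tidy coefficient tibble: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
performance_covariate_check <- function(assignments, design) {
  stopifnot(is_study_design(design))
  perf <- if (inherits(assignments, "organelle_assignments")) {
    assignments$performance
  } else {
    assignments
  }
  by_subj <- dplyr::summarise(dplyr::group_by(perf, .data$subject_id),
                              mean_perf = mean(.data$pct_correct),
                              .groups = "drop")
  covars <- dplyr::distinct(
    tibble::as_tibble(design)[, intersect(c("subject_id", "diagnosis", "pmi"),
                                          names(design))],
    .data$subject_id, .keep_all = TRUE)
  dat <- dplyr::inner_join(by_subj, covars, by = "subject_id")
  if (dplyr::n_distinct(dat$diagnosis) < 2 ||
      min(table(dat$diagnosis)) < 2) {
    abort("Need at least two subjects per diagnosis group.",
          class = "organellar_validation_error")
  }
  form <- if ("pmi" %in% names(dat)) mean_perf ~ diagnosis + pmi else mean_perf ~ diagnosis
  if (!"pmi" %in% names(dat)) warn("No pmi covariate in design; using diagnosis only.")
  fit <- lm(form, data = dat)
  cf <- summary(fit)$coefficients
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(aliased) > 0) {
    warn(paste0("Collinear term(s) dropped: ", paste(aliased, collapse = ", ")))
  }
  tibble::tibble(term = rownames(cf), estimate = unname(cf[, 1]),
                 std.error = unname(cf[, 2]), statistic = unname(cf[, 3]),
                 p.value = unname(cf[, 4]))
}
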