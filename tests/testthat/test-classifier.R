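# small separable feature fixture: k classes at distant centroids
separable_features <- function(n_per_class = 35, k = 2, f = 7, sep = 5,
                               seed = 1, subject = "S1") {
  withr::with_seed(seed, {
    cent <- matrix(0, k, f)
    for (i in seq_len(k)) cent[i, ((i - 1) %% f) + 1] <- sep
    X <- cent[rep(seq_len(k), each = n_per_class), ] +
      matrix(rnorm(k * n_per_class * f), k * n_per_class, f)
    rownames(X) <- paste0("M", seq_len(nrow(X)))
    colnames(X) <- paste0("F", seq_len(f))
    markers <- suppressWarnings(as_marker_catalog(tibble::tibble(
      protein_id = rownames(X),
      organelle = rep(letters[seq_len(k)], each = n_per_class)),
      n_per_class = n_per_class))
    feat <- structure(list(subject_id = subject, features = X,
                           centers = rep(0, f), scales = rep(1, f),
                           training_ids = rownames(X), dropped = character(),
                           values = "ratio", scale_on = "markers"),
                      class = "subject_features")
    list(features = feat, markers = markers)
  })
}

test_that("marker down-sampling is balanced, seeded and exhaustive on toys", {
  cat40 <- suppressWarnings(as_marker_catalog(tibble::tibble(
    protein_id = paste0("M", 1:80), organelle = rep(c("a", "b"), each = 40))))
  out <- downsample_markers(cat40, 35, seed = 7)
  expect_equal(as.integer(table(out$organelle)), c(35L, 35L))
  expect_identical(downsample_markers(cat40, 35, seed = 7)$protein_id,
                   out$protein_id)

  cat35 <- suppressWarnings(as_marker_catalog(tibble::tibble(
    protein_id = paste0("M", 1:35), organelle = "a"), n_per_class = 35))
  expect_setequal(downsample_markers(cat35, 35, seed = 1)$protein_id,
                  cat35$protein_id)

  # 6-choose-3: all 20 subsets reachable, seeds vary the selection
  cat6 <- suppressWarnings(as_marker_catalog(tibble::tibble(
    protein_id = paste0("M", 1:6), organelle = "a"), n_per_class = 3))
  picks <- vapply(1:200, function(s)
    paste(sort(downsample_markers(cat6, 3, seed = s)$protein_id), collapse = "+"),
    character(1))
  expect_equal(length(unique(picks)), choose(6, 3))

  small <- suppressWarnings(as_marker_catalog(tibble::tibble(
    protein_id = paste0("M", 1:50),
    organelle = rep(c("a", "b"), c(40, 10)))))
  expect_warning(kept <- downsample_markers(small, 35, seed = 1),
                 regexp = "fewer than 35")
  expect_setequal(unique(kept$organelle), "a")
})

test_that("feature standardization uses training-marker moments", {
  design <- toy_design1(2)
  m <- rbind(c(2, 10), c(4, 30), c(9, 20)) # P1, P2 markers; P3 extra
  x <- toy_lfq(m, sample_ids = design$sample_id)
  markers <- suppressWarnings(as_marker_catalog(tibble::tibble(
    protein_id = c("P1", "P2"), organelle = c("a", "b")), n_per_class = 1))
  feat <- build_features(x, design, "S1", training = markers, values = "lfq")
  # training markers {2, 4} in fraction 1 -> standardized to -1, +1 (sample SD)
  expect_equal(unname(feat$features[c("P1", "P2"), "F1"]),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(feat$centers["F1"]), 3)
  expect_equal(unname(feat$scales["F1"]), sd(c(2, 4)))
  # all proteins transformed with the same parameters
  expect_equal(unname(feat$features["P3", "F1"]), (9 - 3) / sd(c(2, 4)))

  # constant fraction across markers: centred, not rescaled
  m2 <- rbind(c(5, 10), c(5, 30))
  x2 <- toy_lfq(m2, sample_ids = design$sample_id)
  expect_warning(f2 <- build_features(x2, design, "S1", training = markers,
                                      values = "lfq"),
                 regexp = "Zero-variance")
  expect_equal(unname(f2$features[, "F1"]), c(0, 0))

  # moment oracle on a random fixture
  d3 <- toy_design1(4)
  x3 <- random_lfq(d3, n_proteins = 30, seed = 17)
  mk3 <- suppressWarnings(as_marker_catalog(tibble::tibble(
    protein_id = paste0("P", 1:10), organelle = rep(c("a", "b"), 5)),
    n_per_class = 5))
  f3 <- build_features(x3, d3, "S1", training = mk3, values = "lfq")
  raw <- lfq_matrix(apply_missing_policy(x3, missing_policy("zero")))
  expect_equal(unname(f3$centers), unname(colMeans(raw[1:10, ])), tolerance = 1e-12)
  expect_equal(unname(f3$scales), unname(apply(raw[1:10, ], 2, sd)), tolerance = 1e-12)
})

test_that("linearly separable classes train to perfect per-class performance", {
  fx <- separable_features(n_per_class = 35, k = 2, sep = 5, seed = 2)
  mod <- train_subject_svm(fx$features, fx$markers, cv_folds = 5, n_tuning = 3,
                           seed = 3)
  expect_true(all(mod$performance$pct_correct == 100))
  expect_equal(mod$cv_accuracy, 1)
  # determinism under the seed
  mod2 <- train_subject_svm(fx$features, fx$markers, cv_folds = 5, n_tuning = 3,
                            seed = 3)
  expect_equal(mod2$sigma, mod$sigma)
  expect_equal(mod2$C, mod$C)
  expect_equal(mod2$performance, mod$performance)
})

test_that("permuted labels drop CV accuracy to chance", {
  accs <- vapply(1:20, function(s) {
    fx <- separable_features(n_per_class = 20, k = 4, sep = 5, seed = 100 + s)
    withr::with_seed(200 + s, {
      perm_markers <- fx$markers
      perm_markers$organelle <- sample(perm_markers$organelle)
    })
    mod <- train_subject_svm(fx$features, perm_markers, cv_folds = 5,
                             n_tuning = 3, seed = 300 + s)
    mod$cv_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.10)
})

test_that("classification covers exactly the non-training proteins", {
  fx <- separable_features(n_per_class = 20, k = 3, sep = 6, seed = 5)
  # add held-out points at the class centroids
  X <- fx$features$features
  extra <- matrix(0, 3, ncol(X))
  for (i in 1:3) extra[i, i] <- 6
  rownames(extra) <- paste0("HELD", 1:3)
  fx$features$features <- rbind(X, extra)
  mod <- train_subject_svm(fx$features, fx$markers, cv_folds = 5, n_tuning = 3,
                           seed = 6)
  pred <- classify_nonmarkers(mod, fx$features)
  expect_setequal(pred$protein_id, paste0("HELD", 1:3))
  expect_false(any(mod$training_ids %in% pred$protein_id))
  # centroid points classified as their class
  expect_equal(pred$organelle[match(paste0("HELD", 1:3), pred$protein_id)],
               c("a", "b", "c"))
})

test_that("consensus tiers follow the agreement rules on all label patterns", {
  d <- toy_design(5, 2)
  tier_of <- function(labs) {
    asn <- tibble::tibble(protein_id = "P", subject_id = paste0("CTRL", seq_along(labs)),
                          organelle = labs)
    out <- consensus_confidence(asn, d)
    as.character(out$tier)
  }
  expect_equal(tier_of(c("mito", "mito", "mito", "mito", "er")), "HIGH")
  expect_equal(tier_of(c("a", "b", "c", "d", "e")), "LOW")
  expect_equal(tier_of(c("a", "a", "b", "b", "c")), "LOW")   # tied mode
  expect_equal(tier_of(c("a", "a", "a", "b", "c")), "MEDIUM")

  # exhaustive: every 5-label pattern over 5 symbols obeys the rule table
  pats <- expand.grid(rep(list(letters[1:5]), 5), stringsAsFactors = FALSE)
  pats <- withr::with_seed(8, pats[sample(nrow(pats), 300), ])
  for (i in seq_len(nrow(pats))) {
    labs <- as.character(unlist(pats[i, ]))
    counts <- sort(table(labs), decreasing = TRUE)
    expected <- if (counts[1] >= 4) "HIGH"
    else if (length(counts) == 5 || sum(counts == counts[1]) > 1) "LOW"
    else "MEDIUM"
    expect_equal(tier_of(labs), expected)
  }

  # missing subject labels: thresholds rescale, flag recorded
  asn4 <- tibble::tibble(protein_id = "P", subject_id = paste0("CTRL", 1:4),
                         organelle = c("a", "a", "a", "a"))
  out4 <- consensus_confidence(asn4, d)
  expect_equal(as.character(out4$tier), "HIGH") # 4/4 >= ceiling(4/5*4)
  expect_true(out4$rescaled)
})

test_that("consensus tiers partition the classified proteins", {
  withr::with_seed(33, {
    d <- toy_design(5, 2)
    prot <- paste0("P", 1:40)
    asn <- tidyr::expand_grid(protein_id = prot,
                              subject_id = paste0("CTRL", 1:5))
    asn$organelle <- sample(letters[1:6], nrow(asn), replace = TRUE)
  })
  out <- consensus_confidence(asn, d)
  expect_equal(nrow(out), 40)
  expect_equal(sum(table(out$tier)), 40)
})

test_that("covariate model recovers constructed coefficients", {
  d <- toy_design(3, 2, covariates = TRUE)
  subj <- unique(d$subject_id)
  pmi <- d$pmi[match(subj, d$subject_id)]
  perf <- tibble::tibble(subject_id = rep(subj, each = 2),
                         organelle = rep(c("a", "b"), 6),
                         pct_correct = rep(70 + 2 * pmi, each = 2))
  # exact-fit fixture: lm warns that the fit is perfect, which is the point
  out <- suppressWarnings(performance_covariate_check(perf, d))
  expect_equal(out$estimate[out$term == "pmi"], 2, tolerance = 1e-8)
  expect_equal(out$estimate[out$term == "diagnosisCONTROL"], 0, tolerance = 1e-8)

  # normal-equations oracle on a random fixture
  withr::with_seed(44, {
    perf2 <- tibble::tibble(subject_id = subj, organelle = "a",
                            pct_correct = 50 + 10 * runif(6))
  })
  out2 <- performance_covariate_check(perf2, d)
  dg <- as.integer(d$diagnosis[match(subj, d$subject_id)] == "CONTROL")
  X <- cbind(1, dg, pmi)
  beta <- solve(t(X) %*% X, t(X) %*% perf2$pct_correct)
  expect_equal(out2$estimate, as.numeric(beta), tolerance = 1e-8)
})

test_that("the full per-subject classification is deterministic by seed", {
  ds <- suppressWarnings(simulate_dataset(sim_config(
    n_classes = 8, n_markers_per_class = 12, n_nonmarkers = 40,
    n_effect = 0, seed = 55)))
  run <- function() classify_all_subjects(
    ds$lfq, ds$design, ds$markers, n_per_class = 10,
    cv_folds = 3, n_tuning = 3, seed = 9)
  a <- suppressWarnings(run())
  b <- suppressWarnings(run())
  expect_equal(a$assignments, b$assignments)
  expect_equal(a$performance, b$performance)
  # balanced training in every subject
  for (s in names(a$training)) {
    expect_true(all(table(a$training[[s]]$organelle) == 10))
  }
})
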