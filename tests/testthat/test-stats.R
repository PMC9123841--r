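test_that("entropy hits its closed-form values", {
  expect_equal(shannon_entropy(rep(1 / 7, 7)), 1, tolerance = 1e-12)
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0, 0, 0, 0)),
               1 / log2(7), tolerance = 1e-5)
  expect_lt(shannon_entropy(c(1, 0, 0, 0, 0, 0, 0)), 1e-6)
  expect_equal(shannon_entropy(c(0.5, NA, 0.5, NA)), 0.5, tolerance = 1e-6)
  expect_error(shannon_entropy(c(-0.1, 1.1)), class = "organellar_validation_error")
  expect_error(shannon_entropy(0.5), class = "organellar_validation_error")
})

test_that("entropy is bounded and Schur-concave toward the uniform profile", {
  withr::with_seed(31, {
    n <- 10000
    r <- matrix(rgamma(n * 7, shape = 0.5), n, 7)
    r <- r / rowSums(r)
    ents <- apply(r, 1, shannon_entropy)
    expect_true(all(ents >= 0 & ents <= 1 + 1e-12))
    t_mix <- runif(n)
    mixed <- t_mix * matrix(1 / 7, n, 7) + (1 - t_mix) * r
    ents_mixed <- apply(mixed, 1, shannon_entropy)
    expect_true(all(ents_mixed >= ents - 1e-12))
  })
})

test_that("entropy table reproduces per-profile brute force and delta sign", {
  design <- toy_design(2, 7)
  x <- random_lfq(design, n_proteins = 10, miss_frac = 0.15, seed = 41)
  pr <- to_proportions(x, design, missing_policy("epsilon"))
  ent <- entropy_table(pr)
  by_subj <- entropy_by_subject(ent)
  # brute force, protein by protein
  for (i in sample(nrow(by_subj), 10)) {
    rr <- pr$ratio[pr$protein_id == by_subj$protein_id[i] &
                     pr$subject_id == by_subj$subject_id[i]]
    expect_equal(by_subj$entropy[i], shannon_entropy(rr), tolerance = 1e-12)
  }
  # delta = control mean - case mean
  one <- ent[1, ]
  m_ctrl <- mean(by_subj$entropy[by_subj$protein_id == one$protein_id &
                                   by_subj$diagnosis == "CONTROL"])
  m_case <- mean(by_subj$entropy[by_subj$protein_id == one$protein_id &
                                   by_subj$diagnosis == "CASE"])
  expect_equal(one$delta_entropy, m_ctrl - m_case, tolerance = 1e-12)

  # uniform profiles everywhere -> entropy 1, delta 0
  xu <- toy_lfq(matrix(5, 3, nrow(design)), sample_ids = design$sample_id)
  entu <- entropy_table(to_proportions(xu, design, missing_policy("epsilon")))
  expect_true(all(abs(entropy_by_subject(entu)$entropy - 1) < 1e-9))
  expect_true(all(abs(entu$delta_entropy) < 1e-9))
})

test_that("an extreme contrast yields delta entropy near one", {
  design <- toy_design(2, 7)
  m <- matrix(0, 1, nrow(design))
  colnames(m) <- design$sample_id
  for (s in unique(design$subject_id)) {
    ids <- design$sample_id[design$subject_id == s]
    if (unique(design$diagnosis[design$subject_id == s]) == "CONTROL") {
      m[1, ids] <- 10 # uniform -> entropy 1
    } else {
      m[1, ids[1]] <- 70 # single fraction -> entropy ~ 0
      m[1, ids[-1]] <- NA
    }
  }
  x <- toy_lfq(m, sample_ids = design$sample_id)
  ent <- entropy_table(to_proportions(x, design, missing_policy("epsilon")))
  expect_equal(ent$delta_entropy, 1, tolerance = 1e-3)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), class = "organellar_validation_error")
  expect_equal(benjamini_hochberg(c(0.9, NA, 0.1)), c(0.9, NA, 0.2))

  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
      adj[i] <- min(1, min(m * p[o][i:m] / (i:m)))
    }
    out <- numeric(m); out[o] <- adj; out
  }
  withr::with_seed(51, {
    for (rep in 1:25) {
      p <- runif(sample(2:40, 1))^sample(1:3, 1)
      got <- benjamini_hochberg(p)
      expect_equal(got, brute_bh(p), tolerance = 1e-12)
      expect_true(all(got >= p - 1e-15))
      perm <- sample(length(p))
      expect_equal(benjamini_hochberg(p[perm]), got[perm], tolerance = 1e-12)
    }
  })
})

test_that("within-fraction t matches stats::t.test on each cell", {
  design <- toy_design(5, 3)
  x <- random_lfq(design, n_proteins = 6, miss_frac = 0.1, seed = 61)
  pr <- to_proportions(x, design)
  out <- within_fraction_tests(pr)
  tb <- tibble::as_tibble(pr)
  for (i in sample(nrow(out), 8)) {
    g <- tb[tb$protein_id == out$protein_id[i] & tb$fraction == out$fraction[i], ]
    tt <- t.test(g$ratio[g$diagnosis == "CONTROL"], g$ratio[g$diagnosis == "CASE"],
                 var.equal = TRUE)
    expect_equal(out$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(out$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(out$df[i], unname(tt$parameter), tolerance = 1e-10)
  }
  expect_true(all(out$p_adj >= out$p - 1e-15, na.rm = TRUE))
})

test_that("degenerate group values give the null result", {
  design <- toy_design(3, 2)
  # every subject has the identical profile (0.3, 0.7)
  mm <- matrix(0, 2, nrow(design)); colnames(mm) <- design$sample_id
  mm[, design$fraction == 1] <- 3
  mm[, design$fraction == 2] <- 7
  x <- toy_lfq(mm, sample_ids = design$sample_id)
  out <- within_fraction_tests(to_proportions(x, design))
  expect_true(all(out$t == 0))
  expect_true(all(out$p == 1))
})

test_that("a constructed group shift is detected against a null background", {
  design <- toy_design(5, 7)
  withr::with_seed(71, {
    n <- 100
    mm <- matrix(rlnorm(n * nrow(design), 12, 0.05), n, nrow(design))
    colnames(mm) <- design$sample_id
    # protein 1, fraction 1: cases hold 0.3 of signal, controls 0.1
    case_f1 <- design$sample_id[design$diagnosis == "CASE" & design$fraction == 1]
    ctrl_f1 <- design$sample_id[design$diagnosis == "CONTROL" & design$fraction == 1]
    base <- 162754 # e^12 scale
    mm[1, ] <- base
    mm[1, ctrl_f1] <- base * (6 * 0.1 / 0.9) * exp(rnorm(5, 0, 0.01))
    mm[1, case_f1] <- base * (6 * 0.3 / 0.7) * exp(rnorm(5, 0, 0.01))
    x <- toy_lfq(mm, sample_ids = design$sample_id)
  })
  out <- within_fraction_tests(to_proportions(x, design))
  hit <- out[out$protein_id == "P1" & out$fraction == 1, ]
  expect_lt(hit$p_adj, 0.05)
  expect_lt(hit$t, 0) # control minus case is negative here
})

test_that("ANOVA F equals the brute-force mean-square ratio", {
  design <- toy_design(2, 3) # 4 subjects x 3 fractions
  x <- random_lfq(design, n_proteins = 5, seed = 81)
  fit <- fraction_anova(x, design, transform = "log2", tukey = FALSE)
  res <- tidy(fit)
  m <- log2(lfq_matrix(apply_missing_policy(x, missing_policy("protein_min"))))
  fr <- factor(design$fraction[match(colnames(m), design$sample_id)])
  for (i in seq_len(nrow(res))) {
    y <- m[i, ]
    gm <- tapply(y, fr, mean)
    ssb <- sum(table(fr) * (gm - mean(y))^2)
    ssw <- sum((y - gm[fr])^2)
    Fb <- (ssb / (nlevels(fr) - 1)) / (ssw / (length(y) - nlevels(fr)))
    expect_equal(res$F[i], Fb, tolerance = 1e-10)
  }
  # 2-group limit: F equals t^2
  d2 <- toy_design(5, 2)
  x2 <- random_lfq(d2, n_proteins = 4, seed = 82)
  f2 <- tidy(fraction_anova(x2, d2, tukey = FALSE))
  m2 <- log2(lfq_matrix(apply_missing_policy(x2, missing_policy("protein_min"))))
  fr2 <- factor(d2$fraction[match(colnames(m2), d2$sample_id)])
  for (i in seq_len(nrow(f2))) {
    tt <- t.test(m2[i, fr2 == 1], m2[i, fr2 == 2], var.equal = TRUE)
    expect_equal(f2$F[i], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(f2$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA null gives p = 1 and a shifted fraction drives Tukey", {
  design <- toy_design(5, 7)
  mm <- matrix(1000, 2, nrow(design))
  colnames(mm) <- design$sample_id
  withr::with_seed(91, {
    mm[2, ] <- 1000 * exp(rnorm(nrow(design), 0, 0.01))
    # protein 2: fraction 4 shifted by ~10 SD on the log scale
    mm[2, design$fraction == 4] <- mm[2, design$fraction == 4] * exp(0.15)
  })
  x <- toy_lfq(mm, sample_ids = design$sample_id)
  fit <- fraction_anova(x, design)
  res <- tidy(fit)
  expect_equal(res$F[res$protein_id == "P1"], 0)
  expect_equal(res$p[res$protein_id == "P1"], 1)
  expect_lt(res$p_adj[res$protein_id == "P2"], 0.05)
  tk <- fit$tukey[fit$tukey$protein_id == "P2", ]
  expect_equal(nrow(tk), choose(7, 2)) # all pairwise fraction contrasts
  has4 <- grepl("(^4-|-4$)", tk$contrast)
  expect_true(all(tk$p_tukey[has4] < 0.05))
  expect_true(all(tk$p_tukey[!has4] > 0.05))
})

test_that("candidate ranking is order-invariant and sorts by |delta|", {
  design <- toy_design(3, 7)
  x <- random_lfq(design, n_proteins = 30, seed = 101)
  pr_eps <- to_proportions(x, design, missing_policy("epsilon"))
  pr_zero <- to_proportions(x, design)
  ent <- entropy_table(pr_eps)
  wt <- within_fraction_tests(pr_zero)
  rk <- rank_candidates(ent, wt)
  expect_true(all(diff(abs(rk$delta_entropy)) <= 1e-15))
  perm <- withr::with_seed(2, sample(nrow(x)))
  rk2 <- rank_candidates(entropy_table(to_proportions(x[perm, ], design,
                                                      missing_policy("epsilon"))),
                         within_fraction_tests(to_proportions(x[perm, ], design)))
  expect_equal(as.data.frame(rk2), as.data.frame(rk), tolerance = 1e-12)
})

test_that("a single strongly re-localized protein tops the ranking", {
  # dropout off: the epsilon convention makes per-subject entropy sensitive
  # to missing high-ratio cells, so the ranking property is a statement
  # about the statistic itself, not about dropout noise
  hits <- 0L
  for (s in 1:20) {
    ds <- simulate_dataset(sim_config(n_markers_per_class = 10, n_nonmarkers = 420,
                                      n_effect = 1, effect_lambda = 0.8,
                                      effect_target = "max_contrast",
                                      miss_model = "none", seed = 600 + s))
    ent <- entropy_table(to_proportions(ds$lfq, ds$design, missing_policy("epsilon")))
    wt <- within_fraction_tests(to_proportions(ds$lfq, ds$design))
    rk <- rank_candidates(ent, wt)
    eff <- ds$truth$protein_id[ds$truth$is_effect]
    if (rk$protein_id[1] == eff) hits <- hits + 1L
  }
  expect_gte(hits, 18)
})
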