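test_that("fold plans are patient-disjoint, exhaustive, and stratified", {
  coh <- tiny_cohort(n_patients = 40, n_pairs = 100, seed = 11)
  plan <- make_fold_plan(coh, k = 5, test_ratio = 0.2, seed = 1)
  all_p <- unique(cohort_patients(coh))

  parts <- c(plan$folds, list(plan$holdout))
  for (i in seq_along(parts)) {
    for (j in seq_along(parts)) {
      if (i < j) expect_length(intersect(parts[[i]], parts[[j]]), 0)
    }
  }
  expect_setequal(unlist(parts), all_p)

  # per-fold positive fraction within one patient of the global split
  plab <- plan$patient_labels
  rest <- setdiff(all_p, plan$holdout)
  per_fold_pos <- vapply(plan$folds, function(f) sum(plab[f]), numeric(1))
  expected <- sum(plab[rest]) / plan$k
  expect_true(all(abs(per_fold_pos - expected) <= 1))

  expect_identical(plan, make_fold_plan(coh, k = 5, test_ratio = 0.2,
                                        seed = 1))
})

test_that("fold plan edge cases: exhaustive partition and holdout size", {
  coh10 <- tiny_cohort(n_patients = 10, n_pairs = 20, seed = 12)
  plan <- make_fold_plan(coh10, k = 10, test_ratio = 0, seed = 2)
  expect_length(plan$holdout, 0)
  expect_true(all(lengths(plan$folds) == 1))

  coh300 <- generate_cohort(generate_vocabulary(30, 6, seed = 3),
                            n_patients = 300, n_pairs = 380, seed = 3)
  plan300 <- make_fold_plan(coh300, k = 10, test_ratio = 0.2, seed = 3)
  expect_length(plan300$holdout, 60)

  expect_invalid(make_fold_plan(coh10, k = 11, test_ratio = 0, seed = 1))
})

test_that("accuracy and F1 follow the confusion-table formulas", {
  perfect <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unname(perfect), c(1, 1, 1, 1))

  # TP=2 FP=1 FN=1 TN=6 -> accuracy 0.8, F1 = 2*2/(1 + 4 + 1)
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  p <- c(0.9, 0.8, 0.3, 0.7, 0.1, 0.2, 0.1, 0.1, 0.2, 0.3)
  m <- classification_metrics(y, p)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["f1"]), 4 / 6)

  # enumerated confusion tables through score construction
  tables <- list(c(tp = 3, fp = 0, fn = 0, tn = 5),
                 c(tp = 1, fp = 2, fn = 3, tn = 4),
                 c(tp = 0, fp = 1, fn = 2, tn = 3))
  for (tb in tables) {
    y <- c(rep(1, tb["tp"]), rep(0, tb["fp"]), rep(1, tb["fn"]),
           rep(0, tb["tn"]))
    s <- c(rep(0.9, tb["tp"] + tb["fp"]), rep(0.1, tb["fn"] + tb["tn"]))
    if (length(unique(y)) < 2) next
    m <- classification_metrics(y, s)
    expect_equal(unname(m["accuracy"]),
                 (tb[["tp"]] + tb[["tn"]]) / sum(tb))
    expect_equal(unname(m["f1"]),
                 2 * tb[["tp"]] /
                   (tb[["fn"]] + 2 * tb[["tp"]] + tb[["fp"]]))
  }
})

test_that("AUC equals the exhaustive concordant-pair statistic, ties by midrank", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:20, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 1)  # coarse scores force ties
    expect_equal(unname(classification_metrics(y, s)["auc"]),
                 brute_auc(y, s), tolerance = 1e-12)
  }
})

test_that("AUC and AUPRC agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (rep in 1:5) {
    y <- c(0, 1, sample(0:1, 30, replace = TRUE))
    s <- rnorm(32)
    ours <- classification_metrics(y, s)
    ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<")))
    expect_equal(unname(ours["auc"]), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  y <- sample(0:1, 25, replace = TRUE)
  y[1:2] <- c(0, 1)
  s <- rnorm(25)
  a0 <- classification_metrics(y, s)["auc"]
  for (f in list(function(x) 3 * x + 1, function(x) exp(x),
                 function(x) atan(x))) {
    expect_equal(unname(classification_metrics(y, f(s))["auc"]),
                 unname(a0), tolerance = 1e-12)
  }
})

test_that("AUPRC step integration matches a hand-computed curve", {
  # scores (desc): y = 1, 0, 1, 0 -> precision at recalls .5 and 1
  y <- c(1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.6, 0.2)
  # thresholds: after 1 pos: P=1, R=.5; after pos at rank 3: P=2/3, R=1
  expected <- 0.5 * 1 + 0.5 * (2 / 3)
  expect_equal(unname(classification_metrics(y, s)["auprc"]), expected,
               tolerance = 1e-12)
  expect_degenerate(classification_metrics(c(1, 1), c(0.5, 0.6)))
})

test_that("Cohen's d follows the pooled-SD formula", {
  a <- c(0.8, 0.9, 0.85)
  expect_equal(cohens_d(a, a), 0)
  b <- a - 0.1
  expect_equal(cohens_d(a, b), 0.1 / sd(a), tolerance = 1e-12)

  set.seed(8)
  x <- rnorm(10); z <- rnorm(10)
  sp <- sqrt((9 * var(x) + 9 * var(z)) / 18)
  expect_equal(cohens_d(x, z), (mean(x) - mean(z)) / sp, tolerance = 1e-12)

  expect_degenerate(cohens_d(c(1, 1), c(1, 1)))
  expect_invalid(cohens_d(1, c(1, 2)))
  expect_identical(effect_size_label(c(0.9, -0.6, 0.1)),
                   c("large", "moderate", "small"))
})

test_that("pooled and weighted features reduce and agree with loop oracles", {
  v <- tiny_vocab(n_codes = 10, n_groups = 2, seed = 13)
  emb <- rand_embedding(v, D = 6, seed = 14)
  ten <- make_tensor(v$code[c(1, 5)], emb, labs = c(1.5, -2))

  pf <- pooled_features(ten)
  expect_length(pf, 8)
  expect_equal(pf[1:6],
               (emb$vectors[v$code[1], ] + emb$vectors[v$code[5], ]) / 10,
               ignore_attr = TRUE)
  expect_equal(pf[7:8], c(1.5, -2))

  empty <- make_tensor(character(), emb)
  expect_true(all(pooled_features(empty)[1:6] == 0))

  expect_equal(weighted_features(ten, rep(1 / 10, 10)), pf,
               tolerance = 1e-12)
  onehot <- numeric(10); onehot[ten$code_idx[1]] <- 1
  expect_equal(weighted_features(ten, onehot)[1:6],
               unname(emb$vectors[ten$codes[1], ]), tolerance = 1e-12)

  set.seed(15)
  w <- rnorm(10)
  wf <- weighted_features(ten, w)
  manual <- numeric(6)
  for (m in 1:10) manual <- manual + w[m] * ten$X[m, ]
  expect_equal(wf[1:6], manual, tolerance = 1e-12)
  expect_invalid(weighted_features(ten, w[1:3]))
})

test_that("cross-validation separates a separable cohort for every model", {
  vocab <- generate_vocabulary(30, 6, seed = 16)
  coh <- generate_cohort(vocab, n_patients = 60, n_pairs = 150, seed = 16)
  y <- cohort_labels(coh)
  # plant an unambiguous class signal in the first lab feature and shuffle
  # the code sets across samples so labs are the only informative feature
  set.seed(16)
  perm <- sample(length(coh$samples))
  code_sets <- lapply(coh$samples, `[[`, "codes")
  for (i in seq_along(coh$samples)) {
    coh$samples[[i]]$labs[1] <- ifelse(y[i] == 1, 40, -40) + rnorm(1, 0, 0.5)
    coh$samples[[i]]$codes <- code_sets[[perm[i]]]
  }
  emb <- train_embeddings(coh, D = 8, epochs = 3, seed = 16)
  plan <- make_fold_plan(coh, k = 5, test_ratio = 0, seed = 16)
  rep <- run_cv(coh, emb, plan = plan,
                cfg = train_config(max_steps = 800, lambda = 1e-2,
                                   seed = 16), pe = FALSE)
  expect_true(all(rep$folds$auc == 1))
  expect_setequal(unique(rep$folds$model),
                  c("s_ltr", "p_ltr", "lr", "svm", "nb", "rf"))
  expect_equal(nrow(rep$summary), 6 * 4)
  expect_true(all(rep$summary$sd >= 0))
  d_auc <- rep$cohens_d
  expect_true(all(c("s_ltr", "p_ltr") %in% d_auc$reference))
})

test_that("the holdout evaluation is reported separately", {
  coh <- tiny_cohort(n_patients = 40, n_pairs = 120, seed = 17)
  emb <- truth_embedding(coh)
  plan <- make_fold_plan(coh, k = 4, test_ratio = 0.25, seed = 17)
  rep <- run_cv(coh, emb, models = c("s_ltr", "lr"), plan = plan,
                cfg = train_config(max_steps = 300, seed = 17), pe = FALSE,
                include_holdout = TRUE)
  expect_false(is.null(rep$holdout))
  expect_setequal(rep$holdout$model, c("s_ltr", "lr"))
})
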