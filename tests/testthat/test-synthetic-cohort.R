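test_that("vocabulary generation is deterministic and respects sizes", {
  v1 <- generate_vocabulary(50, 10, seed = 7)
  v2 <- generate_vocabulary(50, 10, seed = 7)
  expect_identical(v1, v2)
  expect_false(identical(v1, generate_vocabulary(50, 10, seed = 8)))

  expect_equal(nrow(v1), 50)
  expect_equal(anyDuplicated(v1$code), 0)
  expect_true(all(v1$category %in% c("diagnosis", "procedure", "drug")))
  expect_lte(max(v1$group_id), 10)

  expect_invalid(generate_vocabulary(0, 1))
  expect_invalid(generate_vocabulary(5, 9))
})

test_that("vocabulary category mix scales like a hospital coding corpus", {
  v <- generate_vocabulary(8438, 500, seed = 1)
  counts <- table(v$category)
  expect_equal(nrow(v), 8438)
  expect_equal(unname(counts[["diagnosis"]]), 5970)
  expect_equal(unname(counts[["procedure"]]), 2229)
  expect_equal(unname(counts[["drug"]]), 239)
  # enough multi-member groups for pair-based evaluation
  expect_gte(sum(table(v$group_id) >= 2), 2)
})

test_that("singleton groups are allowed and yield no positive pairs", {
  v <- generate_vocabulary(5, 5, seed = 0)
  expect_equal(length(unique(v$group_id)), 5)
  emb <- rand_embedding(v, D = 4, seed = 1)
  expect_degenerate(evaluate_embedding_auc(emb))
})

test_that("cohort generation is deterministic per seed", {
  v <- tiny_vocab(seed = 3)
  c1 <- generate_cohort(v, 20, 40, seed = 11)
  c2 <- generate_cohort(v, 20, 40, seed = 11)
  expect_identical(c1, c2)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(readLines(paste0(f1, ".json")),
                   readLines(paste0(f2, ".json")))
})

test_that("cohort invariants hold: patients, codes, gaps, labels", {
  coh <- tiny_cohort(n_patients = 15, n_pairs = 40, seed = 2)
  expect_equal(length(coh$samples), 40)
  pid <- cohort_patients(coh)
  expect_equal(length(unique(pid)), 15)
  for (s in coh$samples) {
    expect_true(all(s$codes %in% coh$vocabulary$code))
    expect_gt(s$elapsed_days, 0)
    expect_true(all(is.finite(s$labs)))
    expect_true(s$label %in% c(0L, 1L))
  }
  expect_invalid(generate_cohort(coh$vocabulary, 50, 40, seed = 1))
  expect_invalid(generate_cohort(coh$vocabulary, 10, 40, noise = 0.6, seed = 1))
})

test_that("stored ground truth regenerates the labels exactly at noise = 0", {
  coh <- tiny_cohort(n_patients = 20, n_pairs = 50, seed = 4, noise = 0)
  tr <- coh$truth
  emb <- truth_embedding(coh)
  ten <- build_tensors(coh, emb, pe = FALSE,
                       lab_center = tr$lab_center, lab_scale = tr$lab_scale)
  params <- standard_ltr(tr$u, tr$v, tr$b)
  p <- vapply(ten, function(s) as.numeric(forward_standard(params, s)),
              numeric(1))
  expect_equal(p, tr$sampling$prob, tolerance = 1e-12)
  y_regen <- as.integer(tr$sampling$label_uniform < p)
  expect_identical(y_regen, cohort_labels(coh))
})

test_that("a null generating model yields coin-flip probabilities", {
  v <- tiny_vocab(n_codes = 12, n_groups = 3, seed = 5)
  D <- 4; d <- 2
  truth <- list(
    u = numeric(12), u_effective = numeric(12),
    v = numeric(D + d), b = 0,
    embedding = matrix(rnorm(12 * D), 12, D), noise = 0
  )
  coh <- generate_cohort(v, 10, 20, d = d, D = D, noise = 0, seed = 6,
                         truth = truth)
  expect_true(all(coh$truth$sampling$prob == 0.5))
})

test_that("empirical label rate matches the stored generating probabilities", {
  coh <- tiny_cohort(n_patients = 50, n_pairs = 200, seed = 3, noise = 0)
  p <- coh$truth$sampling$prob
  rate <- mean(cohort_labels(coh))
  sigma <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(rate - mean(p)), 3 * sigma + 1e-12)
})

test_that("dimension mismatches against a supplied ground truth error", {
  v <- tiny_vocab(seed = 1)
  coh <- generate_cohort(v, 10, 20, d = 4, D = 8, seed = 1)
  expect_invalid(
    generate_cohort(v, 10, 20, d = 3, D = 8, seed = 1, truth = coh$truth)
  )
  expect_invalid(
    generate_cohort(v, 10, 20, d = 4, D = 6, seed = 1, truth = coh$truth)
  )
})

test_that("same-group codes co-occur more often than cross-group codes", {
  coh <- generate_cohort(generate_vocabulary(60, 10, seed = 9),
                         n_patients = 100, n_pairs = 250, seed = 9)
  P <- ltrEHR:::presence_matrix(coh)
  C <- crossprod(P)
  grp <- coh$vocabulary$group_id
  same <- outer(grp, grp, "==") & upper.tri(C)
  diff <- outer(grp, grp, "!=") & upper.tri(C)
  expect_gt(mean(C[same]), mean(C[diff]))
})

test_that("correlation screen matches a brute-force Pearson computation", {
  coh <- tiny_cohort(n_patients = 20, n_pairs = 50, seed = 8)
  scr <- code_label_correlation_screen(coh)
  P <- ltrEHR:::presence_matrix(coh)
  y <- cohort_labels(coh)
  for (i in sample(nrow(scr), 10)) {
    x <- P[, scr$code[i]]
    expected <- if (var(x) == 0) 0 else {
      n <- length(x)
      num <- sum(x * y) - n * mean(x) * mean(y)
      den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      num / den
    }
    expect_equal(scr$pearson_r[i], expected, tolerance = 1e-12)
  }
  # sorted by |r| descending
  expect_true(!is.unsorted(rev(abs(scr$pearson_r))))
})

test_that("screen conventions: perfect association, zero variance, toy case", {
  v <- tiny_vocab(n_codes = 6, n_groups = 2, seed = 2)
  cds <- v$code
  # c1 present exactly in label-1 samples; c2 present everywhere;
  # c3 presence (1,1,0,0) against labels (1,0,1,0)
  codes_list <- list(
    c(cds[1], cds[2], cds[3]),
    c(cds[2], cds[3]),
    c(cds[1], cds[2]),
    c(cds[2])
  )
  labels <- c(1, 0, 1, 0)
  coh <- make_cohort(v, codes_list, labels)
  scr <- code_label_correlation_screen(coh)
  r <- stats::setNames(scr$pearson_r, scr$code)
  expect_equal(unname(r[cds[1]]), 1)
  expect_equal(unname(r[cds[2]]), 0)
  expect_equal(unname(r[cds[3]]), 0)

  coh_const <- make_cohort(v, codes_list, c(1, 1, 1, 1))
  expect_degenerate(code_label_correlation_screen(coh_const))
  coh_single <- make_cohort(v, codes_list[1], 1)
  expect_degenerate(code_label_correlation_screen(coh_single))
})

test_that("cohort CSV + sidecar round-trips", {
  coh <- tiny_cohort(n_patients = 10, n_pairs = 25, seed = 12)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)

  expect_identical(cohort_labels(back), cohort_labels(coh))
  expect_identical(cohort_patients(back), cohort_patients(coh))
  for (i in seq_along(coh$samples)) {
    expect_identical(back$samples[[i]]$codes, coh$samples[[i]]$codes)
    expect_equal(unname(back$samples[[i]]$labs),
                 unname(coh$samples[[i]]$labs), tolerance = 1e-11)
    expect_equal(back$samples[[i]]$elapsed_days,
                 coh$samples[[i]]$elapsed_days, tolerance = 1e-11)
  }
  # the JSON sidecar preserves the generating state exactly
  expect_identical(back$truth$u, coh$truth$u)
  expect_identical(back$truth$v, coh$truth$v)
  expect_identical(back$truth$embedding, coh$truth$embedding)
  expect_identical(as.data.frame(back$vocabulary),
                   as.data.frame(coh$vocabulary))
})
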