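# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

tiny_vocab <- function(n_codes = 20, n_groups = 4, seed = 1) {
  generate_vocabulary(n_codes, n_groups, seed = seed)
}

tiny_cohort <- function(n_patients = 25, n_pairs = 60, seed = 1, ...) {
  generate_cohort(tiny_vocab(seed = seed), n_patients = n_patients,
                  n_pairs = n_pairs, seed = seed, ...)
}

# A code_embedding with an explicitly supplied matrix.
hand_embedding <- function(vocab, vectors) {
  rownames(vectors) <- vocab$code
  ltrEHR:::new_code_embedding(vocab, vectors, method = "hand")
}

rand_embedding <- function(vocab, D = 6, seed = 1, sd = 1) {
  vec <- ltrEHR:::with_seed(seed, {
    matrix(rnorm(nrow(vocab) * D, sd = sd), nrow(vocab), D)
  })
  hand_embedding(vocab, vec)
}

# Build a sample tensor directly from a code list.
make_tensor <- function(codes, emb, labs = c(0.1, -0.2), t = 30, y = 1,
                        patient_id = "P1") {
  build_sample_tensor(
    list(patient_id = patient_id, codes = codes, labs = labs,
         elapsed_days = t, label = y),
    emb
  )
}

# Hand-assemble an ehr_cohort from per-sample fields (no ground truth).
make_cohort <- function(vocab, codes_list, labels,
                        patient_ids = sprintf("P%03d", seq_along(labels)),
                        labs = NULL, elapsed = NULL) {
  n <- length(labels)
  if (is.null(labs)) labs <- matrix(0, n, 2)
  if (is.null(elapsed)) elapsed <- rep(30, n)
  samples <- lapply(seq_len(n), function(i) {
    list(patient_id = patient_ids[i], codes = codes_list[[i]],
         labs = labs[i, ], elapsed_days = elapsed[i],
         label = as.integer(labels[i]))
  })
  structure(
    list(samples = samples, vocabulary = vocab, truth = NULL,
         d = ncol(labs), D = NA_integer_),
    class = "ehr_cohort"
  )
}

# Independent scalar-loop evaluation of the standard LTR logit.
loop_logit_standard <- function(u, v, b, X, x) {
  D <- ncol(X); d <- length(x)
  acc <- 0
  for (k in seq_len(D)) {
    uxk <- 0
    for (m in seq_len(nrow(X))) uxk <- uxk + u[m] * X[m, k]
    acc <- acc + uxk * v[k]
  }
  for (k in seq_len(d)) acc <- acc + x[k] * v[D + k]
  acc + b
}

# Exhaustive concordant-pair AUC with midrank tie handling.
brute_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  tot / (length(pos) * length(neg))
}

expect_invalid <- function(expr) {
  expect_error(expr, class = "ltrEHR_invalid_argument")
}

expect_degenerate <- function(expr) {
  expect_error(expr, class = "ltrEHR_degenerate_input")
}
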