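new_code_embedding <- function(vocabulary, vectors, method) {
  structure(
    list(vocabulary = vocabulary, vectors = vectors, D = ncol(vectors),
         method = method),
    class = "code_embedding"
  )
}

#' @export
print.code_embedding <- function(x, ...) {
  cat(sprintf("<code_embedding> %d codes, D=%d, method=%s\n",
              nrow(x$vectors), x$D, x$method))
  invisible(x)
}

#' Train medical-code embeddings on a cohort corpus
#'
#' Treats every visit as an unordered "document" of medical codes and trains
#' word2vec-style embeddings, either skip-gram with negative sampling
#' (`"sgns"`, the default) or continuous bag-of-words (`"cbow"`). Codes are
#' shuffled within each visit every epoch so the context window carries no
#' spurious order, and the default window spans the whole visit. Training is
#' single-threaded and fully seeded: identical inputs give identical vectors.
#' Codes never observed in the corpus receive a zero vector.
#'
#' @param cohort An `ehr_cohort`.
#' @param D Embedding dimension (>= 2).
#' @param method `"sgns"` or `"cbow"`.
#' @param epochs Training epochs.
#' @param window Context half-window; `NULL` uses the longest visit (full-visit
#'   context).
#' @param negatives Negative samples per positive pair.
#' @param lr Initial learning rate (linearly decayed).
#' @param seed Integer seed.
#' @return A `code_embedding` with a codes-by-`D` matrix `$vectors`.
#' @export
train_embeddings <- function(cohort, D = 100, method = c("sgns", "cbow"),
                             epochs = 5, window = NULL, negatives = 5,
                             lr = 0.025, seed = 1) {
  if (!inherits(cohort, "ehr_cohort")) stop_invalid("`cohort` must be an ehr_cohort")
  D <- check_count(D, "D", min = 2L)
  epochs <- check_count(epochs, "epochs")
  negatives <- check_count(negatives, "negatives", min = 0L)
  method <- match.arg(method)
  codes <- cohort$vocabulary$code

  sentences <- lapply(cohort$samples, function(s) {
    idx <- match(unique(s$codes), codes)
    idx[!is.na(idx)] - 1L
  })
  sentences <- Filter(length, sentences)
  if (length(sentences) == 0) stop_invalid("empty corpus: no visit has codes")

  counts <- numeric(length(codes))
  tab <- table(unlist(sentences) + 1L)
  counts[as.integer(names(tab))] <- as.numeric(tab)

  if (is.null(window)) window <- max(vapply(sentences, length, integer(1)))
  window <- check_count(window, "window")

  vec <- w2v_train_cpp(sentences, length(codes), D, window, negatives,
                       epochs, lr, method, counts, as.double(seed %% 2^31))
  vec[counts == 0, ] <- 0
  rownames(vec) <- codes
  new_code_embedding(cohort$vocabulary, vec, method = method)
}

#' Build the per-sample embedding tensor
#'
#' Stacks code-embedding vectors into the `M x D` sample matrix `X`: row `m`
#' equals the embedding of code `m` when that code was recorded at the visit
#' and is zero otherwise (presence convention; duplicate recordings collapse
#' unless `use_counts = TRUE`, in which case rows are scaled by the
#' recording count).
#'
#' @param pair A visit-pair sample (element of `cohort$samples`).
#' @param emb A `code_embedding`.
#' @param use_counts Scale rows by recording multiplicity instead of presence.
#' @return A `sample_tensor`: list with `X` (`M x D`), `x` (labs), `t`
#'   (elapsed days), `y` (label), `codes`, `code_idx`, `patient_id`,
#'   `pe_applied`, and a reference to `emb`.
#' @export
build_sample_tensor <- function(pair, emb, use_counts = FALSE) {
  if (!inherits(emb, "code_embedding")) stop_invalid("`emb` must be a code_embedding")
  vocab_codes <- rownames(emb$vectors)
  idx_all <- match(pair$codes, vocab_codes)
  if (anyNA(idx_all)) {
    stop_missing_code(unique(pair$codes[is.na(idx_all)]))
  }
  M <- length(vocab_codes)
  X <- matrix(0, M, emb$D)
  if (length(idx_all)) {
    if (use_counts) {
      cnt <- table(idx_all)
      idx <- as.integer(names(cnt))
      X[idx, ] <- emb$vectors[idx, , drop = FALSE] * as.numeric(cnt)
    } else {
      idx <- sort(unique(idx_all))
      X[idx, ] <- emb$vectors[idx, , drop = FALSE]
    }
  } else {
    idx <- integer()
  }
  structure(
    list(
      X = X,
      x = as.numeric(pair$labs),
      t = as.numeric(pair$elapsed_days),
      y = as.integer(pair$label),
      codes = vocab_codes[idx],
      code_idx = idx,
      patient_id = pair$patient_id,
      pe_applied = FALSE,
      emb = emb
    ),
    class = "sample_tensor"
  )
}

#' Build (and optionally time-encode) tensors for a whole cohort
#'
#' Converts every sample of a cohort into a [build_sample_tensor()] tensor,
#' z-scoring the lab block with cohort-level means/SDs (recorded in the
#' result's attributes) and applying positional encoding of the elapsed days
#' unless `pe = FALSE`.
#'
#' @param cohort An `ehr_cohort`.
#' @param emb A `code_embedding`.
#' @param pe Apply positional encoding?
#' @param pe_mode Passed to [apply_pe()].
#' @param use_counts Passed to [build_sample_tensor()].
#' @param standardize_labs Z-score labs using cohort means/SDs.
#' @param lab_center,lab_scale Optional explicit centering constants
#'   (override the cohort estimates).
#' @return List of `sample_tensor`s with attributes `lab_center`,
#'   `lab_scale`, `pe`, `pe_mode`.
#' @export
build_tensors <- function(cohort, emb, pe = TRUE,
                          pe_mode = c("multiplicative", "additive"),
                          use_counts = FALSE, standardize_labs = TRUE,
                          lab_center = NULL, lab_scale = NULL) {
  pe_mode <- match.arg(pe_mode)
  labs <- cohort_lab_matrix(cohort)
  if (standardize_labs) {
    if (is.null(lab_center)) lab_center <- colMeans(labs)
    if (is.null(lab_scale)) {
      lab_scale <- apply(labs, 2, sd)
      lab_scale[lab_scale < 1e-12] <- 1
    }
  } else {
    lab_center <- rep(0, ncol(labs))
    lab_scale <- rep(1, ncol(labs))
  }
  tensors <- lapply(cohort$samples, function(s) {
    ten <- build_sample_tensor(s, emb, use_counts = use_counts)
    ten$x <- (ten$x - lab_center) / lab_scale
    if (pe) ten <- apply_pe(ten, mode = pe_mode)
    ten
  })
  attr(tensors, "lab_center") <- lab_center
  attr(tensors, "lab_scale") <- lab_scale
  attr(tensors, "pe") <- pe
  attr(tensors, "pe_mode") <- if (pe) pe_mode else "none"
  tensors
}

#' Score embedding quality by phenotype-group pair classification
#'
#' Every unordered pair of diagnosis-category codes is labeled positive when
#' the two codes share a phenotype group, and the pair is scored by the
#' cosine similarity of the two embedding vectors. The AUC of that score
#' against the same-group indicator measures how well the embedding space
#' recovers clinically meaningful groupings. Pairs involving a zero vector
#' (never-observed codes) are excluded because cosine similarity is
#' undefined for them. When the pair count exceeds `max_pairs`, all positive
#' pairs are kept and negatives are subsampled with `seed`.
#'
#' @param emb A `code_embedding` whose vocabulary carries `group_id`.
#' @param category Code category evaluated (default diagnosis codes, the
#'   analog of Phecode-grouped ICD codes).
#' @param max_pairs Cap on evaluated pairs.
#' @param seed Seed for negative subsampling.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_embedding_auc <- function(emb, category = "diagnosis",
                                   max_pairs = 200000, seed = 1) {
  vocab <- emb$vocabulary
  keep <- vocab$category == category
  vecs <- emb$vectors[match(vocab$code[keep], rownames(emb$vectors)), ,
                      drop = FALSE]
  grp <- vocab$group_id[keep]
  norms <- sqrt(rowSums(vecs^2))
  nz <- norms > 0
  vecs <- vecs[nz, , drop = FALSE]
  grp <- grp[nz]
  n <- nrow(vecs)
  if (n < 2) stop_degenerate("fewer than 2 usable codes in category")
  vn <- vecs / sqrt(rowSums(vecs^2))

  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= max_pairs) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- ij[, 1]; j <- ij[, 2]
  } else {
    # all positive pairs, subsampled negatives
    pos_list <- lapply(split(seq_len(n), grp), function(idx) {
      if (length(idx) < 2) return(NULL)
      cmb <- utils::combn(idx, 2)
      cbind(cmb[1, ], cmb[2, ])
    })
    pos <- do.call(rbind, pos_list)
    n_neg <- max_pairs - nrow(pos)
    if (n_neg < 1) stop_invalid("`max_pairs` smaller than the positive pair count")
    neg <- with_seed(seed, {
      i <- sample.int(n, 3 * n_neg, replace = TRUE)
      j <- sample.int(n, 3 * n_neg, replace = TRUE)
      ok <- i < j & grp[i] != grp[j]
      cbind(i[ok], j[ok])[seq_len(min(n_neg, sum(ok))), , drop = FALSE]
    })
    i <- c(pos[, 1], neg[, 1]); j <- c(pos[, 2], neg[, 2])
  }

  same <- as.integer(grp[i] == grp[j])
  if (all(same == 1) || all(same == 0)) {
    stop_degenerate("need both positive and negative code pairs")
  }
  sims <- rowSums(vn[i, , drop = FALSE] * vn[j, , drop = FALSE])
  auc_midrank(same, sims)
}

#' Read and write embeddings in word2vec text format
#'
#' The standard interchange format: a header line `"<n_codes> <D>"` followed
#' by one line per code, `"<code> v1 ... vD"`.
#'
#' @param emb A `code_embedding`.
#' @param path File path.
#' @param vocabulary Optional `code_vocabulary` to re-attach on read (needed
#'   for group-based evaluation).
#' @param digits Significant digits written per coordinate.
#' @return `write_embedding()` returns `path` invisibly; `read_embedding()`
#'   a `code_embedding`.
#' @export
write_embedding <- function(emb, path, digits = 8) {
  vec <- emb$vectors
  lines <- c(
    sprintf("%d %d", nrow(vec), ncol(vec)),
    vapply(seq_len(nrow(vec)), function(i) {
      paste(c(rownames(vec)[i], sprintf("%.*g", digits, vec[i, ])),
            collapse = " ")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path, vocabulary = NULL) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  codes <- vapply(parts, `[[`, character(1), 1)
  vec <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  if (nrow(vec) != hdr[1] || ncol(vec) != hdr[2]) {
    stop_invalid("embedding file header disagrees with its contents")
  }
  rownames(vec) <- codes
  if (is.null(vocabulary)) {
    vocabulary <- data.frame(code = codes, category = NA_character_,
                             group_id = NA_integer_, stringsAsFactors = FALSE)
    class(vocabulary) <- c("code_vocabulary", "data.frame")
  } else {
    vec <- vec[match(vocabulary$code, codes), , drop = FALSE]
    rownames(vec) <- vocabulary$code
  }
  new_code_embedding(vocabulary, vec, method = "file")
}
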