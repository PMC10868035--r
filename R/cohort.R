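#' Default lab-feature profile for the synthetic generator
#'
#' Class-conditional means and standard deviations for the four vital/lab
#' features carried by each visit: systolic blood pressure (mmHg), heart rate
#' (bpm), chloride (mmol/L) and sodium (mmol/L). Values echo the clinical
#' profile of an advanced-heart-failure cohort, where eventual advanced-therapy
#' recipients run lower blood pressure and mildly lower sodium/chloride.
#' Features beyond the fourth (when `d > 4`) are generic standardized labs
#' with a modest class shift.
#'
#' @param d Number of lab features.
#' @return A list with `names`, `mean_pos`, `sd_pos`, `mean_neg`, `sd_neg`,
#'   `center`, `scale` (pooled centering constants used by the generator's
#'   linear predictor).
#' @export
lab_profile <- function(d = 4) {
  d <- check_count(d, "d")
  base <- list(
    names = c("sbp", "hr", "chloride", "sodium"),
    mean_pos = c(102.74, 86.09, 100.62, 137.48),
    sd_pos = c(14.95, 18.85, 4.88, 3.58),
    mean_neg = c(121.68, 86.15, 101.60, 138.06),
    sd_neg = c(22.74, 16.68, 5.79, 4.35)
  )
  if (d > 4) {
    extra <- d - 4
    base$names <- c(base$names, sprintf("lab%d", seq_len(extra) + 4L))
    base$mean_pos <- c(base$mean_pos, rep(-0.3, extra))
    base$sd_pos <- c(base$sd_pos, rep(1, extra))
    base$mean_neg <- c(base$mean_neg, rep(0, extra))
    base$sd_neg <- c(base$sd_neg, rep(1, extra))
  } else if (d < 4) {
    base <- lapply(base, function(x) x[seq_len(d)])
  }
  base$center <- (base$mean_pos + base$mean_neg) / 2
  base$scale <- (base$sd_pos + base$sd_neg) / 2
  base
}

# Lab-block regression coefficients used by the generating model, on the
# z-scored lab scale. Signs follow the clinical direction encoded in
# lab_profile(): lower pressure / sodium / chloride in the positive class.
default_lab_coef <- function(d) {
  v <- c(-0.5, -0.05, -0.15, -0.15)
  if (d <= 4) v[seq_len(d)] else c(v, rep(-0.1, d - 4))
}

#' Generate a synthetic paired-visit EHR cohort
#'
#' Simulates a cohort of paired-visit samples with known generating
#' parameters. Each sample carries the medical codes recorded at the first
#' visit, a lab vector, the elapsed days until the follow-up visit, and a
#' binary label drawn from a sparse logistic tensor regression model
#' `P(y=1) = sigmoid([u' X | x'] v + b)` where `X` stacks code-embedding rows
#' (presence convention) and `x` is the z-scored lab vector. The full
#' generating state — `u_true`, `v_true`, `b_true`, the embedding matrix, the
#' per-sample probabilities and the uniform draws behind each label — is
#' recorded in `$truth`, enabling exact label regeneration and
#' parameter-recovery experiments.
#'
#' Codes co-occur by phenotype group: each visit picks a small number of
#' "theme" groups and draws most of its codes from them, so code embeddings
#' trained on the corpus can learn the group structure. Elapsed days are
#' log-normal (heavy-tailed, median `exp(gap_meanlog)` days), emulating
#' irregular revisit gaps. Labs are drawn per latent severity class from
#' [lab_profile()].
#'
#' @param vocab A [generate_vocabulary()] result.
#' @param n_patients,n_pairs Number of patients and paired-visit samples
#'   (`n_pairs >= n_patients`; a patient with `n` visits contributes `n - 1`
#'   pairs, so patients may own several samples).
#' @param d Number of lab features.
#' @param D Embedding dimension of the generating model.
#' @param sparsity Fraction of codes with a nonzero generating weight.
#' @param noise Label-flip probability in `[0, 0.5)`.
#' @param seed Integer seed; the cohort is byte-reproducible given identical
#'   arguments.
#' @param truth Optional ground truth from a previous cohort (its `u`, `v`,
#'   `b` and embedding are reused; dimensions must match `vocab`, `d`, `D`).
#' @param label_mode `"bernoulli"` draws `y ~ Bernoulli(p)` (the generating
#'   model proper); `"threshold"` sets `y = 1{p > 0.5}`, yielding a
#'   deterministic, essentially separable labeling for sanity checks.
#' @param codes_lambda,codes_min Codes per visit are
#'   `codes_min + Poisson(codes_lambda)` draws (a multiset; duplicates
#'   collapse to presence downstream).
#' @param theme_groups,theme_prob Number of theme groups per visit and the
#'   probability each drawn code comes from a theme group rather than the
#'   whole vocabulary.
#' @param gap_meanlog,gap_sdlog Log-normal parameters of the elapsed days.
#' @param b_true Intercept of the generating model.
#' @return An `ehr_cohort`: list with `samples` (list of visit pairs),
#'   `vocabulary`, `truth`, `d`, `D`.
#' @examples
#' vocab <- generate_vocabulary(40, 8, seed = 1)
#' coh <- generate_cohort(vocab, n_patients = 30, n_pairs = 60, seed = 1)
#' mean(cohort_labels(coh))
#' @export
generate_cohort <- function(vocab, n_patients = 300, n_pairs = 557, d = 4,
                            D = 8, sparsity = 0.2, noise = 0.05, seed = 1,
                            truth = NULL,
                            label_mode = c("bernoulli", "threshold"),
                            codes_lambda = 9, codes_min = 3,
                            theme_groups = 2, theme_prob = 0.8,
                            gap_meanlog = log(60), gap_sdlog = 0.8,
                            b_true = -2) {
  if (!inherits(vocab, "code_vocabulary")) {
    stop_invalid("`vocab` must be a code_vocabulary")
  }
  n_patients <- check_count(n_patients, "n_patients")
  n_pairs <- check_count(n_pairs, "n_pairs")
  d <- check_count(d, "d")
  D <- check_count(D, "D", min = 2L)
  check_fraction(sparsity, "sparsity", max = 1 + 1e-12)
  noise <- check_fraction(noise, "noise", max = 0.5)
  if (n_pairs < n_patients) stop_invalid("`n_pairs` must be >= `n_patients`")
  label_mode <- match.arg(label_mode)
  M <- nrow(vocab)

  if (!is.null(truth)) {
    ok <- is.list(truth) &&
      length(truth$u) == M &&
      is.matrix(truth$embedding) &&
      all(dim(truth$embedding) == c(M, D)) &&
      length(truth$v) == D + d
    if (!ok) stop_invalid("`truth` dimensions inconsistent with vocab/d/D")
  }

  with_seed(seed, {
    if (is.null(truth)) {
      truth <- make_ground_truth(M, D, d, sparsity, noise, b_true)
    }
    truth$noise <- noise

    # per-code contribution to the linear predictor: beta_c = u_c * (e_c . v1)
    beta <- truth$u * drop(truth$embedding %*% truth$v[seq_len(D)])
    v_lab <- truth$v[D + seq_len(d)]
    prof <- lab_profile(d)

    patient_ids <- sprintf("P%04d", seq_len(n_patients))
    owner <- c(seq_len(n_patients),
               sample.int(n_patients, n_pairs - n_patients, replace = TRUE))
    owner <- sample(owner)

    groups <- split(seq_len(M), vocab$group_id)
    n_codes_visit <- codes_min + rpois(n_pairs, codes_lambda)
    elapsed <- rlnorm(n_pairs, gap_meanlog, gap_sdlog)

    samples <- vector("list", n_pairs)
    eta <- numeric(n_pairs)
    latent <- integer(n_pairs)
    probs <- numeric(n_pairs)
    lab_mat <- matrix(NA_real_, n_pairs, d)
    code_sets <- vector("list", n_pairs)

    for (i in seq_len(n_pairs)) {
      themes <- sample(length(groups), min(theme_groups, length(groups)))
      k <- n_codes_visit[i]
      from_theme <- runif(k) < theme_prob
      draw <- integer(k)
      theme_pick <- sample(themes, k, replace = TRUE)
      for (s in seq_len(k)) {
        draw[s] <- if (from_theme[s]) {
          g <- groups[[theme_pick[s]]]
          g[sample.int(length(g), 1L)]
        } else {
          sample.int(M, 1L)
        }
      }
      code_sets[[i]] <- draw
      eta[i] <- sum(beta[unique(draw)])
    }

    # latent severity drives lab draws; labels come from the full model below
    latent <- as.integer(runif(n_pairs) < plogis(eta + truth$b))
    for (j in seq_len(d)) {
      mu <- ifelse(latent == 1L, prof$mean_pos[j], prof$mean_neg[j])
      sg <- ifelse(latent == 1L, prof$sd_pos[j], prof$sd_neg[j])
      lab_mat[, j] <- rnorm(n_pairs, mu, sg)
    }
    zlab <- sweep(sweep(lab_mat, 2, prof$center), 2, prof$scale, "/")
    probs <- plogis(eta + drop(zlab %*% v_lab) + truth$b)

    label_u <- runif(n_pairs)
    flip_u <- runif(n_pairs)
    y0 <- if (label_mode == "bernoulli") {
      as.integer(label_u < probs)
    } else {
      as.integer(probs > 0.5)
    }
    y <- ifelse(flip_u < noise, 1L - y0, y0)

    for (i in seq_len(n_pairs)) {
      samples[[i]] <- list(
        patient_id = patient_ids[owner[i]],
        codes = vocab$code[code_sets[[i]]],
        labs = stats::setNames(lab_mat[i, ], prof$names),
        elapsed_days = elapsed[i],
        label = y[i]
      )
    }

    truth$lab_center <- prof$center
    truth$lab_scale <- prof$scale
    truth$sampling <- list(
      eta = eta, prob = probs, latent = latent,
      label_uniform = label_u, flip_uniform = flip_u,
      pre_flip_label = y0, label_mode = label_mode
    )

    structure(
      list(samples = samples, vocabulary = vocab, truth = truth,
           d = d, D = D),
      class = "ehr_cohort"
    )
  })
}

# The bilinear form u' X v identifies a code's contribution to the linear
# predictor only through the product alpha_c = u_c * (e_c . v1) (the logit
# shift when code c is present); u and v1 are not separately identified. The
# generator therefore draws the interpretable *effective* weights u_effective
# on a fixed, well-spaced grid and backs out the model parameter u = u_eff /
# (E v1) on the support, restricted to codes where |e_c . v1| is not small so
# u stays bounded. Both vectors are recorded.
make_ground_truth <- function(M, D, d, sparsity, noise, b_true) {
  nnz <- max(2L, round(sparsity * M))
  nnz <- min(nnz, M)
  npos <- ceiling(0.6 * nnz)
  nneg <- nnz - npos
  v1 <- rnorm(D)
  E <- matrix(rnorm(M * D, sd = 1 / sqrt(D)), M, D)
  cstar <- drop(E %*% v1)
  eligible <- which(abs(cstar) >= stats::median(abs(cstar)))
  idx <- sample(eligible, min(nnz, length(eligible)))
  u_eff <- numeric(M)
  u_eff[idx[seq_len(npos)]] <- seq(6.5, 2, length.out = npos)
  if (nneg > 0) {
    u_eff[idx[npos + seq_len(nneg)]] <- -seq(4.3, 2, length.out = nneg)
  }
  u <- ifelse(u_eff != 0, u_eff / cstar, 0)
  list(
    u = u,
    u_effective = u_eff,
    v = c(v1, default_lab_coef(d)),
    b = b_true,
    embedding = E,
    noise = noise
  )
}

#' @export
print.ehr_cohort <- function(x, ...) {
  y <- cohort_labels(x)
  cat(sprintf(
    "<ehr_cohort> %d samples, %d patients, %d codes (D=%d, d=%d), %.1f%% positive\n",
    length(x$samples), length(unique(cohort_patients(x))),
    nrow(x$vocabulary), x$D, x$d, 100 * mean(y)
  ))
  invisible(x)
}

#' Cohort accessors
#'
#' Convenience extractors over the sample list of an `ehr_cohort`.
#'
#' @param cohort An `ehr_cohort`.
#' @return `cohort_labels`: integer vector of 0/1 labels; `cohort_patients`:
#'   character vector of patient ids; `cohort_lab_matrix`: samples-by-`d`
#'   numeric matrix.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$samples, function(s) as.integer(s$label), integer(1))
}

#' @rdname cohort_labels
#' @export
cohort_patients <- function(cohort) {
  vapply(cohort$samples, function(s) s$patient_id, character(1))
}

#' @rdname cohort_labels
#' @export
cohort_lab_matrix <- function(cohort) {
  do.call(rbind, lapply(cohort$samples, function(s) s$labs))
}

#' Embedding used by the generating model
#'
#' Wraps the ground-truth embedding matrix of a synthetic cohort as a
#' `code_embedding`, so the generating model can be refit on exactly the
#' features that produced the labels (parameter-recovery experiments).
#'
#' @param cohort A synthetic `ehr_cohort` (must carry `$truth`).
#' @return A `code_embedding`.
#' @export
truth_embedding <- function(cohort) {
  if (is.null(cohort$truth)) stop_invalid("cohort has no recorded ground truth")
  vec <- cohort$truth$embedding
  rownames(vec) <- cohort$vocabulary$code
  new_code_embedding(cohort$vocabulary, vec, method = "truth")
}

#' Pearson screen between code presence and labels
#'
#' Represents each vocabulary code as a binary presence variable across the
#' cohort's samples and computes its Pearson correlation with the 0/1 label.
#' Codes whose presence never varies (absent everywhere or present
#' everywhere) are assigned `r = 0` by convention. This mirrors the standard
#' pre-modeling audit that no single code trivially encodes the outcome.
#'
#' @param cohort An `ehr_cohort`.
#' @return Data frame `(code, pearson_r)` sorted by `|r|` descending (ties
#'   broken by code).
#' @export
code_label_correlation_screen <- function(cohort) {
  if (!inherits(cohort, "ehr_cohort")) stop_invalid("`cohort` must be an ehr_cohort")
  y <- cohort_labels(cohort)
  if (length(y) < 2) stop_degenerate("need at least 2 samples")
  if (var(y) == 0) stop_degenerate("labels are constant; screen undefined")
  pres <- presence_matrix(cohort)
  r <- suppressWarnings(as.vector(cor(pres, y)))
  r[!is.finite(r)] <- 0
  out <- data.frame(code = colnames(pres), pearson_r = r,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$pearson_r), out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# samples x codes binary presence matrix, columns in vocabulary order
presence_matrix <- function(cohort) {
  codes <- cohort$vocabulary$code
  n <- length(cohort$samples)
  mat <- matrix(0L, n, length(codes), dimnames = list(NULL, codes))
  for (i in seq_len(n)) {
    idx <- match(unique(cohort$samples[[i]]$codes), codes)
    mat[i, idx[!is.na(idx)]] <- 1L
  }
  mat
}
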