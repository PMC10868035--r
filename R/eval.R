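# Rank-based AUC with midrank tie handling (equals the normalized
# Mann-Whitney U statistic).
auc_midrank <- function(y_true, scores) {
  y <- as.integer(y_true > 0)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_degenerate("AUC needs both classes")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve by step integration over descending
# score thresholds.
auprc_step <- function(y_true, scores) {
  y <- as.integer(y_true > 0)
  P <- sum(y)
  if (P == 0 || P == length(y)) stop_degenerate("AUPRC needs both classes")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate only at the last index of each tied score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / P
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Binary classification metrics
#'
#' Computes the four panel metrics from true labels and predicted
#' probabilities: accuracy and F1 at the given threshold (F1 as
#' `2 TP / (FN + 2 TP + FP)`), AUC by the rank (Mann-Whitney) statistic with
#' midrank tie handling, and AUPRC by step integration of the
#' precision-recall curve.
#'
#' @param y_true 0/1 labels (both classes must be present).
#' @param y_prob Predicted probabilities or scores.
#' @param threshold Classification threshold for accuracy/F1.
#' @return Named numeric vector `accuracy`, `f1`, `auc`, `auprc`.
#' @export
classification_metrics <- function(y_true, y_prob, threshold = 0.5) {
  y <- as.integer(y_true > 0)
  if (length(y) != length(y_prob)) stop_invalid("length mismatch")
  pred <- as.integer(y_prob > threshold)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  acc <- (tp + tn) / length(y)
  f1 <- if (fn + 2 * tp + fp == 0) 0 else 2 * tp / (fn + 2 * tp + fp)
  c(accuracy = acc, f1 = f1,
    auc = auc_midrank(y, y_prob), auprc = auprc_step(y, y_prob))
}

#' Cohen's d effect size between two metric samples
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled standard deviation
#' `sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`. Conventionally
#' `|d| >= 0.8` is a large effect and `0.5 <= |d| < 0.8` moderate;
#' [effect_size_label()] applies that convention.
#'
#' @param a,b Numeric vectors (length >= 2 each), e.g. per-fold AUCs of two
#'   models.
#' @return Scalar effect size.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_invalid("need >= 2 values per group")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop_degenerate("pooled standard deviation is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' @rdname cohens_d
#' @param d Effect size value.
#' @export
effect_size_label <- function(d) {
  a <- abs(d)
  ifelse(a >= 0.8, "large", ifelse(a >= 0.5, "moderate", "small"))
}

#' Patient-wise stratified fold plan
#'
#' Splits patients (never samples) into a held-out test set of ratio
#' `test_ratio` plus `k` cross-validation folds, stratified on the
#' patient-level label: a patient is positive when any of their paired-visit
#' samples is positive. The holdout size is `round(test_ratio * n)` applied
#' per class; folds are dealt round-robin per class after a seeded shuffle,
#' so per-fold class balance is within one patient of the global balance.
#' No patient appears in two folds or in both a fold and the holdout.
#'
#' @param cohort An `ehr_cohort`.
#' @param k Number of folds.
#' @param test_ratio Fraction of patients held out before folding.
#' @param seed Integer seed.
#' @return A `fold_plan`: `holdout` (patient ids), `folds` (list of k
#'   patient-id vectors), `patient_labels`.
#' @export
make_fold_plan <- function(cohort, k = 10, test_ratio = 0.2, seed = 1) {
  k <- check_count(k, "k")
  check_fraction(test_ratio, "test_ratio")
  pid <- cohort_patients(cohort)
  y <- cohort_labels(cohort)
  plab <- vapply(split(y, pid), max, numeric(1))
  patients <- names(plab)
  if (k > length(patients)) stop_invalid("`k` exceeds the number of patients")

  with_seed(seed, {
    holdout <- unlist(lapply(split(patients, plab), function(p) {
      n_hold <- round(test_ratio * length(p))
      if (n_hold == 0) character() else sample(p, n_hold)
    }), use.names = FALSE)
    rest <- setdiff(patients, holdout)
    if (k > length(rest)) stop_invalid("`k` exceeds the patients left after holdout")
    folds <- vector("list", k)
    offset <- 0L
    for (cls in unique(plab[rest])) {
      p <- sample(rest[plab[rest] == cls])
      # continue the round-robin across classes so fold sizes stay balanced
      assignment <- ((seq_along(p) - 1L + offset) %% k) + 1L
      offset <- (offset + length(p)) %% k
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], p[assignment == f])
      }
    }
    structure(
      list(holdout = sort(holdout), folds = lapply(folds, sort), k = k,
           test_ratio = test_ratio, seed = seed, patient_labels = plab),
      class = "fold_plan"
    )
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf(
    "<fold_plan> %d folds (%s patients), %d held out\n",
    x$k, paste(range(lengths(x$folds)), collapse = "-"),
    length(x$holdout)
  ))
  invisible(x)
}

#' Pooled and weighted visit representations for baseline models
#'
#' `pooled_features()` performs global average pooling along the code axis:
#' the mean over all `M` rows of `X` (zero rows included), concatenated with
#' the lab vector — a `D + d` feature vector. `weighted_features()` replaces
#' the plain average by a weighted sum `sum_m weight_m X[m, ]`, which is how
#' code weights learned by an LTR model are transferred to baseline
#' classifiers (a global `u` for the standard model, the per-sample
#' `u_i = X_i w` for the personalized model).
#'
#' @param sample A `sample_tensor`.
#' @param code_weights Numeric weight per code (length `M`).
#' @return Numeric vector of length `D + d`.
#' @export
pooled_features <- function(sample) {
  c(colMeans(sample$X), sample$x)
}

#' @rdname pooled_features
#' @export
weighted_features <- function(sample, code_weights) {
  if (length(code_weights) != nrow(sample$X)) {
    stop_invalid("`code_weights` length must equal the number of codes")
  }
  if (!all(is.finite(code_weights))) stop_invalid("`code_weights` must be finite")
  c(drop(crossprod(sample$X, code_weights)), sample$x)
}

baseline_spec <- c("lr", "svm", "nb", "rf")

# Train one baseline on standardized features and return test scores.
baseline_scores <- function(model, Xtr, ytr, Xte, seed) {
  keep <- apply(Xtr, 2, sd) > 1e-10
  if (!any(keep)) stop_degenerate("all baseline features are constant")
  mu <- colMeans(Xtr[, keep, drop = FALSE])
  sg <- apply(Xtr[, keep, drop = FALSE], 2, sd)
  ztr <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, mu), 2, sg, "/")
  zte <- sweep(sweep(Xte[, keep, drop = FALSE], 2, mu), 2, sg, "/")
  ztr <- as.data.frame(ztr); zte <- as.data.frame(zte)
  names(ztr) <- names(zte) <- sprintf("f%d", seq_len(ncol(ztr)))

  switch(model,
    lr = {
      dat <- cbind(ztr, .y = ytr)
      m <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
      suppressWarnings(as.numeric(predict(m, zte, type = "response")))
    },
    svm = {
      m <- e1071::svm(x = as.matrix(ztr), y = factor(ytr, levels = c(0, 1)),
                      kernel = "linear", scale = FALSE)
      dv <- attr(predict(m, as.matrix(zte), decision.values = TRUE),
                 "decision.values")
      s <- as.numeric(dv[, 1])
      # orient decision values so larger means class "1"
      if (colnames(dv)[1] == "0/1") s <- -s
      plogis(s)
    },
    nb = {
      m <- e1071::naiveBayes(x = ztr, y = factor(ytr, levels = c(0, 1)))
      as.numeric(predict(m, zte, type = "raw")[, "1"])
    },
    rf = {
      with_seed(seed, {
        m <- randomForest::randomForest(
          x = ztr, y = factor(ytr, levels = c(0, 1)), ntree = 300
        )
        as.numeric(predict(m, zte, type = "prob")[, "1"])
      })
    },
    stop_invalid(sprintf("unknown baseline '%s'", model))
  )
}

#' Cross-validated model comparison with optional weight transfer
#'
#' Runs the patient-wise stratified cross-validation protocol: for each fold
#' of `plan`, the LTR models are trained on the remaining folds' tensors and
#' the baselines (logistic regression, linear SVM, Gaussian naive Bayes,
#' random forest) on pooled — or, with `transfer`, LTR-weighted — visit
#' representations, then everything is scored on the fold. With
#' `transfer = "standard"` the fold's fitted global code weights `u`
#' aggregate the code embeddings; with `"personalized"` each sample uses its
#' own `u_i = X_i w`. SVM scores are platt-free decision values mapped
#' through a sigmoid; RF and NB use library probabilities. Folds whose
#' training split has a single class are skipped with a warning and
#' recorded.
#'
#' @param cohort An `ehr_cohort`.
#' @param emb A `code_embedding`.
#' @param models Character subset of
#'   `c("s_ltr", "p_ltr", "lr", "svm", "nb", "rf")`.
#' @param plan A [make_fold_plan()].
#' @param transfer `"none"`, `"standard"` or `"personalized"`.
#' @param cfg [train_config()] for the LTR fits.
#' @param pe,pe_mode Positional-encoding options for [build_tensors()].
#' @param include_holdout Also refit on all non-holdout patients and report
#'   a single evaluation on the holdout set.
#' @return An `ltr_eval_report`: `folds` (long data frame of per-fold
#'   metrics), `summary` (mean and SD per model/metric), `cohens_d`
#'   (effect sizes on AUC against each LTR model), `holdout`, `skipped`.
#' @export
run_cv <- function(cohort, emb,
                   models = c("s_ltr", "p_ltr", "lr", "svm", "nb", "rf"),
                   plan = make_fold_plan(cohort),
                   transfer = c("none", "standard", "personalized"),
                   cfg = train_config(max_steps = 1500),
                   pe = TRUE, pe_mode = "multiplicative",
                   include_holdout = FALSE) {
  transfer <- match.arg(transfer)
  models <- match.arg(models, several.ok = TRUE)
  tensors <- build_tensors(cohort, emb, pe = pe, pe_mode = pe_mode)
  pid <- vapply(tensors, `[[`, character(1), "patient_id")
  y_all <- vapply(tensors, function(s) as.numeric(s$y), numeric(1))

  need_s <- "s_ltr" %in% models || transfer == "standard"
  need_p <- "p_ltr" %in% models || transfer == "personalized"
  cv_patients <- unlist(plan$folds)

  rows <- list()
  skipped <- integer()

  eval_fold <- function(train_idx, test_idx, tag, fold_seed) {
    ytr <- y_all[train_idx]
    yte <- y_all[test_idx]
    if (length(unique(ytr)) < 2 || length(unique(yte)) < 2) return(NULL)
    out <- list()
    fit_s <- fit_p <- NULL
    cfg_fold <- modify_config(cfg, seed = fold_seed)
    if (need_s) fit_s <- fit_ltr("standard", tensors[train_idx], cfg_fold)
    if (need_p) fit_p <- fit_ltr("personalized", tensors[train_idx], cfg_fold)

    if ("s_ltr" %in% models) {
      out$s_ltr <- classification_metrics(yte, predict(fit_s, tensors[test_idx]))
    }
    if ("p_ltr" %in% models) {
      out$p_ltr <- classification_metrics(yte, predict(fit_p, tensors[test_idx]))
    }

    base_models <- intersect(models, baseline_spec)
    if (length(base_models)) {
      feat <- function(idx) {
        do.call(rbind, lapply(tensors[idx], function(s) {
          switch(transfer,
            none = pooled_features(s),
            standard = weighted_features(s, fit_s$params$u),
            personalized = weighted_features(
              s, personal_code_weights(fit_p$params, s))
          )
        }))
      }
      Xtr <- feat(train_idx)
      Xte <- feat(test_idx)
      for (bm in base_models) {
        sc <- baseline_scores(bm, Xtr, ytr, Xte, seed = fold_seed * 31L)
        out[[bm]] <- classification_metrics(yte, sc)
      }
    }
    do.call(rbind, lapply(names(out), function(mn) {
      data.frame(model = mn, fold = tag, t(out[[mn]]),
                 stringsAsFactors = FALSE)
    }))
  }

  for (f in seq_len(plan$k)) {
    test_p <- plan$folds[[f]]
    train_p <- setdiff(cv_patients, test_p)
    res <- eval_fold(which(pid %in% train_p), which(pid %in% test_p),
                     tag = f, fold_seed = cfg$seed * 1000L + f)
    if (is.null(res)) {
      warning(sprintf("fold %d skipped: single-class split", f))
      skipped <- c(skipped, f)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  folds_df <- do.call(rbind, rows)

  metric_names <- c("accuracy", "f1", "auc", "auprc")
  summary_df <- do.call(rbind, lapply(split(folds_df, folds_df$model),
    function(dd) {
      data.frame(
        model = dd$model[1],
        metric = metric_names,
        mean = vapply(metric_names, function(m) mean(dd[[m]]), numeric(1)),
        sd = vapply(metric_names, function(m) sd(dd[[m]]), numeric(1)),
        stringsAsFactors = FALSE
      )
    }))
  rownames(summary_df) <- NULL

  d_rows <- list()
  for (ref in intersect(c("s_ltr", "p_ltr"), unique(folds_df$model))) {
    for (other in setdiff(unique(folds_df$model), ref)) {
      a <- folds_df$auc[folds_df$model == ref]
      b <- folds_df$auc[folds_df$model == other]
      dval <- tryCatch(cohens_d(a, b), ltrEHR_degenerate_input = function(e) NA_real_)
      d_rows[[length(d_rows) + 1L]] <- data.frame(
        reference = ref, model = other, cohens_d = dval,
        effect = if (is.na(dval)) NA_character_ else effect_size_label(dval),
        stringsAsFactors = FALSE
      )
    }
  }
  cohens_df <- if (length(d_rows)) do.call(rbind, d_rows) else NULL

  holdout_df <- NULL
  if (include_holdout && length(plan$holdout)) {
    res <- eval_fold(which(pid %in% cv_patients),
                     which(pid %in% plan$holdout),
                     tag = 0L, fold_seed = cfg$seed * 1000L)
    if (!is.null(res)) {
      holdout_df <- res[, setdiff(names(res), "fold")]
    }
  }

  structure(
    list(folds = folds_df, summary = summary_df, cohens_d = cohens_df,
         holdout = holdout_df, transfer = transfer, skipped = skipped,
         pe = pe),
    class = "ltr_eval_report"
  )
}

#' @export
print.ltr_eval_report <- function(x, ...) {
  cat(sprintf("<ltr_eval_report> transfer=%s, %d fold rows%s\n",
              x$transfer, nrow(x$folds),
              if (length(x$skipped)) sprintf(", %d skipped", length(x$skipped))
              else ""))
  auc <- x$summary[x$summary$metric == "auc", ]
  for (i in seq_len(nrow(auc))) {
    cat(sprintf("  %-6s AUC %.3f (%.3f)\n", auc$model[i], auc$mean[i],
                auc$sd[i]))
  }
  invisible(x)
}

#' Write an evaluation report as JSON plus a readable TSV
#'
#' @param report An `ltr_eval_report`.
#' @param json_path,tsv_path Output paths (`NULL` skips that format).
#' @return `report`, invisibly.
#' @export
write_eval_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(folds = report$folds, summary = report$summary,
           cohens_d = report$cohens_d, holdout = report$holdout,
           transfer = report$transfer, skipped = report$skipped),
      json_path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  if (!is.null(tsv_path)) {
    utils::write.table(report$summary, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
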