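#' Population-level code importance from a standard LTR fit
#'
#' Ranks medical codes by their fitted global weight `u_c`, keeping codes
#' whose weight exceeds `min_weight`, that occur in at least `min_patients`
#' distinct patients (counted at the patient level, not the sample level),
#' and that belong to `category_filter`. Rows are sorted by weight
#' descending, ties broken by patient count descending then code. The
#' bilinear form makes the global sign of `u` arbitrary; use
#' [flip_ltr_sign()] first if the fit's orientation needs to be aligned with
#' a reference.
#'
#' @param fit An `ltr_fit` of kind `"standard"`.
#' @param cohort The cohort the fit was trained on (for patient counts and
#'   code categories).
#' @param emb The `code_embedding` the fit was trained on; when supplied the
#'   report ranks codes by their effective weights
#'   ([effective_code_weights()], the identifiable per-code logit
#'   contribution). Without it the raw bilinear factor `u` is used, which is
#'   only meaningful jointly with the fitted `v`.
#' @param min_weight Keep codes with weight strictly greater than this.
#' @param min_patients Keep codes present in at least this many patients.
#' @param category_filter Character vector of categories to keep (`NULL`
#'   keeps all).
#' @return A `code_importance_report` data frame
#'   `(code, weight, n_patients, category)`.
#' @export
population_importance <- function(fit, cohort, emb = NULL, min_weight = 0.1,
                                  min_patients = 30,
                                  category_filter = "diagnosis") {
  if (!inherits(fit, "ltr_fit") || fit$kind != "standard") {
    stop_invalid("`fit` must be a standard-LTR ltr_fit")
  }
  vocab <- cohort$vocabulary
  u <- if (is.null(emb)) {
    fit$params$u
  } else {
    unname(effective_code_weights(fit$params, emb))
  }
  if (length(u) != nrow(vocab)) stop_invalid("fit and cohort vocabulary disagree")

  pid <- cohort_patients(cohort)
  counts <- integer(nrow(vocab))
  names(counts) <- vocab$code
  per_patient <- lapply(split(cohort$samples, pid), function(ss) {
    unique(unlist(lapply(ss, `[[`, "codes")))
  })
  tab <- table(unlist(per_patient))
  counts[names(tab)] <- as.integer(tab)

  rep <- data.frame(
    code = vocab$code, weight = u, n_patients = as.integer(counts),
    category = vocab$category, stringsAsFactors = FALSE
  )
  keep <- rep$weight > min_weight & rep$n_patients >= min_patients
  if (!is.null(category_filter)) {
    keep <- keep & rep$category %in% category_filter
  }
  rep <- rep[keep, , drop = FALSE]
  rep <- rep[order(-rep$weight, -rep$n_patients, rep$code), , drop = FALSE]
  rownames(rep) <- NULL
  structure(rep,
            class = c("code_importance_report", "data.frame"),
            level = "population",
            filters = list(min_weight = min_weight,
                           min_patients = min_patients,
                           category_filter = category_filter))
}

#' Per-patient code importance from a personalized LTR fit
#'
#' Reports the sample-specific code weights `u_i = X_i w` for the codes
#' present at the visit, sorted by absolute weight descending — the personal
#' risk profile of one patient visit.
#'
#' @param fit An `ltr_fit` of kind `"personalized"`.
#' @param sample A `sample_tensor`.
#' @return A `code_importance_report` data frame
#'   `(code, weight, category)`.
#' @export
personalized_importance <- function(fit, sample) {
  if (!inherits(fit, "ltr_fit") || fit$kind != "personalized") {
    stop_invalid("`fit` must be a personalized-LTR ltr_fit")
  }
  u_i <- personal_code_weights(fit$params, sample)
  vocab <- sample$emb$vocabulary
  idx <- sample$code_idx
  rep <- data.frame(
    code = sample$codes,
    weight = unname(u_i[idx]),
    category = vocab$category[match(sample$codes, vocab$code)],
    stringsAsFactors = FALSE
  )
  rep <- rep[order(-abs(rep$weight), rep$code), , drop = FALSE]
  rownames(rep) <- NULL
  structure(rep,
            class = c("code_importance_report", "data.frame"),
            level = "personalized",
            filters = list())
}

#' Simulate the risk impact of toggling one medical code
#'
#' Rebuilds the sample tensor with `code` added to or removed from the
#' visit, re-applies the positional encoding the original tensor carried,
#' and recomputes the predicted probability under `fit`. For the
#' personalized model the per-sample weights `u_i = X_i w` are implicitly
#' recomputed, since they depend on the visit's contents.
#'
#' @param fit An `ltr_fit` (either kind).
#' @param sample A `sample_tensor`.
#' @param code A vocabulary code; must be absent for `action = "add"` and
#'   present for `action = "remove"`.
#' @param action `"add"` or `"remove"`.
#' @return Named numeric vector `c(risk_before, risk_after)` with attribute
#'   `"logits"`.
#' @export
code_perturbation_risk <- function(fit, sample, code,
                                   action = c("add", "remove")) {
  action <- match.arg(action)
  if (!inherits(fit, "ltr_fit")) stop_invalid("`fit` must be an ltr_fit")
  emb <- sample$emb
  if (is.null(emb)) stop_invalid("sample tensor carries no embedding reference")
  if (!code %in% rownames(emb$vectors)) stop_missing_code(code)
  present <- code %in% sample$codes
  if (action == "add" && present) {
    stop_invalid(sprintf("code %s is already present", code))
  }
  if (action == "remove" && !present) {
    stop_invalid(sprintf("code %s is not present", code))
  }

  new_codes <- if (action == "add") c(sample$codes, code) else {
    setdiff(sample$codes, code)
  }
  pair <- list(patient_id = sample$patient_id, codes = new_codes,
               labs = sample$x, elapsed_days = sample$t, label = sample$y)
  # sample$x is already on the model scale (z-scored / PE-free), so rebuild
  # without re-standardizing, then re-apply PE if the original had it
  ten <- build_sample_tensor(pair, emb)
  if (isTRUE(sample$pe_applied)) {
    ten <- apply_pe(ten, mode = sample$pe_mode %||% "multiplicative")
    # the original labs were PE-scaled already; keep them as given
    ten$x <- sample$x
  }

  fwd <- function(s) {
    if (fit$kind == "standard") forward_standard(fit$params, s)
    else forward_personalized(fit$params, s)
  }
  before <- fwd(sample)
  after <- fwd(ten)
  out <- c(risk_before = as.numeric(before), risk_after = as.numeric(after))
  attr(out, "logits") <- c(before = attr(before, "logit"),
                           after = attr(after, "logit"))
  out
}

#' Write a code-importance report
#'
#' @param report A `code_importance_report`.
#' @param csv_path,json_path Output paths (`NULL` skips).
#' @return `report`, invisibly.
#' @export
write_importance_report <- function(report, csv_path = NULL,
                                    json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(level = attr(report, "level"), filters = attr(report, "filters"),
           rows = as.data.frame(report)),
      json_path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(report)
}
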