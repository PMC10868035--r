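#' Generate a synthetic medical-code vocabulary
#'
#' Builds a vocabulary of unique medical-code identifiers styled after ICD-10
#' diagnosis codes (e.g. `"I50.2"`), CPT-4 procedure codes (e.g. `"80076"`)
#' and VA drug-class codes (e.g. `"CV701"`), each assigned to one category and
#' one synthetic phenotype group. Phenotype groups play the role that Phecode
#' groupings play for real ICD codes: codes in the same group are treated as
#' clinically related, both when the cohort generator draws co-occurring codes
#' and when embeddings are scored by pair classification.
#'
#' @param n_codes Total number of codes.
#' @param n_groups Number of phenotype groups (must not exceed `n_codes`).
#' @param seed Integer seed; the vocabulary is deterministic given
#'   `(n_codes, n_groups, seed)`.
#' @param category_props Named numeric vector of relative category sizes for
#'   `diagnosis`, `procedure` and `drug` codes. The default mirrors a large
#'   hospital coding mix dominated by diagnoses.
#' @return A `code_vocabulary`: a data frame with columns `code`, `category`
#'   and `group_id`.
#' @examples
#' vocab <- generate_vocabulary(n_codes = 60, n_groups = 12, seed = 1)
#' table(vocab$category)
#' @export
generate_vocabulary <- function(n_codes = 8438, n_groups = 500, seed = 1,
                                category_props = c(diagnosis = 5970,
                                                   procedure = 2229,
                                                   drug = 239)) {
  n_codes <- check_count(n_codes, "n_codes")
  n_groups <- check_count(n_groups, "n_groups")
  if (n_groups > n_codes) stop_invalid("`n_groups` must not exceed `n_codes`")
  if (!all(c("diagnosis", "procedure", "drug") %in% names(category_props)) ||
        any(category_props < 0) || sum(category_props) <= 0) {
    stop_invalid("`category_props` must name diagnosis/procedure/drug sizes")
  }

  counts <- largest_remainder(
    category_props[c("diagnosis", "procedure", "drug")], n_codes
  )
  # Every vocabulary keeps at least one diagnosis code so that the embedding
  # pair-classification evaluation has a population to draw from.
  if (counts[["diagnosis"]] == 0 && n_codes > 0) {
    donor <- which.max(counts)
    counts[donor] <- counts[donor] - 1L
    counts[["diagnosis"]] <- 1L
  }

  with_seed(seed, {
    codes <- c(
      make_codes_diagnosis(counts[["diagnosis"]]),
      make_codes_procedure(counts[["procedure"]]),
      make_codes_drug(counts[["drug"]])
    )
    category <- rep(c("diagnosis", "procedure", "drug"), times = counts)
    group_id <- sample(rep(seq_len(n_groups), length.out = n_codes))
    vocab <- data.frame(
      code = codes, category = category, group_id = group_id,
      stringsAsFactors = FALSE
    )
    # shuffle row order so category blocks are not positionally informative
    vocab <- vocab[sample(n_codes), , drop = FALSE]
    rownames(vocab) <- NULL
    class(vocab) <- c("code_vocabulary", "data.frame")
    vocab
  })
}

largest_remainder <- function(weights, total) {
  shares <- weights / sum(weights) * total
  base <- floor(shares)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(shares - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

make_codes_diagnosis <- function(n) {
  if (n == 0) return(character())
  pool <- as.vector(outer(
    as.vector(outer(LETTERS, sprintf("%02d", 0:99), paste0)),
    sprintf(".%d", 0:9), paste0
  ))
  sample(pool, n)
}

make_codes_procedure <- function(n) {
  if (n == 0) return(character())
  sample(sprintf("%05d", 0:99999), n)
}

make_codes_drug <- function(n) {
  if (n == 0) return(character())
  prefixes <- c("CV", "CN", "GA", "BL", "AM", "RE", "DE", "HS", "IM", "MS",
                "NT", "OP", "OT", "PH", "AD", "AN", "AP", "AU", "DX", "EL",
                "ER", "GU", "HA", "IR", "TN", "VT")
  pool <- as.vector(outer(prefixes, sprintf("%03d", 100:999), paste0))
  sample(pool, n)
}

#' @export
print.code_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<code_vocabulary> %d codes (%s), %d phenotype groups\n",
    nrow(x),
    paste(sprintf("%d %s", table(x$category)[unique(x$category)],
                  unique(x$category)), collapse = ", "),
    length(unique(x$group_id))
  ))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
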