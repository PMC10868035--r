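#' Read and write cohorts
#'
#' A cohort is persisted as a CSV (one row per paired-visit sample:
#' `patient_id`, pipe-delimited `codes`, one column per lab feature,
#' `elapsed_days`, `label`) plus a JSON sidecar holding the vocabulary and,
#' for synthetic cohorts, the full generating ground truth. Numeric CSV
#' fields are written with 12 significant digits; the sidecar keeps full
#' double precision, so `write_cohort()` followed by [read_cohort()]
#' round-trips the ground truth exactly.
#'
#' @param cohort An `ehr_cohort`.
#' @param path CSV path.
#' @param sidecar JSON sidecar path (defaults to `<path>.json`).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   an `ehr_cohort`.
#' @export
write_cohort <- function(cohort, path, sidecar = paste0(path, ".json")) {
  if (!inherits(cohort, "ehr_cohort")) stop_invalid("`cohort` must be an ehr_cohort")
  labs <- cohort_lab_matrix(cohort)
  lab_names <- colnames(labs)
  if (is.null(lab_names)) lab_names <- sprintf("lab%d", seq_len(ncol(labs)))
  header <- c("patient_id", "codes", lab_names, "elapsed_days", "label")
  rows <- vapply(seq_along(cohort$samples), function(i) {
    s <- cohort$samples[[i]]
    paste(c(
      s$patient_id,
      paste(s$codes, collapse = "|"),
      fmt_num(s$labs),
      fmt_num(s$elapsed_days),
      as.character(s$label)
    ), collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), rows), path)

  side <- list(
    vocabulary = as.data.frame(cohort$vocabulary),
    d = cohort$d,
    D = cohort$D,
    lab_names = lab_names,
    truth = cohort$truth
  )
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, sidecar = paste0(path, ".json")) {
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  vocab <- side$vocabulary
  class(vocab) <- c("code_vocabulary", "data.frame")
  lab_names <- side$lab_names
  d <- as.integer(side$d)

  samples <- lapply(seq_len(nrow(tab)), function(i) {
    list(
      patient_id = tab$patient_id[i],
      codes = if (nzchar(tab$codes[i])) {
        strsplit(tab$codes[i], "|", fixed = TRUE)[[1]]
      } else character(),
      labs = stats::setNames(
        as.numeric(tab[i, lab_names, drop = TRUE]), lab_names
      ),
      elapsed_days = as.numeric(tab$elapsed_days[i]),
      label = as.integer(tab$label[i])
    )
  })

  truth <- side$truth
  if (!is.null(truth)) {
    truth$u <- as.numeric(truth$u)
    if (!is.null(truth$u_effective)) {
      truth$u_effective <- as.numeric(truth$u_effective)
    }
    truth$v <- as.numeric(truth$v)
    truth$embedding <- as.matrix(truth$embedding)
    dimnames(truth$embedding) <- NULL
  }

  structure(
    list(samples = samples, vocabulary = vocab, truth = truth,
         d = d, D = as.integer(side$D)),
    class = "ehr_cohort"
  )
}
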