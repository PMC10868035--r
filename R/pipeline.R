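#' Pipeline run configuration
#'
#' Assembles and validates the configuration of a full synthetic-cohort run:
#' simulate, embed, encode, fit, evaluate, interpret. All randomness flows
#' from the named seeds. The demo defaults finish in a few CPU minutes.
#'
#' @param outdir Output directory (created if missing).
#' @param n_codes,n_groups,n_patients,n_pairs,d,D Problem dimensions
#'   (`D + d` must be even).
#' @param sparsity,noise Generator settings, see [generate_cohort()].
#' @param embed_method,embed_epochs,embed_negatives Embedding-training
#'   settings, see [train_embeddings()].
#' @param pe `"multiplicative"`, `"additive"` or `"none"`.
#' @param models Models evaluated, see [run_cv()].
#' @param k,test_ratio Cross-validation plan settings.
#' @param max_steps,lr,lambda LTR training settings.
#' @param grid Run [grid_search()] instead of a single [fit_ltr()].
#' @param seeds Named list of integer seeds
#'   (`cohort`, `embedding`, `fit`, `cv`).
#' @return A validated `run_config` list.
#' @export
run_config <- function(outdir,
                       n_codes = 200, n_groups = 20, n_patients = 300,
                       n_pairs = 500, d = 4, D = 20,
                       sparsity = 0.2, noise = 0.05,
                       embed_method = "sgns", embed_epochs = 10,
                       embed_negatives = 5,
                       pe = "multiplicative",
                       models = c("s_ltr", "p_ltr", "lr", "svm", "nb", "rf"),
                       k = 10, test_ratio = 0.2,
                       max_steps = 1500, lr = 1e-2, lambda = 1e-3,
                       grid = FALSE,
                       seeds = list(cohort = 1, embedding = 2, fit = 3,
                                    cv = 4)) {
  cfg <- list(
    outdir = outdir, n_codes = n_codes, n_groups = n_groups,
    n_patients = n_patients, n_pairs = n_pairs, d = d, D = D,
    sparsity = sparsity, noise = noise, embed_method = embed_method,
    embed_epochs = embed_epochs, embed_negatives = embed_negatives,
    pe = pe, models = models, k = k, test_ratio = test_ratio,
    max_steps = max_steps, lr = lr, lambda = lambda, grid = grid,
    seeds = seeds
  )
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  required <- c("outdir", "n_codes", "n_groups", "n_patients", "n_pairs",
                "d", "D", "pe", "models", "k", "test_ratio", "seeds")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop_invalid(sprintf("config lacks fields: %s",
                         paste(missing, collapse = ", ")))
  }
  if ((cfg$D + cfg$d) %% 2 != 0) stop_invalid("`D + d` must be even")
  if (!cfg$pe %in% c("multiplicative", "additive", "none")) {
    stop_invalid("`pe` must be multiplicative/additive/none")
  }
  for (nm in c("cohort", "embedding", "fit", "cv")) {
    if (is.null(cfg$seeds[[nm]])) {
      stop_invalid(sprintf("seeds$%s missing", nm))
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @param outdir Optional override of the configured output directory.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, outdir = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(outdir)) cfg$outdir <- outdir
  defaults <- formals(run_config)
  for (nm in setdiff(names(defaults), c("outdir", "..."))) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- eval(defaults[[nm]])
  }
  validate_run_config(cfg)
}

pipeline_paths <- function(cfg) {
  o <- cfg$outdir
  list(
    config = file.path(o, "config.yaml"),
    cohort = file.path(o, "cohort.csv"),
    cohort_sidecar = file.path(o, "cohort.csv.json"),
    embedding = file.path(o, "embedding.txt"),
    encode = file.path(o, "encode.json"),
    fit_standard = file.path(o, "fit_standard.json"),
    fit_personalized = file.path(o, "fit_personalized.json"),
    train_log = file.path(o, "train_log.tsv"),
    report = file.path(o, "report.json"),
    report_tsv = file.path(o, "report.tsv"),
    importance = file.path(o, "importance.csv"),
    profile = file.path(o, "personal_profile.json"),
    manifest = file.path(o, "manifest.json")
  )
}

stage_outputs <- function(paths) {
  list(
    simulate = c(paths$cohort, paths$cohort_sidecar),
    embed = paths$embedding,
    encode = paths$encode,
    fit = c(paths$fit_standard, paths$fit_personalized, paths$train_log),
    evaluate = c(paths$report, paths$report_tsv),
    interpret = c(paths$importance, paths$profile)
  )
}

#' Run the full pipeline
#'
#' Executes simulate, embed, encode, fit, evaluate and interpret in order,
#' writing each stage's outputs under `cfg$outdir`. A stage whose outputs
#' already exist is skipped, so deleting a downstream file and re-running
#' recomputes only what is missing. The manifest (config hash, package
#' version, per-stage outputs and wall-clock seconds) is written last. Runs
#' are deterministic: identical configurations produce byte-identical
#' reports.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return A `run_manifest` list, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  cfg <- validate_run_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(cfg)
  outputs <- stage_outputs(paths)
  say <- function(...) if (!quiet) message(sprintf(...))

  cfg_plain <- unclass(cfg)
  cfg_plain$outdir <- NULL  # hash the science, not the filesystem location
  yaml::write_yaml(cfg_plain, paths$config)
  config_hash <- unname(tools::md5sum(paths$config))

  timings <- list()
  run_stage <- function(name, fun) {
    outs <- outputs[[name]]
    if (all(file.exists(outs))) {
      say("[%s] outputs present, skipping", name)
      timings[[name]] <<- 0
      return(invisible(NULL))
    }
    say("[%s] running", name)
    tm <- system.time(fun())[["elapsed"]]
    missing <- outs[!file.exists(outs)]
    if (length(missing)) {
      stop_invalid(sprintf("stage '%s' failed to produce: %s", name,
                           paste(missing, collapse = ", ")))
    }
    timings[[name]] <<- tm
  }

  run_stage("simulate", function() {
    vocab <- generate_vocabulary(cfg$n_codes, cfg$n_groups,
                                 seed = cfg$seeds$cohort)
    coh <- generate_cohort(vocab, cfg$n_patients, cfg$n_pairs, d = cfg$d,
                           D = cfg$D, sparsity = cfg$sparsity,
                           noise = cfg$noise, seed = cfg$seeds$cohort)
    write_cohort(coh, paths$cohort)
  })

  cohort <- read_cohort(paths$cohort)

  run_stage("embed", function() {
    emb <- train_embeddings(cohort, D = cfg$D, method = cfg$embed_method,
                            epochs = cfg$embed_epochs,
                            negatives = cfg$embed_negatives,
                            seed = cfg$seeds$embedding)
    write_embedding(emb, paths$embedding)
  })

  emb <- read_embedding(paths$embedding, cohort$vocabulary)

  run_stage("encode", function() {
    labs <- cohort_lab_matrix(cohort)
    enc <- list(
      pe = cfg$pe,
      lab_center = colMeans(labs),
      lab_scale = apply(labs, 2, sd)
    )
    jsonlite::write_json(enc, paths$encode, auto_unbox = TRUE, digits = NA)
  })

  enc <- jsonlite::read_json(paths$encode, simplifyVector = TRUE)
  tensors <- build_tensors(
    cohort, emb, pe = enc$pe != "none",
    pe_mode = if (enc$pe == "none") "multiplicative" else enc$pe,
    lab_center = enc$lab_center, lab_scale = enc$lab_scale
  )

  tcfg <- train_config(lr = cfg$lr, lambda = cfg$lambda,
                       max_steps = cfg$max_steps, seed = cfg$seeds$fit)

  run_stage("fit", function() {
    fits <- lapply(c("standard", "personalized"), function(kind) {
      if (isTRUE(cfg$grid)) grid_search(kind, tensors, tcfg)
      else fit_ltr(kind, tensors, tcfg)
    })
    write_ltr_params(fits[[1]]$params, paths$fit_standard)
    write_ltr_params(fits[[2]]$params, paths$fit_personalized)
    log <- do.call(rbind, lapply(seq_along(fits), function(i) {
      data.frame(model = c("standard", "personalized")[i],
                 step = seq_along(fits[[i]]$history),
                 loss = fits[[i]]$history)
    }))
    utils::write.table(log, paths$train_log, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  plan <- make_fold_plan(cohort, k = cfg$k, test_ratio = cfg$test_ratio,
                         seed = cfg$seeds$cv)

  run_stage("evaluate", function() {
    report <- run_cv(cohort, emb, models = cfg$models, plan = plan,
                     transfer = "none", cfg = tcfg,
                     pe = cfg$pe != "none",
                     pe_mode = if (cfg$pe == "none") "multiplicative" else cfg$pe,
                     include_holdout = TRUE)
    write_eval_report(report, paths$report, paths$report_tsv)
  })

  run_stage("interpret", function() {
    fit_s <- structure(
      list(kind = "standard", params = read_ltr_params(paths$fit_standard)),
      class = "ltr_fit"
    )
    fit_p <- structure(
      list(kind = "personalized",
           params = read_ltr_params(paths$fit_personalized)),
      class = "ltr_fit"
    )
    imp <- population_importance(fit_s, cohort, emb, min_weight = 0,
                                 min_patients = 1)
    write_importance_report(imp, csv_path = paths$importance)
    # personal profile of the highest-risk holdout sample
    pid <- cohort_patients(cohort)
    idx <- which(pid %in% plan$holdout)
    if (!length(idx)) idx <- seq_along(tensors)
    risk <- predict(fit_p, tensors[idx])
    top <- idx[which.max(risk)]
    prof <- personalized_importance(fit_p, tensors[[top]])
    write_importance_report(prof, json_path = paths$profile)
  })

  manifest <- list(
    config_hash = config_hash,
    package_version = as.character(utils::packageVersion("ltrEHR")),
    outputs = outputs,
    timings = timings
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  say("pipeline complete: %s", paths$manifest)
  invisible(structure(manifest, class = "run_manifest"))
}
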