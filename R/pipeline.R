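#' Pipeline configuration
#'
#' Validates paths and options for the end-to-end run: feature extraction,
#' per-label association screens, the repeated-run ML protocol with error
#' analysis, and (optionally) the CNN branch with pattern extraction.
#' Criterion-level targets (crit_B \ldots crit_G) run as independent binary
#' problems sharing the one feature table.
#'
#' @param corpus Path to the corpus (directory of .txt or JSONL file).
#' @param metadata Path to the metadata CSV.
#' @param lexicons Directory of lexicon CSVs (term, category, weight).
#' @param out Output directory (created if needed).
#' @param labels Label targets: `"diagnosis"` (binary: full or partial PTSD
#'   vs none) and/or criterion flags.
#' @param models Model families to run.
#' @param n_runs Repeated runs per task (default 100).
#' @param seed Master seed.
#' @param dl Run the CNN branch.
#' @param seq_cfg,net_cfg DL configurations (see [sequence_config()],
#'   [cnn_config()]).
#' @return Validated config, class `lf_pipeline_config`.
#' @export
pipeline_config <- function(corpus, metadata, lexicons, out,
                            labels = c("diagnosis", "crit_B", "crit_C",
                                       "crit_D", "crit_E", "crit_G"),
                            models = c("logistic_elasticnet", "random_forest",
                                       "ebm"),
                            n_runs = 100L, seed = 1L, dl = FALSE,
                            seq_cfg = sequence_config(seed = seed),
                            net_cfg = cnn_config()) {
  for (p in c(corpus, metadata, lexicons))
    if (!file.exists(p)) stop("path does not exist: ", p)
  md <- read_metadata(metadata)
  bad <- setdiff(setdiff(labels, "diagnosis"), names(md))
  if (length(bad))
    stop("label target(s) absent from metadata: ", paste(bad, collapse = ", "))
  structure(list(corpus = corpus, metadata = metadata, lexicons = lexicons,
                 out = out, labels = labels, models = models,
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 dl = dl, seq_cfg = seq_cfg, net_cfg = net_cfg),
            class = "lf_pipeline_config")
}

read_lexicon_dir <- function(path) {
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no lexicon CSVs in ", path)
  lapply(files, read_lexicon)
}

binary_label <- function(md, target) {
  v <- if (target == "diagnosis")
    factor(ifelse(md$diagnosis == "no_ptsd", "negative", "positive"),
           levels = c("negative", "positive"))
  else factor(ifelse(md[[target]], "positive", "negative"),
              levels = c("negative", "positive"))
  stats::setNames(v, md$doc_id)
}

#' Run the full analysis pipeline
#'
#' Stage order: read corpus/metadata/lexicons, tokenize, extract the feature
#' table (written as `features.csv`), screen every feature per label target
#' (`assoc_<label>.csv`), run the repeated-run protocol for each configured
#' model family (`ml_summary.csv`, `importances_<label>.csv` for the best
#' family), error analysis on the most misclassified documents
#' (`error_analysis.json`), optionally the CNN branch (`cnn_metrics.json`,
#' `patterns.tsv`), and a reproducibility manifest (`manifest.json` with
#' versions, seeds and file hashes).  A stage failure aborts with the stage
#' name; artifacts already written are kept.
#'
#' @param config `lf_pipeline_config`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lf_pipeline_config"))
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage \"", name, "\" failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_line <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  log_line("stage corpus_io")
  corpus <- stage("corpus_io", read_corpus(config$corpus))
  md <- stage("corpus_io", read_metadata(config$metadata))
  lexicons <- stage("corpus_io", read_lexicon_dir(config$lexicons))
  docs <- stage("corpus_io", tokenize_corpus(corpus))

  log_line("stage features (", length(docs), " documents)")
  features <- stage("features", extract_features(docs, lexicons))
  write_feature_table(features, file.path(out_dir, "features.csv"))
  reduced <- reduce_features(features)

  assoc <- list()
  for (target in config$labels) {
    log_line("stage stats: ", target)
    lab <- binary_label(md, target)
    assoc[[target]] <- stage("stats",
      association_table(features, lab, B = 500,
                        power_seed = config$seed))
    utils::write.csv(as.data.frame(assoc[[target]]),
                     file.path(out_dir, paste0("assoc_", target, ".csv")),
                     row.names = FALSE)
  }

  strata <- stats::setNames(interaction(md$exposure, md$diagnosis, drop = TRUE),
                            md$doc_id)
  ml_rows <- list(); runs_by_task <- list()
  for (target in config$labels) {
    lab <- binary_label(md, target)
    runs_by_task[[target]] <- list()
    for (fam in config$models) {
      log_line("stage ml: ", target, " / ", fam)
      rs <- stage("ml", repeated_runs(model_spec(fam), reduced, lab,
                                      strata = strata,
                                      n_runs = config$n_runs,
                                      base_seed = config$seed))
      runs_by_task[[target]][[fam]] <- rs
      ml_rows[[length(ml_rows) + 1L]] <-
        data.frame(task = target, model = fam, mean_auc = rs$mean_auc,
                   std_auc = rs$std_auc, n_runs = rs$n_runs)
    }
  }
  ml_summary <- do.call(rbind, ml_rows)
  utils::write.csv(ml_summary, file.path(out_dir, "ml_summary.csv"),
                   row.names = FALSE)

  errors <- list()
  for (target in config$labels) {
    fams <- runs_by_task[[target]]
    best <- fams[[which.max(vapply(fams, `[[`, 0, "mean_auc"))]]
    imp <- data.frame(feature = names(best$importances),
                      importance = unname(best$importances))
    utils::write.csv(imp, file.path(out_dir, paste0("importances_", target,
                                                    ".csv")),
                     row.names = FALSE)
    log_line("stage error_analysis: ", target)
    ea <- stage("error_analysis",
                error_analysis(best, md, B = 500))
    errors[[target]] <- list(best_model = best$family,
                             top_misclassified = ea$top,
                             no_errors = ea$no_errors, tests = ea$tests)
  }
  jsonlite::write_json(errors, file.path(out_dir, "error_analysis.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  cnn <- NULL
  if (isTRUE(config$dl)) {
    log_line("stage dl")
    lab <- binary_label(md, "diagnosis")
    ds <- stage("dl", build_sequence_dataset(docs, lab, config$seq_cfg,
                                             config$net_cfg))
    model <- stage("dl", train_cnn(ds, seed = config$seed))
    test_probs <- predict(model, ds$test$ids)
    metrics <- list(val_auc = model$val_auc,
                    test_auc = roc_auc(test_probs, ds$test$y),
                    epochs = nrow(model$history), K = ds$K)
    jsonlite::write_json(metrics, file.path(out_dir, "cnn_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    pat <- stage("dl", extract_top_patterns(model, ds, "positive", top_n = 10))
    utils::write.table(pat, file.path(out_dir, "patterns.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    cnn <- list(model = model, metrics = metrics, patterns = pat)
  }

  arts <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = "ptsdlang",
    version = tryCatch(as.character(utils::packageVersion("ptsdlang")),
                       error = function(e) "dev"),
    r_version = R.version.string,
    seed = config$seed, n_runs = config$n_runs,
    labels = config$labels, models = config$models,
    inputs = list(corpus = config$corpus, metadata = config$metadata,
                  lexicons = config$lexicons),
    artifacts = stats::setNames(as.list(unname(tools::md5sum(arts))),
                                basename(arts)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(features = features, associations = assoc,
                 ml_summary = ml_summary, errors = errors, cnn = cnn,
                 manifest = manifest))
}
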