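# Repeated-run interpretable classification protocol: stratified 80/20
# document splits, SMOTE oversampling of the training fold, three model
# families (elastic-net logistic regression, random forest, cyclic-boosting
# additive model), ROC-AUC and feature importances averaged over runs, and
# error analysis of the most misclassified documents.

#' Rank-based ROC-AUC
#'
#' Probability that a random positive scores above a random negative
#' (ties count one half) — the Mann-Whitney formulation of the area under
#' the ROC curve.
#'
#' @param scores Numeric predictions.
#' @param labels Binary labels (logical, 0/1, or two-level factor whose
#'   second level is positive).
#' @return AUC in [0, 1]; NA if a class is empty.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2]))
  if (all(labels %in% c(0, 1))) return(as.integer(labels))
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("binary labels required")
  as.integer(f == levels(f)[2])
}

#' Model specification for the classification protocol
#'
#' Families and their defaults: elastic-net logistic regression
#' (`l1_ratio = 0.6`, `C = 0.1`, features z-scored on training-fold
#' statistics; fitted with glmnet, where `C` maps to
#' `lambda = 1 / (C * n_train)`); random forest (`n_estimators = 40`,
#' `min_sample_split = 0.4` as a fraction of the training fold,
#' `min_samples_leaf = 15`; fitted with ranger); and `ebm`, a
#' cyclic-boosting additive model (`max_leaves = 10`,
#' `min_samples_leaf = 15`, `max_bins = 20`,
#' `early_stopping_rounds = 20`).
#'
#' @param family `"logistic_elasticnet"`, `"random_forest"` or `"ebm"`.
#' @param ... Hyperparameter overrides.
#' @return Object of class `lf_model_spec`.
#' @export
model_spec <- function(family = c("logistic_elasticnet", "random_forest", "ebm"),
                       ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    logistic_elasticnet = list(l1_ratio = 0.6, C = 0.1),
    random_forest = list(n_estimators = 40, min_sample_split = 0.4,
                         min_samples_leaf = 15),
    ebm = list(max_leaves = 10, min_samples_leaf = 15, max_bins = 20,
               early_stopping_rounds = 20, learning_rate = 0.05,
               max_rounds = 500))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown hyperparameter: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  out <- list(family = family, hyperparameters = defaults)
  class(out) <- "lf_model_spec"
  out
}

#' Stratified train/test split
#'
#' Document-level 80/20 split stratified on the crossing of exposure and
#' diagnosis (or any supplied strata): per stratum the test count is the
#' half-up rounding of `test_frac * n`, then repaired (largest/smallest
#' fractional remainder first) so the global test size equals the half-up
#' rounding of `test_frac * N`.
#'
#' @param doc_ids Character vector of document ids.
#' @param strata Vector/factor aligned with `doc_ids` (e.g.
#'   `interaction(exposure, diagnosis)`).
#' @param test_frac Test fraction (default 0.2).
#' @param seed Integer seed; the split is a deterministic function of
#'   (doc_ids, strata, test_frac, seed).
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
stratified_split <- function(doc_ids, strata, test_frac = 0.2, seed = 1L) {
  stopifnot(length(doc_ids) == length(strata))
  strata <- as.character(strata)
  strata <- factor(strata, levels = unique(strata)[order_c(unique(strata))])
  ns <- table(strata)
  if (any(ns < 2L))
    stop("singleton stratum \"", names(ns)[which(ns < 2L)[1]],
         "\": merge strata before splitting")
  round_half_up <- function(x) floor(x + 0.5)
  target_total <- round_half_up(test_frac * length(doc_ids))
  per <- round_half_up(test_frac * as.numeric(ns))
  per <- pmin(pmax(per, 0L), as.numeric(ns) - 1L)  # keep every stratum in train
  # repair to the global target, always adjusting the currently most
  # over-/under-allocated stratum so deviations stay within one document
  while (sum(per) > target_total) {
    cand <- which(per > 0)
    i <- cand[which.max(per[cand] - test_frac * as.numeric(ns)[cand])]
    per[i] <- per[i] - 1L
  }
  while (sum(per) < target_total) {
    cand <- which(per < as.numeric(ns) - 1L)
    i <- cand[which.min(per[cand] - test_frac * as.numeric(ns)[cand])]
    per[i] <- per[i] + 1L
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  test <- character(0)
  for (s in names(ns)) {
    ids <- doc_ids[strata == s]
    k <- per[match(s, names(ns))]
    if (k > 0) test <- c(test, sample(ids, k))
  }
  list(train = setdiff(doc_ids, test), test = sort(test))
}

#' SMOTE minority oversampling
#'
#' Balances a binary problem by synthesizing minority-class rows on the
#' segment between a minority point and one of its `k_neighbors` nearest
#' minority neighbors (Euclidean metric):
#' `x' = x_i + lambda (x_j - x_i)`, `lambda ~ U(0, 1)`.
#'
#' @param X Numeric matrix/data.frame of features.
#' @param y Binary labels aligned with rows of `X`.
#' @param k_neighbors Number of nearest minority neighbors (default 5).
#' @param seed Integer seed.
#' @return List with balanced `X` (matrix) and `y` (integer 0/1); already
#'   balanced input is returned unchanged.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as_binary(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == n0) return(list(X = X, y = y))
  minority <- if (n1 < n0) 1L else 0L
  n_min <- min(n1, n0); n_need <- abs(n1 - n0)
  if (n_min <= k_neighbors)
    stop("minority class has ", n_min, " <= k_neighbors = ", k_neighbors,
         " members; lower k_neighbors")
  Xm <- X[y == minority, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(r) order(r)[seq_len(k_neighbors)]))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  i <- sample(nrow(Xm), n_need, replace = TRUE)
  j <- nn[cbind(i, sample(k_neighbors, n_need, replace = TRUE))]
  lam <- stats::runif(n_need)
  synth <- Xm[i, , drop = FALSE] + lam * (Xm[j, , drop = FALSE] - Xm[i, , drop = FALSE])
  list(X = rbind(X, synth), y = c(y, rep(minority, n_need)))
}

# -- model family fit/predict/importance ------------------------------------

fit_family <- function(spec, X, y, seed) {
  hp <- spec$hyperparameters
  switch(spec$family,
    logistic_elasticnet = {
      mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
      Xs <- scale(X, mu, sdv)
      lambda <- 1 / (hp$C * nrow(X))
      fit <- glmnet::glmnet(Xs, factor(y, levels = c(0, 1)),
                            family = "binomial", alpha = hp$l1_ratio,
                            lambda = lambda, standardize = FALSE)
      list(fit = fit, mu = mu, sd = sdv,
           importance = stats::setNames(as.numeric(fit$beta), rownames(fit$beta)))
    },
    random_forest = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- factor(y, levels = c(0, 1))
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = hp$n_estimators, probability = TRUE,
        min.node.size = max(2L, ceiling(hp$min_sample_split * nrow(X))),
        min.bucket = hp$min_samples_leaf,
        importance = "impurity", seed = seed, num.threads = 1)
      list(fit = fit, importance = ranger::importance(fit))
    },
    ebm = {
      fit <- ebm_fit(X, y, max_leaves = hp$max_leaves,
                     min_samples_leaf = hp$min_samples_leaf,
                     max_bins = hp$max_bins,
                     early_stopping_rounds = hp$early_stopping_rounds,
                     learning_rate = hp$learning_rate,
                     max_rounds = hp$max_rounds, seed = seed)
      list(fit = fit, importance = fit$importance)
    })
}

predict_family <- function(spec, model, X) {
  switch(spec$family,
    logistic_elasticnet = {
      Xs <- scale(X, model$mu, model$sd)
      as.numeric(stats::predict(model$fit, Xs, type = "response"))
    },
    random_forest = {
      pr <- stats::predict(model$fit, data.frame(X, check.names = FALSE),
                           num.threads = 1)$predictions
      pr[, "1"]
    },
    ebm = ebm_predict(model$fit, X))
}

#' Single stratified run: fit on the training fold, score the test fold
#'
#' One run of the protocol: SMOTE is applied to the training fold only (and
#' feature standardization for the logistic family uses training-fold
#' statistics only), the model is fitted with the family's printed
#' hyperparameters, and ROC-AUC is computed on the untouched test fold.
#' Importances are |standardized coefficients| signs kept (logistic),
#' impurity importances (forest) or mean absolute term contributions (ebm).
#'
#' @param spec `lf_model_spec`.
#' @param split List with `train`/`test` doc_id vectors
#'   (see [stratified_split()]).
#' @param features Feature table (typically [reduce_features()] output).
#' @param labels Named binary labels (names = doc_ids).
#' @param seed Integer seed (SMOTE and any stochastic fit).
#' @param smote Logical: oversample the training fold (default TRUE).
#' @return List of class `lf_run`: seed, train/test ids, roc_auc,
#'   feature_importances, misclassified (named logical over test ids),
#'   probabilities.
#' @export
train_eval_run <- function(spec, split, features, labels, seed = 1L,
                           smote = TRUE) {
  X <- as.matrix(features[, setdiff(names(features), "doc_id"), drop = FALSE])
  rownames(X) <- features$doc_id
  y <- as_binary(labels[features$doc_id])
  names(y) <- features$doc_id
  tr <- split$train; te <- split$test
  stopifnot(length(intersect(tr, te)) == 0)
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  if (smote) {
    os <- smote_oversample(Xtr, ytr, seed = seed)
    Xtr <- os$X; ytr <- os$y
  }
  model <- fit_family(spec, Xtr, ytr, seed = seed)
  p <- predict_family(spec, model, X[te, , drop = FALSE])
  auc <- roc_auc(p, y[te])
  out <- list(seed = seed, train = tr, test = te, roc_auc = auc,
              feature_importances = model$importance,
              probabilities = stats::setNames(p, te),
              misclassified = stats::setNames(as.integer(p >= 0.5) != y[te], te))
  class(out) <- "lf_run"
  out
}

#' Repeated randomized runs with averaged AUC and importances
#'
#' Repeats the stratified-split / SMOTE / fit / test protocol `n_runs`
#' times with per-run seeds derived from `base_seed`, and averages ROC-AUC
#' and feature importances over runs.  A run whose test fold contains a
#' single class (AUC undefined) is re-drawn with a fresh seed so exactly
#' `n_runs` valid runs are aggregated.
#'
#' @param spec `lf_model_spec`.
#' @param features Feature table (reduced registry recommended).
#' @param labels Named binary labels over `features$doc_id`.
#' @param strata Stratification vector aligned with `features$doc_id`
#'   (default: the labels themselves).
#' @param n_runs Number of runs (default 100).
#' @param base_seed Base seed; run r uses `base_seed + r`.
#' @param test_frac Test fraction per split.
#' @param smote Oversample training folds (default TRUE).
#' @return Object of class `lf_runs`: mean_auc, std_auc, n_runs, aucs,
#'   importances (averaged, ranked), misclassification_rate per document
#'   (share of the test appearances in which it was misclassified),
#'   test_counts.
#' @export
repeated_runs <- function(spec, features, labels, strata = NULL, n_runs = 100L,
                          base_seed = 1L, test_frac = 0.2, smote = TRUE) {
  ids <- features$doc_id
  if (is.null(strata)) strata <- labels[ids]
  aucs <- numeric(n_runs)
  imp_sum <- NULL
  mis <- stats::setNames(numeric(length(ids)), ids)
  cnt <- stats::setNames(numeric(length(ids)), ids)
  reseed_log <- integer(0)
  for (r in seq_len(n_runs)) {
    seed <- base_seed + r
    repeat {
      split <- stratified_split(ids, strata, test_frac = test_frac, seed = seed)
      if (length(unique(as_binary(labels[split$test]))) > 1L) break
      reseed_log <- c(reseed_log, seed)
      seed <- seed + 100003L  # single-class test fold: redraw
    }
    run <- train_eval_run(spec, split, features, labels, seed = seed,
                          smote = smote)
    aucs[r] <- run$roc_auc
    imp_sum <- if (is.null(imp_sum)) run$feature_importances else
      imp_sum + run$feature_importances
    mis[run$test] <- mis[run$test] + run$misclassified
    cnt[run$test] <- cnt[run$test] + 1
  }
  imp <- imp_sum / n_runs
  out <- list(family = spec$family, mean_auc = mean(aucs),
              std_auc = stats::sd(aucs), n_runs = n_runs, aucs = aucs,
              importances = imp[order(-abs(imp))],
              misclassification_rate = ifelse(cnt > 0, mis / cnt, 0),
              test_counts = cnt, reseeded = reseed_log)
  class(out) <- "lf_runs"
  out
}

#' Error analysis of the most misclassified documents
#'
#' Selects the `n_top` documents with the highest average misclassification
#' frequency (ties broken by doc_id for determinism) and screens this
#' subgroup against the rest on metadata covariates: chi-squared tests for
#' categorical covariates, Mann-Whitney for numeric ones.
#'
#' @param summary `lf_runs` from [repeated_runs()].
#' @param metadata Metadata data.frame with `doc_id`.
#' @param covariates Covariate columns to screen (default: the
#'   socio-demographic set present in the metadata).
#' @param n_top Subgroup size (default 20).
#' @param B Power Monte-Carlo replicates.
#' @return List of class `lf_error_analysis`: `top` (doc_ids), `frequencies`,
#'   `tests` (data.frame covariate/test/p_value/effect_size/power),
#'   `no_errors` flag.
#' @export
error_analysis <- function(summary, metadata,
                           covariates = intersect(
                             c("exposure", "sex", "age", "education",
                               "profession", "single", "living_alone"),
                             names(metadata)),
                           n_top = 20L, B = 2000) {
  fr <- summary$misclassification_rate
  eligible <- names(fr)[summary$test_counts > 0]
  if (length(eligible) < n_top) {
    warning("only ", length(eligible), " documents appeared in test folds; ",
            "selecting all")
    n_top <- length(eligible)
  }
  ord <- order(-fr[eligible], eligible)   # deterministic doc_id tie-break
  top <- eligible[ord][seq_len(n_top)]
  no_errors <- all(fr[eligible] == 0)
  tests <- NULL
  if (!no_errors && nrow(metadata) > 0) {
    grp <- factor(ifelse(metadata$doc_id %in% top, "misclassified", "rest"),
                  levels = c("misclassified", "rest"))
    rows <- lapply(covariates, function(cv) {
      v <- metadata[[cv]]
      res <- tryCatch({
        if (is.numeric(v)) mann_whitney_assoc(v, grp, feature = cv, B = B)
        else chi2_assoc(table(factor(v), grp), feature = cv, B = B)
      }, error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(covariate = cv, test = res$test, p_value = res$p_value,
                 effect_size = res$effect_size, power = res$power,
                 stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, rows)
  }
  if (is.null(tests))
    tests <- data.frame(covariate = character(), test = character(),
                        p_value = numeric(), effect_size = numeric(),
                        power = numeric())
  out <- list(top = top, frequencies = fr[top], tests = tests,
              no_errors = no_errors)
  class(out) <- "lf_error_analysis"
  out
}

#' @export
print.lf_runs <- function(x, ...) {
  cat("<lf_runs> ", x$family, ": mean AUC = ", round(x$mean_auc, 3),
      " ∓ ", round(x$std_auc, 3), " over ", x$n_runs, " runs\n", sep = "")
  cat("top importances:\n")
  print(round(utils::head(x$importances, 5), 4))
  invisible(x)
}

#' @export
summary.lf_runs <- function(object, ...) {
  data.frame(family = object$family, mean_auc = object$mean_auc,
             std_auc = object$std_auc, n_runs = object$n_runs)
}

#' @export
print.lf_error_analysis <- function(x, ...) {
  if (x$no_errors) {
    cat("<lf_error_analysis> no errors: all documents always classified correctly\n")
  } else {
    cat("<lf_error_analysis> ", length(x$top),
        " most misclassified documents\n", sep = "")
    if (nrow(x$tests)) print(format(x$tests, digits = 3), row.names = FALSE)
  }
  invisible(x)
}
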