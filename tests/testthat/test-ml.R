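test_that("stratified split: sizes, stratification, determinism", {
  b <- syn_null_bundle()
  md <- b$metadata
  strata <- exposure_strata(md)
  sp <- stratified_split(md$doc_id, strata[md$doc_id], seed = 4)
  expect_equal(length(sp$test), 30)   # 20% of 148, half-up
  expect_equal(length(sp$train), 118)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), md$doc_id)
  # per-stratum share within one document of 20%
  for (s in levels(strata)) {
    ids <- md$doc_id[strata[md$doc_id] == s]
    n_test <- sum(sp$test %in% ids)
    expect_lte(abs(n_test - 0.2 * length(ids)), 1)
  }
  expect_identical(sp, stratified_split(md$doc_id, strata[md$doc_id], seed = 4))
  expect_error(stratified_split(c("a", "b", "c"), c("s1", "s1", "s2")),
               "singleton stratum")
})

test_that("SMOTE balances classes with on-segment synthetic points", {
  set.seed(21)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(c(0, 1), c(40, 20))
  os <- smote_oversample(X, y, seed = 2)
  expect_equal(sum(os$y == 1), sum(os$y == 0))
  synth <- os$X[-seq_len(60), , drop = FALSE]
  Xm <- X[y == 1, , drop = FALSE]
  # brute-force check: each synthetic row lies on a segment between a
  # minority point and one of its 5 nearest minority neighbours
  D <- as.matrix(dist(Xm)); diag(D) <- Inf
  nn <- t(apply(D, 1, function(r) order(r)[1:5]))
  for (r in seq_len(nrow(synth))) {
    ok <- FALSE
    for (i in seq_len(nrow(Xm))) {
      for (j in nn[i, ]) {
        dir <- Xm[j, ] - Xm[i, ]
        rel <- synth[r, ] - Xm[i, ]
        if (sum(dir^2) == 0) next
        lam <- sum(rel * dir) / sum(dir^2)
        if (lam >= -1e-8 && lam <= 1 + 1e-8 &&
            sqrt(sum((rel - lam * dir)^2)) < 1e-8) { ok <- TRUE; break }
      }
      if (ok) break
    }
    expect_true(ok, info = paste("synthetic row", r))
  }
  # balanced input untouched
  yb <- rep(c(0, 1), 30)
  os2 <- smote_oversample(X, yb)
  expect_identical(os2$X, X)
  expect_error(smote_oversample(X[1:43, ], rep(c(0, 1), c(40, 3))),
               "k_neighbors")
})

test_that("separable data reaches AUC 1; shuffled labels hover at chance", {
  set.seed(31)
  n <- 120
  X <- data.frame(doc_id = sprintf("d%03d", 1:n),
                  f1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                  f2 = rnorm(n), check.names = FALSE)
  lab <- stats::setNames(rep(c(0, 1), each = n / 2), X$doc_id)
  sp <- stratified_split(X$doc_id, lab[X$doc_id], seed = 8)
  run <- train_eval_run(model_spec("logistic_elasticnet"), sp, X, lab, seed = 8)
  expect_equal(run$roc_auc, 1)
  expect_length(intersect(run$train, run$test), 0)

  sh <- stats::setNames(sample(lab), names(lab))
  aucs <- vapply(1:5, function(s) {
    spp <- stratified_split(X$doc_id, sh[X$doc_id], seed = s)
    train_eval_run(model_spec("logistic_elasticnet"), spp, X, sh,
                   seed = s)$roc_auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})

test_that("elastic-net importances match a generic convex optimizer", {
  set.seed(41)
  n <- 200
  X <- cbind(sig = c(rnorm(n / 2, -1), rnorm(n / 2, 1)),
             noise = rnorm(n), const = 1)
  y <- rep(c(0, 1), each = n / 2)
  Xs <- scale(X); Xs[, "const"] <- 0
  spec <- model_spec("logistic_elasticnet")
  hp <- spec$hyperparameters
  lambda <- 1 / (hp$C * n)
  fit <- glmnet::glmnet(Xs, factor(y), family = "binomial",
                        alpha = hp$l1_ratio, lambda = lambda,
                        standardize = FALSE)
  beta_glmnet <- as.numeric(fit$beta)
  # independent oracle: direct minimization of the penalized likelihood
  obj <- function(par) {
    eta <- par[1] + Xs %*% par[-1]
    -mean(y * eta - log(1 + exp(eta))) +
      lambda * (hp$l1_ratio * sum(abs(par[-1])) +
                  (1 - hp$l1_ratio) / 2 * sum(par[-1]^2))
  }
  opt <- optim(rep(0, 4), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(beta_glmnet, opt$par[-1], tolerance = 0.02)
  # the constant feature is fully shrunk
  expect_lt(abs(beta_glmnet[3]), 1e-8)
})

test_that("no information flows from the test fold into training", {
  b <- syn_planted_bundle()
  red <- reduce_features(b$features)
  lab <- diagnosis_label(b$metadata)
  sp <- stratified_split(red$doc_id, lab[red$doc_id], seed = 6)
  run1 <- train_eval_run(model_spec("logistic_elasticnet"), sp, red, lab,
                         seed = 6)
  # perturb the test rows: fitted importances must be identical
  red2 <- red
  for (cn in setdiff(names(red2), "doc_id"))
    red2[[cn]][red2$doc_id %in% sp$test] <-
      red2[[cn]][red2$doc_id %in% sp$test] + 100
  run2 <- train_eval_run(model_spec("logistic_elasticnet"), sp, red2, lab,
                         seed = 6)
  expect_identical(run1$feature_importances, run2$feature_importances)
})

test_that("repeated runs are deterministic and order-invariant in averaging", {
  b <- syn_planted_bundle()
  red <- reduce_features(b$features)
  lab <- diagnosis_label(b$metadata)
  strata <- exposure_strata(b$metadata)
  rs1 <- repeated_runs(model_spec("logistic_elasticnet"), red, lab,
                       strata = strata, n_runs = 10, base_seed = 3)
  rs2 <- repeated_runs(model_spec("logistic_elasticnet"), red, lab,
                       strata = strata, n_runs = 10, base_seed = 3)
  expect_identical(rs1$mean_auc, rs2$mean_auc)
  expect_identical(rs1$importances, rs2$importances)
  expect_equal(rs1$n_runs, 10)
  expect_length(rs1$importances, ncol(red) - 1)
})

test_that("scoring against anti-labels mirrors the AUC", {
  b <- syn_planted_bundle()
  red <- reduce_features(b$features)
  lab <- diagnosis_label(b$metadata)
  sp <- stratified_split(red$doc_id, lab[red$doc_id], seed = 9)
  run <- train_eval_run(model_spec("logistic_elasticnet"), sp, red, lab,
                        seed = 9)
  y_test <- as.integer(lab[sp$test] == "positive")
  expect_equal(roc_auc(run$probabilities, 1 - y_test), 1 - run$roc_auc,
               tolerance = 1e-12)
})

test_that("ebm family trains, predicts in range, honors its defaults", {
  spec <- model_spec("ebm")
  expect_equal(spec$hyperparameters$max_leaves, 10)
  expect_equal(spec$hyperparameters$min_samples_leaf, 15)
  expect_equal(spec$hyperparameters$max_bins, 20)
  expect_equal(spec$hyperparameters$early_stopping_rounds, 20)
  set.seed(51)
  n <- 150
  X <- cbind(a = c(rnorm(n / 2, -1.5), rnorm(n / 2, 1.5)), b = rnorm(n))
  y <- rep(c(0, 1), each = n / 2)
  fit <- ptsdlang:::ebm_fit(X, y, seed = 5)
  p <- ptsdlang:::ebm_predict(fit, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(roc_auc(p, y), 0.85)
  expect_gt(fit$importance["a"], fit$importance["b"])
})

test_that("error analysis selects a deterministic top-20 and finds planted strata", {
  b <- syn_null_bundle()
  # no-errors path
  rs0 <- list(misclassification_rate = stats::setNames(numeric(30),
                                                       sprintf("d%02d", 1:30)),
              test_counts = stats::setNames(rep(3, 30), sprintf("d%02d", 1:30)))
  class(rs0) <- "lf_runs"
  ea0 <- error_analysis(rs0, b$metadata[1:30, ], n_top = 20, B = 10)
  expect_true(ea0$no_errors)
  expect_equal(nrow(ea0$tests), 0)
  # deterministic tie-break at the cut
  fr <- stats::setNames(c(rep(1, 10), rep(0.5, 15), rep(0, 5)),
                        sprintf("d%02d", 30:1))
  rs1 <- list(misclassification_rate = fr,
              test_counts = stats::setNames(rep(2, 30), names(fr)))
  class(rs1) <- "lf_runs"
  ea1 <- error_analysis(rs1, b$metadata[1:30, ], n_top = 20, B = 10)
  ea2 <- error_analysis(rs1, b$metadata[1:30, ], n_top = 20, B = 10)
  expect_identical(ea1$top, ea2$top)
  expect_length(ea1$top, 20)

  # planted label noise confined to the A2 stratum surfaces as an
  # exposure association among the most misclassified documents
  cfg <- synthetic_config(
    length_mean = 900, length_sd = 300, length_range = c(300, 2500),
    seed = 33L, label_noise = c(A1 = 0, A2 = 0.5),
    planted_effects = lapply(c("model_death", "model_body"), function(k)
      list(knob = k, classes = c("full_ptsd", "partial_ptsd"), d = 3.0)))
  g <- generate_corpus(cfg)
  docs <- tokenize_corpus(g$corpus)
  red <- reduce_features(extract_features(docs, g$lexicons))
  lab <- diagnosis_label(g$metadata)
  rs <- repeated_runs(model_spec("logistic_elasticnet"), red, lab,
                      strata = exposure_strata(g$metadata),
                      n_runs = 30, base_seed = 7)
  ea <- error_analysis(rs, g$metadata, B = 50)
  exp_row <- ea$tests[ea$tests$covariate == "exposure", ]
  expect_lt(exp_row$p_value, 0.05)
})
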