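test_that("focal loss reduces to weighted cross-entropy and matches closed form", {
  expect_equal(focal_loss(1), 0)
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_equal(focal_loss(grid, alpha = 0.5, gamma = 0), 0.5 * (-log(grid)),
               tolerance = 1e-12)
  expect_equal(focal_loss(grid, alpha = 0.3, gamma = 0, positive = FALSE),
               0.7 * (-log(grid)), tolerance = 1e-12)
  expect_equal(focal_loss(0.9, alpha = 0.7, gamma = 2),
               0.7 * 0.1^2 * (-log(0.9)), tolerance = 1e-12)
  expect_true(is.finite(focal_loss(0)))
})

test_that("sequence dataset: auto-K formula, leak freedom, OOV handling", {
  b <- dl_bundle()
  ds <- b$dataset
  lens <- vapply(b$docs, function(d) nrow(d$tokens), 0L)
  expect_equal(ds$K, max(1L, as.integer(ceiling(quantile(lens, 0.75) / 64))))
  folds <- list(ds$train$doc_id, ds$val$doc_id, ds$test$doc_id)
  for (i in 1:2) for (j in (i + 1):3)
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  # every sequence inherits its document's label
  expect_identical(ds$train$y, unname(b$labels[ds$train$doc_id]))
  # OOV maps to UNK (id 2), PAD is id 1
  v <- ds$vocabs[[1]]
  expect_identical(ptsdlang:::encode_tokens(c("zzz-not-in-vocab"), v), 2L)
  expect_identical(v$id2token[1:2], c("<pad>", "<unk>"))
  # vocabulary built from the training fold only
  expect_lte(v$size, 600)
})

test_that("short documents are padded; K windows sampled with replacement", {
  doc <- tokenize("un deux trois.")
  labs <- c(doc = 1L)
  docs <- structure(list(doc = doc), class = "lf_docs")
  ds <- suppressWarnings(build_sequence_dataset(
    docs, labs, sequence_config(seq_len = 8, K = 4, vocab_size = 50, seed = 3),
    cnn_config(embedding_dim = 4, hidden = 2, kernel = 3),
    split = list(train = "doc", val = character(), test = character())))
  expect_equal(dim(ds$train$ids[[1]]), c(4, 8))
  expect_true(all(ds$train$ids[[1]][, 5:8] == 1L))  # PAD tail
})

test_that("document inference is the mean of sequence probabilities", {
  b <- dl_bundle()
  m <- b$model
  doc <- b$docs[[b$dataset$split$test[1]]]
  enc <- ptsdlang:::encode_document(m, doc)
  n <- length(enc[[1]])
  starts <- seq(1, n, by = m$seq_len)
  ids <- lapply(enc, function(e) {
    mat <- matrix(1L, length(starts), m$seq_len)
    for (r in seq_along(starts)) {
      w <- e[starts[r]:min(n, starts[r] + m$seq_len - 1)]
      mat[r, seq_along(w)] <- w
    }
    mat
  })
  expect_equal(infer_document(m, doc), mean(predict(m, ids)), tolerance = 1e-12)
  # order invariance of the sequence average
  perm <- sample(nrow(ids[[1]]))
  expect_equal(mean(predict(m, lapply(ids, function(x) x[perm, , drop = FALSE]))),
               infer_document(m, doc), tolerance = 1e-12)
  # single-sequence document: identity
  short <- tokenize("mot seul.")
  short$doc_id <- "s"
  expect_equal(infer_document(m, short),
               predict(m, lapply(ptsdlang:::encode_document(m, short),
                                 function(e) {
                                   mat <- matrix(1L, 1, m$seq_len)
                                   mat[1, seq_along(e)] <- e
                                   mat
                                 }))[1], tolerance = 1e-12)
})

test_that("training learns the marker vocabulary and stays deterministic", {
  b <- dl_bundle()
  # the reduced-capacity fixture must clearly learn the markers (the
  # full-scale separability bound is asserted in the acceptance suite)
  expect_gt(b$model$val_auc, 0.8)
  expect_lte(nrow(b$model$history), 60)
  m2 <- train_cnn(b$dataset, seed = 11)
  expect_identical(b$model$par, m2$par)   # bit-identical weights
})

test_that("saliency has the sequence shape and highlights planted markers", {
  b <- dl_bundle()
  m <- b$model
  ds <- b$dataset
  # all-PAD sequence: finite, uniform scores
  pad <- lapply(ds$test$ids, function(x) matrix(1L, 1, ncol(x)))
  sal0 <- tds_saliency(m, pad)
  expect_length(sal0$combined, ncol(ds$test$ids[[1]]))
  expect_true(all(is.finite(sal0$combined)))
  # interior positions (a full kernel width from either end) see identical
  # receptive fields on a constant input
  k <- b$model$cfg$kernel
  interior <- (k + 1):(length(sal0$combined) - k)
  expect_lt(diff(range(sal0$combined[interior])), 1e-8)

  pos <- which(ds$test$y == 1)
  hit <- 0; tot <- 0
  for (i in pos) {
    toks <- m$vocabs[[1]]$id2token[ds$test$ids[[1]][i, ]]
    sal <- tds_saliency(m, lapply(ds$test$ids, function(x) x[i, , drop = FALSE]))
    expect_length(sal$combined, ncol(ds$test$ids[[1]]))
    mk <- grepl("^xmarker", toks) & !sal$pad
    bg <- !grepl("^xmarker", toks) & !sal$pad
    if (sum(mk) > 0 && sum(bg) > 0) {
      tot <- tot + 1
      hit <- hit + (mean(sal$combined[mk]) > mean(sal$combined[bg]))
    }
  }
  expect_gt(hit / tot, 0.9)
})

test_that("pattern extraction returns scored spans with text", {
  b <- dl_bundle()
  pat <- extract_top_patterns(b$model, b$dataset, "positive", top_n = 8)
  expect_true(nrow(pat) > 0)
  expect_true(all(c("doc_id", "from", "to", "text", "score") %in% names(pat)))
  expect_true(all(pat$from <= pat$to))
  expect_false(is.unsorted(rev(pat$score)))
})

test_that("multi-channel model with extra channels zeroed matches single-channel", {
  b <- dl_bundle()
  cfg1 <- cnn_config(embedding_dim = 8, hidden = 4, kernel = 3)
  cfg3 <- cnn_config(embedding_dim = 8, hidden = 4, kernel = 3,
                     channels = "multi")
  vocab1 <- b$dataset$vocabs[1]
  par1 <- ptsdlang:::cnn_init(cfg1, vocab1, seed = 2)
  vocab3 <- c(vocab1, list(lemma = list(size = 30), pos = list(size = 20)))
  par3 <- ptsdlang:::cnn_init(cfg3, vocab3, seed = 2)
  # zero the lemma/POS embeddings and copy the surface-block conv weights
  par3$E[[1]] <- par1$E[[1]]
  par3$E[[2]][] <- 0; par3$E[[3]][] <- 0
  par3$W[] <- 0
  D <- 8; k <- 3
  for (o in seq_len(k) - 1) {
    rows1 <- o * D + seq_len(D)
    rows3 <- o * 3 * D + seq_len(D)
    par3$W[rows3, ] <- par1$W[rows1, ]
  }
  par3$b <- par1$b; par3$v <- par1$v; par3$c <- par1$c
  ids1 <- list(b$dataset$test$ids[[1]][1:4, , drop = FALSE])
  ids3 <- c(ids1, list(matrix(3L, 4, ncol(ids1[[1]])),
                       matrix(4L, 4, ncol(ids1[[1]]))))
  f1 <- ptsdlang:::cnn_forward(par1, cfg1, ids1)
  f3 <- ptsdlang:::cnn_forward(par3, cfg3, ids3)
  expect_equal(f3$logit, f1$logit, tolerance = 1e-12)
})
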