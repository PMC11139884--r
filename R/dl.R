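# Text-CNN branch: fixed-length token sequences cut from documents after a
# document-level split (leak-free), a single-block convolutional classifier
# (embedding -> spatial dropout -> 1-D convolution -> global max pooling ->
# dense sigmoid) trained with focal loss and Adam, document inference by
# averaging sequence probabilities, and deconvolution/class-activation
# per-token saliency.  The network is implemented directly with matrix
# algebra (im2col convolution), single-threaded and fully seeded, so runs
# are bit-reproducible.

#' Sequence-dataset configuration
#'
#' @param seq_len Tokens per sequence (default 512).
#' @param K Sequences sampled per document at training time; `NULL` (default)
#'   derives K as `ceiling(Q75 / seq_len)` where Q75 is the document length
#'   at the threshold of the 25% longest documents.
#' @param vocab_size Vocabulary size including PAD and UNK (default 2000).
#' @param val_frac Fraction of training documents held out for validation
#'   (default 0.2).
#' @param seed Integer seed for splitting and offset sampling.
#' @return List of class `lf_seq_config`.
#' @export
sequence_config <- function(seq_len = 512L, K = NULL, vocab_size = 2000L,
                            val_frac = 0.2, seed = 1L) {
  stopifnot(seq_len > 0, vocab_size > 2)
  structure(list(seq_len = as.integer(seq_len), K = K,
                 vocab_size = as.integer(vocab_size), val_frac = val_frac,
                 seed = as.integer(seed)), class = "lf_seq_config")
}

#' CNN configuration
#'
#' Defaults: embedding size 128, hidden (filter) size 32, kernel size 9,
#' focal loss with `alpha = 0.7`, `gamma = 2`, at most 50 epochs with early
#' stopping on validation loss, spatial dropout and L2 regularization.
#' `channels = "multi"` adds lemma and POS-tag channels whose embeddings are
#' concatenated with the full-form channel before the convolution.
#'
#' @param embedding_dim,hidden,kernel Network sizes.
#' @param dropout Spatial-dropout rate on embedding channels.
#' @param l2_penalty L2 coefficient on convolution and dense weights.
#' @param max_epochs,patience Epoch budget and early-stopping patience.
#' @param focal_alpha,focal_gamma Focal-loss parameters.
#' @param learning_rate,batch_size Adam step size and minibatch size.
#' @param channels `"single"` (full form only) or `"multi"` (full form +
#'   lemma + POS).
#' @return List of class `lf_cnn_config`.
#' @export
cnn_config <- function(embedding_dim = 128L, hidden = 32L, kernel = 9L,
                       dropout = 0.2, l2_penalty = 1e-4, max_epochs = 50L,
                       patience = 5L, focal_alpha = 0.7, focal_gamma = 2,
                       learning_rate = 1e-3, batch_size = 32L,
                       channels = c("single", "multi")) {
  channels <- match.arg(channels)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden = as.integer(hidden), kernel = as.integer(kernel),
                 dropout = dropout, l2_penalty = l2_penalty,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 channels = channels), class = "lf_cnn_config")
}

#' Focal loss
#'
#' `-alpha_t (1 - p)^gamma log(p)` where `p` is the predicted probability of
#' the true class and `alpha_t = alpha` for positives, `1 - alpha` for
#' negatives.  At `gamma = 0` this is alpha-weighted cross-entropy.
#' Probabilities of exactly 0 are clipped to `1e-12`.
#'
#' @param p Predicted probability of the true class.
#' @param alpha Class weight for the positive class (default 0.7).
#' @param gamma Focusing exponent (default 2).
#' @param positive Logical: is the true class the positive one?
#' @return Loss value(s).
#' @export
focal_loss <- function(p, alpha = 0.7, gamma = 2, positive = TRUE) {
  p <- pmax(p, 1e-12)
  a <- ifelse(positive, alpha, 1 - alpha)
  -a * (1 - p)^gamma * log(p)
}

# token streams per channel (lower-cased); all tokens kept, including
# ellipses and punctuation — transcription marks are part of the signal
doc_channels <- function(doc) {
  list(surface = tolower(doc$tokens$surface),
       lemma = tolower(doc$tokens$lemma),
       pos = doc$tokens$pos)
}

build_vocab <- function(streams, vocab_size) {
  freq <- table(unlist(streams, use.names = FALSE))
  nm <- names(freq)
  # order by descending frequency, ties by code point — locale-independent
  rank_c <- integer(length(nm)); rank_c[order_c(nm)] <- seq_along(nm)
  keep <- utils::head(nm[order(-as.integer(freq), rank_c)], vocab_size - 2L)
  # ids: 1 = PAD, 2 = UNK, words from 3 (exported files use 0-based ids)
  tok2id <- stats::setNames(seq_along(keep) + 2L, keep)
  list(token2id = tok2id, size = length(keep) + 2L,
       id2token = c("<pad>", "<unk>", keep))
}

encode_tokens <- function(tokens, vocab) {
  id <- unname(vocab$token2id[tokens])
  id[is.na(id)] <- 2L
  id
}

# K windows of seq_len from one encoded stream; random starts at training
# time, exhaustive non-overlapping windows at inference
cut_sequences <- function(ids, seq_len, K = NULL, random = TRUE) {
  n <- length(ids)
  if (n == 0L) return(NULL)
  if (random) {
    max_start <- max(1L, n - seq_len + 1L)
    starts <- sample.int(max_start, K, replace = TRUE)
  } else {
    starts <- seq(1L, n, by = seq_len)
  }
  out <- matrix(1L, nrow = length(starts), ncol = seq_len)  # PAD = 1
  for (r in seq_along(starts)) {
    w <- ids[starts[r]:min(n, starts[r] + seq_len - 1L)]
    out[r, seq_along(w)] <- w
  }
  out
}

#' Build the leak-free sequence dataset
#'
#' Splits at the document level first (80/20 test, then 20% of the training
#' documents for validation, stratified on the label), then cuts sequences:
#' the train/validation folds get K random-offset windows per document (with
#' replacement when the document is shorter than `K * seq_len`; short
#' documents are PAD-filled), the test fold gets exhaustive non-overlapping
#' windows.  The token-to-id vocabulary is built from the training fold only
#' (top `vocab_size - 2` frequencies plus PAD and UNK), so no test-fold
#' information leaks into the representation.  Every sequence inherits its
#' document's label.  Empty documents are skipped with a warning.
#'
#' @param docs `lf_docs` from [tokenize_corpus()].
#' @param labels Named binary labels over doc_ids.
#' @param cfg `lf_seq_config`.
#' @param net_cfg `lf_cnn_config` (controls single vs multi channel).
#' @param split Optional list(train, val, test) of doc_ids; computed from
#'   `cfg$seed` when `NULL`.
#' @return List of class `lf_seq_dataset` with elements `train`, `val`,
#'   `test` (each: `ids` = list of per-channel integer matrices, `y`,
#'   `doc_id`), `vocabs`, `K`, `cfg`, `split`.
#' @export
build_sequence_dataset <- function(docs, labels, cfg = sequence_config(),
                                   net_cfg = cnn_config(), split = NULL) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  ids_all <- names(docs)
  lens <- vapply(docs, function(d) nrow(d$tokens), 0L)
  empty <- ids_all[lens == 0L]
  if (length(empty)) {
    warning("skipping empty document(s): ", paste(empty, collapse = ", "))
    docs <- docs[lens > 0L]
    ids_all <- names(docs)
  }
  if (is.null(split)) {
    tt <- stratified_split(ids_all, labels[ids_all], test_frac = 0.2,
                           seed = cfg$seed)
    tv <- stratified_split(tt$train, labels[tt$train],
                           test_frac = cfg$val_frac, seed = cfg$seed + 1L)
    split <- list(train = tv$train, val = tv$test, test = tt$test)
  }
  stopifnot(length(intersect(split$train, split$val)) == 0,
            length(intersect(split$train, split$test)) == 0,
            length(intersect(split$val, split$test)) == 0)

  K <- cfg$K
  if (is.null(K)) {
    q75 <- stats::quantile(vapply(docs, function(d) nrow(d$tokens), 0L), 0.75,
                           type = 7)
    K <- max(1L, as.integer(ceiling(q75 / cfg$seq_len)))
  }

  channel_names <- if (net_cfg$channels == "multi")
    c("surface", "lemma", "pos") else "surface"
  streams <- lapply(docs, doc_channels)
  vocabs <- lapply(channel_names, function(ch) {
    vs <- if (ch == "pos") 64L else cfg$vocab_size
    build_vocab(lapply(streams[split$train], `[[`, ch), vs)
  })
  names(vocabs) <- channel_names

  # cut windows once on start positions, then encode every channel with the
  # same windows (channels must stay aligned token-for-token)
  make_fold <- function(fold_ids, random) {
    per_ch <- stats::setNames(lapply(channel_names, function(ch) list()),
                              channel_names)
    y <- integer(0); did <- character(0)
    for (d in fold_ids) {
      n <- length(streams[[d]]$surface)
      if (random) {
        max_start <- max(1L, n - cfg$seq_len + 1L)
        starts <- sample.int(max_start, K, replace = TRUE)
      } else {
        starts <- seq(1L, n, by = cfg$seq_len)
      }
      for (ch in channel_names) {
        enc <- encode_tokens(streams[[d]][[ch]], vocabs[[ch]])
        m <- matrix(1L, length(starts), cfg$seq_len)
        for (r in seq_along(starts)) {
          w <- enc[starts[r]:min(n, starts[r] + cfg$seq_len - 1L)]
          m[r, seq_along(w)] <- w
        }
        per_ch[[ch]][[d]] <- m
      }
      y <- c(y, rep(as_binary(labels[d]), length(starts)))
      did <- c(did, rep(d, length(starts)))
    }
    ids <- lapply(per_ch, function(lst) do.call(rbind, lst))
    list(ids = ids, y = y, doc_id = did)
  }

  out <- list(train = make_fold(split$train, random = TRUE),
              val = make_fold(split$val, random = TRUE),
              test = make_fold(split$test, random = FALSE),
              vocabs = vocabs, K = K, cfg = cfg, net_cfg = net_cfg,
              split = split)
  # leak-freedom assertion: no document feeds more than one fold
  stopifnot(length(intersect(unique(out$train$doc_id),
                             unique(out$val$doc_id))) == 0,
            length(intersect(unique(out$train$doc_id),
                             unique(out$test$doc_id))) == 0,
            length(intersect(unique(out$val$doc_id),
                             unique(out$test$doc_id))) == 0)
  class(out) <- "lf_seq_dataset"
  out
}

# ---------------------------------------------------------------------------
# network core ---------------------------------------------------------------

cnn_init <- function(cfg, vocabs, seed) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  D <- cfg$embedding_dim
  nc <- length(vocabs)
  Dtot <- D * nc
  E <- lapply(vocabs, function(v)
    matrix(stats::rnorm(v$size * D, sd = 0.05), v$size, D))
  W <- matrix(stats::rnorm(cfg$kernel * Dtot * cfg$hidden,
                           sd = sqrt(2 / (cfg$kernel * Dtot))),
              cfg$kernel * Dtot, cfg$hidden)
  list(E = E, W = W, b = numeric(cfg$hidden),
       v = matrix(stats::rnorm(cfg$hidden, sd = sqrt(1 / cfg$hidden)),
                  cfg$hidden, 1),
       c = 0)
}

# forward pass on a list of per-channel id matrices (B x L); returns
# intermediates needed for backprop/saliency
cnn_forward <- function(par, cfg, ids, dropout_mask = NULL) {
  B <- nrow(ids[[1]]); L <- ncol(ids[[1]])
  k <- cfg$kernel; P <- L - k + 1L
  stopifnot(P >= 1L)
  D <- cfg$embedding_dim
  nc <- length(ids)
  flat <- lapply(ids, function(m) as.vector(t(m)))   # (B*L), sequence-major
  X <- matrix(0, B * L, D * nc)
  for (ci in seq_len(nc))
    X[, (ci - 1L) * D + seq_len(D)] <- par$E[[ci]][flat[[ci]], , drop = FALSE]
  if (!is.null(dropout_mask))
    X <- X * dropout_mask[rep(seq_len(B), each = L), , drop = FALSE]
  idx_base <- rep((seq_len(B) - 1L) * L, each = P) + rep(seq_len(P), B)
  Xcol <- matrix(0, B * P, k * D * nc)
  for (o in seq_len(k) - 1L)
    Xcol[, o * D * nc + seq_len(D * nc)] <- X[idx_base + o, , drop = FALSE]
  H <- sweep(Xcol %*% par$W, 2, par$b, "+")
  A <- pmax(H, 0)
  arr <- A; dim(arr) <- c(P, B, cfg$hidden)
  pooled <- apply(arr, c(2, 3), max)
  if (B == 1L) pooled <- matrix(pooled, 1L)
  amax <- apply(arr, c(2, 3), which.max)
  if (B == 1L) amax <- matrix(amax, 1L)
  logit <- as.numeric(pooled %*% par$v) + par$c
  list(p = stats::plogis(logit), logit = logit, pooled = pooled, amax = amax,
       A = A, Xcol = Xcol, X = X, flat = flat, idx_base = idx_base,
       B = B, L = L, P = P)
}

# d(focal loss)/d(logit), mean-reduced later
focal_grad_logit <- function(p, y, alpha, gamma) {
  u <- 1 - p
  gpos <- alpha * gamma * p * u^gamma * log(pmax(p, 1e-12)) - alpha * u^(gamma + 1)
  gneg <- -(1 - alpha) * gamma * u * p^gamma * log(pmax(u, 1e-12)) +
    (1 - alpha) * p^(gamma + 1)
  ifelse(y == 1, gpos, gneg)
}

cnn_backward <- function(par, cfg, ids, fw, y, dropout_mask = NULL) {
  B <- fw$B; L <- fw$L; P <- fw$P
  D <- cfg$embedding_dim; nc <- length(ids); k <- cfg$kernel
  dlogit <- focal_grad_logit(fw$p, y, cfg$focal_alpha, cfg$focal_gamma) / B
  dv <- t(fw$pooled) %*% dlogit + 2 * cfg$l2_penalty * par$v
  dc <- sum(dlogit)
  dpooled <- dlogit %*% t(par$v)                       # B x hidden
  dA <- matrix(0, B * P, cfg$hidden)
  rows <- (rep(seq_len(B), cfg$hidden) - 1L) * P + as.vector(fw$amax)
  cols <- rep(seq_len(cfg$hidden), each = B)
  dA[cbind(rows, cols)] <- as.vector(dpooled)
  dA[fw$A <= 0] <- 0
  dW <- t(fw$Xcol) %*% dA + 2 * cfg$l2_penalty * par$W
  db <- colSums(dA)
  dXcol <- dA %*% t(par$W)
  dX <- matrix(0, B * L, D * nc)
  for (o in seq_len(k) - 1L) {
    blk <- o * D * nc + seq_len(D * nc)
    add <- dXcol[, blk, drop = FALSE]
    tgt <- fw$idx_base + o
    dX[tgt, ] <- dX[tgt, ] + add
  }
  if (!is.null(dropout_mask))
    dX <- dX * dropout_mask[rep(seq_len(B), each = L), , drop = FALSE]
  dE <- vector("list", nc)
  for (ci in seq_len(nc)) {
    blk <- (ci - 1L) * D + seq_len(D)
    agg <- rowsum(dX[, blk, drop = FALSE], group = fw$flat[[ci]])
    dEc <- matrix(0, nrow(par$E[[ci]]), D)
    dEc[as.integer(rownames(agg)), ] <- agg
    dE[[ci]] <- dEc
  }
  list(dE = dE, dW = dW, db = db, dv = dv, dc = dc)
}

adam_new <- function(par) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else x * 0
  }
  list(m = zeros(par), v = zeros(par), t = 0)
}

adam_step <- function(par, grad, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^state$t); vh <- v / (1 - b2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (ci in seq_along(par$E)) {
    r <- upd(par$E[[ci]], grad$dE[[ci]], state$m$E[[ci]], state$v$E[[ci]])
    par$E[[ci]] <- r$p; state$m$E[[ci]] <- r$m; state$v$E[[ci]] <- r$v
  }
  for (nm in c("W", "b", "v", "c")) {
    g <- grad[[paste0("d", nm)]]
    r <- upd(par[[nm]], g, state$m[[nm]], state$v[[nm]])
    par[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  list(par = par, state = state)
}

fold_loss <- function(par, cfg, fold, batch = 256L) {
  n <- length(fold$y)
  tot <- 0; probs <- numeric(n)
  for (s in seq(1L, n, by = batch)) {
    sel <- s:min(n, s + batch - 1L)
    fw <- cnn_forward(par, cfg, lapply(fold$ids, function(m) m[sel, , drop = FALSE]))
    probs[sel] <- fw$p
    ptrue <- ifelse(fold$y[sel] == 1, fw$p, 1 - fw$p)
    tot <- tot + sum(focal_loss(ptrue, cfg$focal_alpha, cfg$focal_gamma,
                                positive = fold$y[sel] == 1))
  }
  list(loss = tot / n, probs = probs)
}

#' Train the text CNN
#'
#' Single convolution block (embedding, spatial dropout, 1-D convolution
#' with `hidden` filters of width `kernel`, global max pooling, dense
#' sigmoid) trained with Adam on the focal loss, L2 regularization on
#' convolution and dense weights, early stopping on validation loss
#' (`patience` epochs, best weights restored), at most `max_epochs` epochs.
#' Deterministic for a fixed seed (single-threaded, one seeded generator).
#'
#' @param dataset `lf_seq_dataset` from [build_sequence_dataset()].
#' @param cfg `lf_cnn_config` (defaults taken from the dataset).
#' @param seed Integer seed for initialization, dropout and batching.
#' @param verbose Print per-epoch losses.
#' @return Object of class `lf_cnn`: parameters, configs, vocabularies,
#'   training `history`, `val_auc`.
#' @export
train_cnn <- function(dataset, cfg = dataset$net_cfg, seed = 1L,
                      verbose = FALSE) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  par <- cnn_init(cfg, dataset$vocabs, seed)
  set.seed(seed + 1L)
  state <- adam_new(par)
  tr <- dataset$train
  n <- length(tr$y)
  D <- cfg$embedding_dim; nc <- length(dataset$vocabs)
  best <- Inf; best_par <- par; stall <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(n)
    ep_loss <- 0
    for (s in seq(1L, n, by = cfg$batch_size)) {
      sel <- ord[s:min(n, s + cfg$batch_size - 1L)]
      ids <- lapply(tr$ids, function(m) m[sel, , drop = FALSE])
      mask <- NULL
      if (cfg$dropout > 0) {
        keep <- matrix(stats::rbinom(length(sel) * D * nc, 1, 1 - cfg$dropout),
                       length(sel), D * nc)
        mask <- keep / (1 - cfg$dropout)
      }
      fw <- cnn_forward(par, cfg, ids, dropout_mask = mask)
      grad <- cnn_backward(par, cfg, ids, fw, tr$y[sel], dropout_mask = mask)
      if (!all(is.finite(fw$logit)))
        stop("CNN training diverged (non-finite loss) at seed ", seed)
      st <- adam_step(par, grad, state, cfg$learning_rate)
      par <- st$par; state <- st$state
      ptrue <- ifelse(tr$y[sel] == 1, fw$p, 1 - fw$p)
      ep_loss <- ep_loss + sum(focal_loss(ptrue, cfg$focal_alpha,
                                          cfg$focal_gamma,
                                          positive = tr$y[sel] == 1))
    }
    vl <- fold_loss(par, cfg, dataset$val)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         val_loss = vl$loss))
    if (verbose)
      message(sprintf("epoch %d  train %.4f  val %.4f", epoch, ep_loss / n,
                      vl$loss))
    if (vl$loss < best - 1e-6) {
      best <- vl$loss; best_par <- par; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  vl <- fold_loss(best_par, cfg, dataset$val)
  model <- list(par = best_par, cfg = cfg, vocabs = dataset$vocabs,
                seq_len = ncol(dataset$train$ids[[1]]),
                history = history, val_loss = best,
                val_auc = roc_auc(vl$probs, dataset$val$y), seed = seed)
  class(model) <- "lf_cnn"
  model
}

#' Predict sequence probabilities
#' @param object `lf_cnn`.
#' @param ids List of per-channel integer id matrices (B x seq_len), or a
#'   single matrix for single-channel models.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.lf_cnn <- function(object, ids, ...) {
  if (is.matrix(ids)) ids <- list(ids)
  n <- nrow(ids[[1]])
  probs <- numeric(n)
  for (s in seq(1L, n, by = 256L)) {
    sel <- s:min(n, s + 255L)
    probs[sel] <- cnn_forward(object$par, object$cfg,
                              lapply(ids, function(m) m[sel, , drop = FALSE]))$p
  }
  probs
}

encode_document <- function(model, doc) {
  streams <- doc_channels(doc)
  lapply(names(model$vocabs), function(ch)
    encode_tokens(streams[[ch]], model$vocabs[[ch]]))
}

#' Infer the document-level probability
#'
#' Cuts the document into exhaustive non-overlapping windows of the model's
#' sequence length (last window PAD-filled), scores each, and returns the
#' arithmetic mean of the sequence probabilities.
#'
#' @param model `lf_cnn`.
#' @param doc `lf_doc`.
#' @return Scalar probability.
#' @export
infer_document <- function(model, doc) {
  enc <- encode_document(model, doc)
  n <- length(enc[[1]])
  if (n == 0L) return(NA_real_)
  starts <- seq(1L, n, by = model$seq_len)
  ids <- lapply(enc, function(e) {
    m <- matrix(1L, length(starts), model$seq_len)
    for (r in seq_along(starts)) {
      w <- e[starts[r]:min(n, starts[r] + model$seq_len - 1L)]
      m[r, seq_along(w)] <- w
    }
    m
  })
  mean(predict(model, ids))
}

#' Per-token deconvolution saliency (TDS)
#'
#' Class-activation weighting combined with deconvolution: the post-ReLU
#' feature maps are weighted by the dense (class) weights, propagated back
#' through the transposed convolution to token positions, and projected onto
#' the input embedding (gradient-times-input), giving one score per token
#' and channel.  PAD positions are excluded from the normalization used for
#' pattern extraction.
#'
#' @param model `lf_cnn`.
#' @param ids One sequence: integer vector/1-row matrix per channel (list),
#'   or a single vector for single-channel models.
#' @param combine How to combine channel scores into the overall score:
#'   `"sum"` (default) or `"max"`.
#' @return List of class `lf_saliency`: `scores` (seq_len x channels
#'   matrix), `combined` (length seq_len), `pad` (logical mask),
#'   `probability`.
#' @export
tds_saliency <- function(model, ids, combine = c("sum", "max")) {
  combine <- match.arg(combine)
  if (!is.list(ids)) ids <- list(matrix(as.integer(ids), 1L))
  ids <- lapply(ids, function(m) if (is.matrix(m)) m else matrix(as.integer(m), 1L))
  cfg <- model$cfg; par <- model$par
  fw <- cnn_forward(par, cfg, ids)
  L <- fw$L; P <- fw$P
  D <- cfg$embedding_dim; nc <- length(ids); k <- cfg$kernel
  G <- fw$A * matrix(par$v, P, cfg$hidden, byrow = TRUE)   # CAM-weighted maps
  dXcol <- G %*% t(par$W)
  dX <- matrix(0, L, D * nc)
  for (o in seq_len(k) - 1L) {
    blk <- o * D * nc + seq_len(D * nc)
    tgt <- seq_len(P) + o
    dX[tgt, ] <- dX[tgt, ] + dXcol[, blk, drop = FALSE]
  }
  scores <- vapply(seq_len(nc), function(ci) {
    blk <- (ci - 1L) * D + seq_len(D)
    rowSums(dX[, blk, drop = FALSE] * fw$X[, blk, drop = FALSE])
  }, numeric(L))
  scores <- matrix(scores, nrow = L)
  colnames(scores) <- names(model$vocabs)
  combined <- if (combine == "sum") rowSums(scores) else
    apply(scores, 1, max)
  pad <- ids[[1]][1, ] == 1L
  out <- list(scores = scores, combined = combined, pad = pad,
              probability = fw$p)
  class(out) <- "lf_saliency"
  out
}

# maximal runs of tokens whose combined saliency exceeds mean + 1 sd over
# non-PAD positions
saliency_spans <- function(sal) {
  s <- sal$combined; ok <- !sal$pad
  if (!any(ok)) return(data.frame(from = integer(), to = integer(),
                                  score = numeric()))
  thr <- mean(s[ok]) + stats::sd(s[ok])
  if (!is.finite(thr)) return(data.frame(from = integer(), to = integer(),
                                         score = numeric()))
  hot <- which(ok & s > thr)
  if (!length(hot)) return(data.frame(from = integer(), to = integer(),
                                      score = numeric()))
  brk <- c(0, which(diff(hot) > 1), length(hot))
  spans <- lapply(seq_len(length(brk) - 1L), function(i) {
    run <- hot[(brk[i] + 1L):brk[i + 1L]]
    data.frame(from = min(run), to = max(run), score = max(s[run]))
  })
  do.call(rbind, spans)
}

#' Extract the most salient patterns for a class
#'
#' Ranks the class's sequences by predicted class probability (the most
#' representative sequences), computes TDS saliency on the top ones, and
#' returns the maximal token spans whose combined score exceeds the
#' sequence's mean + 1 sd, with their text.
#'
#' @param model `lf_cnn`.
#' @param dataset `lf_seq_dataset` (its test fold is used) or a fold list.
#' @param class `"positive"` or `"negative"`.
#' @param top_n Number of patterns to return.
#' @param fold Which dataset fold to mine (default `"test"`).
#' @return data.frame: doc_id, from, to, text, score, probability.
#' @export
extract_top_patterns <- function(model, dataset, class = c("positive", "negative"),
                                 top_n = 10L, fold = "test") {
  class <- match.arg(class)
  fl <- if (!is.null(dataset[[fold]])) dataset[[fold]] else dataset
  want <- if (class == "positive") 1L else 0L
  sel <- which(fl$y == want)
  if (!length(sel)) return(data.frame())
  probs <- predict(model, lapply(fl$ids, function(m) m[sel, , drop = FALSE]))
  score <- if (want == 1L) probs else 1 - probs
  ord <- sel[order(-score)]
  out <- list()
  for (i in utils::head(ord, max(top_n, 5L))) {
    ids_i <- lapply(fl$ids, function(m) m[i, , drop = FALSE])
    sal <- tds_saliency(model, ids_i)
    sp <- saliency_spans(sal)
    if (!nrow(sp)) next
    toks <- model$vocabs[[1]]$id2token[fl$ids[[1]][i, ]]
    sp$text <- vapply(seq_len(nrow(sp)), function(r)
      paste(toks[sp$from[r]:sp$to[r]], collapse = " "), "")
    sp$doc_id <- fl$doc_id[i]
    sp$probability <- sal$probability
    out[[length(out) + 1L]] <- sp
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  res <- res[order(-res$score), c("doc_id", "from", "to", "text", "score",
                                  "probability")]
  utils::head(res, top_n)
}

#' @export
print.lf_cnn <- function(x, ...) {
  cat("<lf_cnn> ", length(x$vocabs), "-channel text CNN: embedding ",
      x$cfg$embedding_dim, ", hidden ", x$cfg$hidden, ", kernel ",
      x$cfg$kernel, "\n", sep = "")
  cat("trained ", nrow(x$history), " epochs; val loss ",
      signif(x$val_loss, 4), ", val AUC ", signif(x$val_auc, 3), "\n", sep = "")
  invisible(x)
}
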