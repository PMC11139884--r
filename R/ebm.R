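# Cyclic-boosting additive classifier ("ebm" family): a generalized additive
# model on binned features, learned by gradient boosting restricted to one
# feature at a time in round-robin order with a low learning rate, so that
# feature order does not matter, with early stopping on a held-out fraction
# of the training data.  No pairwise interactions and no bagging: the model
# is the piecewise-constant shape function per feature plus an intercept.

ebm_bin_feature <- function(x, max_bins, min_samples_leaf) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = max_bins + 1),
                               type = 7))
  if (length(qs) <= 2) return(list(breaks = NULL, nbin = 1L))
  breaks <- qs[-c(1, length(qs))]
  repeat {
    bins <- findInterval(x, breaks) + 1L
    sizes <- tabulate(bins, length(breaks) + 1L)
    small <- which(sizes < min_samples_leaf)
    if (!length(small) || length(breaks) == 0L) break
    # merge the smallest bin into a neighbor by dropping the adjacent break
    b <- small[which.min(sizes[small])]
    drop_idx <- if (b == 1L) 1L else min(b - 1L, length(breaks))
    breaks <- breaks[-drop_idx]
    if (!length(breaks)) break
  }
  list(breaks = breaks, nbin = length(breaks) + 1L)
}

ebm_fit <- function(X, y, max_leaves = 10, min_samples_leaf = 15,
                    max_bins = 20, early_stopping_rounds = 20,
                    learning_rate = 0.05, max_rounds = 500, val_frac = 0.15,
                    seed = 1L) {
  X <- as.matrix(X); y <- as_binary(y)
  n <- nrow(X); p <- ncol(X)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  val <- sample(n, max(2L, floor(val_frac * n)))
  tr <- setdiff(seq_len(n), val)

  # bins per feature: capped by max_bins and max_leaves (pieces of the shape
  # function), each holding >= min_samples_leaf training rows
  cap <- min(max_bins, max_leaves)
  bins <- lapply(seq_len(p), function(j)
    ebm_bin_feature(X[tr, j], cap, min_samples_leaf))
  bin_of <- function(j, x) {
    if (is.null(bins[[j]]$breaks)) rep(1L, length(x))
    else findInterval(x, bins[[j]]$breaks) + 1L
  }
  btr <- vapply(seq_len(p), function(j) bin_of(j, X[tr, j]), integer(length(tr)))
  bval <- vapply(seq_len(p), function(j) bin_of(j, X[val, j]), integer(length(val)))

  f <- lapply(seq_len(p), function(j) numeric(bins[[j]]$nbin))
  intercept <- stats::qlogis(mean(y[tr]) * 0.998 + 0.001)
  eta_tr <- rep(intercept, length(tr))
  eta_val <- rep(intercept, length(val))
  logloss <- function(eta, yy) {
    pr <- stats::plogis(eta)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -mean(yy * log(pr) + (1 - yy) * log(1 - pr))
  }
  best <- logloss(eta_val, y[val]); best_f <- f; best_intercept <- intercept
  stall <- 0L
  for (round in seq_len(max_rounds)) {
    for (j in seq_len(p)) {
      resid <- y[tr] - stats::plogis(eta_tr)
      upd <- vapply(seq_len(bins[[j]]$nbin), function(b) {
        sel <- btr[, j] == b
        if (any(sel)) mean(resid[sel]) else 0
      }, 0)
      upd <- learning_rate * upd
      f[[j]] <- f[[j]] + upd
      eta_tr <- eta_tr + upd[btr[, j]]
      eta_val <- eta_val + upd[bval[, j]]
    }
    cur <- logloss(eta_val, y[val])
    if (cur < best - 1e-8) {
      best <- cur; best_f <- f; best_intercept <- intercept; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= early_stopping_rounds) break
    }
  }
  # center shape functions; fold the offsets into the intercept
  wtr <- lapply(seq_len(p), function(j) tabulate(btr[, j], bins[[j]]$nbin))
  for (j in seq_len(p)) {
    off <- sum(best_f[[j]] * wtr[[j]]) / length(tr)
    best_f[[j]] <- best_f[[j]] - off
    best_intercept <- best_intercept + off
  }
  importance <- vapply(seq_len(p), function(j)
    mean(abs(best_f[[j]][btr[, j]])), 0)
  names(importance) <- colnames(X)
  structure(list(bins = bins, f = best_f, intercept = best_intercept,
                 importance = importance, features = colnames(X)),
            class = "lf_ebm")
}

ebm_predict <- function(model, X) {
  X <- as.matrix(X)
  eta <- rep(model$intercept, nrow(X))
  for (j in seq_along(model$f)) {
    b <- if (is.null(model$bins[[j]]$breaks)) rep(1L, nrow(X))
    else findInterval(X[, j], model$bins[[j]]$breaks) + 1L
    eta <- eta + model$f[[j]][b]
  }
  stats::plogis(eta)
}
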