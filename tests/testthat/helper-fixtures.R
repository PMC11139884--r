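# Shared fixtures, memoized so expensive corpora are generated once per
# test run.  All sizes are desk-scale: the cohort structure (148 documents,
# 110/38 exposure, 70/42/36 diagnosis) is kept, document lengths are scaled
# down to keep feature extraction fast.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

short_lengths <- function(cfg_args = list()) {
  c(list(length_mean = 900, length_sd = 400, length_range = c(250, 2500)),
    cfg_args)
}

syn_null_bundle <- function() {
  fixture("null148", function() {
    cfg <- do.call(synthetic_config, short_lengths(list(seed = 42L)))
    g <- generate_corpus(cfg)
    g$docs <- tokenize_corpus(g$corpus)
    g$features <- extract_features(g$docs, g$lexicons)
    g
  })
}

syn_planted_bundle <- function() {
  fixture("planted148", function() {
    pe <- lapply(c("model_death", "model_body", "model_physical_sensations"),
                 function(k) list(knob = k,
                                  classes = c("full_ptsd", "partial_ptsd"),
                                  d = 1.5))
    cfg <- do.call(synthetic_config,
                   short_lengths(list(seed = 19L, planted_effects = pe)))
    g <- generate_corpus(cfg)
    g$docs <- tokenize_corpus(g$corpus)
    g$features <- extract_features(g$docs, g$lexicons)
    g
  })
}

diagnosis_label <- function(md) {
  stats::setNames(factor(ifelse(md$diagnosis == "no_ptsd", "negative",
                                "positive"),
                         levels = c("negative", "positive")), md$doc_id)
}

exposure_strata <- function(md) {
  stats::setNames(interaction(md$exposure, md$diagnosis, drop = TRUE),
                  md$doc_id)
}

# small marker-token corpus with a trained CNN, shared by the DL tests
dl_bundle <- function() {
  fixture("dl60", function() {
    cfg <- synthetic_config(
      n_docs = 60, exposure_split = c(A1 = 45, A2 = 15),
      diagnosis_split = c(full_ptsd = 28, partial_ptsd = 16, no_ptsd = 16),
      length_mean = 300, length_sd = 100, length_range = c(120, 600),
      seed = 5L, marker = list(n_tokens = 5, rate = 0.05,
                               classes = c("full_ptsd", "partial_ptsd")))
    g <- generate_corpus(cfg)
    g$docs <- tokenize_corpus(g$corpus)
    g$labels <- stats::setNames(as.integer(g$metadata$diagnosis != "no_ptsd"),
                                g$metadata$doc_id)
    g$dataset <- build_sequence_dataset(
      g$docs, g$labels, sequence_config(seq_len = 64, vocab_size = 600, seed = 7),
      cnn_config(embedding_dim = 32, hidden = 16, kernel = 5, max_epochs = 60,
                 patience = 15, learning_rate = 3e-3))
    g$model <- train_cnn(g$dataset, seed = 11)
    g
  })
}

# tiny two-category lexicon for arithmetic tests
tiny_lexicons <- function() {
  list(ptsdlang:::as_lexicon(
         data.frame(term = c("bien", "mort"),
                    category = c("liwc_positive_emotion",
                                 "liwc_negative_emotion"),
                    weight = 1), "tiny"),
       ptsdlang:::as_lexicon(
         data.frame(term = c("bien", "mort"), category = "labmt_happiness",
                    weight = c(7, 2)), "tiny_labmt"))
}

# random directed multigraph on <= max_nodes nodes, as an lf_speech_graph
random_multigraph <- function(max_nodes = 8L) {
  n <- sample(1:max_nodes, 1)
  m <- sample(0:(3 * n), 1)
  edges <- if (m > 0)
    cbind(from = sample(n, m, TRUE), to = sample(n, m, TRUE))
  else cbind(from = integer(), to = integer())
  g <- list(nodes = paste0("n", seq_len(n)), edges = edges,
            n_nodes = n, n_edges = nrow(edges))
  class(g) <- "lf_speech_graph"
  g
}

# brute-force oracle for the loop / parallel-edge / degree / path features
graph_features_oracle <- function(g) {
  e <- g$edges; n <- g$n_nodes
  l1 <- sum(e[, 1] == e[, 2])
  l2 <- 0; pe <- 0
  m <- nrow(e)
  if (m >= 2) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (e[i, 1] == e[j, 2] && e[i, 2] == e[j, 1] && e[i, 1] != e[i, 2])
        l2 <- l2 + 1
      if (e[i, 1] == e[j, 1] && e[i, 2] == e[j, 2]) pe <- pe + 1
    }
  }
  # directed 3-cycles through distinct nodes, per edge-instance triple
  l3 <- 0
  if (m >= 3) {
    A <- matrix(0, n, n)
    for (i in seq_len(m)) if (e[i, 1] != e[i, 2])
      A[e[i, 1], e[i, 2]] <- A[e[i, 1], e[i, 2]] + 1
    for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
      if (a < b || a < cc) next  # count each cyclic triple once (min first)
      if (length(unique(c(a, b, cc))) == 3)
        l3 <- l3 + A[a, b] * A[b, cc] * A[cc, a]
    }
  }
  deg <- tabulate(e[, 1], n) + tabulate(e[, 2], n)
  # undirected simple projection + weak components by Floyd-Warshall
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (i in seq_len(m)) if (e[i, 1] != e[i, 2]) {
    D[e[i, 1], e[i, 2]] <- 1; D[e[i, 2], e[i, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  comp <- rep(NA_integer_, n); cid <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1L
    comp[is.finite(D[i, ])] <- cid
  }
  sizes <- tabulate(comp)
  lcc <- which.max(sizes)
  members <- which(comp == lcc)
  avg_sp <- 0
  if (length(members) > 1) {
    ds <- D[members, members]
    avg_sp <- mean(ds[upper.tri(ds)])
  }
  # clustering / transitivity on the simple undirected projection of the lcc
  Adj <- (is.finite(D) & D == 1)[members, members, drop = FALSE]
  k_i <- rowSums(Adj)
  tri_i <- vapply(seq_along(members), function(i) {
    nb <- which(Adj[i, ])
    if (length(nb) < 2) return(0)
    sum(Adj[nb, nb, drop = FALSE]) / 2
  }, 0)
  local_c <- ifelse(k_i >= 2, tri_i / (k_i * (k_i - 1) / 2), 0)
  avg_clust <- if (length(members) > 1) mean(local_c) else 0
  # 3 * triangles = sum of per-vertex triangle counts
  open_triples <- sum(k_i * (k_i - 1) / 2)
  transit <- if (open_triples > 0) sum(tri_i) / open_triples else 0
  c(graph_l1 = l1, graph_l2 = l2, graph_l3 = l3, graph_pe = pe,
    graph_degree_average = if (n > 0) 2 * m / n else 0,
    graph_degree_std = if (n > 1) stats::sd(deg) else 0,
    graph_average_clustering = avg_clust,
    graph_average_shortest_path = avg_sp,
    graph_transitivity = transit,
    graph_n_nodes = n, graph_n_edges = m,
    graph_lcc_size = if (n > 0) max(sizes) else 0)
}
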