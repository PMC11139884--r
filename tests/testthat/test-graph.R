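test_that("speech-graph construction counts nodes, multi-edges, segments", {
  g <- build_speech_graph(tokenize("a b a b"))
  expect_equal(g$n_nodes, 2)
  expect_equal(g$n_edges, 3)

  g2 <- build_speech_graph(tokenize("a a"))
  expect_equal(g2$n_nodes, 1)
  expect_equal(graph_features(g2)[["graph_l1"]], 1)

  g3 <- build_speech_graph(tokenize("a b c"))
  f3 <- graph_features(g3)
  expect_equal(unname(f3[c("graph_l1", "graph_l2", "graph_l3", "graph_pe")]),
               c(0, 0, 0, 0))
  expect_equal(f3[["graph_n_edges"]], 2)

  # per-sentence scope: E = units - segments
  g4 <- build_speech_graph(tokenize("a b. c d."), scope = "sentence")
  expect_equal(g4$n_edges, 4 - 2)
})

test_that("punctuation and ellipses never enter the graph", {
  g <- build_speech_graph(tokenize("xa… xb. xa, xb !"))
  expect_setequal(g$nodes, c("xa", "xb"))
})

test_that("alternating bigram stream shows 2-cycles and parallel edges", {
  f <- graph_features(build_speech_graph(tokenize("a b a b")))
  expect_true(f[["graph_l2"]] >= 1)
  expect_equal(f[["graph_pe"]], 1)
  expect_equal(f[["graph_degree_average"]], 3)
})

test_that("graph features equal the brute-force oracle on random multigraphs", {
  set.seed(101)
  for (case in 1:220) {
    g <- random_multigraph(8L)
    got <- graph_features(g)
    want <- graph_features_oracle(g)
    expect_equal(got[names(want)], want, tolerance = 1e-10,
                 info = paste("case", case, "n =", g$n_nodes,
                              "m =", g$n_edges))
  }
})

test_that("degenerate graphs return sentinels", {
  empty <- build_speech_graph(tokenize(""))
  f <- graph_features(empty)
  expect_true(all(f == 0))
  single <- graph_features(build_speech_graph(tokenize("mot")))
  expect_equal(single[["graph_average_shortest_path"]], 0)
  expect_equal(single[["graph_lcc_size"]], 1)
})
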