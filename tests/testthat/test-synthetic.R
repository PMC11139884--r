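test_that("generation is deterministic in (config, seed)", {
  cfg <- synthetic_config(n_docs = 12, exposure_split = c(A1 = 9, A2 = 3),
                          diagnosis_split = c(full_ptsd = 5, partial_ptsd = 4,
                                              no_ptsd = 3),
                          length_mean = 200, length_sd = 80,
                          length_range = c(80, 500), seed = 8)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(lapply(g1$corpus, `[[`, "raw_text"),
                   lapply(g2$corpus, `[[`, "raw_text"))
  expect_identical(g1$metadata, g2$metadata)
  expect_identical(generate_lexicons(4), generate_lexicons(4))
})

test_that("configured marginals are honored and infeasible configs rejected", {
  b <- syn_null_bundle()
  md <- b$metadata
  expect_equal(unname(table(md$exposure)[c("A1", "A2")]), c(110L, 38L),
               ignore_attr = TRUE)
  expect_equal(as.integer(table(md$diagnosis)[c("full_ptsd", "partial_ptsd",
                                                "no_ptsd")]),
               c(70L, 42L, 36L))
  # partial-PTSD invariant holds by construction
  expect_true(all(md$crit_B[md$diagnosis == "partial_ptsd"]))
  expect_true(all(md$crit_G[md$diagnosis == "partial_ptsd"]))
  expect_error(synthetic_config(n_docs = 10,
                                exposure_split = c(A1 = 9, A2 = 3)),
               "sum to n_docs")
})

test_that("lexicons cover every registered category with generator terms", {
  lx <- generate_lexicons(3)
  lex <- ptsdlang:::combine_lexicons(lx)
  need <- setdiff(names(ptsdlang:::lf_lexicon_categories()),
                  c("textblob_polarity", "textblob_subjectivity"))
  for (cat in need)
    expect_gte(sum(lex$category == cat), 20)
  for (cat in unname(ptsdlang:::lf_tagger_categories()))
    expect_gte(sum(lex$category == cat), 20)
  # all weights finite, happiness weights spread over the valence scale
  expect_true(all(is.finite(lex$weight)))
  expect_gt(diff(range(lex$weight[lex$category == "labmt_happiness"])), 1)
})

test_that("planted rate deltas are realized within binomial tolerance", {
  cfg <- synthetic_config(
    n_docs = 40, exposure_split = c(A1 = 30, A2 = 10),
    diagnosis_split = c(full_ptsd = 20, partial_ptsd = 10, no_ptsd = 10),
    length_mean = 5000, length_sd = 500, length_range = c(3000, 8000),
    seed = 14,
    planted_effects = list(list(knob = "model_death",
                                classes = c("full_ptsd", "partial_ptsd"),
                                delta = 0.03)))
  g <- generate_corpus(cfg)
  docs <- tokenize_corpus(g$corpus)
  tg <- lexicon_tagger(g$lexicons)
  rates <- vapply(docs, function(d) lexical_field_rates(d, tg)[["model_death"]], 0)
  cls <- g$ground_truth$true_class[names(rates)]
  gap <- mean(rates[cls != "no_ptsd"]) - mean(rates[cls == "no_ptsd"])
  expect_lt(abs(gap - 0.03), 0.005)
})

test_that("the repetition knob monotonically raises PE and L2", {
  mean_rep <- function(delta) {
    cfg <- synthetic_config(
      n_docs = 12, exposure_split = c(A1 = 9, A2 = 3),
      diagnosis_split = c(full_ptsd = 6, partial_ptsd = 3, no_ptsd = 3),
      length_mean = 400, length_sd = 100, length_range = c(200, 800),
      seed = 25,
      planted_effects = if (delta > 0)
        list(list(knob = "repetition_rate",
                  classes = c("full_ptsd", "partial_ptsd", "no_ptsd"),
                  delta = delta)) else list())
    g <- generate_corpus(cfg)
    ft <- extract_features(tokenize_corpus(g$corpus), g$lexicons)
    c(pe = mean(ft$graph_pe), l2 = mean(ft$graph_l2))
  }
  lo <- mean_rep(0); mid <- mean_rep(0.03); hi <- mean_rep(0.08)
  expect_lt(lo["pe"], mid["pe"]); expect_lt(mid["pe"], hi["pe"])
  expect_lt(lo["l2"], hi["l2"])
})

test_that("marker tokens stay exclusive to the configured classes", {
  cfg <- synthetic_config(
    n_docs = 20, exposure_split = c(A1 = 15, A2 = 5),
    diagnosis_split = c(full_ptsd = 8, partial_ptsd = 6, no_ptsd = 6),
    length_mean = 250, length_sd = 80, length_range = c(120, 500), seed = 31,
    marker = list(n_tokens = 3, rate = 0.04,
                  classes = c("full_ptsd", "partial_ptsd")))
  g <- generate_corpus(cfg)
  has_marker <- vapply(g$corpus, function(tr)
    grepl("xmarker", tr$raw_text, fixed = TRUE), TRUE)
  cls <- g$ground_truth$true_class[names(has_marker)]
  expect_false(any(has_marker[cls == "no_ptsd"]))
  expect_true(mean(has_marker[cls != "no_ptsd"]) > 0.9)
})
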