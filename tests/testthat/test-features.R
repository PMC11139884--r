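test_that("registry has the printed family sizes and retention counts", {
  reg <- lf_registry()
  sizes <- table(reg$group)
  expect_equal(as.integer(sizes[c("textual", "sentiment_emotion", "lexical",
                              "morphosyntactic", "syntactic_passive",
                              "disfluency", "readability", "graph")]),
               c(2L, 27L, 4L, 18L, 4L, 9L, 5L, 12L))
  expect_equal(sum(reg$retained_for_ml & reg$group == "sentiment_emotion"), 6)
  expect_identical(reg$name[reg$retained_for_ml &
                              reg$group == "syntactic_passive"],
                   "passive_count_norm")
})

test_that("textual counts follow the word-token convention", {
  expect_equal(textual_features(tokenize("Il court. Elle dort.")),
               c(words_number = 4, sentence_number = 2))
  expect_equal(textual_features(tokenize("")),
               c(words_number = 0, sentence_number = 0))
  # ellipses and truncated fragments are not words
  expect_equal(textual_features(tokenize("Je… je voulais."))[["words_number"]], 3)
  expect_equal(textual_features(
    tokenize("je… je voulais euh par… partir"))[["words_number"]], 5)
})

test_that("emotion rates and weighted happiness follow lexicon arithmetic", {
  lx <- tiny_lexicons()
  e <- emotion_features(tokenize("mort mort bien"), lx)
  expect_equal(e[["liwc_positive_emotion"]], 1 / 3)
  expect_equal(e[["liwc_negative_emotion"]], 2 / 3)
  expect_equal(e[["labmt_happiness"]], (2 + 2 + 7) / 3)
  expect_true(e[["textblob_polarity"]] >= -1 && e[["textblob_polarity"]] <= 1)

  empty <- emotion_features(tokenize(""), lx)
  expect_true(all(empty == 0))
})

test_that("lexical-field rates come from the tagger contract", {
  lx <- ptsdlang:::as_lexicon(
    data.frame(term = "sang", category = "BODY", weight = 1), "m")
  r <- lexical_field_rates(tokenize("le sang coulait"), lexicon_tagger(list(lx)))
  expect_equal(r[["model_body"]], 1 / 3)
  expect_equal(r[["model_death"]], 0)
})

test_that("morphosyntactic proportions use the right denominators", {
  m <- morphosyntactic_features(tokenize("Je cours. Je courais."))
  expect_equal(m[["verb_indicatif_present"]], 0.5)
  expect_equal(m[["verb_indicatif_past"]], 0.5)
  expect_equal(m[["first_personal_pronoun_sing"]], 2 / 4)
  expect_true(all(m >= 0 & m <= 1))

  # "on" values by contextual rules
  on_feats <- function(txt) {
    v <- morphosyntactic_features(tokenize(txt))
    v[c("model_on_we", "model_on_someone", "model_on_generic")]
  }
  expect_equal(unname(on_feats("On est entré dans la salle à 21h45")), c(1, 0, 0))
  expect_equal(unname(on_feats("On m'a marché dessus")), c(0, 1, 0))
  expect_equal(unname(on_feats("on n'est jamais mieux servi que par soi même")),
               c(0, 0, 1))
  # no verbs: tense features at the 0 sentinel
  expect_equal(morphosyntactic_features(
    tokenize("le chat"))[["verb_indicatif_present"]], 0)
})

test_that("passive detection accepts periphrastic passives, rejects compounds", {
  p <- passive_voice_features(tokenize("Il a été blessé par une balle."))
  expect_equal(p[["passive_count"]], 1)
  expect_equal(p[["passive_agented_count"]], 1)
  expect_equal(p[["passive_agentless_count"]], 0)
  # motion-verb compound tense, not a passive
  expect_equal(passive_voice_features(
    tokenize("Elle est partie."))[["passive_count"]], 0)
  expect_equal(passive_voice_features(
    tokenize("Elle était blessée."))[["passive_agentless_count"]], 1)
  expect_true(all(passive_voice_features(tokenize("")) == 0))
})

test_that("disfluency rates follow the hand-counted conventions", {
  d <- tokenize("je… je voulais euh par… partir")
  f <- disfluency_features(d)
  nw <- 5
  expect_equal(f[["filler_rate"]], 1 / nw)
  expect_equal(f[["silent_break_after_word_rate"]], 2 / nw)
  expect_equal(f[["silent_break_between_words_rate"]], 0)
  expect_equal(f[["word_repetition_rate"]], 1 / nw)
  expect_equal(f[["false_start_rate"]], 1 / nw)

  expect_equal(disfluency_features(tokenize("euh euh"))[["filler_rate"]], 1)
  fluent <- disfluency_features(tokenize("Il court vite."))
  expect_true(all(fluent == 0))
})

test_that("readability ratios are in range and words-per-sentence exact", {
  r <- readability_features(tokenize("le chat le chat"))
  expect_equal(r[["token_ratio_score"]], 0.5)
  expect_equal(readability_features(tokenize("chat"))[["token_ratio_score"]], 1)
  expect_equal(readability_features(
    tokenize("Il court. Elle dort."))[["words_per_sentence"]], 2)
})

test_that("extractor returns the full registry, no NaN, deterministic rows", {
  b <- syn_null_bundle()
  sub <- b$docs[1:8]
  ft <- extract_features(sub, b$lexicons)
  expect_identical(setdiff(names(ft), "doc_id"), lf_registry()$name)
  expect_false(anyNA(ft))
  ft2 <- extract_features(sub, b$lexicons)
  expect_identical(ft, ft2)
  # a one-token document yields sentinels, never NaN
  one <- tokenize_corpus(structure(list(list(doc_id = "one", raw_text = "mot")),
                                   class = "lf_corpus"))
  f1 <- extract_features(one, b$lexicons)
  expect_false(anyNA(f1))

  # missing resource names the feature
  expect_error(extract_features(sub, tiny_lexicons()), "gobin_positive")
})

test_that("proportion features stay in [0,1]; counts are nonneg integers", {
  b <- syn_null_bundle()
  reg <- lf_registry()
  props <- reg$name[reg$normalization %in% c("per_token", "per_sentence",
                                             "per_verb", "per_pronoun",
                                             "per_on", "per_present")]
  props <- setdiff(props, "words_per_sentence")
  for (f in setdiff(props, c("score_disfluencies")))
    expect_true(all(b$features[[f]] >= 0 & b$features[[f]] <= 1), info = f)
  for (f in c("passive_count", "passive_agented_count", "graph_l1",
              "graph_n_nodes", "graph_n_edges"))
    expect_true(all(b$features[[f]] >= 0 &
                      b$features[[f]] == round(b$features[[f]])), info = f)
})

test_that("doubling a document preserves rates and doubles counts", {
  b <- syn_null_bundle()
  doc <- b$corpus[[3]]
  doubled <- list(doc_id = "dbl",
                  raw_text = paste(doc$raw_text, doc$raw_text, sep = " "))
  f1 <- extract_features(tokenize_corpus(structure(list(doc), class = "lf_corpus")),
                         b$lexicons)
  f2 <- extract_features(tokenize_corpus(structure(list(doubled), class = "lf_corpus")),
                         b$lexicons)
  expect_equal(f2$words_number, 2 * f1$words_number)
  expect_equal(f2$passive_count, 2 * f1$passive_count)
  for (f in c("liwc_death", "model_death", "filler_rate", "passive_count_norm"))
    expect_equal(f2[[f]], f1[[f]], tolerance = 0.02, info = f)
  # graph edge count gains exactly the one boundary edge
  expect_equal(f2$graph_n_edges, 2 * f1$graph_n_edges + 1)
})

test_that("extraction is permutation-stable across corpus order", {
  b <- syn_null_bundle()
  sub <- b$docs[1:6]
  ft <- extract_features(sub, b$lexicons)
  perm <- sample(seq_along(sub))
  ft2 <- extract_features(sub[perm], b$lexicons)
  ft2 <- ft2[match(ft$doc_id, ft2$doc_id), ]
  rownames(ft2) <- NULL
  expect_equal(ft, ft2, ignore_attr = TRUE)
})

test_that("reduction keeps the valence sentiment set and is idempotent", {
  b <- syn_null_bundle()
  red <- reduce_features(b$features)
  reg <- lf_registry()
  kept_sent <- intersect(names(red), reg$name[reg$group == "sentiment_emotion"])
  expect_setequal(kept_sent, c("textblob_polarity", "textblob_subjectivity",
                               "feel_positive", "labmt_happiness",
                               "liwc_positive_emotion", "liwc_negative_emotion"))
  kept_pass <- intersect(names(red), reg$name[reg$group == "syntactic_passive"])
  expect_identical(kept_pass, "passive_count_norm")
  expect_identical(reduce_features(red), red)
  # column order preserved
  expect_identical(setdiff(names(red), "doc_id"),
                   intersect(reg$name, names(red)))
})
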