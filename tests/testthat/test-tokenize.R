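test_that("transcription conventions are preserved by tokenization", {
  d <- tokenize("Je… je voulais euh par… partir.")
  tok <- d$tokens
  expect_equal(sum(tok$is_ellipsis), 1)          # one standalone break
  expect_equal(sum(tok$truncated), 1)            # "par…" kept whole
  expect_identical(tok$surface[tok$truncated], "par…")
  # spans are 0-based half-open and reproduce the surfaces
  expect_true(all(substring(d$raw_text, tok$start + 1, tok$end) == tok$surface))
  expect_true(all(tok$start[-1] >= tok$end[-nrow(tok)]))
})

test_that("sentences split on terminal punctuation and partition tokens", {
  d <- tokenize("Il court. Elle dort.")
  expect_equal(nrow(d$sentences), 2)
  covered <- unlist(Map(seq, d$sentences$from, d$sentences$to))
  expect_identical(covered, seq_len(nrow(d$tokens)))

  e <- tokenize("")
  expect_equal(nrow(e$tokens), 0)
  expect_equal(nrow(e$sentences), 0)
})

test_that("tokenization is deterministic", {
  txt <- "On est entré dans la salle à 21h45. Et euh… bah voilà."
  expect_identical(tokenize(txt), tokenize(txt))
})

test_that("rule annotator covers closed classes and verb morphology", {
  d <- tokenize("Je cours. Je courais.")
  tok <- d$tokens
  expect_identical(tok$pos[tok$surface == "Je"], c("PRON", "PRON"))
  expect_identical(tok$tense[tok$surface == "cours"], "present")
  expect_identical(tok$tense[tok$surface == "courais"], "imperfect")

  d2 <- tokenize("Il a dit non.")
  # "dit" after auxiliary resolves to past participle
  expect_identical(d2$tokens$verbform[d2$tokens$surface == "dit"], "participle")

  d3 <- tokenize("Nous avons vu Marie.")
  expect_identical(d3$tokens$pos[d3$tokens$surface == "Marie"], "PROPN")
})
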