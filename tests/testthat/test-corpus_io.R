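test_that("directory corpora read with lexicographic ids and byte-exact text", {
  dir <- withr::local_tempdir()
  writeLines("Bonjour.", file.path(dir, "b.txt"))
  txt <- "Je… je voulais euh par… partir."
  con <- file(file.path(dir, "a.txt"), "wb")
  writeBin(charToRaw(enc2utf8(txt)), con); close(con)
  corpus <- read_corpus(dir)
  expect_length(corpus, 2)
  expect_identical(names(corpus), c("a", "b"))
  expect_identical(corpus[["a"]]$raw_text, txt)

  out <- withr::local_tempdir()
  write_corpus(corpus, out)
  again <- read_corpus(out)
  expect_identical(again[["a"]]$raw_text, txt)
})

test_that("JSONL corpora validate records and name offending lines", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"x","text":"Un."}',
               '{"doc_id":"y","text":"Deux."}',
               '{"doc_id":"z"}'), f)
  expect_error(read_corpus(f), "line 3")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"x","text":"Un."}',
               '{"doc_id":"x","text":"Deux."}'), f2)
  expect_error(read_corpus(f2), "duplicate doc_id")
})

test_that("metadata reader enforces enums and the partial-PTSD invariant", {
  f <- withr::local_tempfile(fileext = ".csv")
  md <- data.frame(doc_id = c("a", "b", "c"),
                   exposure = c("A1", "A2", "A1"),
                   diagnosis = c("full_ptsd", "partial_ptsd", "no_ptsd"),
                   crit_B = c(TRUE, TRUE, FALSE), crit_C = FALSE,
                   crit_D = FALSE, crit_E = FALSE,
                   crit_G = c(TRUE, TRUE, FALSE))
  write.csv(md, f, row.names = FALSE)
  rec <- read_metadata(f)
  expect_equal(nrow(rec), 3)
  expect_type(rec$crit_B, "logical")

  md2 <- md; md2$crit_B[2] <- FALSE
  write.csv(md2, f, row.names = FALSE)
  expect_error(read_metadata(f), "partial_ptsd requires criteria B and G")

  md3 <- md; md3$exposure[1] <- "A3"
  write.csv(md3, f, row.names = FALSE)
  expect_error(read_metadata(f), "invalid exposure .*row 1")
})

test_that("lexicon CSV round-trips and rejects duplicate entries", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("term,category,weight", "mort,death,1.0", "sang,body,1.0"), f)
  lx <- read_lexicon(f)
  expect_s3_class(lx, "lf_lexicon")
  expect_identical(lx$category, c("death", "body"))
  expect_identical(attr(lx, "match_policy"), "lemma")

  writeLines(c("term,category,weight", "mort,death,1", "mort,death,2"), f)
  expect_error(read_lexicon(f), "duplicate")
})

test_that("feature tables round-trip losslessly in registry column order", {
  b <- syn_null_bundle()
  tab <- b$features[1:3, ]
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_identical(names(back), names(tab))
  for (cn in setdiff(names(tab), "doc_id"))
    expect_equal(back[[cn]], tab[[cn]], tolerance = 1e-12)
})
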