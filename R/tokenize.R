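#' Tokenize and annotate a transcript
#'
#' Deterministic whitespace/punctuation tokenizer for transcribed spoken
#' French, preserving transcription conventions: the ellipsis mark
#' \dQuote{\ldots} is always a token of its own, and a truncated word (a
#' fragment glued to an ellipsis and resumed by the following word, as in
#' \code{"par… partir"}) is kept as a single token flagged
#' \code{truncated = TRUE}.  Sentences are segmented on terminal punctuation
#' (\code{. ! ?}).  Character spans are 0-based half-open into `raw_text`.
#'
#' @param transcript A transcript: a list with `doc_id` and `raw_text`, as
#'   produced by [read_corpus()], or a single character string.
#' @param annotator Annotation backend filling lemma, coarse POS (UPOS) and
#'   morphology.  Defaults to the built-in French rule annotator; any
#'   function with the same contract (takes and returns the token
#'   data.frame) can be plugged in.
#' @return An object of class `lf_doc`: list with `doc_id`, `raw_text`,
#'   `tokens` (data.frame with columns surface, lemma, pos, mood, tense,
#'   person, number, verbform, truncated, is_ellipsis, is_word, start, end,
#'   sentence) and `sentences` (data.frame with token-index ranges `from`,
#'   `to`, 1-based inclusive).
#' @examples
#' d <- tokenize("Il court. Elle dort.")
#' nrow(d$sentences)  # 2
#' @export
tokenize <- function(transcript, annotator = french_annotator()) {
  if (is.character(transcript))
    transcript <- list(doc_id = "doc", raw_text = transcript)
  text <- transcript$raw_text
  tok <- tokenize_raw(text)
  tok <- annotator(tok)
  sent <- segment_sentences(tok)
  tok$sentence <- sent$sentence_of
  doc <- list(doc_id = transcript$doc_id, raw_text = text,
              tokens = tok, sentences = sent$ranges)
  class(doc) <- "lf_doc"
  doc
}

# raw tokenization: surfaces + 0-based half-open spans + ellipsis/truncation
tokenize_raw <- function(text) {
  empty <- data.frame(surface = character(), start = integer(),
                      end = integer(), is_ellipsis = logical(),
                      truncated = logical(), stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty)
  pat <- paste0("\\.{3}|…",                      # ellipsis
                "|\\p{L}+['’]",                  # elided clitic (j', n')
                "|\\p{L}+(?:-\\p{L}+)*",              # word, maybe hyphenated
                "|[0-9]+(?:h[0-9]*)?",                # numbers, clock times
                "|[\\p{P}\\p{S}]")                    # single punctuation
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  start <- as.integer(m) - 1L                         # 0-based
  len <- attr(m, "match.length")
  # extract matches in one pass over the character vector: substring() on a
  # long UTF-8 string is linear per call, quadratic overall
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  surface <- vapply(seq_along(start), function(i)
    paste(chars[(start[i] + 1L):(start[i] + len[i])], collapse = ""), "")
  end <- start + len
  is_ell <- surface %in% c("…", "...")
  truncated <- rep(FALSE, length(surface))

  # merge "word+ellipsis" into one truncated token when the word is resumed
  # by the next word ("par… partir"); otherwise the ellipsis stays standalone
  drop <- rep(FALSE, length(surface))
  i <- 1L
  while (i < length(surface)) {
    if (!is_ell[i] && !is_punct_surface(surface[i]) &&
        is_ell[i + 1L] && end[i] == start[i + 1L]) {
      nxt <- i + 2L
      while (nxt <= length(surface) && is_ell[nxt]) nxt <- nxt + 1L
      if (nxt <= length(surface)) {
        w <- tolower(surface[i]); f <- tolower(surface[nxt])
        if (nchar(f) > nchar(w) && startsWith(f, w)) {
          surface[i] <- paste0(surface[i], surface[i + 1L])
          end[i] <- end[i + 1L]
          truncated[i] <- TRUE
          drop[i + 1L] <- TRUE
          i <- i + 1L
        }
      }
    }
    i <- i + 1L
  }
  out <- data.frame(surface = surface, start = start, end = end,
                    is_ellipsis = is_ell, truncated = truncated,
                    stringsAsFactors = FALSE)[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_punct_surface <- function(s) grepl("^[\\p{P}\\p{S}]$", s, perl = TRUE)

segment_sentences <- function(tok) {
  n <- nrow(tok)
  if (n == 0L)
    return(list(ranges = data.frame(from = integer(), to = integer()),
                sentence_of = integer()))
  terminal <- tok$surface %in% c(".", "!", "?")
  sentence_of <- integer(n)
  ranges <- list()
  from <- 1L; s <- 1L
  for (i in seq_len(n)) {
    sentence_of[i] <- s
    if (terminal[i]) {
      ranges[[s]] <- c(from, i)
      from <- i + 1L; s <- s + 1L
    }
  }
  if (from <= n) ranges[[s]] <- c(from, n)
  r <- do.call(rbind, ranges)
  list(ranges = data.frame(from = r[, 1], to = r[, 2]),
       sentence_of = sentence_of)
}

#' Built-in French rule annotator
#'
#' Assigns lemma, coarse POS and morphological attributes (mood, tense,
#' person, number, verb form) using closed-class lists and a verb-form table
#' (regular first-group conjugation plus frequent irregulars).  Unknown
#' content words default to NOUN; capitalized non-sentence-initial words to
#' PROPN; `-ment` words to ADV.  Forms ambiguous between finite verb and past
#' participle ("dit", "fait") are resolved as participles after an auxiliary.
#'
#' @return A function from token data.frame to annotated token data.frame.
#' @export
french_annotator <- function() {
  vt <- fr_verb_table()
  pron_names <- names(fr_pron_person)
  pron_person <- vapply(fr_pron_person, function(p) as.integer(p[1]), 0L)
  pron_number <- vapply(fr_pron_person, `[`, "", 2)
  sconj <- c("que", "si", "quand", "comme", "parce", "lorsque", "puisque")
  function(tok) {
    n <- nrow(tok)
    tok$lemma <- character(n); tok$pos <- character(n)
    tok$mood <- character(n); tok$tense <- character(n)
    tok$person <- rep(NA_integer_, n); tok$number <- character(n)
    tok$verbform <- character(n)
    if (n == 0L) {
      tok$is_word <- logical(0)
      return(tok)
    }
    low <- tolower(tok$surface)
    low <- gsub("’", "'", low, fixed = TRUE)
    s <- sub("(…|\\.\\.\\.)$", "", low)              # strip trailing ellipsis
    apo <- endsWith(s, "'")
    if (any(apo)) {
      rep_apo <- fr_apostrophe_lemma[s[apo]]
      rep_apo[is.na(rep_apo)] <- sub("'$", "", s[apo][is.na(rep_apo)])
      s[apo] <- rep_apo
    }
    punct <- grepl("^[\\p{P}\\p{S}]$", tok$surface, perl = TRUE)
    num <- grepl("^[0-9]", s)

    # classify by ascending priority: later assignments win
    pos <- rep("NOUN", n)
    lemma <- s
    # noun lemma: naive plural stripping
    strip <- nchar(s) > 3 & endsWith(s, "s") & !endsWith(s, "ss")
    lemma[strip] <- substr(s[strip], 1, nchar(s[strip]) - 1)

    cap <- grepl("^\\p{Lu}", tok$surface, perl = TRUE)
    if (any(cap)) {
      init <- vapply(which(cap), function(i) is_sentence_initial(tok, i), TRUE)
      propn <- which(cap)[!init]
      pos[propn] <- "PROPN"; lemma[propn] <- tok$surface[propn]
    }
    adv <- s %in% fr_adv | (endsWith(s, "ment") & nchar(s) > 5)
    pos[adv] <- "ADV"; lemma[adv] <- s[adv]

    vm <- match(s, vt$surface)
    vhit <- !is.na(vm)
    if (any(vhit)) {
      vrows <- vm[vhit]
      lemma[vhit] <- vt$lemma[vrows]
      tok$mood[vhit] <- vt$mood[vrows]
      tok$tense[vhit] <- vt$tense[vrows]
      tok$verbform[vhit] <- vt$verbform[vrows]
      pos[vhit] <- ifelse(vt$lemma[vrows] %in% c("être", "avoir"),
                          "AUX", "VERB")
    }
    intj <- s %in% fr_intj
    pos[intj] <- "INTJ"; lemma[intj] <- s[intj]
    conj <- s %in% fr_conj
    pos[conj] <- ifelse(s[conj] %in% sconj, "SCONJ", "CCONJ")
    lemma[conj] <- s[conj]
    adp <- s %in% fr_adp
    pos[adp] <- "ADP"; lemma[adp] <- s[adp]
    det <- s %in% fr_det
    pos[det] <- "DET"; lemma[det] <- s[det]
    pm <- match(s, pron_names)
    phit <- !is.na(pm)
    pos[phit] <- "PRON"; lemma[phit] <- s[phit]
    tok$person[phit] <- pron_person[pm[phit]]
    tok$number[phit] <- pron_number[pm[phit]]

    # closed classes and pronouns beat verb morphology
    clear <- pos != "VERB" & pos != "AUX"
    tok$mood[clear] <- ""; tok$tense[clear] <- ""; tok$verbform[clear] <- ""

    pos[num] <- "NUM"; lemma[num] <- s[num]
    pos[tok$truncated] <- "X"; lemma[tok$truncated] <- s[tok$truncated]
    tok$mood[tok$truncated] <- ""; tok$tense[tok$truncated] <- ""
    tok$verbform[tok$truncated] <- ""
    pos[punct] <- "PUNCT"; lemma[punct] <- tok$surface[punct]
    pos[tok$is_ellipsis] <- "PUNCT"; lemma[tok$is_ellipsis] <- "…"
    tok$pos <- pos; tok$lemma <- lemma

    # finite-or-participle ambiguity ("dit", "fait"): participle after aux
    amb <- which(vhit & vt$ambiguous[vm] & pos %in% c("VERB", "AUX"))
    for (i in amb) {
      j <- prev_core_token(tok, i)
      if (!is.na(j) && tok$pos[j] == "AUX") {
        tok$mood[i] <- "participle"; tok$tense[i] <- "past"
        tok$verbform[i] <- "participle"
      }
    }
    tok$is_word <- !(tok$pos == "PUNCT") & !tok$is_ellipsis & !tok$truncated
    tok
  }
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

# previous token skipping adverbs/punctuation/ellipses (clitic window)
prev_core_token <- function(tok, i) {
  j <- i - 1L
  while (j >= 1L && (tok$is_ellipsis[j] ||
                     is_punct_surface(tok$surface[j]) ||
                     tolower(tok$surface[j]) %in% c(fr_adv, "y"))) j <- j - 1L
  if (j >= 1L) j else NA_integer_
}

is_sentence_initial <- function(tok, i) {
  j <- i - 1L
  while (j >= 1L && (tok$is_ellipsis[j] || is_punct_surface(tok$surface[j]))) {
    if (tok$surface[j] %in% c(".", "!", "?")) return(TRUE)
    j <- j - 1L
  }
  j < 1L
}

#' Tokenize every transcript of a corpus
#'
#' @param corpus List of transcripts from [read_corpus()] or
#'   [generate_corpus()].
#' @param annotator Annotation backend, see [tokenize()].
#' @return List of `lf_doc`, named by `doc_id`, class `lf_docs`.
#' @export
tokenize_corpus <- function(corpus, annotator = french_annotator()) {
  docs <- lapply(corpus, tokenize, annotator = annotator)
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  class(docs) <- "lf_docs"
  docs
}

#' @export
print.lf_doc <- function(x, ...) {
  cat("<lf_doc> ", x$doc_id, ": ", nrow(x$tokens), " tokens, ",
      nrow(x$sentences), " sentences\n", sep = "")
  invisible(x)
}
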