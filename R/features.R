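# Per-document language-feature families.  All count-type features are
# normalized by the length of the testimony (word-token count); features with
# an undefined denominator on a degenerate document return 0 (never NaN) and
# the document is flagged in the extractor's "degenerate" attribute.

word_tokens <- function(doc) doc$tokens[doc$tokens$is_word, , drop = FALSE]

#' Global textual features
#'
#' `words_number` counts word tokens — punctuation, standalone ellipses and
#' truncated word fragments are excluded; `sentence_number` counts sentence
#' ranges.
#'
#' @param doc `lf_doc` from [tokenize()].
#' @return Named numeric vector.
#' @export
textual_features <- function(doc) {
  c(words_number = sum(doc$tokens$is_word),
    sentence_number = nrow(doc$sentences))
}

# flatten a list of lf_lexicon into one lookup data.frame
combine_lexicons <- function(lexicons) {
  if (inherits(lexicons, "lf_lexicon")) lexicons <- list(lexicons)
  rows <- lapply(lexicons, function(lx) {
    df <- as.data.frame(lx)
    df$match_policy <- attr(lx, "match_policy") %||% "lemma"
    df
  })
  do.call(rbind, rows)
}

# matched weight per token for one category; returns numeric vector over
# word tokens (0 where unmatched).  Lemma policy falls back to the surface
# form when the lemma misses, so that nominal uses of forms the annotator
# reads as verbal ("mort" -> mourir) still hit noun-based lexicon entries.
match_category <- function(wt, lex, category) {
  sub <- lex[lex$category == category, , drop = FALSE]
  if (nrow(sub) == 0L) return(numeric(nrow(wt)))
  out <- numeric(nrow(wt))
  for (pol in unique(sub$match_policy)) {
    sp <- sub[sub$match_policy == pol, , drop = FALSE]
    if (pol == "surface") {
      idx <- match(tolower(wt$surface), sp$term)
    } else {
      idx <- match(tolower(wt$lemma), sp$term)
      miss <- is.na(idx)
      idx[miss] <- match(tolower(wt$surface[miss]), sp$term)
    }
    hit <- !is.na(idx)
    out[hit] <- out[hit] + sp$weight[idx[hit]]
  }
  out
}

#' Sentiment and emotion features
#'
#' Category rates from stand-in lexicons (LIWC-, EMA-, FEEL- and
#' EMPATH-style): rate = sum of matched-token weights / words_number.  The
#' valence-weighted happiness score (labMT-style) is the weighted mean over
#' matched tokens; with no overlap it falls back to the sentinel 0.  Polarity
#' (in [-1, 1]) and subjectivity (in [0, 1]) come from a pluggable scorer;
#' the default derives them from the positive/negative valence categories.
#'
#' @param doc `lf_doc`.
#' @param lexicons List of `lf_lexicon` covering the sentiment categories.
#' @param scorer Optional function(doc, lexicon_df) returning
#'   c(polarity, subjectivity).
#' @return Named numeric vector over the 27 sentiment/emotion features.
#' @export
emotion_features <- function(doc, lexicons, scorer = NULL) {
  wt <- word_tokens(doc)
  nw <- nrow(wt)
  lex <- combine_lexicons(lexicons)
  cats <- lf_lexicon_categories()
  reg <- lf_registry()
  rate_feats <- names(cats)[cats %in% reg$name[reg$normalization == "per_token" &
                                                 reg$group == "sentiment_emotion"]]
  out <- stats::setNames(numeric(length(rate_feats)), rate_feats)

  # one-pass tabulation: count every document key once, then aggregate
  # matched weights per category
  stats_by_cat <- if (nw > 0) {
    keys_l <- tolower(wt$lemma); keys_s <- tolower(wt$surface)
    agg <- list()
    for (pol in unique(lex$match_policy)) {
      sub <- lex[lex$match_policy == pol, , drop = FALSE]
      key <- if (pol == "surface") keys_s else
        ifelse(keys_l %in% sub$term, keys_l, keys_s)   # lemma-miss fallback
      tab <- table(key)
      cnt <- as.numeric(tab[match(sub$term, names(tab))])
      cnt[is.na(cnt)] <- 0
      agg[[pol]] <- data.frame(category = sub$category,
                               hits = cnt, wsum = cnt * sub$weight)
    }
    a <- do.call(rbind, agg)
    list(hits = tapply(a$hits, a$category, sum),
         wsum = tapply(a$wsum, a$category, sum))
  } else NULL
  get_stat <- function(which, cat) {
    if (is.null(stats_by_cat)) return(0)
    v <- stats_by_cat[[which]][cat]
    if (is.na(v)) 0 else as.numeric(v)
  }
  for (f in rate_feats) out[f] <- get_stat("wsum", f) / max(1, nw) * (nw > 0)
  hits_h <- get_stat("hits", "labmt_happiness")
  out["labmt_happiness"] <- if (hits_h > 0)
    get_stat("wsum", "labmt_happiness") / hits_h else 0
  ps <- if (is.null(scorer)) {
    pos <- get_stat("hits", "liwc_positive_emotion") +
      get_stat("hits", "feel_positive") + get_stat("hits", "gobin_positive")
    neg <- get_stat("hits", "liwc_negative_emotion") +
      get_stat("hits", "gobin_negative")
    c(if (pos + neg > 0) (pos - neg) / (pos + neg) else 0,
      if (nw > 0) min(1, (pos + neg) / nw) else 0)
  } else scorer(doc, lex)
  out["textblob_polarity"] <- ps[1]
  out["textblob_subjectivity"] <- ps[2]
  out
}

#' Default lexical-field tagger
#'
#' The tagger contract behind the lexical-field features: categories DEATH,
#' BODY, PHYSICAL_SENSATIONS and PERCEPTION (covering perception verbs and
#' perception words), tagged by lexicon lookup on the lemma.  A
#' context-sensitive (e.g. learned) tagger with the same contract — a
#' `categories` field and a `tag(doc)` function returning a data.frame with
#' columns `index` (token index) and `category` — can replace it, e.g. to
#' resolve idiomatic uses that defeat naive lexicon matches.
#'
#' @param lexicons List of `lf_lexicon`; entries whose category is one of
#'   the upper-case tagger categories are used.
#' @return Object of class `lf_tagger`.
#' @export
lexicon_tagger <- function(lexicons) {
  lex <- combine_lexicons(lexicons)
  lex <- lex[lex$category %in% c("DEATH", "BODY", "PHYSICAL_SENSATIONS",
                                 "PERCEPTION", "PERCEPTION_VERB",
                                 "PERCEPTION_WORD"), , drop = FALSE]
  lex$category[lex$category %in% c("PERCEPTION_VERB", "PERCEPTION_WORD")] <-
    "PERCEPTION"
  tg <- list(
    categories = unique(lex$category),
    tag = function(doc) {
      tok <- doc$tokens
      keys <- tolower(tok$lemma)
      surf <- tolower(tok$surface)
      hits <- lapply(unique(lex$category), function(cat) {
        terms <- lex$term[lex$category == cat]
        idx <- which((keys %in% terms | surf %in% terms) & tok$is_word)
        if (length(idx)) data.frame(index = idx, category = cat) else NULL
      })
      out <- do.call(rbind, hits)
      if (is.null(out)) data.frame(index = integer(), category = character())
      else out
    })
  class(tg) <- "lf_tagger"
  tg
}

#' Lexical-field rates
#'
#' Proportion of word tokens tagged in each lexical field (death, body,
#' physical sensations, sensory perception), normalized by `words_number`.
#'
#' @param doc `lf_doc`.
#' @param tagger `lf_tagger` (see [lexicon_tagger()]).
#' @return Named numeric vector over the 4 lexical features.
#' @export
lexical_field_rates <- function(doc, tagger) {
  nw <- sum(doc$tokens$is_word)
  tags <- tagger$tag(doc)
  feats <- lf_tagger_categories()
  out <- stats::setNames(numeric(length(feats)), names(feats))
  if (nw > 0 && nrow(tags) > 0) {
    tb <- table(tags$category)
    for (f in names(feats)) {
      cnt <- tb[feats[f]]
      out[f] <- if (!is.na(cnt)) cnt / nw else 0
    }
  }
  out
}

# classify each finite indicative verb occurrence into a tense, folding
# auxiliary + past-participle compounds into "past"
classify_finite_tenses <- function(tok) {
  fin <- which(tok$verbform == "finite")
  if (!length(fin)) return(data.frame(index = integer(), tense = character()))
  tense <- character(length(fin))
  for (k in seq_along(fin)) {
    i <- fin[k]
    if (tok$mood[i] == "conditional") { tense[k] <- "conditional"; next }
    if (tok$mood[i] != "indicative") { tense[k] <- "other"; next }
    tense[k] <- switch(tok$tense[i], present = "present",
                       imperfect = "past", future = "future", "other")
    # compound tense: auxiliary + past participle within 3 tokens
    if (tok$pos[i] == "AUX" && tok$tense[i] == "present") {
      j <- i + 1L; span <- 0L
      while (j <= nrow(tok) && span < 3L) {
        if (tok$verbform[j] == "participle" && tok$tense[j] == "past") {
          tense[k] <- "past"; break
        }
        if (!(tok$pos[j] %in% c("ADV", "PRON") || tok$is_ellipsis[j])) break
        j <- j + 1L; span <- span + 1L
      }
    }
  }
  data.frame(index = fin, tense = tense)
}

# contextual value of a present-tense occurrence: generic / historical /
# enunciative, from sentence-level cues
classify_present_values <- function(doc, present_idx, tenses) {
  tok <- doc$tokens
  vapply(present_idx, function(i) {
    sent <- which(tok$sentence == tok$sentence[i])
    lemmas <- tolower(tok$lemma[sent])
    has_on_subject <- any(lemmas == "on")
    if (any(lemmas %in% fr_generic_cues) ||
        (has_on_subject && any(lemmas %in% c("jamais", "toujours"))))
      return("generic")
    if (any(lemmas %in% fr_now_cues)) return("enunciative")
    other <- tenses[tenses$index %in% sent & tenses$index != i, ]
    if (any(lemmas %in% fr_past_cues) || any(other$tense == "past"))
      return("historical")
    "enunciative"
  }, "")
}

# contextual value of an "on" occurrence: we / someone / generic
classify_on_values <- function(doc, on_idx) {
  tok <- doc$tokens
  n <- nrow(tok)
  vapply(on_idx, function(i) {
    # object clitic referring to the speaker right after "on": someone
    ahead <- seq(i + 1L, min(n, i + 3L))
    ahead <- ahead[ahead > i & ahead <= n]
    cl <- tolower(tok$lemma[ahead])
    if (length(cl) && any(cl %in% c("me", "nous", "te", "vous") &
                          tok$pos[ahead] == "PRON"))
      return("someone")
    sent <- which(tok$sentence == tok$sentence[i])
    lemmas <- tolower(tok$lemma[sent])
    verb_present <- any(tok$verbform[sent] == "finite" &
                          tok$tense[sent] == "present" &
                          tok$mood[sent] == "indicative")
    if (any(lemmas %in% fr_generic_cues) && verb_present) return("generic")
    "we"
  }, "")
}

#' Morphosyntactic features
#'
#' Pronoun-person proportions (1st singular/plural, 2nd, 3rd), overall
#' pronoun and proper-noun proportions (per word token); indicative
#' present/past/future and conditional proportions among finite verbs, with
#' auxiliary + past-participle compounds folded into the past; past
#' participle and auxiliary proportions (per word token); the contextual
#' values of the present tense (generic / historical / enunciative,
#' normalized by present-tense occurrences) and of the pronoun "on"
#' (we / someone / generic, normalized by "on" occurrences).  The contextual
#' disambiguations default to deterministic cue-based rules; a tagger plugin
#' exposing categories GENERIC_PRESENT / HISTORICAL_PRESENT /
#' ENUNCIATIVE_PRESENT / ON_we / ON_someone / ON_generic overrides them.
#'
#' @param doc `lf_doc`.
#' @param tagger Optional `lf_tagger` overriding the contextual rules.
#' @return Named numeric vector over the 18 morphosyntactic features.
#' @export
morphosyntactic_features <- function(doc, tagger = NULL) {
  tok <- doc$tokens
  nw <- sum(tok$is_word)
  den <- function(x, d) if (d > 0) x / d else 0
  pron <- tok$pos == "PRON"
  out <- c(
    first_personal_pronoun_sing = den(sum(pron & tok$person %in% 1 &
                                            tok$number == "sing"), nw),
    first_personal_pronoun_plur = den(sum(pron & tok$person %in% 1 &
                                            tok$number == "plur"), nw),
    second_personal_pronoun = den(sum(pron & tok$person %in% 2), nw),
    third_personal_pronoun = den(sum(pron & tok$person %in% 3), nw),
    pron = den(sum(pron), nw),
    propn = den(sum(tok$pos == "PROPN"), nw))

  tenses <- classify_finite_tenses(tok)
  nv <- nrow(tenses)
  out["verb_indicatif_present"] <- den(sum(tenses$tense == "present"), nv)
  out["verb_indicatif_past"] <- den(sum(tenses$tense == "past"), nv)
  out["verb_indicatif_future"] <- den(sum(tenses$tense == "future"), nv)
  out["verb_conditional"] <- den(sum(tenses$tense == "conditional"), nv)
  out["past_participle"] <- den(sum(tok$verbform == "participle" &
                                      tok$tense == "past"), nw)
  out["auxiliaries"] <- den(sum(tok$pos == "AUX"), nw)

  tags <- if (!is.null(tagger)) tagger$tag(doc) else
    data.frame(index = integer(), category = character())
  ctx_cats <- c("GENERIC_PRESENT", "HISTORICAL_PRESENT", "ENUNCIATIVE_PRESENT",
                "ON_we", "ON_someone", "ON_generic")
  use_plugin <- any(tags$category %in% ctx_cats)

  present_idx <- tenses$index[tenses$tense == "present"]
  if (use_plugin) {
    np <- length(present_idx)
    out["model_generic_present"] <- den(sum(tags$category == "GENERIC_PRESENT"), np)
    out["model_historical_present"] <- den(sum(tags$category == "HISTORICAL_PRESENT"), np)
    out["model_enunciative_present"] <- den(sum(tags$category == "ENUNCIATIVE_PRESENT"), np)
  } else {
    pv <- classify_present_values(doc, present_idx, tenses)
    np <- length(pv)
    out["model_generic_present"] <- den(sum(pv == "generic"), np)
    out["model_historical_present"] <- den(sum(pv == "historical"), np)
    out["model_enunciative_present"] <- den(sum(pv == "enunciative"), np)
  }

  on_idx <- which(tolower(tok$lemma) == "on" & pron)
  no <- length(on_idx)
  if (use_plugin) {
    out["model_on_we"] <- den(sum(tags$category == "ON_we"), no)
    out["model_on_someone"] <- den(sum(tags$category == "ON_someone"), no)
    out["model_on_generic"] <- den(sum(tags$category == "ON_generic"), no)
  } else {
    ov <- classify_on_values(doc, on_idx)
    out["model_on_we"] <- den(sum(ov == "we"), no)
    out["model_on_someone"] <- den(sum(ov == "someone"), no)
    out["model_on_generic"] <- den(sum(ov == "generic"), no)
  }
  out
}

#' French periphrastic passive features
#'
#' Rule-based detection of the periphrastic passive: a form of the auxiliary
#' "être" (finite, infinitive, or the participle "été" inside a compound)
#' followed — across at most 3 intervening adverbs, clitics or negation
#' particles — by a past participle of a transitive-capable verb.
#' "être + participle" of intransitive motion/state verbs ("elle est
#' partie") is a compound tense, not a passive, and is excluded.  A "par"
#' (or "de") agent phrase within 4 tokens of the participle marks the
#' passive as agented.  `passive_count_norm` is the count divided by
#' `words_number`.
#'
#' @param doc `lf_doc`.
#' @return Named numeric vector: passive_count, passive_count_norm,
#'   passive_agented_count, passive_agentless_count.
#' @export
passive_voice_features <- function(doc) {
  tok <- doc$tokens
  n <- nrow(tok)
  nw <- sum(tok$is_word)
  count <- 0L; agented <- 0L
  i <- 1L
  while (i <= n) {
    is_etre <- tok$lemma[i] == "être" &&
      (tok$verbform[i] %in% c("finite", "infinitive") ||
         (tok$verbform[i] == "participle" && tok$tense[i] == "past"))
    if (is_etre) {
      j <- i + 1L; span <- 0L
      while (j <= n && span <= 3L) {
        if (tok$verbform[j] == "participle" && tok$tense[j] == "past" &&
            !(tok$lemma[j] %in% c(fr_motion_state_verbs, "être", "avoir"))) {
          count <- count + 1L
          # agent phrase: par/de + nominal within 4 tokens
          k <- j + 1L; ag <- FALSE
          while (k <= min(n, j + 4L)) {
            if (tok$lemma[k] %in% c("par", "de") && tok$pos[k] == "ADP") {
              l <- k + 1L
              while (l <= min(n, k + 2L)) {
                if (tok$pos[l] %in% c("NOUN", "PROPN", "PRON", "NUM")) {
                  ag <- TRUE; break
                }
                if (!tok$pos[l] %in% c("DET", "ADV")) break
                l <- l + 1L
              }
            }
            if (ag) break
            k <- k + 1L
          }
          if (ag) agented <- agented + 1L
          i <- j
          break
        }
        ok_intervener <- tok$pos[j] %in% c("ADV", "PRON") || tok$is_ellipsis[j]
        if (!ok_intervener) break
        j <- j + 1L; span <- span + 1L
      }
    }
    i <- i + 1L
  }
  c(passive_count = count,
    passive_count_norm = if (nw > 0) count / nw else 0,
    passive_agented_count = agented,
    passive_agentless_count = count - agented)
}

#' Speech-disfluency features
#'
#' Nine rates, each normalized by `words_number`: fillers (configurable
#' list, default euh/ah/bah/ben/hein/hum); hesitation vowels proper
#' (euh/hum/hm/mmh); repeated word fragments (a truncated fragment repeating
#' the previous fragment or word); immediate word repetitions (identical
#' consecutive word tokens, ignoring intervening breaks); false starts
#' (truncated fragments, "par… partir"); silent breaks "…" directly attached
#' after a word vs free-standing between words (a truncation's mark counts
#' as an attached break); generic-connector matches; and the composite
#' `score_disfluencies` = sum of the six disfluency component rates
#' (fillers, fragment repetitions, word repetitions, false starts, both
#' silent-break types).
#'
#' @param doc `lf_doc`.
#' @param fillers Character vector of filler forms.
#' @param hesitations Character vector of hesitation forms.
#' @param connectors Character vector of generic connector forms.
#' @return Named numeric vector over the 9 disfluency features.
#' @export
disfluency_features <- function(doc, fillers = fr_fillers_default,
                                hesitations = fr_hesitations_default,
                                connectors = fr_connectors_default) {
  tok <- doc$tokens
  nw <- sum(tok$is_word)
  den <- function(x) if (nw > 0) x / nw else 0
  low <- tolower(tok$surface)

  n_filler <- sum(low %in% fillers & tok$is_word)
  n_hesit <- sum(low %in% hesitations & tok$is_word)
  n_trunc <- sum(tok$truncated)

  # silent breaks: standalone ellipses split by attachment; truncations
  # carry an attached break by construction
  ell <- which(tok$is_ellipsis)
  after <- 0L; between <- 0L
  for (i in ell) {
    attached <- i > 1L && tok$end[i - 1L] == tok$start[i] &&
      tok$is_word[i - 1L]
    if (attached) after <- after + 1L else between <- between + 1L
  }
  after <- after + n_trunc

  # immediate word repetition, skipping breaks/punctuation
  wi <- which(tok$is_word)
  wlow <- low[wi]
  n_rep <- if (length(wlow) > 1L) sum(wlow[-1L] == wlow[-length(wlow)]) else 0L

  # fragment repetition: a truncated fragment whose base repeats the
  # previous fragment base or previous word
  n_syl <- 0L
  tr <- which(tok$truncated)
  base <- sub("(…|\\.\\.\\.)$", "", low)
  for (i in tr) {
    j <- i - 1L
    while (j >= 1L && (tok$is_ellipsis[j] || is_punct_surface(tok$surface[j])))
      j <- j - 1L
    if (j >= 1L && base[j] == base[i]) n_syl <- n_syl + 1L
  }

  n_conn <- sum(low %in% connectors & tok$is_word)

  rates <- c(filler_rate = den(n_filler),
             hesitation_rate = den(n_hesit),
             syllable_repetition_rate = den(n_syl),
             word_repetition_rate = den(n_rep),
             false_start_rate = den(n_trunc),
             silent_break_after_word_rate = den(after),
             silent_break_between_words_rate = den(between),
             score_generical_connector_matches = den(n_conn))
  comp <- sum(rates[c("filler_rate", "syllable_repetition_rate",
                      "word_repetition_rate", "false_start_rate",
                      "silent_break_after_word_rate",
                      "silent_break_between_words_rate")])
  c(rates, score_disfluencies = comp)
}

#' Readability / lexical-diversity features
#'
#' Type/token ratio over word tokens, noun-type / noun-token and
#' adverb-type / adverb-token ratios, mean words per sentence, and lexical
#' density (content-word proportion: nouns, proper nouns, verbs,
#' auxiliaries excluded, adverbs included).
#'
#' @param doc `lf_doc`.
#' @return Named numeric vector over the 5 readability features.
#' @export
readability_features <- function(doc) {
  tok <- doc$tokens
  wt <- word_tokens(doc)
  nw <- nrow(wt)
  den <- function(x, d) if (d > 0) x / d else 0
  types <- length(unique(tolower(wt$surface)))
  nn <- sum(wt$pos == "NOUN")
  nadv <- sum(wt$pos == "ADV")
  content <- sum(wt$pos %in% c("NOUN", "PROPN", "VERB", "ADV", "ADJ"))
  c(token_ratio_score = den(types, nw),
    noun_ratio_score = den(length(unique(tolower(wt$lemma[wt$pos == "NOUN"]))), nn),
    adverb_ratio_score = den(length(unique(tolower(wt$lemma[wt$pos == "ADV"]))), nadv),
    words_per_sentence = den(nw, nrow(doc$sentences)),
    lexical_density_score = den(content, nw))
}

#' Extract the full language-feature table for a corpus
#'
#' Runs all seven feature families over every tokenized document and returns
#' one row per document with exactly the registered features in registry
#' order.  Lexicon coverage is checked up front: a registered lexicon-based
#' feature with no lexicon category available raises an error naming the
#' feature.
#'
#' @param docs `lf_docs` from [tokenize_corpus()] (or a list of `lf_doc`).
#' @param lexicons List of `lf_lexicon` resources.
#' @param tagger Lexical-field tagger; defaults to
#'   [lexicon_tagger()]`(lexicons)`.
#' @param registry Feature registry, see [lf_registry()].
#' @param scorer Optional polarity scorer, see [emotion_features()].
#' @param graph_unit,graph_scope Speech-graph configuration, see
#'   [build_speech_graph()].
#' @param fillers,hesitations,connectors Disfluency word lists, see
#'   [disfluency_features()].
#' @return data.frame of class `lf_features` (`doc_id` + one numeric column
#'   per feature), with attributes `registry` and `degenerate` (doc_ids
#'   where a zero-denominator sentinel was applied).
#' @export
extract_features <- function(docs, lexicons, tagger = lexicon_tagger(lexicons),
                             registry = lf_registry(), scorer = NULL,
                             graph_unit = "lemma", graph_scope = "document",
                             fillers = fr_fillers_default,
                             hesitations = fr_hesitations_default,
                             connectors = fr_connectors_default) {
  lex <- combine_lexicons(lexicons)
  need <- names(lf_lexicon_categories())
  have <- unique(lex$category)
  missing <- setdiff(setdiff(need, c("textblob_polarity", "textblob_subjectivity")),
                     have)
  if (length(missing))
    stop("no lexicon resource covers feature(s): ",
         paste(missing, collapse = ", "))

  rows <- lapply(docs, function(doc) {
    g <- build_speech_graph(doc, unit = graph_unit, scope = graph_scope)
    c(textual_features(doc),
      emotion_features(doc, lexicons, scorer = scorer),
      lexical_field_rates(doc, tagger),
      morphosyntactic_features(doc),
      passive_voice_features(doc),
      disfluency_features(doc, fillers, hesitations, connectors),
      readability_features(doc),
      graph_features(g))
  })
  mat <- do.call(rbind, rows)
  missing_feats <- setdiff(registry$name, colnames(mat))
  if (length(missing_feats))
    stop("extractor produced no value for feature(s): ",
         paste(missing_feats, collapse = ", "))
  mat <- mat[, registry$name, drop = FALSE]
  stopifnot(!anyNA(mat))
  out <- data.frame(doc_id = vapply(docs, `[[`, "", "doc_id"), mat,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  degenerate <- out$doc_id[out$words_number == 0 | out$sentence_number == 0]
  class(out) <- c("lf_features", "data.frame")
  attr(out, "registry") <- registry
  attr(out, "degenerate") <- degenerate
  out
}

#' @export
print.lf_features <- function(x, ...) {
  cat("<lf_features> ", nrow(x), " documents x ", ncol(x) - 1L,
      " language features\n", sep = "")
  invisible(x)
}
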