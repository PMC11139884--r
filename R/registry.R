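#' The default language-feature registry
#'
#' The registry is the ordered list of per-document language features the
#' extractor computes, organized in seven families plus two global textual
#' measures.  Family sizes are fixed: textual = 2, sentiment/emotion = 27,
#' lexical fields = 4, morphosyntactic = 18, passive voice = 4, speech
#' disfluencies = 9, readability = 5, speech graph = 12 (81 features in all).
#' A subset of 57 features is marked `retained_for_ml`: the sentiment family
#' is cut down to the six valence-based scores (polarity, subjectivity,
#' feel_positive, labmt_happiness, liwc_positive_emotion,
#' liwc_negative_emotion) and the passive family to `passive_count_norm`
#' alone, because the dropped members are nearly collinear with the kept
#' ones.
#'
#' @return A data.frame of class `lf_registry` with columns `name`, `group`,
#'   `normalization` (one of none, per_token, per_sentence, per_verb,
#'   per_pronoun, per_on, per_present, per_match) and `retained_for_ml`.
#' @examples
#' reg <- lf_registry()
#' table(reg$group)
#' sum(reg$retained_for_ml)
#' @export
lf_registry <- function() {
  if (!is.null(lf_registry_env$reg)) return(lf_registry_env$reg)
  def <- function(name, group, normalization, retained = TRUE) {
    data.frame(name = name, group = group, normalization = normalization,
               retained_for_ml = retained, stringsAsFactors = FALSE)
  }
  rows <- list(
    ## textual (2)
    def("words_number", "textual", "none"),
    def("sentence_number", "textual", "none"),

    ## sentiment / emotion (27)
    ## 4 LIWC-style category rates
    def("liwc_death", "sentiment_emotion", "per_token", FALSE),
    def("liwc_body", "sentiment_emotion", "per_token", FALSE),
    def("liwc_positive_emotion", "sentiment_emotion", "per_token", TRUE),
    def("liwc_negative_emotion", "sentiment_emotion", "per_token", TRUE),
    ## 10 EMA-style emotion-category rates
    def("gobin_positive", "sentiment_emotion", "per_token", FALSE),
    def("gobin_negative", "sentiment_emotion", "per_token", FALSE),
    def("gobin_joy", "sentiment_emotion", "per_token", FALSE),
    def("gobin_sadness", "sentiment_emotion", "per_token", FALSE),
    def("gobin_anger", "sentiment_emotion", "per_token", FALSE),
    def("gobin_fear", "sentiment_emotion", "per_token", FALSE),
    def("gobin_disgust", "sentiment_emotion", "per_token", FALSE),
    def("gobin_surprise", "sentiment_emotion", "per_token", FALSE),
    def("gobin_love", "sentiment_emotion", "per_token", FALSE),
    def("gobin_shame", "sentiment_emotion", "per_token", FALSE),
    ## 6 FEEL-style rates (valence + 5 emotions)
    def("feel_positive", "sentiment_emotion", "per_token", TRUE),
    def("feel_joy", "sentiment_emotion", "per_token", FALSE),
    def("feel_fear", "sentiment_emotion", "per_token", FALSE),
    def("feel_sadness", "sentiment_emotion", "per_token", FALSE),
    def("feel_anger", "sentiment_emotion", "per_token", FALSE),
    def("feel_surprise", "sentiment_emotion", "per_token", FALSE),
    ## valence-weighted happiness score
    def("labmt_happiness", "sentiment_emotion", "per_match", TRUE),
    ## pluggable polarity/subjectivity scorer
    def("textblob_polarity", "sentiment_emotion", "none", TRUE),
    def("textblob_subjectivity", "sentiment_emotion", "none", TRUE),
    ## 4 EMPATH-style rates
    def("empath_angry", "sentiment_emotion", "per_token", FALSE),
    def("empath_fear", "sentiment_emotion", "per_token", FALSE),
    def("empath_sadness", "sentiment_emotion", "per_token", FALSE),
    def("empath_negative_emotion", "sentiment_emotion", "per_token", FALSE),

    ## lexical fields (4)
    def("model_death", "lexical", "per_token"),
    def("model_body", "lexical", "per_token"),
    def("model_physical_sensations", "lexical", "per_token"),
    def("model_perception", "lexical", "per_token"),

    ## morphosyntactic (18)
    def("first_personal_pronoun_sing", "morphosyntactic", "per_token"),
    def("first_personal_pronoun_plur", "morphosyntactic", "per_token"),
    def("second_personal_pronoun", "morphosyntactic", "per_token"),
    def("third_personal_pronoun", "morphosyntactic", "per_token"),
    def("pron", "morphosyntactic", "per_token"),
    def("propn", "morphosyntactic", "per_token"),
    def("verb_indicatif_present", "morphosyntactic", "per_verb"),
    def("verb_indicatif_past", "morphosyntactic", "per_verb"),
    def("verb_indicatif_future", "morphosyntactic", "per_verb"),
    def("verb_conditional", "morphosyntactic", "per_verb"),
    def("past_participle", "morphosyntactic", "per_token"),
    def("auxiliaries", "morphosyntactic", "per_token"),
    def("model_generic_present", "morphosyntactic", "per_present"),
    def("model_historical_present", "morphosyntactic", "per_present"),
    def("model_enunciative_present", "morphosyntactic", "per_present"),
    def("model_on_we", "morphosyntactic", "per_on"),
    def("model_on_someone", "morphosyntactic", "per_on"),
    def("model_on_generic", "morphosyntactic", "per_on"),

    ## syntactic: periphrastic passive (4)
    def("passive_count", "syntactic_passive", "none", FALSE),
    def("passive_count_norm", "syntactic_passive", "per_token", TRUE),
    def("passive_agented_count", "syntactic_passive", "none", FALSE),
    def("passive_agentless_count", "syntactic_passive", "none", FALSE),

    ## speech disfluencies (9)
    def("filler_rate", "disfluency", "per_token"),
    def("hesitation_rate", "disfluency", "per_token"),
    def("syllable_repetition_rate", "disfluency", "per_token"),
    def("word_repetition_rate", "disfluency", "per_token"),
    def("false_start_rate", "disfluency", "per_token"),
    def("silent_break_after_word_rate", "disfluency", "per_token"),
    def("silent_break_between_words_rate", "disfluency", "per_token"),
    def("score_generical_connector_matches", "disfluency", "per_token"),
    def("score_disfluencies", "disfluency", "per_token"),

    ## readability (5)
    def("token_ratio_score", "readability", "none"),
    def("noun_ratio_score", "readability", "none"),
    def("adverb_ratio_score", "readability", "none"),
    def("words_per_sentence", "readability", "per_sentence"),
    def("lexical_density_score", "readability", "per_token"),

    ## speech graph (12)
    def("graph_l1", "graph", "none"),
    def("graph_l2", "graph", "none"),
    def("graph_l3", "graph", "none"),
    def("graph_pe", "graph", "none"),
    def("graph_degree_average", "graph", "none"),
    def("graph_degree_std", "graph", "none"),
    def("graph_average_clustering", "graph", "none"),
    def("graph_average_shortest_path", "graph", "none"),
    def("graph_transitivity", "graph", "none"),
    def("graph_n_nodes", "graph", "none"),
    def("graph_n_edges", "graph", "none"),
    def("graph_lcc_size", "graph", "none")
  )
  reg <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(reg$name))
  class(reg) <- c("lf_registry", "data.frame")
  lf_registry_env$reg <- reg
  reg
}

lf_registry_env <- new.env(parent = emptyenv())

#' Emotion/lexical category names required from lexicon resources
#'
#' Maps registry feature names to the lexicon category each rate feature is
#' computed from.  Used by the extractor to check lexicon coverage and by
#' [generate_lexicons()] to emit stand-in resources.
#'
#' @return Named character vector: names are registry feature names, values
#'   are lexicon categories.
#' @keywords internal
lf_lexicon_categories <- function() {
  reg <- lf_registry()
  sent <- reg$name[reg$group == "sentiment_emotion" &
                     reg$normalization %in% c("per_token", "per_match")]
  out <- sent
  names(out) <- sent
  out
}

#' Tagger categories for the lexical-field features
#' @keywords internal
lf_tagger_categories <- function() {
  c(model_death = "DEATH",
    model_body = "BODY",
    model_physical_sensations = "PHYSICAL_SENSATIONS",
    model_perception = "PERCEPTION")
}

#' Reduce a feature table to the subset retained for machine learning
#'
#' Drops the sentiment/emotion features that are not valence-based (21 of 27)
#' and the passive-voice counts other than `passive_count_norm` (3 of 4),
#' leaving 57 of the 81 registered features.  Column order is preserved;
#' unknown columns pass through with a warning.  The operation is idempotent.
#'
#' @param table A feature table as returned by [extract_features()] or
#'   [read_feature_table()]: a data.frame with a `doc_id` column and one
#'   column per feature.
#' @param registry Feature registry; defaults to [lf_registry()].
#' @return The reduced feature table (class preserved).
#' @export
reduce_features <- function(table, registry = lf_registry()) {
  stopifnot(is.data.frame(table))
  feat_cols <- setdiff(names(table), "doc_id")
  unknown <- setdiff(feat_cols, registry$name)
  if (length(unknown))
    warning("unknown feature columns passed through: ",
            paste(unknown, collapse = ", "))
  keep_reg <- registry$name[registry$retained_for_ml]
  keep <- feat_cols[feat_cols %in% keep_reg | feat_cols %in% unknown]
  out <- table[, c("doc_id", keep), drop = FALSE]
  attr(out, "registry") <- registry[registry$name %in% keep, , drop = FALSE]
  class(out) <- class(table)
  out
}

#' @export
print.lf_registry <- function(x, ...) {
  cat("<lf_registry> ", nrow(x), " language features, ",
      sum(x$retained_for_ml), " retained for ML\n", sep = "")
  print(table(factor(x$group, levels = unique(x$group))))
  invisible(x)
}
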