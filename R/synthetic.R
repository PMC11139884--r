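# Synthetic trauma-narrative corpus generator.  Documents are token streams
# over a French function-word skeleton with pseudo-word content slots — not
# grammatical prose — with planted, per-class manipulations: elevated
# lexicon-category rates, inserted disfluency marks ("…", fillers,
# truncations), passive-voice templates, n-gram recycling (raising the
# speech-graph repetition measures) and class-exclusive marker tokens for
# the CNN branch.  Every feature family except the learned-tagger categories
# is exercised; ground truth (true classes, planted and realized rates) is
# returned for recovery tests.

syn_make_terms <- function(n) {
  onsets <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v",
              "br", "cr", "dr", "fl", "gr", "pl", "tr", "ch", "cl")
  vowels <- c("a", "e", "i", "o", "u", "ai", "ou", "an", "on", "é", "eu")
  pool <- character(0)
  while (length(pool) < n) {
    k <- sample(2:3, n, replace = TRUE)
    w <- vapply(k, function(ns)
      paste0(paste0(sample(onsets, ns, TRUE), sample(vowels, ns, TRUE)),
             collapse = ""), "")
    pool <- unique(c(pool, w))
  }
  pool[seq_len(n)]
}

syn_reserved_words <- function() {
  unique(c(fr_det, fr_adp, fr_conj, fr_adv, fr_intj, names(fr_pron_person),
           fr_verb_table()$surface))
}

#' Generate stand-in lexicon resources
#'
#' Emits one lexicon per resource family (LIWC-, EMA-, FEEL-, EMPATH-style,
#' the valence-weighted happiness dictionary, and the lexical-field tagger
#' categories DEATH / BODY / PHYSICAL_SENSATIONS / PERCEPTION), each
#' category holding `terms_per_category` pseudo-French terms.  Term pools
#' are mutually disjoint and disjoint from the generator's function-word and
#' verb vocabulary, so category rates are identifiable.  Deterministic in
#' the seed.
#'
#' @param seed Integer seed.
#' @param terms_per_category Terms per category (default 25).
#' @return Named list of `lf_lexicon`.
#' @export
generate_lexicons <- function(seed = 1L, terms_per_category = 25L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  sent_cats <- setdiff(names(lf_lexicon_categories()),
                       c("textblob_polarity", "textblob_subjectivity"))
  tag_cats <- unname(lf_tagger_categories())
  cats <- c(sent_cats, tag_cats)
  reserved <- syn_reserved_words()
  terms <- setdiff(syn_make_terms(length(cats) * terms_per_category + 200L),
                   reserved)[seq_len(length(cats) * terms_per_category)]
  by_cat <- split(terms, rep(cats, each = terms_per_category))
  resource_of <- function(cat) {
    if (startsWith(cat, "liwc_")) "liwc"
    else if (startsWith(cat, "gobin_")) "gobin"
    else if (startsWith(cat, "feel_")) "feel"
    else if (startsWith(cat, "empath_")) "empath"
    else if (cat == "labmt_happiness") "labmt"
    else "model"
  }
  res_names <- vapply(cats, resource_of, "")
  out <- lapply(unique(res_names), function(rn) {
    cc <- cats[res_names == rn]
    df <- do.call(rbind, lapply(cc, function(cat) {
      w <- if (cat == "labmt_happiness")
        round(stats::runif(terms_per_category, 1, 9), 2) else 1
      data.frame(term = by_cat[[cat]], category = cat, weight = w,
                 stringsAsFactors = FALSE)
    }))
    as_lexicon(df, name = paste0("synthetic_", rn))
  })
  names(out) <- unique(res_names)
  out
}

# per-document insertion knobs: mean and between-document sd of each rate
syn_default_knobs <- function() {
  sent_cats <- setdiff(names(lf_lexicon_categories()),
                       c("textblob_polarity", "textblob_subjectivity"))
  knobs <- data.frame(knob = sent_cats, base = 0.008, sd = 0.004,
                      stringsAsFactors = FALSE)
  knobs <- rbind(knobs, data.frame(
    knob = c("model_death", "model_body", "model_physical_sensations",
             "model_perception",
             "filler_rate", "ellipsis_rate", "truncation_rate",
             "word_repetition_rate", "passive_rate", "repetition_rate",
             "marker_rate"),
    base = c(0.008, 0.008, 0.008, 0.008,
             0.020, 0.015, 0.004, 0.004, 0.004, 0.015, 0),
    sd = c(0.004, 0.004, 0.004, 0.004,
           0.008, 0.006, 0.002, 0.002, 0.002, 0.006, 0)))
  knobs
}

#' Synthetic-cohort configuration
#'
#' Defaults reproduce the study conditions: 148 documents, exposure split
#' 110 directly exposed (A1) / 38 witnesses (A2), probable diagnosis split
#' 70 full / 42 partial / 36 no PTSD, log-normal document lengths with mean
#' 5553 and sd 3628 tokens, truncated to [200, 20000].
#'
#' @param n_docs Number of documents.
#' @param exposure_split Named counts for A1/A2.
#' @param diagnosis_split Named counts for full_ptsd/partial_ptsd/no_ptsd.
#' @param length_mean,length_sd Target token-count mean and sd.
#' @param length_range Truncation bounds for document lengths.
#' @param planted_effects List of planted group effects; each element a list
#'   with `knob` (a knob/feature name from the generator's knob table),
#'   `classes` (affected diagnosis classes) and either `d` (shift in units
#'   of the knob's between-document sd) or `delta` (absolute rate shift).
#' @param marker List with `n_tokens`, `rate` and `classes`: class-exclusive
#'   marker tokens inserted at `rate` in the affected classes (CNN ground
#'   truth).
#' @param label_noise Named per-exposure-stratum flip rates, e.g.
#'   `c(A1 = 0, A2 = 0.3)`: the recorded diagnosis of affected documents is
#'   flipped (symptomatic <-> none) while the text keeps the true class.
#' @param seed Integer seed.
#' @return List of class `lf_syn_config`.
#' @export
synthetic_config <- function(n_docs = 148L,
                             exposure_split = c(A1 = 110L, A2 = 38L),
                             diagnosis_split = c(full_ptsd = 70L,
                                                 partial_ptsd = 42L,
                                                 no_ptsd = 36L),
                             length_mean = 5553, length_sd = 3628,
                             length_range = c(200L, 20000L),
                             planted_effects = list(),
                             marker = list(n_tokens = 0L, rate = 0,
                                           classes = c("full_ptsd",
                                                       "partial_ptsd")),
                             label_noise = NULL, seed = 1L) {
  if (sum(exposure_split) != n_docs || sum(diagnosis_split) != n_docs)
    stop("splits must sum to n_docs")
  structure(list(n_docs = as.integer(n_docs),
                 exposure_split = exposure_split,
                 diagnosis_split = diagnosis_split,
                 length_mean = length_mean, length_sd = length_sd,
                 length_range = length_range,
                 planted_effects = planted_effects, marker = marker,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "lf_syn_config")
}

# resolve per-class knob means from config
syn_knob_means <- function(cfg, knobs) {
  classes <- names(cfg$diagnosis_split)
  means <- matrix(rep(knobs$base, length(classes)), ncol = length(classes),
                  dimnames = list(knobs$knob, classes))
  for (pe in cfg$planted_effects) {
    if (!pe$knob %in% knobs$knob)
      stop("unknown generator knob: ", pe$knob)
    shift <- if (!is.null(pe$delta)) pe$delta
    else pe$d * knobs$sd[knobs$knob == pe$knob]
    means[pe$knob, pe$classes] <- means[pe$knob, pe$classes] + shift
  }
  means
}

# one synthetic document as a vector of text chunks; returns realized rates
syn_make_doc <- function(n_tokens, rates, pools, markers) {
  n <- max(20L, n_tokens)
  cls <- sample(c("fun", "noun", "verb", "adv"), n, replace = TRUE,
                prob = c(0.50, 0.28, 0.15, 0.07))
  zipf <- function(pool, k) sample(pool, k, replace = TRUE,
                                   prob = 1 / seq_along(pool)^1.05)
  base <- character(n)
  for (cl in c("fun", "noun", "verb", "adv")) {
    sel <- cls == cl
    if (any(sel)) base[sel] <- zipf(pools[[cl]], sum(sel))
  }
  ins <- vector("list", n)
  add <- function(pos, tokens) ins[[pos]] <<- c(ins[[pos]], tokens)
  counts <- stats::setNames(numeric(length(rates)), names(rates))
  # insertion rates are meant per final word token, but insertions inflate
  # the denominator; compensate by the expected word-mass expansion factor
  word_weight <- c(filler_rate = 1, ellipsis_rate = 0, truncation_rate = 1,
                   word_repetition_rate = 1, passive_rate = 5,
                   repetition_rate = 2, marker_rate = 1)
  wm <- 0
  for (nm in names(rates)) {
    w <- if (nm %in% names(word_weight)) word_weight[[nm]] else 1
    wm <- wm + w * rates[[nm]]
  }
  expansion <- 1 / max(0.4, 1 - wm)
  # shrink the base stream so the FINAL word count matches the requested
  # length: insertions multiply the word mass by the expansion factor
  n <- max(20L, as.integer(round(n / expansion)))
  cls <- cls[seq_len(n)]; base <- base[seq_len(n)]
  ins <- vector("list", n)
  draw_pos <- function(rate) {
    k <- stats::rbinom(1, n, max(0, min(rate * expansion, 0.5)))
    if (k > 0) sample(n, k, replace = FALSE) else integer(0)
  }
  # lexicon-category insertions
  for (cat in names(pools$categories)) {
    for (p in draw_pos(rates[[cat]])) {
      add(p, sample(pools$categories[[cat]], 1))
      counts[cat] <- counts[cat] + 1
    }
  }
  # fillers
  for (p in draw_pos(rates[["filler_rate"]])) {
    add(p, sample(fr_fillers_default, 1)); counts["filler_rate"] <- counts["filler_rate"] + 1
  }
  # standalone silent breaks (attached handled at assembly)
  for (p in draw_pos(rates[["ellipsis_rate"]])) {
    add(p, "…"); counts["ellipsis_rate"] <- counts["ellipsis_rate"] + 1
  }
  # truncation / false start: fragment + "…" + resumed word
  for (p in draw_pos(rates[["truncation_rate"]])) {
    w <- sample(pools$noun[nchar(pools$noun) >= 5], 1)
    add(p, c(paste0(substr(w, 1, 3), "…"), w))
    counts["truncation_rate"] <- counts["truncation_rate"] + 1
  }
  # immediate word repetition
  for (p in draw_pos(rates[["word_repetition_rate"]])) {
    add(p, base[p]); counts["word_repetition_rate"] <- counts["word_repetition_rate"] + 1
  }
  # periphrastic passive templates (half agented)
  for (p in draw_pos(rates[["passive_rate"]])) {
    pp <- sample(pools$participles, 1)
    tpl <- if (stats::runif(1) < 0.5)
      c("il", "a", "été", pp, "par", "le", zipf(pools$noun, 1))
    else c("elle", "était", pp)
    add(p, tpl); counts["passive_rate"] <- counts["passive_rate"] + 1
  }
  # n-gram recycling (repetition knob): re-insert the bigram ending at p
  # immediately after itself — the stutter "a b a b" — which creates both a
  # parallel edge (a->b twice) and a 2-cycle (b->a at the join) in the
  # speech graph
  for (p in draw_pos(rates[["repetition_rate"]])) {
    if (p >= 2L) {
      add(p, base[(p - 1L):p])
      counts["repetition_rate"] <- counts["repetition_rate"] + 1
    }
  }
  # class-exclusive marker tokens
  if (length(markers) && rates[["marker_rate"]] > 0) {
    for (p in draw_pos(rates[["marker_rate"]])) {
      add(p, sample(markers, 1)); counts["marker_rate"] <- counts["marker_rate"] + 1
    }
  }
  # sentence terminators
  for (p in draw_pos(1 / 12)) add(p, ".")

  chunks <- vector("list", n)
  for (i in seq_len(n)) chunks[[i]] <- c(base[i], ins[[i]])
  out <- unlist(chunks, use.names = FALSE)
  # attach a share of standalone ellipses to the preceding word ("mot…"),
  # unless that would read as a truncation of the following word
  ell <- which(out == "…")
  for (i in ell) {
    if (i > 1L && stats::runif(1) < 0.5) {
      prev <- out[i - 1L]
      nxt <- if (i < length(out)) out[i + 1L] else ""
      if (!grepl("…|[.!?]", prev) &&
          !(startsWith(tolower(nxt), tolower(prev)) && nchar(nxt) > nchar(prev))) {
        out[i - 1L] <- paste0(prev, "…")
        out[i] <- ""
      }
    }
  }
  out <- out[nzchar(out)]
  if (out[length(out)] != ".") out <- c(out, ".")
  list(text = paste(out, collapse = " "),
       realized = counts / length(out))
}

#' Generate a synthetic corpus with known ground truth
#'
#' Draws the cohort (exposure, diagnosis, criteria, socio-demographics) to
#' the configured marginals, document lengths from the truncated log-normal,
#' and token streams with the configured planted manipulations.  Criterion
#' flags follow the diagnosis: full PTSD sets all of B/C/D/E/G, partial sets
#' B and G (its defining pair) plus C/D/E at low probability, none leaves
#' all unset.  Deterministic in `(config, seed)`.
#'
#' @param cfg `lf_syn_config` from [synthetic_config()].
#' @param lexicons Optional lexicons from [generate_lexicons()]; generated
#'   from `cfg$seed` when `NULL` (so corpus and lexicons stay consistent).
#' @return List with `corpus` (`lf_corpus`), `metadata` (data.frame),
#'   `lexicons`, and `ground_truth` (true per-document class, planted-knob
#'   registry, realized per-document insertion rates, marker tokens).
#' @export
generate_corpus <- function(cfg = synthetic_config(), lexicons = NULL) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  if (is.null(lexicons)) lexicons <- generate_lexicons(cfg$seed)
  n <- cfg$n_docs
  ids <- sprintf("doc%03d", seq_len(n))

  exposure <- sample(rep(names(cfg$exposure_split), cfg$exposure_split))
  true_class <- sample(rep(names(cfg$diagnosis_split), cfg$diagnosis_split))

  # document lengths: log-normal matched to the target mean/sd, truncated
  s2 <- log(1 + (cfg$length_sd / cfg$length_mean)^2)
  lens <- round(stats::rlnorm(n, log(cfg$length_mean) - s2 / 2, sqrt(s2)))
  lens <- pmin(pmax(lens, cfg$length_range[1]), cfg$length_range[2])

  knobs <- syn_default_knobs()
  means <- syn_knob_means(cfg, knobs)

  lex <- combine_lexicons(lexicons)
  cat_pools <- split(lex$term, lex$category)
  feat_of_tag <- lf_tagger_categories()
  names(cat_pools)[match(unname(feat_of_tag), names(cat_pools))] <-
    names(feat_of_tag)
  cat_knobs <- intersect(knobs$knob, names(cat_pools))

  reserved <- syn_reserved_words()
  nouns <- setdiff(syn_make_terms(600L), c(reserved, lex$term))[seq_len(400L)]
  vt <- fr_verb_table()
  verbs <- vt$surface[vt$verbform == "finite"]
  participles <- vt$surface[vt$verbform == "participle" & vt$tense == "past" &
                              !vt$lemma %in% c(fr_motion_state_verbs, "être",
                                               "avoir")]
  pools <- list(fun = c(names(fr_pron_person), fr_det, fr_adp, fr_conj),
                noun = nouns, verb = verbs, adv = fr_adv,
                participles = participles,
                categories = cat_pools[cat_knobs])

  markers <- if (cfg$marker$n_tokens > 0)
    paste0("xmarker", letters[seq_len(cfg$marker$n_tokens)]) else character(0)

  realized <- matrix(0, n, nrow(knobs), dimnames = list(ids, knobs$knob))
  texts <- character(n)
  for (i in seq_len(n)) {
    mu <- means[, true_class[i]]
    rates <- pmax(0, stats::rnorm(nrow(knobs), mu, knobs$sd))
    names(rates) <- knobs$knob
    rates["marker_rate"] <- if (length(markers) &&
                                true_class[i] %in% cfg$marker$classes)
      cfg$marker$rate else 0
    d <- syn_make_doc(lens[i], as.list(rates), pools, markers)
    texts[i] <- d$text
    realized[i, names(d$realized)] <- d$realized
  }

  # recorded diagnosis: optional per-stratum label noise flips
  # symptomatic <-> none
  diagnosis <- true_class
  flipped <- rep(FALSE, n)
  if (!is.null(cfg$label_noise)) {
    for (s in names(cfg$label_noise)) {
      rate <- cfg$label_noise[[s]]
      cand <- which(exposure == s)
      k <- round(rate * length(cand))
      if (k > 0) {
        fl <- sample(cand, k)
        flipped[fl] <- TRUE
        diagnosis[fl] <- ifelse(diagnosis[fl] == "no_ptsd", "full_ptsd",
                                "no_ptsd")
      }
    }
  }

  crit <- matrix(FALSE, n, 5, dimnames = list(NULL, c("crit_B", "crit_C",
                                                      "crit_D", "crit_E",
                                                      "crit_G")))
  full <- diagnosis == "full_ptsd"; part <- diagnosis == "partial_ptsd"
  crit[full, ] <- TRUE
  crit[part, c("crit_B", "crit_G")] <- TRUE
  for (cc in c("crit_C", "crit_D", "crit_E"))
    crit[part, cc] <- stats::runif(sum(part)) < 0.3

  female <- stats::runif(n) < ifelse(exposure == "A1", 0.555, 0.684)
  age <- round(ifelse(exposure == "A1", stats::rnorm(n, 37, 9),
                      stats::rnorm(n, 42, 12)))
  age <- pmin(pmax(age, 18), 80)
  metadata <- data.frame(
    doc_id = ids, exposure = exposure, diagnosis = diagnosis,
    crit_B = crit[, 1], crit_C = crit[, 2], crit_D = crit[, 3],
    crit_E = crit[, 4], crit_G = crit[, 5],
    sex = ifelse(female, "F", "M"), age = age,
    education = sample(c("master_or_higher", "bachelor", "highschool_or_less"),
                       n, TRUE, prob = c(0.58, 0.26, 0.16)),
    profession = sample(c("executive", "intermediate", "employee", "student",
                          "other"), n, TRUE,
                        prob = c(0.49, 0.20, 0.07, 0.05, 0.19)),
    single = stats::runif(n) < 0.62,
    living_alone = stats::runif(n) <
      c(full_ptsd = 0.26, partial_ptsd = 0.31, no_ptsd = 0.50)[diagnosis],
    stringsAsFactors = FALSE)

  corpus <- Map(function(id, txt) list(doc_id = id, raw_text = txt), ids, texts)
  names(corpus) <- ids
  class(corpus) <- "lf_corpus"
  list(corpus = corpus, metadata = validate_metadata(metadata),
       lexicons = lexicons,
       ground_truth = list(config = cfg, true_class = stats::setNames(true_class, ids),
                           flipped = stats::setNames(flipped, ids),
                           knob_means = means, realized_rates = realized,
                           markers = markers))
}
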