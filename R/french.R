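# Closed-class word lists and a compact verb-form table for French.
# The annotator built on these is a deterministic rule backend: it covers the
# closed classes exhaustively and open-class verbs through regular first-group
# conjugation plus a table of frequent irregular forms.  An industrial French
# pipeline can be plugged in instead (see `tokenize`'s `annotator` argument).

fr_apostrophe_lemma <- c(
  "j'" = "je", "n'" = "ne", "m'" = "me", "t'" = "te", "s'" = "se",
  "l'" = "le", "d'" = "de", "c'" = "ce", "qu'" = "que", "aujourd'" = "aujourd'hui",
  "jusqu'" = "jusque", "lorsqu'" = "lorsque", "puisqu'" = "puisque")

fr_pron_person <- list(
  # person, number per pronoun surface (lower-cased, apostrophes resolved)
  "je" = c(1, "sing"), "me" = c(1, "sing"), "moi" = c(1, "sing"),
  "nous" = c(1, "plur"),
  "tu" = c(2, "sing"), "te" = c(2, "sing"), "toi" = c(2, "sing"),
  "vous" = c(2, "plur"),
  "il" = c(3, "sing"), "elle" = c(3, "sing"), "ils" = c(3, "plur"),
  "elles" = c(3, "plur"), "lui" = c(3, "sing"), "eux" = c(3, "plur"),
  "se" = c(3, "sing"), "soi" = c(3, "sing"), "on" = c(3, "sing"),
  "y" = c(3, "sing"), "cela" = c(3, "sing"), "ça" = c(3, "sing"),
  "ceci" = c(3, "sing"), "rien" = c(3, "sing"), "personne" = c(3, "sing"),
  "chacun" = c(3, "sing"), "quelqu'un" = c(3, "sing"))

fr_det <- c("le", "la", "les", "un", "une", "des", "du", "ce", "cet", "cette",
            "ces", "mon", "ma", "mes", "ton", "ta", "tes", "son", "sa", "ses",
            "notre", "nos", "votre", "vos", "leur", "leurs", "quel", "quelle",
            "quels", "quelles", "chaque", "plusieurs", "quelques", "tout",
            "toute", "tous", "toutes", "aucun", "aucune")

fr_adp <- c("à", "au", "aux", "de", "dans", "sur", "sous", "avec", "sans",
            "chez", "vers", "entre", "par", "pour", "en", "derrière", "devant",
            "après", "avant", "depuis", "pendant", "contre", "dès", "parmi",
            "selon", "dessus", "dessous", "malgré", "jusque")

fr_conj <- c("et", "ou", "mais", "donc", "or", "ni", "car", "que", "si",
             "quand", "comme", "parce", "lorsque", "puisque", "quoique", "sinon")

fr_adv <- c("ne", "pas", "plus", "très", "bien", "mal", "vite", "toujours",
            "jamais", "souvent", "encore", "aussi", "alors", "puis", "enfin",
            "là", "ici", "hier", "demain", "aujourd'hui", "maintenant",
            "ensuite", "déjà", "peut-être", "vraiment", "trop", "peu",
            "beaucoup", "assez", "presque", "ainsi", "autrefois", "soudain",
            "longtemps", "parfois", "mieux", "moins", "tant", "tellement",
            "surtout", "voilà", "voici", "oui", "non", "pareil", "quoi")

# fillers / interjections typical of transcribed spoken French
fr_fillers_default <- c("euh", "ah", "bah", "ben", "hein", "hum")
fr_intj <- c(fr_fillers_default, "oh", "hé", "eh", "hop", "clack", "boum", "hm",
             "mmh", "ouais")

# hesitation vowels proper (subset of fillers)
fr_hesitations_default <- c("euh", "hum", "hm", "mmh")

# generic logical/discourse connectors
fr_connectors_default <- c("donc", "alors", "enfin", "bon", "ben", "quoi",
                           "puis", "ensuite", "bref", "finalement", "ainsi")

# past-time adverbial cues (historical-present detection)
fr_past_cues <- c("hier", "autrefois", "soudain", "ensuite", "puis", "après",
                  "avant", "pendant", "lorsque", "quand")
# now-time cues (enunciative present)
fr_now_cues <- c("maintenant", "aujourd'hui", "actuellement", "désormais")
# genericity cues (generic present / generic "on")
fr_generic_cues <- c("toujours", "jamais", "souvent", "chacun", "général",
                     "généralement", "parfois")

# intransitive motion/state verbs whose "être + participle" is a compound
# tense, not a passive
fr_motion_state_verbs <- c("aller", "venir", "partir", "arriver", "rester",
                           "devenir", "entrer", "sortir", "monter", "descendre",
                           "tomber", "retourner", "naître", "mourir", "décéder",
                           "passer", "revenir", "rentrer", "apparaître")

# ---------------------------------------------------------------------------
# Verb-form table ------------------------------------------------------------

fr_verb_row <- function(surface, lemma, mood, tense, verbform, ambiguous = FALSE) {
  data.frame(surface = surface, lemma = lemma, mood = mood, tense = tense,
             verbform = verbform, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

# regular first-group (-er) conjugation for a stem, e.g. "parl" -> parler
fr_conjugate_er <- function(stem) {
  lemma <- paste0(stem, "er")
  rbind(
    fr_verb_row(paste0(stem, c("e", "es", "e", "ons", "ez", "ent")),
                lemma, "indicative", "present", "finite"),
    fr_verb_row(paste0(stem, c("ais", "ait", "ions", "iez", "aient")),
                lemma, "indicative", "imperfect", "finite"),
    fr_verb_row(paste0(stem, c("erai", "eras", "era", "erons", "erez", "eront")),
                lemma, "indicative", "future", "finite"),
    fr_verb_row(paste0(stem, c("erais", "erait", "erions", "eriez", "eraient")),
                lemma, "conditional", "present", "finite"),
    fr_verb_row(paste0(stem, c("é", "ée", "és", "ées")),
                lemma, "participle", "past", "participle"),
    fr_verb_row(paste0(stem, "ant"), lemma, "participle", "present", "gerund"),
    fr_verb_row(lemma, lemma, "infinitive", "", "infinitive")
  )
}

# participle-only entries (stem + fem/plur endings)
fr_participles <- function(stem, lemma, endings = c("", "e", "s", "es")) {
  fr_verb_row(paste0(stem, endings), lemma, "participle", "past", "participle")
}

fr_build_verb_table <- function() {
  er_stems <- c("parl", "march", "pens", "cri", "pleur", "tomb", "entr",
                "rest", "arriv", "mont", "retourn", "bless", "tu", "regard",
                "écout", "trembl", "saign", "touch", "rêv", "cass", "aid",
                "port", "jet", "pass", "rentr", "écras", "évacu", "pans",
                "soign", "frapp", "attaqu", "hurl", "racont", "continu",
                "cherch", "trouv", "laiss", "donn", "appel", "rappel",
                "attrap", "pos", "tir", "détourn", "observ")
  tabs <- lapply(er_stems, fr_conjugate_er)

  aux <- rbind(
    fr_verb_row(c("suis", "es", "est", "sommes", "êtes", "sont"),
                "être", "indicative", "present", "finite"),
    fr_verb_row(c("étais", "était", "étions", "étiez", "étaient"),
                "être", "indicative", "imperfect", "finite"),
    fr_verb_row(c("serai", "seras", "sera", "serons", "serez", "seront"),
                "être", "indicative", "future", "finite"),
    fr_verb_row(c("serais", "serait", "serions", "seriez", "seraient"),
                "être", "conditional", "present", "finite"),
    fr_verb_row(c("sois", "soit", "soyons", "soyez", "soient"),
                "être", "subjunctive", "present", "finite"),
    fr_verb_row("été", "être", "participle", "past", "participle"),
    fr_verb_row("étant", "être", "participle", "present", "gerund"),
    fr_verb_row("être", "être", "infinitive", "", "infinitive"),
    fr_verb_row(c("ai", "as", "a", "avons", "avez", "ont"),
                "avoir", "indicative", "present", "finite"),
    fr_verb_row(c("avais", "avait", "avions", "aviez", "avaient"),
                "avoir", "indicative", "imperfect", "finite"),
    fr_verb_row(c("aurai", "auras", "aura", "aurons", "aurez", "auront"),
                "avoir", "indicative", "future", "finite"),
    fr_verb_row(c("aurais", "aurait", "aurions", "auriez", "auraient"),
                "avoir", "conditional", "present", "finite"),
    fr_verb_row(c("aie", "ait", "ayons", "ayez", "aient"),
                "avoir", "subjunctive", "present", "finite"),
    fr_verb_row(c("eu", "eue", "eus", "eues"),
                "avoir", "participle", "past", "participle"),
    fr_verb_row("ayant", "avoir", "participle", "present", "gerund"),
    fr_verb_row("avoir", "avoir", "infinitive", "", "infinitive")
  )

  irregular <- rbind(
    fr_verb_row(c("cours", "court", "courons", "courez", "courent"),
                "courir", "indicative", "present", "finite"),
    fr_verb_row(c("courais", "courait", "couraient"),
                "courir", "indicative", "imperfect", "finite"),
    fr_verb_row(c("dors", "dort", "dorment"),
                "dormir", "indicative", "present", "finite"),
    fr_verb_row(c("dormais", "dormait", "dormaient"),
                "dormir", "indicative", "imperfect", "finite"),
    fr_verb_row(c("veux", "veut", "voulons", "voulez", "veulent"),
                "vouloir", "indicative", "present", "finite"),
    fr_verb_row(c("voulais", "voulait", "voulaient"),
                "vouloir", "indicative", "imperfect", "finite"),
    fr_verb_row(c("vois", "voit", "voyons", "voyez", "voient"),
                "voir", "indicative", "present", "finite"),
    fr_verb_row(c("voyais", "voyait", "voyaient"),
                "voir", "indicative", "imperfect", "finite"),
    fr_verb_row(c("entends", "entend", "entendons", "entendez", "entendent"),
                "entendre", "indicative", "present", "finite"),
    fr_verb_row(c("entendais", "entendait", "entendaient"),
                "entendre", "indicative", "imperfect", "finite"),
    fr_verb_row(c("sens", "sent", "sentons", "sentez", "sentent"),
                "sentir", "indicative", "present", "finite"),
    fr_verb_row(c("sentais", "sentait", "sentaient"),
                "sentir", "indicative", "imperfect", "finite"),
    fr_verb_row(c("vais", "va", "vont", "allons", "allez"),
                "aller", "indicative", "present", "finite"),
    fr_verb_row(c("allais", "allait", "allaient"),
                "aller", "indicative", "imperfect", "finite"),
    fr_verb_row(c("irai", "ira", "iront"),
                "aller", "indicative", "future", "finite"),
    fr_verb_row(c("irais", "irait", "iraient"),
                "aller", "conditional", "present", "finite"),
    fr_verb_row(c("fais", "font", "faisons", "faites"),
                "faire", "indicative", "present", "finite"),
    fr_verb_row(c("faisais", "faisait", "faisaient"),
                "faire", "indicative", "imperfect", "finite"),
    fr_verb_row(c("dis", "disons", "disent"),
                "dire", "indicative", "present", "finite"),
    fr_verb_row(c("disais", "disait", "disaient"),
                "dire", "indicative", "imperfect", "finite"),
    fr_verb_row(c("prends", "prend", "prenons", "prenez", "prennent"),
                "prendre", "indicative", "present", "finite"),
    fr_verb_row(c("prenais", "prenait", "prenaient"),
                "prendre", "indicative", "imperfect", "finite"),
    fr_verb_row(c("mets", "met", "mettons", "mettent"),
                "mettre", "indicative", "present", "finite"),
    fr_verb_row(c("mettais", "mettait", "mettaient"),
                "mettre", "indicative", "imperfect", "finite"),
    fr_verb_row(c("sais", "sait", "savons", "savent"),
                "savoir", "indicative", "present", "finite"),
    fr_verb_row(c("savais", "savait", "savaient"),
                "savoir", "indicative", "imperfect", "finite"),
    fr_verb_row(c("peux", "peut", "pouvons", "pouvez", "peuvent"),
                "pouvoir", "indicative", "present", "finite"),
    fr_verb_row(c("pouvais", "pouvait", "pouvaient"),
                "pouvoir", "indicative", "imperfect", "finite"),
    fr_verb_row(c("meurs", "meurt", "meurent"),
                "mourir", "indicative", "present", "finite"),
    fr_verb_row(c("mourais", "mourait", "mouraient"),
                "mourir", "indicative", "imperfect", "finite"),
    fr_verb_row(c("pars", "part", "partons", "partez", "partent"),
                "partir", "indicative", "present", "finite"),
    fr_verb_row(c("partais", "partait", "partaient"),
                "partir", "indicative", "imperfect", "finite"),
    fr_verb_row(c("viens", "vient", "venons", "viennent"),
                "venir", "indicative", "present", "finite"),
    fr_verb_row(c("venais", "venait", "venaient"),
                "venir", "indicative", "imperfect", "finite"),
    fr_verb_row(c("courir", "dormir", "vouloir", "voir", "entendre", "sentir",
                  "aller", "faire", "dire", "prendre", "mettre", "savoir",
                  "pouvoir", "mourir", "partir", "venir", "servir", "sortir",
                  "vivre", "souvenir", "réaliser", "respirer"),
                c("courir", "dormir", "vouloir", "voir", "entendre", "sentir",
                  "aller", "faire", "dire", "prendre", "mettre", "savoir",
                  "pouvoir", "mourir", "partir", "venir", "servir", "sortir",
                  "vivre", "souvenir", "réaliser", "respirer"),
                "infinitive", "", "infinitive")
  )

  part <- rbind(
    fr_participles("parti", "partir"),
    fr_participles("sorti", "sortir"),
    fr_participles("venu", "venir"),
    fr_participles("revenu", "revenir"),
    fr_participles("devenu", "devenir"),
    fr_participles("descendu", "descendre"),
    fr_participles("mort", "mourir", c("", "e", "s", "es")),
    fr_participles("né", "naître", c("", "e", "s", "es")),
    fr_participles("décédé", "décéder", c("", "e", "s", "es")),
    fr_participles("couru", "courir"),
    fr_participles("dormi", "dormir", ""),
    fr_participles("voulu", "vouloir"),
    fr_participles("vu", "voir"),
    fr_participles("entendu", "entendre"),
    fr_participles("senti", "sentir"),
    fr_participles("servi", "servir"),
    fr_participles("pris", "prendre", c("", "e", "es")),
    fr_participles("mis", "mettre", c("", "e", "es")),
    fr_participles("su", "savoir", ""),
    fr_participles("pu", "pouvoir", ""),
    fr_participles("vécu", "vivre"),
    # frequent ambiguous forms: finite present vs participle, resolved in
    # context (participle after an auxiliary)
    fr_verb_row(c("dit", "fait"), c("dire", "faire"),
                "indicative", "present", "finite", ambiguous = TRUE)
  )

  tab <- rbind(do.call(rbind, tabs), aux, irregular, part)
  # keep first entry per surface (specific irregulars come after -er but
  # -er stems were chosen not to collide with them)
  tab[!duplicated(tab$surface), , drop = FALSE]
}

# cached singleton
fr_verb_env <- new.env(parent = emptyenv())
fr_verb_table <- function() {
  if (is.null(fr_verb_env$tab)) {
    tab <- fr_build_verb_table()
    fr_verb_env$tab <- tab
    fr_verb_env$idx <- stats::setNames(seq_len(nrow(tab)), tab$surface)
  }
  fr_verb_env$tab
}
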