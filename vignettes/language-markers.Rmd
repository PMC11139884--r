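---
title: "Language markers of PTSD in trauma narratives: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Language markers of PTSD in trauma narratives: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ptsdlang` implements a transparent, interpretable analysis chain for the
question: *do transcribed trauma narratives carry measurable linguistic
markers of post-traumatic stress disorder (PTSD)?*  The package assumes a
cohort of interview transcripts (spoken French, with transcription marks
preserved) together with a metadata table holding the DSM-5 exposure type
(A1 direct exposure, A2 witnessing), a probable diagnosis (full, partial or
no PTSD; partial PTSD is defined as intrusion symptoms — criterion B — with
significant distress or functional impairment — criterion G), and the
individual criterion flags B, C, D, E, G.  The chain has four stages:

1. **Feature extraction** — 81 named per-document language features in
   seven families.
2. **Univariate screen** — each feature against each label, with effect
   size and post-hoc power.
3. **Repeated-run classification** — three interpretable model families,
   averaged over randomized stratified runs, with averaged importances and
   error analysis.
4. **A convolutional text classifier** — a hypothesis-free branch with
   focal loss and per-token saliency, for pattern discovery.

A synthetic-corpus generator with planted effects provides ground truth for
calibration and recovery testing, since real trauma-interview corpora are
not distributable.

## The feature registry

The registry fixes the names, grouping and normalization of every feature
(`lf_registry()`).  Family sizes are: 2 textual, 27 sentiment/emotion, 4
lexical fields, 18 morphosyntactic, 4 passive voice, 9 disfluency, 5
readability, 12 speech graph — 81 features in all.  These group sizes are
taken as authoritative; note that they are not perfectly reconcilable with
the rounder totals sometimes quoted for this kind of registry (80 built, 55
kept after reduction).  We keep the per-family counts exact and treat the
totals as approximate: the reduction below leaves 57 features.

The sentiment family is assembled from stand-ins for the usual lexicon
resources: 4 LIWC-style categories (death, body, positive and negative
emotion), 10 EMA-style emotion categories, 6 FEEL-style categories
(including the positive-valence score), a valence-weighted happiness score
(labMT style: the mean valence weight over matched tokens), a pluggable
polarity/subjectivity scorer, and 4 EMPATH-style categories.  The licensed
term lists themselves are not reproduced; any CSV of `term, category,
weight` can be supplied, and `generate_lexicons()` emits consistent
synthetic stand-ins.

**Feature reduction for classification.** Within the sentiment family most
scores are nearly collinear, so only the six valence-based ones are kept
(polarity, subjectivity, FEEL positive, happiness, LIWC positive/negative
emotion); of the passive family only the length-normalized count survives.
`reduce_features()` applies both rules and is idempotent.

The lexical family has four features (death, body, physical sensations,
sensory perception); the perception category covers both perception verbs
and perception words through the tagger contract, since the printed family
size is four while five category names circulate.

## Tokenization and annotation conventions

The tokenizer is deterministic and preserves the transcription dialect:

* the ellipsis "…" (or "...") is always a token of its own — it encodes a
  silent break;
* a word glued to an ellipsis and *resumed* by the next word ("par…
  partir") is one token flagged `truncated` — a false start.  A glued
  ellipsis whose next word does not resume the fragment ("Je… je") stays a
  separate break token.  Resumption is the only signal that reliably
  separates the two cases in this dialect;
* character spans are 0-based half-open into the raw text, and sentences
  split on `.`, `!`, `?`.

`words_number` counts word tokens: punctuation, standalone ellipses and
truncated fragments are excluded.  All count-type features are normalized
by this document length.

The default annotation backend is a rule system: closed-class lists
(pronouns with person/number, determiners, prepositions, conjunctions,
interjections), a verb-form table (full conjugations of être/avoir, regular
first-group conjugation for ~45 stems, frequent irregular forms and past
participles), a participle/finite disambiguation rule (participle after an
auxiliary), and defaults (unknown content word → noun; capitalized
non-sentence-initial → proper noun; `-ment` → adverb).  It is a *contract*,
not a commitment: any function mapping the token table to an annotated
token table can replace it (e.g. an industrial French pipeline), and a
learned tagger plugin can override the contextual disambiguations below.

**Values of the present tense** (generic / historical / enunciative) are
assigned by sentence-level cues: genericity adverbs ("toujours", "jamais")
or a generic "on" subject → generic; now-cues ("maintenant",
"aujourd'hui") → enunciative; past-time cues or surrounding past-tense
verbs → historical; otherwise enunciative.  **Values of "on"** (we /
someone / generic): an object clitic referring to the speaker right after
"on" ("On m'a marché dessus") → someone; genericity cue with present tense
→ generic; otherwise (the narrative case, "On est entré dans la salle") → we.
These are deterministic approximations of contextual classifiers; they are
exact on the calibration examples and, more importantly for the synthetic
studies, they are *consistent*, so planted effects on these categories are
recoverable.

**Passive voice.** French periphrastic passive: a form of "être" (finite,
infinitive, or the participle "été" inside a compound) followed by a past
participle, crossing at most three intervening adverbs/clitics/negation
particles.  Two guards matter in spoken French: participles of intransitive
motion/state verbs ("elle est partie") form compound tenses, not passives,
and are excluded by a lemma list; and an optional "par"/"de" agent phrase
within four tokens marks the passive as agented.

**Disfluencies.** Nine rates: fillers (default list euh/ah/bah/ben/hein/
hum), hesitation vowels proper, fragment repetitions, immediate word
repetitions, false starts (truncations), silent breaks attached after a
word vs free-standing between words, generic connectors, and the composite
`score_disfluencies`.  The composite is defined here as the sum of the six
disfluency component rates (connectors and the hesitation subset are
reported separately) — the composite has no standard definition, and a sum
of rates keeps it interpretable and monotone in each component.

## Speech-graph features

The narrative is mapped to a directed multigraph: one node per distinct
unit, one edge per consecutive word-token pair.  The unit defaults to the
lemma over the whole document (punctuation excluded), configurable to
surface forms and per-sentence scope — the methodology literature does not
fix the unit, and lemma units make repetition structure visible through
inflection changes.  From the multigraph: L1 (self-edges), L2 (pairings of
opposite-direction edges between two nodes), L3 (directed 3-cycles through
distinct nodes, each counted once), PE (pairs of same-direction parallel
edges), degree mean/sd (in+out, multi-edge), and — on the undirected simple
projection of the largest weakly connected component — average local
clustering, global transitivity and average shortest path.  All of these
are validated against brute-force enumeration (including Floyd–Warshall
distances) on random multigraphs with at most 8 nodes.

## The univariate screen

Two-group comparisons use the Mann–Whitney U test: exact two-sided p by
complete enumeration of label assignments when $n_1+n_2 \le 12$, otherwise
the tie-corrected normal approximation with continuity correction (the
package's own implementation; `wilcox.test` serves as an independent check
in the test suite).  Three-group comparisons use one-way ANOVA with
eta-squared; categorical covariates use the chi-squared test with Yates
continuity correction for 2×2 tables only — with that correction the
reconstructed cohort sex-by-exposure table (61/110 vs 26/38 female) gives
p ≈ 0.22.

Effect size for two groups is pooled-sd Cohen's d with the group1 − group2
convention; screens pass the symptomatic group second, so elevated markers
in the symptomatic group carry **negative** d.  Statistical power is
post-hoc Monte-Carlo: simulate normal populations at the observed |d| (or
eta-squared) and group sizes, B = 2000 seeded replicates, and report the
rejection rate at α = 0.05.  Closed-form power is awkward for rank tests;
the Monte-Carlo estimate is transparent and seeded, hence reproducible.
Raw p-values are reported by default (matching the descriptive,
single-table character of the screen); Benjamini–Hochberg adjustment is
available by flag.

## The repeated-run classification protocol

Each run: a stratified 80/20 document split (strata = exposure ×
diagnosis; per-stratum counts are half-up rounded and then repaired so the
global test share is exact — 148 documents give 118/30), SMOTE
oversampling of the training fold to balance classes (synthetic points on
segments between minority points and their k = 5 nearest minority
neighbours; k is the method's canonical default, the protocol source does
not state it), model fitting, ROC-AUC on the untouched test fold.  AUC and
feature importances are averaged over 100 runs by default; a run whose
test fold is single-class is re-drawn with a fresh seed so the run count
stays exact.

Families and hyperparameters:

* **Elastic-net logistic regression** (`l1_ratio = 0.6`, `C = 0.1`).
  Features are z-scored on training-fold statistics (penalties are
  scale-sensitive; the protocol source is silent, standardization is the
  defensible default).  Fitted with glmnet; the inverse-regularization `C`
  maps to `lambda = 1/(C·n)` by equating the penalized objectives.
  Importances are the standardized coefficients.
* **Random forest** (`n_estimators = 40`, `min_sample_split = 0.4` as a
  fraction of the training fold, `min_samples_leaf = 15`), fitted with
  ranger (`min.node.size = ceil(0.4 n)`, `min.bucket = 15`); impurity
  importances.
* **EBM-style additive model** (`max_leaves = 10`, `min_samples_leaf =
  15`, `max_bins = 20`, `early_stopping_rounds = 20`): implemented in the
  package as cyclic gradient boosting of per-feature piecewise-constant
  shape functions on quantile bins, one feature at a time in round-robin
  order at a low learning rate, with early stopping on a held-out
  fraction.  No installed R library provides this model family, so it is
  authored here in its minimal form — no pairwise interactions, no
  bagging; importances are mean absolute term contributions.

**Error analysis** takes the 20 documents with the highest average
misclassification frequency under the best family (ties broken by document
id, so the selection is deterministic), and screens this subgroup against
the rest on the socio-demographic covariates, re-using the univariate
machinery (chi-squared for categorical, Mann–Whitney for numeric).

## The convolutional branch

Documents are cut into fixed-length token sequences *after* a
document-level split (80/20 test, then 20% of training for validation), so
no document contributes sequences to two folds and the vocabulary (top
1998 training-fold tokens plus PAD and UNK) carries no test information.
K random-offset windows per document are drawn at training time, with
K = ceil(Q75/seq_len) by default, where Q75 is the length threshold of the
25% longest documents; inference uses exhaustive non-overlapping windows
and averages their probabilities (`infer_document`).

The classifier is the minimal interpretable topology consistent with
class-activation mapping: embedding (size 128) → spatial dropout → one 1-D
convolution (32 filters, kernel 9) → global max pooling → dense sigmoid.
The exact depth/pooling scheme is an assumption of this package (only the
sizes are prescribed by the protocol).  Training minimizes focal loss
(α = 0.7, γ = 2; at γ = 0 it reduces exactly to α-weighted cross-entropy)
with Adam, L2 regularization and early stopping on validation loss, at
most 50 epochs.  Class imbalance is handled by the focal loss alone — no
oversampling in this branch.  The network and its gradients are
implemented directly in matrix algebra; everything runs single-threaded
from one seeded generator, so fixed seeds give bit-identical weights
(asserted in the tests).

**Saliency (TDS).** Per-token attribution combines class-activation
weighting with deconvolution: post-ReLU feature maps are weighted by the
dense-layer class weights, propagated back through the transposed
convolution to token positions, and projected onto the input embedding
(gradient × input), per channel.  Channel scores combine by sum (a `max`
rule is available; the cited combination is external and unspecified).
PAD positions are excluded from normalization.  Patterns are maximal token
runs scoring above the sequence mean + 1 sd, mined from the sequences with
the highest class probability.  The multi-channel variant concatenates
full-form, lemma and POS embeddings before the convolution; with the extra
channels zeroed it reproduces the single-channel logits exactly, which the
tests assert.

## The synthetic cohort

`generate_corpus()` emulates the study conditions: 148 documents, 110 A1 /
38 A2, 70 full / 42 partial / 36 no PTSD, log-normal lengths with mean
5553 and sd 3628 tokens truncated to [200, 20000], socio-demographics
drawn to the cohort's printed marginals (e.g. 55.5% / 68.4% female by
exposure, age 37±9 / 42±12).  Texts are token streams over a French
function-word skeleton with pseudo-word content slots — *not* grammatical
prose.  Planted manipulations: per-class shifts of lexicon-category rates
(in units of the between-document sd or as absolute deltas), disfluency
marks, passive templates, n-gram recycling (raising PE/L2), class-exclusive
marker tokens, and optional per-stratum label flips.  Insertion rates are
corrected by the expected word-mass expansion factor so a planted delta is
realized per final word token (verified by a binomial concentration test).

What passing tests on this generator do show: the extractor measures the
planted quantities consistently, the screen and the classifiers recover
planted group differences at the expected power, nulls are calibrated, and
the CNN finds class-exclusive vocabulary.  What they cannot show: behavior
on real discourse — grammatical structure, topical coherence, pragmatics,
and the learned-tagger categories are outside the generator's reach.

## Numerical choices and degenerate inputs

* Zero-denominator features (empty document, no verbs, no "on") return 0
  and the document is listed in the extractor's `degenerate` attribute —
  never NaN.
* Weighted happiness with zero lexicon overlap returns the 0 sentinel.
* Probabilities are clipped at 1e-12 inside the focal loss; Monte-Carlo
  power and all split/SMOTE/training randomness run from local seeded
  generators that restore the caller's RNG state.
* Ties in the misclassification ranking break by document id; document
  ids collate by Unicode code point, independent of the session locale.

## Problem sizes in the tests and the acceptance script

The test corpora keep the cohort structure (148 documents and the exposure/
diagnosis splits) but scale document lengths down (means of 300–900
tokens) and use 10–30 repeated runs where only determinism or calibration
is at stake; the acceptance script uses study-scale lengths for the null
calibration, 10 generator seeds for the recovery study, the full 100-run
protocol for the planted-effect AUC, and sequence length 128 for the CNN
sanity run.  These sizes are the package's choices for a reproducible
desk-scale demonstration; all of them are arguments, not constants.

## Known limitations

* The rule annotator's coverage of open-class French morphology is
  intentionally small; real-corpus use should plug in an industrial
  pipeline through the annotator contract.
* The EBM-style family omits interactions and bagging, so its accuracy is
  a lower bound on the reference implementation's.
* The CNN topology beyond the prescribed sizes is an assumption; saliency
  scores are comparative (marker vs background), not calibrated
  attributions.
* Post-hoc Monte-Carlo power at the observed effect is known to be an
  optimistic summary when effects are estimated from the same data; it is
  reported for table compatibility, not for planning.
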