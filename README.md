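# ptsdlang

Language markers of post-traumatic stress disorder (PTSD) in transcribed
trauma narratives.

Clinical PTSD assessment has no practical biomarker; the language of trauma
narratives is a candidate. `ptsdlang` is for researchers in computational
psychiatry and clinical NLP who have a cohort of interview transcripts
(spoken French, transcription marks preserved) with DSM-5 exposure and
diagnosis metadata, and who want a transparent, fully reproducible analysis
rather than a black box. The package implements the complete chain:

1. **Language features.** 81 named per-document features in seven families:
   textual (length), sentiment/emotion (lexicon category rates, weighted
   happiness, polarity/subjectivity), lexical fields (death, body, physical
   sensations, perception), morphosyntax (pronoun persons, tense
   proportions, contextual values of the present tense and of the pronoun
   *on*), French periphrastic passive (rule-based *être* + past participle
   detection with agent phrases), speech disfluencies (fillers, false
   starts *"par… partir"*, silent breaks *"…"*, repetitions), readability
   (type/token ratios, lexical density), and word-adjacency speech-graph
   structure (loops L1/L2/L3, parallel edges PE, degree, clustering,
   shortest paths).
2. **Univariate screen.** Per feature: Mann–Whitney U (exact permutation p
   for n₁+n₂ ≤ 12, tie-corrected normal approximation otherwise), one-way
   ANOVA for three groups, chi-squared with Yates correction for 2×2
   contingency tables; pooled-sd Cohen's d (symptomatic group second, so
   elevated markers have d < 0) and seeded Monte-Carlo post-hoc power.
3. **Repeated-run classification.** Stratified 80/20 splits (exposure ×
   diagnosis), SMOTE oversampling of the training fold, three
   interpretable families — elastic-net logistic regression (l1_ratio 0.6,
   C 0.1), random forest (40 trees, min split fraction 0.4, min leaf 15),
   and a cyclic-boosting additive (EBM-style) model — with ROC-AUC and
   feature importances averaged over 100 randomized runs, and error
   analysis of the 20 most misclassified documents.
4. **Text CNN.** Leak-free sequence datasets (document-level split before
   sequence cutting; K = ⌈Q75/512⌉ windows per document), a single-block
   convolutional classifier (embedding 128, 32 filters, kernel 9) trained
   with focal loss (α = 0.7, γ = 2), document inference by averaging
   sequence probabilities, and deconvolution/class-activation per-token
   saliency (TDS) for pattern extraction.

A synthetic-corpus generator reproduces the cohort structure this design
targets (148 documents; 110 directly exposed / 38 witnesses; 70 full / 42
partial / 36 no PTSD; log-normal lengths, mean 5553 ± 3628 tokens) with
planted, recoverable effects — real trauma-interview corpora are not
distributable.

## Worked example

```r
library(ptsdlang)

# a synthetic cohort with a planted death-vocabulary effect (d = 1.5)
cfg <- synthetic_config(
  length_mean = 800, length_sd = 350, length_range = c(200, 2500),
  planted_effects = list(list(knob = "model_death",
                              classes = c("full_ptsd", "partial_ptsd"),
                              d = 1.5)),
  seed = 9)
g <- generate_corpus(cfg)

docs     <- tokenize_corpus(g$corpus)
features <- extract_features(docs, g$lexicons)
features
#> <lf_features> 148 documents x 81 language features

label <- setNames(factor(ifelse(g$metadata$diagnosis == "no_ptsd",
                                "negative", "positive"),
                         levels = c("negative", "positive")),
                  g$metadata$doc_id)

screen <- association_table(features, label, B = 200)
screen[screen$feature == "model_death",
       c("feature", "p_value", "effect_size", "power")]
#>        feature      p_value effect_size power
#> 30 model_death 1.058247e-06  -0.9621894 0.995

runs <- repeated_runs(model_spec("logistic_elasticnet"),
                      reduce_features(features), label,
                      strata = setNames(interaction(g$metadata$exposure,
                                                    g$metadata$diagnosis,
                                                    drop = TRUE),
                                        g$metadata$doc_id),
                      n_runs = 100, base_seed = 7)
runs
#> <lf_runs> logistic_elasticnet: mean AUC = 0.673 ∓ 0.098 over 100 runs
#> top importances:
#>               model_death model_physical_sensations     lexical_density_score
#>                    0.9062                   -0.2345                    0.1028
```

The screen prints a two-sided Mann–Whitney p-value of about 1e-6 for the
planted feature, an effect size of −0.96 (negative because the symptomatic
group uses *more* death vocabulary under the group1 − group2 convention)
and power 0.995; the repeated-run elastic-net protocol reaches a mean
test-fold ROC-AUC of 0.673 ∓ 0.098 over 100 runs — a single moderate
lexical marker supports only moderate discrimination — and ranks the
planted feature first by averaged importance. The numbers above are what
the code prints for seed 9 / base seed 7.

`run_pipeline(pipeline_config(...))` chains every stage (features →
screens per label → repeated-run ML → error analysis → optional CNN) and
writes `features.csv`, `assoc_<label>.csv`, `ml_summary.csv`, importance
tables, `error_analysis.json` and a reproducibility `manifest.json`. A
thin command-line front end is installed at `inst/cli/ptsdlang.R` with
subcommands `simulate`, `extract-features`, `associate`, `train-ml`, and
`run`.

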