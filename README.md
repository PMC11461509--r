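# pkner

Named-entity recognition of pharmacokinetic (PK) parameter mentions in
sentences from the scientific literature — a complete, desk-scale R toolkit
for building, evaluating and simulating PK NER pipelines.

## The problem

Pharmacokinetic parameters — clearance (CL), area under the
concentration–time curve (AUC), peak concentration (Cmax), elimination
half-life (t1/2), volume of distribution (Vd), bioavailability (F) —
quantify a drug's absorption, distribution, metabolism and excretion.
Their published estimates are locked in free text, and extracting them
automatically starts with recognising the parameter mentions themselves.
That task is hard in three specific ways: mentions are long spans whose
modifiers matter ("total body clearance" is not "clearance"), acronyms are
context-dependent ("F" is bioavailability near dosing vocabulary and a test
statistic elsewhere), and pharmacodynamic look-alikes (AUEC, MTD, Emax) must
be rejected.

`pkner` is aimed at text-mining researchers and pharmacometricians who need
the machinery around PK NER: a span-annotated corpus data model, a
rule-based matcher, a trainable sequence tagger, entity-level evaluation,
inter-annotator agreement, and an active-learning simulator, plus a
synthetic corpus generator so that every component is exercisable without
downloading anything.

## What is inside

| Component | Functions | What it does |
|---|---|---|
| Corpus model | `read_corpus`, `write_corpus`, `pk_tokenize`, `spans_to_bio`, `bio_to_spans`, `corpus_stats` | 0-based half-open character-offset spans; JSON-Lines and CoNLL BIO interchange; BIO codec with documented repair; corpus statistics |
| Synthetic corpus | `generator_config`, `generate_corpus`, `make_splits`, `default_inventory` | seeded template generator of PK-like sentences with exact gold spans, emulating the 16.4% (random-sampling) vs ~64% (selective-sampling) prevalence regimes, modifier-rich long mentions, ambiguous "F", and PD distractors |
| Rule matcher | `default_pk_ruleset`, `compile_rules`, `match_rules` | declarative token patterns (shipped as a reviewable JSON file) with optional modifier tokens, regex acronym families, lexical context gating and longest-match resolution |
| Sequence tagger | `pk_train_config`, `train_tagger`, `predict`, `uncertainty`, `save_tagger`, `encoder_tagger` | averaged-perceptron BIO tagger (C++ core) with transition-constrained decoding, dev-set model selection, long-sentence split-and-rejoin, softmax-margin uncertainty, and a pluggable encoder contract carrying a transformer fine-tuning recipe (20 epochs, batch 16, lr 3e-5, weight decay 0.05, dropout 0.1, max length 256) |
| Evaluation | `align_spans`, `score_counts`, `evaluate_corpus`, `pairwise_iaa` | MUC/SemEval-style entity-level strict and partial matching (COR/INC/PAR/MIS/SPU), micro-averaged P/R/F1, pairwise-F1 inter-annotator agreement |
| Active learning | `al_config`, `run_al`, `simulated_annotator`, `bootstrap_initial_set`, `compare_al_vs_random` | model-in-the-loop simulation (updates every 10 sentences, binary accept/reject plus correction round, heuristic rule bootstrap) and the uncertainty-vs-random sampling experiment |
| CLI | `pkner_main`, `exec/pkner` | `generate`, `stats`, `convert`, `rules-match`, `train`, `predict`, `evaluate`, `iaa`, `al-simulate`, `al-compare`, each writing a provenance record |

The evaluation schemes in standard notation, with COR exact
boundary-and-label matches, PAR partial overlaps, MIS missed gold spans and
SPU spurious predictions:

```
strict:   P = COR / (COR + INC + PAR + SPU)        R = COR / (COR + INC + PAR + MIS)
partial:  P = (COR + 0.5 PAR) / (COR + INC + PAR + SPU)
          R = (COR + 0.5 PAR) / (COR + INC + PAR + MIS)
F1 = 2PR / (P + R)
```

## Worked example

```r
library(pkner)

# a synthetic corpus in the random-sampling regime
corp <- generate_corpus(generator_config(n_sentences = 1500, prevalence = 0.164, seed = 21))
corpus_stats(corp)
#> Corpus statistics (split = pool)
#>   sentences:               1500
#>   entity mentions:         341
#>   sentences with mentions: 14.07%
#>   full-text sentences:     49.07%

# rule-based matching: high precision, bounded recall
matcher <- compile_rules(default_pk_ruleset())
evaluate_corpus(corp, match_rules(matcher, corp))
#> Entity-level evaluation over 1500 sentences
#>   counts:  COR=149 INC=0 PAR=1 MIS=191 SPU=0
#>   strict:  P= 99.33 R= 43.70 F1= 60.69
#>   partial: P= 99.67 R= 43.84 F1= 60.90

# a learned tagger trained on the enriched regime overtakes the rules
train <- generate_corpus(generator_config(n_sentences = 1500, prevalence = 0.6425, seed = 22))
tagger <- train_tagger(train, config = pk_train_config(epochs = 5, seed = 3))
evaluate_corpus(corp, predict(tagger, corp))
#> Entity-level evaluation over 1500 sentences
#>   strict:  P= 98.53 R= 98.53 F1= 98.53

# context-dependent acronym handling
match_rules(matcher, "absolute bioavailability (F) was 52%")
#>   start end label        ("absolute bioavailability" and "F")
#> 1     0  24    PK
#> 2    26  27    PK
match_rules(matcher, "the F statistic was 3.1")   # no spans
```

The first block shows the generator reproducing the random-sampling regime
(14.07% of sentences carry a mention in this draw, against the configured
16.4%). The
rule matcher's profile — strict precision above 99% with recall near 44% —
is the signature of expert-written lexical rules: what they match is right,
but the long tail of modifier combinations is missed. The tagger, trained
on selectively enriched synthetic data, recovers that tail.

## Notes

- The methods vignette (`vignettes/pkner-methods.Rmd`) documents the
  models, the generator's assumptions and limits, numerical choices, and
  the design decisions in detail.
- The shipped ruleset is a reconstruction of the coverage described for
  expert-written PK rule systems, not a copy of any published rule list.
- Transformer fine-tuning on real corpora is deliberately out of scope; the
  encoder contract (`encoder_tagger`) carries the recipe so one can be
  plugged in without touching other modules.
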