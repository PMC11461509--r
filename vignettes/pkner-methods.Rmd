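---
title: "Methods: recognising pharmacokinetic parameter mentions in text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recognising pharmacokinetic parameter mentions in text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pharmacokinetic (PK) parameters — clearance (CL), the area under the
concentration–time curve (AUC), peak concentration (Cmax), elimination
half-life (t1/2), volume of distribution (Vd), bioavailability (F) — are
reported throughout the pharmacological literature in highly variable
surface forms. Automatic extraction of parameter estimates starts with
named entity recognition (NER) of the parameter mentions themselves. Three
properties make PK NER harder than it looks:

1. **Long spans with complementary modifiers.** "clearance" is a complete
   mention, but so is "total body clearance" or "steady-state volume of
   distribution"; the modifier determines the parameter sub-type, and strict
   entity-level evaluation counts a bare-head match as an error.
2. **Context-dependent acronyms.** "F" denotes bioavailability near dosing
   or percentage vocabulary, and an F statistic in statistical reporting.
3. **Pharmacodynamic (PD) confusables.** AUEC (area under the *effect*
   curve), MTD (maximum tolerated dose) or Emax look like PK acronyms but
   are out of class.

`pkner` implements the full desk-scale stack for this task: a corpus data
model, a synthetic corpus generator, a rule-based matcher, a trainable BIO
sequence tagger, entity-level evaluation, and a model-in-the-loop
active-learning simulator.

## Corpus model and offset conventions

Spans are character offsets into a sentence, 0-based and half-open, with one
default entity class `"PK"` (the type system is multi-class for reuse).
Spans in one sentence must be flat: nested or overlapping gold spans are
rejected at load time. The native interchange format is JSON-Lines (one
object per line: `id`, `text`, `spans`, `section`, `doc_id`); the reader
also accepts minimal records without `id` (generated from the line number)
or `section` (imputed as `full_text` and flagged in `corpus_stats()`).
CoNLL-style `TOKEN<TAB>TAG` export round-trips tokens and tags but loses
original character offsets — they are re-derived by joining tokens with
single spaces; this loss is deliberate and documented.

**Tokenizer.** A deterministic regex tokenizer: a token is a run of
alphanumeric characters, with internal `-`, `/`, `.` and the middle dot `·`
glueing runs together (`AUC0-24`, `t1/2`, `4.2`, `mg·h/L` stay whole; the
infinity sign counts as a word character so `AUC0-∞` is one token); any
other non-whitespace character is a single-character token. The rationale
is reproducibility without external models while keeping PK acronyms
intact. Tokenisation is lossless on non-whitespace characters.

**BIO codec.** `spans_to_bio()` defaults to the `snap` policy: a span whose
boundary falls inside a token is expanded to the covering tokens with a
warning. This is robust against tokenizer mismatch when reading externally
produced corpora; the `strict` policy turns the same situation into an
error. `bio_to_spans()` repairs a dangling `I-X` (after `O`, sentence start,
or a different label) to `B-X` — the conservative standard repair — so its
output always satisfies the span invariants.

## The synthetic corpus generator

Every module is testable without downloading anything because
`generate_corpus()` emulates the *statistical structure* of a PK sentence
corpus; it does not try to imitate PubMed prose. The generator is
template-based: entity templates embed 1–3 PK surface forms with numbers
and units and record the exact character offsets of the inserted forms, so
gold spans are exact by construction; distractor templates embed PD terms
(never labelled); filler templates are methods-style prose. All sampling is
driven by one seed; generation is byte-identical across runs.

The defaults are the study conditions of the corpus the package models:

* `prevalence = 0.164` — the fraction of sentences with at least one PK
  mention under random sampling of the PK literature; selectively sampled
  training data reach ~0.64, and the same knob reproduces that regime.
* `pct_full_text = 0.508` — the full-text/abstract mix of the randomly
  sampled evaluation splits (the enriched training regime uses 0.7946).
* `ambiguity_rate = 0.2` — the fraction of entity sentences that use the
  context-dependent "F" (with its long form nearby); a small multiple of it
  (0.15 × rate, ~3% of filler at defaults) yields filler sentences using
  "F" as a test statistic, so both context classes of the acronym exist and
  are separable.
* `distractor_rate = 0.3` — the fraction of non-entity sentences carrying a
  PD distractor, keeping false-positive pressure on both recognisers.

**Surface variety is a first-class property.** The inventory ships ~145
distinct PK surfaces: core long forms with modifier variants, acronyms with
variable AUC integration windows (`AUC0-6` … `AUC0-∞`), and a combinatorial
long tail (study-level qualifiers × parameter heads, e.g. "dose-normalized
trough concentration"). The long tail exists because the real phenomenon
the active-learning experiment rests on — span variety too large for a
few hundred randomly sampled sentences to cover — disappears in a toy
vocabulary. An early version of the generator used ~50 surfaces; a
500-sentence random sample then covered essentially everything and both
sampling strategies saturated, which is not the regime of interest.

What the generator does **not** emulate: real PubMed sentence syntax,
per-parameter frequency distributions (sampling weights are uniform), table
fragments and parsing noise, discontinuous mentions (assumed absent), and
annotation disagreement. Passing tests therefore demonstrate the machinery
is correct under controlled conditions, not that any score will transfer to
real corpora.

## The rule-based matcher

The matcher is declarative: a ruleset is data (a versioned JSON file under
`inst/extdata/`), not code, so domain experts can extend it without
touching the engine. Each rule is a token pattern — exact forms or regular
expressions, with optional elements (e.g. optional
`total|apparent|oral|systemic` before `clearance`) — plus an optional
lexical context gate. Design choices:

* **Context windows instead of POS/dependency constraints.** The
  disambiguation function (firing "F" only near
  bioavailability/dose/percent vocabulary, window 5 tokens) is preserved
  without depending on an external parser.
* **Case policy.** Acronym rules match case-sensitively ("f" in lowercase
  is overwhelmingly non-entity); long-form rules are case-insensitive.
* **Deterministic overlap resolution.** Longest span wins, ties go to the
  leftmost start, then to the earliest rule in the ruleset. "total body
  clearance" therefore yields one maximal span, never a nested
  "clearance".

The shipped ruleset intentionally covers the *well-known* forms and none of
the combinatorial long tail, mirroring how expert-written rules behave:
precision stays high (distractors and statistic-F are avoided by
construction) while recall degrades as unseen modifier combinations enter
the data. On default synthetic test corpora the matcher scores roughly
strict precision >90% with recall near 45% — the characteristic
high-precision/low-recall profile of rule-based PK NER.

## The sequence tagger

The reference backend is a structured averaged perceptron over windowed
lexical features (lowercase form, word shape, 2–4 character
prefixes/suffixes, digit indicators, a PK-lexicon flag, ±2 neighbour forms
and shapes) with transition-constrained greedy decoding: `I-X` is only
reachable from `B-X`/`I-X`, so predictions are BIO-valid by construction.
Training is deterministic given the seed, takes seconds on a CPU at desk
scale, and has enough capacity to memorise a consistent training set —
which is exactly what the downstream contracts need. The inner loops
(scoring, decoding, epoch updates, uncertainty) are C++.

Model selection follows the fine-tuning recipe recorded in
`pk_train_config()`: train for `epochs` (default 20), evaluate entity-level
strict F1 on the development set after each epoch, and keep the best state;
without a development set the final epoch is kept and logged. The remaining
config fields (batch size 16, learning rate 3e-5, weight decay 0.05,
dropout 0.1, maximum sequence length 256) parameterise the pluggable
encoder backend: `encoder_tagger()` accepts any function from a token
vector to a per-token score matrix, so a transformer token-classification
head can be dropped in without changing any other module. For sub-word
encoders the convention is that the first piece of a token carries the
label and continuation pieces are masked from the loss. The stated "linear
weight decay of 0.05" of the recipe plausibly conflates a linear
learning-rate schedule with weight decay; the config exposes the
coefficient as `weight_decay` and leaves scheduling to the encoder rather
than guessing intent. No loss re-weighting is applied to the dominant `O`
class, matching the recipe's silence on imbalance.

**Long sentences.** At prediction time, sentences beyond
`max_sequence_length` tokens are split at token boundaries, decoded per
chunk, and re-joined before spans are formed. A cut that would fall inside
a predicted entity is shifted to the nearest preceding O-predicted token
within 10 tokens (re-joining behaviour is otherwise unspecified in the
recipe; this rule keeps straddling entities intact and is covered by a
dedicated test).

**Uncertainty.** Sentence uncertainty is the mean over tokens of one minus
the softmax margin between the best and second-best label. One-hot
confidence gives 0, uniform scores give 1, and empty sentences give 0
(annotating them gains nothing). This margin measure is a documented
stand-in: the annotation tool modelled here does not disclose its internal
scorer.

## Entity-level evaluation

Evaluation is MUC/SemEval-style at the entity level. `align_spans()`
matches gold and predicted spans greedily in span order, claiming
exact-boundary matches first, then partial overlaps (≥1 character):
exact+correct label → COR, exact+wrong label → INC, overlap → PAR,
leftover gold → MIS, leftover predictions → SPU. Because spans within one
list are flat and sorted, crossing matchings are impossible, and the greedy
result coincides with the optimal injective matching that maximises exact
then overlap matches — the test suite pins this against a brute-force
enumeration oracle on random instances. Strict scores credit only COR
(`P = COR/n_pred`, `R = COR/n_gold`); partial scores give half credit to
PAR in both numerators, so partial F1 ≥ strict F1 always. Counts are summed
over sentences before scoring (micro-average). With one entity class INC
is structurally zero; the multi-class path stays alive and tested with a
second synthetic label. Percentages (0–100, two decimals) are the external
representation, matching how such results are tabulated.

Inter-annotator agreement is pairwise strict F1, treating one annotator as
gold and the other as prediction; swapping the two exchanges precision and
recall and leaves F1 fixed, so the matrix is symmetric with a diagonal of
100, and the mean excludes the diagonal. No chance-corrected coefficient is
computed — for span annotation with an open negative class, pairwise F1 is
the appropriate agreement measure.

## Active-learning simulation

`run_al()` reproduces the model-in-the-loop annotation protocol: rank the
pool by model uncertainty, take a batch (default 10 sentences — the update
cadence of the modelled protocol), have the simulated annotator label them,
retrain, repeat to budget. The simulated annotator is two-phase, matching
how span suggestions are reviewed: binary accept/reject of each proposal by
exact match against the hidden gold, then a correction round that restores
the full gold annotation, with bookkeeping of acceptances and boundary
corrections. The in-loop model is fully retrained after every update
(rather than incrementally updated) for determinism; at desk scale a
retraining takes well under a second. The heuristic-bootstrap stage — a
rule-matched, annotator-corrected initial set — is modelled by
`bootstrap_initial_set()` and can seed the loop via `initial_set`.

**Selection rule.** Two uncertainty modes ship. `"uncertainty_topk"` takes
the argmax — strictly the most uncertain sentences. Experimentation showed
it to be degenerate with a lexical in-loop model: sentences the model gets
*confidently wrong* (rare negative contexts such as statistic-"F" or
spelled-out PD distractors) have low uncertainty, are never selected, and
the resulting tagger overfires on exactly those contexts. Production
annotation samplers do not take argmaxes; they mix exploration into the
uncertainty preference. The default `"uncertainty"` mode therefore samples
without replacement with probability proportional to squared uncertainty,
which preserves the prevalence enrichment that makes selective sampling
attractive while negative context classes keep leaking into the labelled
set. The top-k pathology is kept available because it is instructive.

**The comparison experiment.** `compare_al_vs_random()` is the machine twin
of the sampling-strategy comparison: per run, build a 5000-sentence pool at
prevalence 0.164, label 500 sentences per arm — the selective arm via the
two-stage protocol (300-sentence rule bootstrap + uncertainty loop, then a
random 500-sentence draw from everything the protocol labelled, mirroring
how the published comparison sampled from the collected training set), the
random arm by one-shot random sampling — train a fresh tagger per arm
(5 epochs, same seed both arms) and score it on a shared held-out test set;
10 runs with distinct seeds. Reported quantities are per-arm medians, the
median strict-F1 gain, and the labelled-set prevalences. On synthetic data
the gain's *direction* (selective ≥ random, driven by recall) and the
prevalence enrichment are the claims; the magnitude is reported for context
only, because the published absolute scores require the real corpus and a
fine-tuned transformer, both out of scope here.

## Numerical and degenerate-input choices

* Percentages are rounded to two decimals at the reporting boundary;
  internal arithmetic is double precision.
* Zero denominators (empty predictions, empty corpus) yield 0 with an
  `empty_input`/`undefined_pct` flag, never an error.
* Decoding ties (equal scores) resolve to the earliest label in the
  alphabet (`O` first), making untrained models predict all-O.
* All randomness flows through per-call seeds; library calls save and
  restore the caller's RNG state.
* Derived seeds are kept below 2^31 (R integers are 32-bit).
* Problem sizes used by the shipped experiments: 10,000 sentences for the
  codec/tokenizer property sweeps, 1,000 random pairs for the evaluation
  oracle, 200/1,500-sentence training sets for the tagger checks, and the
  5000-pool/500-budget/10-run active-learning experiment. These sizes give
  stable statistics in minutes on one CPU.

## Known limitations

* The shipped ruleset is a reconstruction of the *described* coverage of an
  expert rule set whose full listing is not public; it is not a copy, and
  no claim is made that its scores match the published rule-based scores.
* The linear backend is a reference model: strong enough to memorise and to
  expose every contract (uncertainty, chunking, serialisation), but it
  generalises lexically, not semantically. Transformer-scale scores on real
  corpora are explicitly out of scope; the encoder contract carries the
  recipe for plugging one in.
* The generator's prose is templated; models trained on it will not
  transfer to real text, and no pharmacological validity is claimed for the
  numeric values (units and ranges are cosmetic).
* The evaluation module implements the strict and partial schemes only;
  type-match variants of entity-level scoring are trivially addable but not
  claimed. IAA support is functional with no reference value to reproduce.
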