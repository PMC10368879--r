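---
title: "Methods: drug-ADE relation extraction and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-ADE relation extraction and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aderelex)
```

## The problem and the model

Adverse drug events (ADEs) — unintended harms attributable to a medication
— are documented mostly in the free text of clinical notes. Immune
checkpoint inhibitors (nivolumab, pembrolizumab, ipilimumab, ...) have a
characteristic toxicity profile (colitis, pneumonitis, hepatitis, rash,
thyroid abnormalities, ...), and oncology notes record those toxicities
with explicit causal phrasing ("colitis attributed to nivolumab") or mere
co-mention. `aderelex` frames ADE detection as binary classification of
**candidate relations**: every (drug mention, ADE mention) pair occurring
within one sentence is a candidate, labeled positive when the gold
annotation links exactly that pair and negative otherwise (the *derived
negatives*). The classifier sees only the **input span** — the sentence
substring from the earlier entity's start to the later entity's end — on
the premise that the text between a drug and an ADE carries most of the
relational context.

The scientific question the package operationalizes is
**generalizability**: does a classifier trained on one corpus (one
hospital's notes, one annotation guideline) keep its performance on
another? The `run_intra()` / `run_inter()` protocols implement the two
regimes: train/test within a corpus (stratified 5-fold cross-validation,
or a provider-defined fixed split), versus train on corpus A — reserving a
seeded stratified 30% as the internal validation split for model selection
— and test once on all of corpus B.

## Pipeline order is a contract

Cleaning (`clean_text()`) runs **before** tagging and annotation. This
ordering is load-bearing: because annotation happens on cleaned text, gold
character offsets never need remapping across the cleaning step, and the
synthetic generator can likewise inject whitespace noise only *outside*
entity surfaces and keep offsets exact. Any pipeline wiring that cleans
after annotating would break the offset invariants that the corpus reader
enforces (`surface == text[start, end)` for every entity).

Sentence segmentation is a bespoke protect/split/restore rule engine, not a
wrapped NLP toolkit. Substrings matching protected patterns (honorifics
"Dr.", dosing abbreviations "b.i.d.", decimals "1.5", numbered-list
markers) are masked with a placeholder byte chosen outside printable note
text; boundaries go after sentence-final `.?!` followed by whitespace and
at blank lines; offsets are reported against the original string so that
sentence spans partition the non-separator text. Two rules matter for
clinical text: a lone newline is **not** a boundary (notes wrap lines
mid-sentence), a blank line **is**. The shipped protected-pattern list is
illustrative, not a reconstruction of any production system's rules; users
can extend it per corpus.

## Tagging

Dictionary tagging is exact: case-insensitive, word-boundary,
longest-match-wins, ties to the leftmost start. No stemming or fuzzy
matching — in the human-in-the-loop workflow this pre-seeding emulates,
misspellings are the annotator's job. Dates are tagged by rules covering
`M/D/YYYY`, `M-D-YY`, `YYYY-MM-DD` and month-name forms, with guards so
decimals and version strings never match; the tagger deliberately emits a
generic `DATE` label because deciding whether a date is a *drug* date or
an *ADE* date requires relational context the tagger lacks.

The packaged lexicons list the eight checkpoint-inhibitor drugs
(generic + brand surface forms) and eight ADE groups. One reading note: the
published toxicity table wraps "Thyroid abnormalities" across two rows; we
ship eight groups by keeping thyroid abnormalities as one entry and
splitting the "myalgia/arthralgia" pair, which preserves both the count
and the clinical content. The enriched, hospital-specific surface-variant
table such studies build with clinician input is not public; the shipped
variants cover generic + brand names plus common clinical synonyms.

## Candidates, duplicates, degenerate cases

`enumerate_pairs()` emits the full |drugs| × |ADEs| cross product per
sentence in deterministic (drug start, ADE start) order. Positivity is
**entity-level**: if the same drug string appears twice in a sentence and
only one mention is annotated, the other mention's pairs stay negative.
Cross-sentence gold relations are preserved in the corpus objects but
contribute zero candidates — the classification scope is strictly
single-sentence, and the generator marks its planted cross-sentence
relations so tests can assert the exclusion.

Duplicate removal reflects the repetitive nature of EHR text: the dedup
key is the case-folded, whitespace-collapsed concatenation of (drug
surface, input span, ADE surface, containing sentence). "Context" is
defined as the full containing sentence — the smallest unit every model
actually sees. Identical keys with conflicting labels indicate
inconsistent gold and raise an error rather than silently keeping one.
Candidates whose drug and ADE spans overlap are kept but flagged
`degenerate` and excluded from training by default. Sentences with more
than 10 drugs or 10 ADEs warn (combinatorial guard) but are processed.

## Models and numerical choices

* **TF-IDF variant** (the naming alone underdetermines it): raw counts ×
  smoothed idf `ln((1+N)/(1+df)) + 1`, rows L2-normalized; vocabulary and
  idf always come from the rows being fitted, never from validation or
  test text.
* **Margin classifier**: RBF kernel on the TF-IDF rows. No kernel-SVM
  solver exists in the dependency footprint, so the soft-margin problem is
  solved in kernelized primal form with Pegasos (seeded permutation per
  epoch, hence bit-reproducible). Grid search over c ∈ {1, 10} × γ ∈
  {0.5, 1} by positive-class F1 on a 30% internal stratified split, then a
  refit on the full training portion. The grids are intentionally small —
  at desk scale the selection surface is flat — and user-overridable.
* **Tokenizer**: lowercase, split on everything non-alphanumeric, so
  "nivolumab-induced" yields "nivolumab", "induced".
* **Neural defaults**: trained embeddings of dimension 32, CNN filter
  widths {2, 3, 4} with 8 filters each, BiLSTM with 16 units per
  direction. The 300-dimension convention applies when a pretrained
  word-vector file is supplied (`load_embeddings()`; OOV policy zero or
  seeded random-normal); no pretrained weights ship with the package.
* **Training contract**: Adam, binary cross-entropy, dropout on the pooled
  / concatenated-terminal layer, early stopping on validation F1 with
  patience 3 — counted only after 5 epochs, because on imbalanced data the
  first epochs of an all-negative predictor would otherwise trigger the
  stop before any signal is learned; if validation F1 never exceeds zero
  the most-trained weights are kept, since a zero-F1 checkpoint carries no
  information. Hyperparameter value sets follow the studied search space
  (dropout in [0.1, 0.8]; learning rate in {0.1, 0.01, 0.001, 0.0001};
  batch size in {16, 32, 64}); package defaults are dropout 0.3, learning
  rate 0.01, batch 32, 20 epochs. Both backprop implementations are
  verified against numerical gradients in the test suite.
* **Decision threshold** is 0.5 on the sigmoid/calibrated score.
  Inverse-prevalence class weighting exists for the margin classifier but
  is off by default.
* **Epochs/optimizer** for the published experiments are unstated in this
  problem family; the defaults above are documented package choices, not
  reconstructions.
* **Transformers** are a registry plug-point only (`register_model()`):
  fine-tuning them requires downloaded pretrained weights, which this
  artifact deliberately excludes.

## Evaluation choices

Reported F is **positive-class** F1 — ADE detection is the minority
target, and macro-averaging would let the easy negative class mask
failures. Cross-validation pools confusion counts over folds (micro);
`pool = FALSE` switches to fold-mean F1. Stratified splits use the fixed
default seed 1218679, recorded in every report for provenance. Cohen's
kappa uses marginal-product expected agreement; when both raters are
constant on the same category, kappa is defined as 1. Pairwise-F agreement
matches entities by exact span + label and relations by exact
(type, argument-span-pair), so it is invariant to entity-id renumbering.
Cluster maps use Hamming distance on the binary correctness vectors with
average linkage — the published figures of this kind do not state their
clustering parameters, so these are package choices, stated once.

## The synthetic world

Real drug-ADE corpora cannot be shipped (clinical notes, data-use
agreements), so the generator *is* the test bed, and its defaults are a
stated world, chosen once:

* Notes are assembled from templated sentences: cue-bearing relation
  sentences ("Assessment: colitis attributed to nivolumab, plan
  steroids"), neutral co-mentions shared verbatim between cue-less
  positives and plain negatives, multi-entity sentences realizing the
  d1/d2/a1/a2 scenario (2 drugs × 2 ADEs, exactly one gold pair), fillers,
  drug-only and ADE-only sentences, and cross-sentence relation pairs.
* `signal_strength` s is the learnability dial: positives get a causal cue
  with probability s, negatives stay cue-free with probability s. Because
  cue-less positives and plain negatives draw from the *same* neutral
  template pool, s < 1 creates genuinely irreducible confusion, and s = 1
  makes the label a deterministic function of the template — which is why
  the acceptance suite can demand F1 ≥ 0.95 there.
* The positive:negative candidate ratio is hit by deterministic quota: a
  multi-entity sentence contributes 1 positive + 3 negatives, single
  co-mentions 1 of either; the mixture solves a small linear equation for
  the target ratio and errors out when infeasible (e.g. all-multi corpora
  force 1:3).
* Boilerplate: with probability `p_boilerplate_repeat` a relation sentence
  is a verbatim copy of an earlier one, gold structure included. Identical
  (whitespace-collapsed, case-folded) sentence text always carries
  identical gold — as a human annotator would label it — which is also
  what makes the dedup conflict error unreachable on generator output.
* Noise (double spaces, mid-sentence line wraps, brand-name surfaces,
  protected abbreviations in fillers) is injected only between template
  pieces, never inside an entity surface, so gold offsets remain exact by
  construction. 2% of relation sentences carry a 30+-token padding clause
  to exercise the long-sentence failure mode.
* Presets: `"ici-like"` (47 patients × 25–34 notes, target ratio 189:698 ≈
  0.271, sparse positives) and `"n2c2-like"` (505 single-note patients,
  25–40 sentences per note, target ratio 1355:865, and a fixed 303/202
  train/test document split carried into the dataset as a `split` column).
  Event rates were set so the candidate volumes land near those corpus
  sizes; the cue lexicon is a design choice, not a reconstruction of any
  hospital's phrasing.

What a green test **does** establish: offset arithmetic, parsing,
segmentation, enumeration, deduplication and protocol plumbing are exact
(they are checked against the generator's independent accounting), and the
models can recover a planted lexical signal and degrade when the cue
lexicons of two corpora diverge (`make_paired_corpora()` with
`cue_overlap` 0 vs 1 reproduces the intra-vs-inter degradation mechanism).
What it does **not** establish: performance on real clinical language —
templated sentences have none of the syntactic variety, negation,
speculation or discourse structure of actual notes, and published
F-scores on real corpora are expressly out of scope here.

One measured caveat: after deduplication the realized ratio drifts a few
percent above target when `signal_strength` is high, because cued positive
templates carry more variation slots (prefixes, dates, grades) than the
six neutral templates and therefore deduplicate less. The ±10% tolerance
absorbs this at the tested seeds; the drift direction is stable and
documented rather than patched, since the manifest — not the ratio — is
the accounting oracle.

## Known limitations

* Cross-sentence relation classification is out of scope (the generator
  plants such relations only so their exclusion can be asserted).
* The margin classifier is a subgradient solver, not an exact QP: with few
  epochs on tiny datasets its F1 can sit below the separability ceiling;
  the acceptance-scale settings are calibrated in the test suite.
* Concept normalization (UMLS/MedDRA), negation/uncertainty detection,
  de-identification and section detection are all out of scope.
* `read_brat()` collapses discontinuous spans to their envelope (flagged);
  fragment-level layout is not preserved on write.
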