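---
title: "Methods: an integrated NER-RE pipeline for adverse drug event extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrated NER-RE pipeline for adverse drug event extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task

Adverse drug events (ADEs) — harm related to medication use — are often
documented only in the free text of electronic health records. Finding them
automatically is conventionally decomposed into three stacked subtasks:

1. **Named entity recognition (NER).** Locate and type mentions of five
   clinical entity classes: *Finding*, *Drug*, *Disorder*, *Body structure*
   and *ADE cue* (a lexical indicator such as "side effect" that signals an
   ADE without naming the drug–reaction pair). Tokens are labeled under the
   BIO scheme, giving 11 tags: `O` plus `B-`/`I-` per class.
2. **Relation extraction (RE).** Classify the link between two entity
   mentions into *Indication* (Finding/Disorder → Drug), *ADE*
   (Drug → Finding/Disorder), *ADE outcome* (ADE cue → Finding/Disorder),
   *ADE cause* (Drug → ADE cue), or *No relation* — the catch-all for a
   permissible pair that carries none of the four.
3. **Note-level decision.** A note is flagged as containing an ADE when at
   least one extracted relation belongs to an ADE-indicating set.

`ademiner` implements this pipeline end to end in R, together with corpus
I/O for the two standard annotation formats (token-per-line CoNLL-BIO and
brat standoff), a seed-reproducible synthetic corpus generator, and the
full evaluation stack (precision/recall/$F_1$/$F_2$, micro/macro averages,
strict vs relaxed span matching, confusion matrices, term-level error
analysis).

## The permissible-relation schema

Candidate pairs are constrained by entity types. Writing $\{A,B\}$ for an
unordered type pair, the candidate label sets are

| type pair | candidate labels |
|---|---|
| {Drug, Finding}, {Drug, Disorder} | Indication, ADE, NoRelation |
| {ADE cue, Finding}, {ADE cue, Disorder} | AdeOutcome, NoRelation |
| {Drug, ADE cue} | AdeCause, NoRelation |

All other pairs (e.g. Drug with Body structure) are never candidates. The
schema has two consequences the pipeline inherits deliberately. First,
*No-relation instances are not annotated*: they arise at candidate
generation time, as permissible co-occurring pairs that carry no annotated
relation, and they dominate (roughly 92% of candidates on the default
synthetic corpus, mirroring the imbalance of real ADE corpora). Second,
*error propagation is structural*: an entity the NER stage misses or
mistypes either produces no candidates or falls outside the schema, so the
relations it participates in are unrecoverable downstream. This is why
end-to-end recall can only be bounded above by RE-on-gold-entities recall —
a property the test suite checks rather than assumes.

## Windowing choices

Long notes are processed in two different windows, both taken from standard
practice for encoder models with bounded input:

* **NER**: overlapping chunks of 128 tokens with stride 96. Where chunks
  overlap, each token keeps the prediction from the chunk in which it sits
  deepest from a boundary (ties to the earlier chunk). The rationale is that
  boundary tokens lack one-sided context; the merge rule is this package's
  own choice, as no canonical rule exists.
* **RE**: passages of 3 sentences with stride 1. Relations between entities
  rarely span more than three sentences, so a pair that never co-occurs
  inside any passage is not a candidate (the generator likewise never emits
  a relation joining entities more than two sentences apart). A pair
  co-occurring in several overlapping passages yields exactly **one**
  candidate, attached to the passage where the pair sits most centered
  (ties to the earliest passage); deduplication prevents the same pair from
  being counted several times in training and evaluation.

A candidate is rendered as the passage text with the two mentions wrapped
in `[E1]…[/E1]` and `[E2]…[/E2]` markers, truncated symmetrically around
the pair if it exceeds the 512-token input bound.

Directionality is handled by the classifier, not the candidate: pairs are
presented in document order, and the predicted label implies the semantic
direction (e.g. for *ADE* the Drug argument is the source). This matches a
single 5-way classifier over unordered pairs; the alternative — directed
candidate duplication — would double the majority class for no gain.

## The encoder backend

The package is written against a pluggable encoder contract: anything that
maps sparse feature bags to class scores and supports gradient fitting can
serve both stages. The default backend is a deliberately small trainable
model so that the whole pipeline fits in seconds-to-minutes on one CPU:

* an embedding layer over categorical features, mean-pooled into a tanh
  hidden state, followed by a softmax output layer;
* for NER, the features of a token are the word identities at relative
  offsets $-2\dots 2$ inside its chunk (a bidirectional context window);
* for RE, the features are the entity type pair, the tokens strictly
  between the two markers, and a bucketed pair distance. Mention word
  identity is deliberately **not** a feature: the label depends on the type
  pair and intervening context, and memorizing mentions does not transfer.
* training uses minibatch Adam with decoupled weight decay, global-norm
  gradient clipping, hidden-layer dropout, and patience-based early
  stopping on validation loss with best-weights restore.

The reference configurations carry the full-scale fine-tuning
hyperparameters (NER: batch 128, dropout 0.1, learning rate 5e-5, gradient
accumulation 3, clipping 1.0, patience 1600 steps, weight decay 0.01; RE:
batch 32, up to 50 epochs, patience 3 epochs, learning rate 2.575e-5,
cross-entropy, weight decay 1e-4). Those learning rates are tuned for
fine-tuning a large pretrained transformer; training the lightweight
backend *from random initialization* uses the same machinery with a
desk-scale schedule — learning rate 0.02/0.1, embedding dimension 24/32,
15–60 epochs — which is what the tests and the acceptance script use. A
pretrained clinical transformer is a drop-in replacement behind the same
fit/predict surface at full scale; no claim is made that the lightweight
backend reproduces transformer-grade accuracy on real clinical text.

## The synthetic corpus generator

Real ADE-annotated clinical corpora cannot be distributed, so every stage
is exercised on a generated stand-in that emulates the *statistical and
structural* properties the pipeline depends on, with pseudo-Swedish
template filler in place of clinical language:

* entity-class proportions 0.35 / 0.29 / 0.20 / 0.12 / 0.04
  (Finding / Drug / Disorder / Body structure / ADE cue);
* 23% of entity mentions are multiword ("compound") instances;
* a mean of 14 sentences per note (Poisson, floored at 3);
* 62% of notes contain at least one explicit ADE-flavored relation;
* relations join entities at most two sentences apart and are always
  schema-permissible; notes drawn ADE-negative carry only Indication
  relations, and ADE-positive notes are guaranteed at least one relation
  from {ADE, AdeCause, AdeOutcome}.

Within a sentence, entity classes are drawn i.i.d. from the configured
weights; adjacent permissible pairs are then realized as relations with
probability `relation_attach_prob` (default 0.5, chosen so that the
candidate set is NoRelation-dominated at roughly the 92% level) by
inserting a relation-class-specific trigger word between the two mentions.
When both Indication and ADE are available for a {Drug, Finding/Disorder}
pair, Indication is drawn with probability 0.6, echoing the
Indication-heavy mix of annotated relations in real corpora. A fraction of
relations (`cross_sentence_rate`, default 0.15 per sentence boundary)
crosses one sentence boundary so the passage logic is exercised.

By default the generator runs in **separable mode**: per-class vocabularies
(heads, modifiers, fillers, triggers) are pairwise disjoint, so a small
encoder can in principle solve the task exactly. Setting
`lexical_overlap_rate > 0` shares the configured fraction of ADE-cue head
terms with the Disorder vocabulary, qualitatively reproducing the
cue/disorder/finding surface-form ambiguity that drives confusion in real
clinical text.

What the generator does **not** model: negation, speculation and
temporality; Swedish morphology and compound splitting; ICD-code-driven
note sampling; annotator disagreement; any realistic lexical distribution.
Passing tests on this corpus therefore demonstrate that the pipeline
machinery is correct and that the models can recover a learnable signal —
not that comparable scores would be reached on real notes.

## Evaluation

* **Token-level NER report**: predictions are converted back to BIO tags,
  collapsed to entity categories (`B-X`/`I-X` → `X`, `O` → Other);
  per-class P/R/$F_1$/$F_2$ are computed for the five entity classes, macro
  over those five (Other excluded), micro over their pooled counts. An
  entity-level report via span matching is also available.
* **Strict vs relaxed matching**: strict requires identical class and token
  range; relaxed requires identical class and at least one shared token
  (the direct formalization of "at least one word of a multiword entity was
  found"). Matching is one-to-one and greedy by decreasing overlap with
  positional tie-breaks; an exhaustive optimal-assignment oracle backs this
  in the tests at small sizes. Strict true positives are a subset of
  relaxed ones, so strict $F_1 \le$ relaxed $F_1$ always — checked as a
  property over random perturbations.
* **Relation scoring**: a predicted relation is a true positive iff a gold
  relation of the same label joins the gold entities matched to its two
  arguments (direction respected). Because the natural macro scope is
  debatable when a dominant NoRelation class exists, both macros are
  reported: over the four primary classes, and over all classes that occur.
* **$F_\beta$**: $(1+\beta^2)PR/(\beta^2 P + R)$, defined as 0 at
  $P = R = 0$. $F_2 \ge F_1$ exactly when $R > P$.
* **Note level**: binary report over ContainingADE / NoADE with macro
  average. The default ADE-indicating set is {ADE, AdeCause, AdeOutcome} —
  the two incomplete-information classes still indicate that an adverse
  event occurred — but the set is configurable down to {ADE}, since either
  reading of "at least one ADE relation" is defensible.

## Numerical and degenerate-input choices

* Corpus splitting is 70/10/20 by note, computed as: test =
  round(0.2·N), validation = round(0.1·N) (half-up), train = remainder
  (395 notes → 276/40/79). The assignment is a seeded permutation.
* `repair_bio` coerces model output to BIO validity (`I-X` without a valid
  predecessor becomes `B-X`); it is idempotent and the identity on valid
  sequences, so evaluation never sees an unparseable tag sequence.
* brat character spans map to the minimal covering token span, which is
  robust to whitespace drift; tokenization itself is always taken from the
  input file and never re-derived.
* Entity classes with spaces in prose serialize with underscores in tags
  and standoff files (`B-Body_Structure`, `ADE_Cue`), since
  whitespace-delimited formats cannot carry internal spaces.
* All randomness (generation, splitting, initialization, batch shuffling,
  dropout) is seeded; identical configurations reproduce bit-identical
  corpora, splits and training curves under single-threaded execution.
* Grid search trains one model per configuration and selects the highest
  validation macro-$F_1$ (ties to the first grid entry); the selection
  metric is this package's choice, as grid search per se does not fix one.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the full pipeline on a 500-note
separable corpus (≈ 10,000 entities, ≈ 12,000 candidates) with the
70/10/20 split and the desk-scale schedules above; format round trips are
checked on the same 500 notes, the BIO bijection exhaustively over all
valid tag sequences of length ≤ 5, metric implementations against
brute-force counting oracles on 20-note corpora, and matching monotonicity
over 100 perturbed prediction sets. At these sizes the models reliably
reach per-class entity $F_1 \ge 0.95$ (NER, strict) and primary-class
macro $F_1 \ge 0.90$ (RE) on the held-out split — the skill-recovery bar
the package sets for itself on separable synthetic data.

## Known limitations

* The default encoder is a bag-of-context model: it cannot express
  long-range agreement or subword morphology, and in overlap mode its
  ceiling is well below a pretrained transformer's.
* Discontinuous and overlapping entities, brat events/attributes, n-ary
  and cross-note relations are out of scope.
* Gold relations spanning more than three sentences would be silently
  uncapturable by design; the generator never emits them, and candidate
  generation warns when an entity cannot fit any passage.
* The note-level rule is presence-based only; negation, speculation or
  attribution of the relation mention would require upstream modeling that
  is deliberately not attempted here.
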