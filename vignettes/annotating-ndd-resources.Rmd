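---
title: "Annotating NDD web resources and ranking them from a knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating NDD web resources and ranking them from a knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndkg)
```

## The problem and the pipeline

Web resources about neurodevelopmental disorders are scattered, use
inconsistent terminology, and mix clinical, educational, service and
funding content. `ndkg` annotates a corpus of cleaned page texts with
four kinds of structure — controlled-vocabulary entities, topics,
categories and locations — and assembles everything into one weighted
property graph that supports free-text ranked retrieval.

The stages are independent modules behind one wrapper,
`annotate_corpus()`:

1. **Preprocessing** — punctuation removal (hyphens split words),
   lowercasing, whitespace tokenization, lemmatization, stop-word
   removal. One stop list serves both entity matching and topic
   modeling; corpus-specific additions are merged via
   `ndkg_stopwords(extra)` or a stop-list file.
2. **Dictionary NER** — vocabulary surface forms are preprocessed with
   the *same* lemmatizer and matched exactly on lemma sequences,
   longest-match first, left to right, spans consumed.
3. **Relevance** — pivoted unique normalization of logarithmic term
   frequency.
4. **Hierarchical topic modeling** — recursive online-VB LDA.
5. **Classification** — 5-category multilabel model and a 10-way query
   intent model.
6. **Locations** — postal-code regular expressions plus gazetteer names,
   turned into proportional weights.
7. **Graph assembly and export**, then **OWA retrieval**.

## Model assumptions

*Entity relevance.* The weight
`(1 + log tf) / ((1 − slope)·pivot + slope·dl)` assumes that (a) repeated
mentions signal relevance with diminishing returns (hence the log), and
(b) a document's propensity to mention *many distinct* entities should
not inflate each mention's importance (hence normalization by distinct
entity count `dl`, pivoted at the collection mean). `slope` defaults to
0.2, the classical pivoted-normalization setting; `pivot` is computed
once per collection (documents with zero entities included in the mean)
and stored in the graph manifest so that incremental additions can reuse
it. The logarithm is natural by default and base-10 on request; every
monotonicity property holds for either.

*Topics.* LDA assumes exchangeable bags of words. The hierarchical
scheme further assumes that a hard dominant-topic assignment is a
reasonable partition of documents — adequate when mixtures are peaked,
lossy when documents genuinely straddle topics. Only the lowest level of
the hierarchy reaches the graph, on the grounds that recursive re-fitting
inside large topics yields more specific, better-separated word lists
than one flat fit.

*Classification.* The five categories are treated as independent binary
problems with sigmoid outputs; a document may hold several labels or
none. The reference backbone is a linear bag-of-words scorer — the
protocol under test (epoch selection on validation macro F1 at threshold
0.5, *then* an 11-point threshold grid search) is backbone-independent,
and a linear model keeps the whole path bit-reproducible on one CPU. The
transformer fine-tuning recipe (dropout 0.3, AdamW at 3e-4 with warm-up
and cosine decay, betas 0.9/0.95, eps 1e-8, weight decay 0.01, batch 64,
gradient clipping at 1.0, 20 epochs, binary cross entropy) is preserved
verbatim in `classifier_config()` for deployments with a deep-learning
runtime; selecting it here raises a clear error.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `slope` | 0.2 | length-penalty strength; 0 disables length dependence |
| `pivot` | collection mean | distinct-entity count of a "neutral" document |
| `K0` | corpus-size proportional (200–300 at 10^5-page scale) | root topic count |
| `threshold` | 300 docs | topic size that triggers recursive re-modeling |
| `K_child` | `max(2, ceil(n/threshold))` | child topic count; keeps expected leaf size near the threshold and guarantees the recursion shrinks |
| depth cap | 10 | last-resort bound on pathological corpora |
| sparsification floor | 1e-3 | minimum θ, φ, θ·φ weight materialized as an edge; dense products at scale are infeasible and tiny weights are noise; configurable down to 0 |
| LDA | 10 passes, decay 0.7, offset 10, batch 128, priors 1/K, ≤50,000 features | the pinned online-VB configuration |
| `n_init` | 3 | LDA restarts; best in-sample token log-likelihood wins |
| classifier split | 80/10/10 | iterative stratification, exact overall sizes |
| threshold grid | 0.0–1.0 step 0.1 | exactly 11 candidates; ties go to the lowest threshold |
| MOST quantifier | (a, b) = (0.3, 0.8) | classical piecewise-linear "most"; SOME uses (0, 0.5) |

## Numerical and design choices

**Relevance denominator.** Implemented as
`pivot + slope·(dl − pivot)` — algebraically identical to
`(1 − slope)·pivot + slope·dl` but exact in floating point at
`dl = pivot`, where the normalization factor must equal the pivot.

**Lemmatization.** A dictionary-based English lemmatizer (irregular-form
table, then suffix rules for plural/-ing/-ed with silent-e restoration
and consonant de-doubling validated against a base-form dictionary). It
is deliberately conservative and, crucially, *idempotent* and *shared*
between documents, lexicon surfaces, gazetteer names and queries: what
matters for matching is that both sides land on the same lemma, not that
the lemma is linguistically perfect.

**LDA initialization and restarts.** Online VB is multimodal. Topics are
initialized from a random partition of the documents (gamma noise plus
scaled partition counts), which breaks symmetry with real co-occurrence
structure; training E-steps keep random gamma initializations as
annealing noise; the final inference E-step uses a constant
initialization so that *identical documents receive identical topic
assignments*. `fit_lda()` runs 3 restarts and keeps the highest
in-sample token log-likelihood — merged-topic optima sit far below good
ones on that score, so the selection is sharp. Everything is
deterministic given the seed; hierarchy children derive their seeds from
the parent's.

**Degenerate inputs.** A corpus of identical documents collapses into a
single topic under the deterministic final E-step; the recursion then
detects that the child would equal the parent's entire document set and
flags the topic as a no-progress leaf rather than looping. Documents
with no in-vocabulary tokens keep an all-zero count row and receive a
uniform topic mixture. Empty token streams, empty mention sets and
entity-free corpora are all defined (the last is an error for the pivot,
which would be 0/0).

**Ties.** Dominant topic: lowest index. Threshold grid: lowest
threshold. Ranking: ascending document id at equal scores. Count-matrix
vocabulary: lexicographic at equal frequency. All chosen for determinism.

**Graph schema.** Twelve node types and nine relations are implemented —
the enumerated sets, which the prose summary counts slightly differently
(11/8). Topic→unigram `describedBy` edges carry the φ weight: the source
describes these weights explicitly even though an earlier list calls the
relation unweighted; the weighted reading is the only self-consistent
one. `IS_ASSOCIATED_WITH` (same canonical term under two vocabularies)
has no stated formula; its weight here is the number of resources in
which the term is detected under both vocabularies — a deterministic,
testable relevancy proxy. Resource→Category membership is emitted as a
weighted `CONTAINS` edge carrying the classifier probability. The ten
challenging-behavior graph nodes are the *categories*; phrase-level
mentions are collapsed onto their category before counting
(`collapse_behavior()`). Age nodes are the fixed set child/teen/adult,
weighted like other entities. Document text is not stored in the graph;
the corpus file remains the text store.

**Retrieval.** A query criterion with no node anywhere in the graph is
dropped with a notice; a *candidate* missing an edge to an existing
criterion node contributes 0 to its value vector rather than shrinking
the vector — vectors stay comparable across candidates, and MOST then
softly penalizes partial matches. Weight families (entity relevance,
θ·φ, behavior) are aggregated on their native scales by default; an
optional per-family min-max rescaling to [0, 1] exists (`rescale =
TRUE`) for corpora where the families' magnitudes diverge. Zero-support
categories score F1 = 0 (not skipped) in macro F1 — conservative and
deterministic.

**Exports.** Bulk CSVs write weights with 17 significant digits, so the
round trip is exact. N-Triples reify weighted edges as `rdf:Statement`
resources with a `weight` literal; GraphML goes through igraph.

## What the synthetic generator emulates — and what it does not

`generate_all()` produces, from one config and seed: vocabularies with
planted cross-vocabulary canonical overlaps (vocabulary-specific surface
forms, like synonyms), ten challenging-behavior categories with two
phrases each, age terms, a fictional-place gazetteer, and a corpus in
which every document draws a topic mixture from a Dirichlet
(concentration 0.1 — peaked, mostly single-topic documents) over
disjoint Zipf-weighted topic vocabularies, injects entity *surface
forms* (pre-lemma, so the full NER path including lemmatization is
exercised), appends per-label marker tokens, and embeds postal codes and
city names. Ground truth (mixtures, per-entity counts, labels,
locations) is recorded at generation time. Label frequencies follow a
strongly services-heavy skew with rare financial-help and other
categories, mirroring the imbalance such hand-labeled sets show in
practice.

The default scales — 300–500 documents, vocabularies around a hundred
terms, mean document length 80 tokens — run the entire suite in about a
minute on one CPU.

What passing on these fixtures shows: the formulas, the matcher, the
recursion, the protocol and the graph assembly are implemented
correctly, and planted structure is recovered when it is recoverable.
What it does not show: performance on real scraped text, where entity
surface forms are inflected and ambiguous beyond this lemmatizer,
category signals are not marker tokens (the linear classifier's F1 ≥ 0.9
on separable fixtures says nothing about real-data F1), topic
vocabularies overlap heavily, and false-positive locations occur (no
filtering beyond gazetteer membership is applied, since no principled
rule is available).

## Known limitations

- Pivoted unique normalization over-penalizes documents far longer than
  the pivot; co-occurrence-aware relevance (the `OCCURRED_TOGETHER`
  edges are already in the graph) is the natural extension.
- The dominant-topic hard assignment discards mixture information when
  recursing; leaf-local θ is used for `belongsToTopic` rather than a
  globally renormalized weight.
- Retrieval is exact keyword matching in lemma space; no query
  expansion or semantic search.
- The intent classifier is trained on behavior-lexicon phrases; its
  contract (text → category distribution, argmax with lowest-index
  ties) is what the pipeline relies on.
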