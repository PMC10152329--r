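# ndkg

Weighted knowledge-graph construction and ranked retrieval for corpora of
web resources on neurodevelopmental disorders (NDDs: autism spectrum
disorder, intellectual disability, ADHD). Families and clinicians looking
for NDD information face thousands of scattered web pages with no shared
terminology; `ndkg` turns a corpus of cleaned page texts into a typed,
weighted knowledge graph that can be queried with free text and returns a
relevance-ranked list of resources.

The package is aimed at researchers building consumer-health resource
repositories: it takes cleaned plain-text documents (scraping and
boilerplate removal happen upstream), controlled-vocabulary term lists
standing in for UMLS / HPO / ERIC / AIRS, an offline gazetteer, and an
optional hand-labeled subset, and produces a property graph plus a query
interface — all offline and fully seeded.

## The model

**Entity relevance (pivoted unique normalization).** Dictionary-based NER
matches lemmatized vocabulary phrases in each document. An entity with
term frequency *tf* in a document containing *dl* distinct entities gets
the weight

    relevance(tf, dl) = (1 + log tf) / ((1 − slope) · pivot + slope · dl)

where *pivot* is the collection-average number of distinct entities per
document and *slope* = 0.2. At *dl* = *pivot* the normalization factor is
exactly the pivot; entity-richer documents are penalized, sparser ones
rewarded. These weights label the graph's `CONTAINS` edges.

**Hierarchical topic modeling (HTM).** Online variational-Bayes LDA
(10 passes, learning decay 0.7, batch 128, ≤50,000 features) is fitted to
the corpus; every document is hard-assigned to its dominant topic, and
any topic holding more than a threshold number of documents (300 by
default) is recursively re-modeled. Recursion stops at the threshold, on
no progress (a topic swallowing its whole node), or at a depth cap. Only
leaf topics enter the graph: θ weights label `belongsToTopic`, φ weights
label `describedBy`, and the product θ·φ labels `containsNgram`
resource–unigram edges.

**Classification.** A multilabel classifier scores each resource on five
categories (financial help, education, services, core knowledge, other)
with sigmoid outputs; the epoch is selected on validation macro F1, then
the decision threshold is tuned on an 11-point grid (0.0–1.0, step 0.1).
A 10-way intent classifier maps verbose queries ("my child hits other
children at school") to a challenging-behavior category.

**Locations.** Canadian/US postal codes (regular expressions, resolved by
forward-sortation-area prefix or ZIP against an offline gazetteer) and
gazetteer place names yield proportional per-document city and province
weights on `isLocatedIn` edges.

**Retrieval (OWA).** A query is parsed into criteria — lexicon entities,
topic-vocabulary unigrams, and the intent category. Every resource
adjacent to at least one criterion node is scored by ordered weighted
averaging: values sorted descending, dotted with weights derived from a
RIM linguistic quantifier (`w_i = Q(i/n) − Q((i−1)/n)`; MOST with
breakpoints (0.3, 0.8) by default, SOME/ALL/AT-LEAST-n/identity also
available).

## Worked example

```r
library(ndkg)

corpus  <- load_corpus("corpus.jsonl", "jsonl")   # three demo documents
lexicon <- read_lexicon(system.file("extdata", "synthetic_lexicon.csv",
                                    package = "ndkg"))
gaz     <- read_gazetteer(system.file("extdata", "synthetic_gazetteer.csv",
                                      package = "ndkg"))

ann <- annotate_corpus(corpus, lexicon, gazetteer = gaz,
                       K0 = 2, threshold = 300, lda_cfg = lda_config(seed = 1))
ann$graph
#> <ndkg_graph> 63 nodes, 267 edges
#>   nodes: Age=1 AIRS=3 ChallengingBehavior=2 City=2 EricTerm=2 HPO=2
#>          Province=1 Resource=3 Topic=2 UMLS=2 Unigram=43
#>   edges: belongsToTopic=3 CONTAINS=14 containsNgram=129 describedBy=86
#>          inProvince=2 isLocatedIn=5 OCCURRED_TOGETHER=28

intent <- intent_model_from_lexicon(lexicon)
res <- rank_resources(ann$graph, "aggressive behavior and kicking and spitting",
                      ann$lexicon, intent = intent, top_n = 3)
attr(res, "terms")$behavior_category
#> [1] "behavioral concerns"
res[, c("url", "score")]
#>                                    url       score
#> 1 https://example.org/aggression-guide 0.045415382
#> 2          https://example.org/funding 0.008692610
#> 3       https://example.org/sleep-help 0.008566703
```

The query matched the UMLS entity *Spitting*, two challenging-behavior
phrases (collapsed onto the category *behavioral concerns*), and the
intent classifier confirmed the category; OWA aggregation of the edge
weights puts the aggression guide first. `export_graph()` writes the
graph as bulk-import CSVs, N-Triples, or GraphML; `generate_all()`
produces complete seeded synthetic fixtures (corpus, lexicons, gazetteer,
labels, ground truth). A thin command line sits at `inst/cli/ndkg.R`
(`synth`, `annotate`, `query` subcommands).

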