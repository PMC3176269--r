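---
title: "Knowledge-based disambiguation and concept-graph summarization: methods"
author: "wsdsumm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based disambiguation and concept-graph summarization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsdsumm)
```

## The problem

Biomedical text is dense with ambiguous surface terms: *cold* may denote a
common cold, a low temperature, or a sensation, each a distinct concept
(CUI) in a UMLS-style Metathesaurus.  Any pipeline that maps text onto
concepts must pick one candidate per phrase, and downstream consumers —
here, an extractive summarizer that reasons over a concept graph — inherit
whatever the mapper decides.  This package implements three unsupervised
word-sense-disambiguation (WSD) methods that need no manually annotated
training data, a graph-based single-document summarizer that consumes
their decisions, ROUGE evaluation, and a deterministic synthetic world in
which every moving part can be exercised without licensed resources
(UMLS releases, MetaMap, MEDLINE) at desk scale.

## The knowledge base

A `knowledge_base` holds concepts (CUI, preferred name, synonyms,
semantic types, definitions), `is_a` and `other_related` relations, and
symmetric semantic-type associations.  Lookup goes through a normalized
term index (lowercase, boundary punctuation stripped, whitespace
collapsed); a full lexical-variant mapper is deliberately out of scope, so
normalization is deterministic and reproducible.  A concept with several
`is_a` parents follows the lexicographically smallest parent CUI when a
single hypernym chain is required — the methods assume one hierarchy per
concept and no principled rule exists, so the tie-break is fixed for
determinism.  `is_a` cycles are rejected at load time.

The native serialization is a four-file TSV dialect (`concepts.tsv`,
`terms.tsv`, `relations.tsv`, `st_associations.tsv`) that round-trips
exactly; a best-effort RRF reader (`MRCONSO`/`MRSTY`/`MRDEF`/`MRREL`) is
included for users holding a UMLS license and is not exercised by the
test suite.

## MRD: concept profiles against the context

For an ambiguous word $w$ with candidate concepts $C_w$ and context
vector $cx$, the machine-readable-dictionary method selects

$$\mathrm{MRD}(w) = \arg\max_{c \in C_w} \frac{\vec c \cdot \vec{cx}}{|\vec c|\,|\vec{cx}|}.$$

A candidate's profile $\vec c$ is built from its definitions, synonyms,
and the synonyms and definitions of directly related concepts (`is_a`
parents and children, `other_related` neighbours) — **excluding
siblings**, which share a parent without being related directly.  Both
profile and context are lowercased, stop-listed, Porter-stemmed bags of
words.  Profile weights are tf × icf, where the *inverted concept
frequency* down-weights words spread over many concepts.  The literature
names this quantity without fixing a formula, so the package fixes the
smoothed, strictly positive form

$$\mathrm{icf}(t) = \log\frac{1 + N}{1 + n_t} + 1,$$

with $N$ the number of concepts and $n_t$ the number of concepts whose
profile sources contain $t$: a word in every concept gets weight 1, never
0, so profiles built entirely from ubiquitous words still rank.
All-zero similarities (and exact ties) resolve to the smallest candidate
CUI; cosine of a zero vector is defined as 0, never NaN.

The Porter stemmer is implemented in full (the classic 1980 rule set)
because no stemming library is available to the package's dependency
footprint; the test suite pins it to the algorithm's published per-step
examples.  The stop list is a packaged ~130-word English list,
replaceable by file wherever preprocessing happens.

## AEC: pseudo-corpora from monosemous relatives

The automatic-extracted-corpus method trains a classifier per ambiguous
term without manual annotation.  For each candidate sense it builds a
boolean title/abstract query from *monosemous relatives*: synonyms of the
candidate linked to no other concept, OR-joined as quoted phrases, plus
conjunctions of the ambiguous term with monosemous terms of directly
related concepts (one sense per collocation).  Terms longer than 50
characters, shorter than 3, pure numbers and stop words are filtered out;
the `[tiab]` field tag restricts matching to titles/abstracts.  If a
query retrieves nothing, a fallback expression replaces the quotes with
parentheses so the words may match in any position.  Up to 100 documents
per concept (configurable) are labeled with the query's CUI.

Retrieval is abstracted behind a searcher interface: the packaged
implementation is an offline boolean search over an in-memory corpus
(quoted phrase = contiguous token run; fallback = all words anywhere), so
tests and the synthetic world never touch a network service.  Any
function with the same signature can be substituted for a live client.

The classifier is a multinomial naive Bayes over preprocessed bags of
words with add-one smoothing — written here because the installed
ecosystem offers Gaussian/categorical variants only — with document-count
priors.  Out-of-vocabulary context words are ignored at prediction;
candidates with no retrieved documents are excluded with a warning, and
ties again resolve to the smallest CUI.  The feature set (unigram bag)
and smoothing constant are package choices; the method description names
naive Bayes without fixing either.

## JDI: semantic types through journal descriptors

Journal-descriptor indexing scores *semantic types* rather than concepts:
the context is indexed against per-descriptor word-probability vectors
(cosine), the resulting per-descriptor score vector is compared with each
type's pre-computed descriptor indexing, and the candidate carrying the
top-ranked type wins.  Training descriptor vectors from literature
citations requires a citation corpus and is out of scope: a `jd_model` is
an input, loadable from JSON or generated synthetically.  The method
abstains — by construction, not by failure — whenever all candidates
share an identical semantic-type set, when the context is empty, or when
it loads on no descriptor.  Abstentions count as errors in the accuracy
metric (the denominator is all instances), and evaluation also reports
the *JDI subset* with shared-type instances removed, the only terrain on
which the method can compete.

## The summarizer

Four steps per document:

1. **Concept identification.**  A greedy longest-match dictionary mapper
   scans each sentence against the term index — standing in for a full
   lexical mapper, whose role is exactly to emit candidate CUI sets per
   phrase; externally produced candidate mappings can be injected from
   JSON instead.  Unambiguous phrases are accepted; ambiguous ones are
   resolved by the configured WSD method with the sentence as context
   (the natural context unit at summarization time), or by
   `first_mapping` — the smallest candidate CUI, i.e. no disambiguation —
   as baseline.  Concepts all of whose semantic types are in the
   generic-type filter (quantitative/qualitative/temporal/functional
   concepts, ideas, intellectual products, mental processes, spatial
   concepts, language) are discarded as too broad to carry topic.
2. **Document representation.**  Each sentence's concepts are extended
   with their full hypernym chains, merged, and the two upper hierarchy
   levels (depths 1–2, root = depth 1) are removed; retained vertices
   keep their original depths, so an `is_a` edge from parent at depth
   $d_p$ to child at depth $d_c$ weighs $d_p/d_c \in (0,1]$ with no
   division by zero.  Sentence graphs merge into a document graph,
   extended with `other_related` edges between co-present vertex pairs
   and `associated_with` edges between *leaf* vertices with associated
   types — the stated applicability of the weight-1 rule — both at weight
   1.  When a pair is already joined by an `is_a` edge no parallel edge
   is added (a simple graph; multi-edges are not specified).  Vertex
   salience is the sum of incident edge weights.
3. **Topic recognition.**  The $n = \max(1, \lceil 0.1\,|V|\rceil)$
   highest-salience vertices become hubs (the hub count is not specified
   in the literature; it is exposed as `hub_fraction`, default 0.1).
   Connected components of the hub-induced subgraph are the hub vertex
   sets (HVS), the cluster centroids.  Remaining vertices attach, in
   descending salience with ties to the smaller CUI, to the cluster whose
   current members they are most strongly connected to, with live
   membership updates; passes repeat until nothing more can attach —
   "iteratively" does not choose between one pass and a fixed point, and
   the fixed point lets chain-connected vertices join deterministically.
   Vertices connected to no cluster stay unassigned.  Clustering runs
   once per document.
4. **Sentence selection.**  Non-democratic voting: a sentence vertex
   casts 1 vote to a cluster containing it in the HVS, 0.5 if it is a
   non-HVS member, 0 otherwise (vertices are counted as sets; duplicate
   mentions do not multiply votes).  The sentence score is
   $\sum_i \mathrm{sim}(C_i, S_j)/|C_i|$.  Sentences are taken in
   descending score (ties to the earlier sentence) until the summary
   first reaches `compression` (default 0.30) times the document size —
   word count by default, robust to heterogeneous sentence lengths;
   sentence-count mode is available — and returned in document order.

The *common mapping agreement* of two runs is the fraction of phrase
occurrences with more than one candidate on which both chose the same
concept, the quantity that links disambiguation agreement to summary
similarity.

## ROUGE

`rouge_n` is recall with clipped counts: matched n-grams (each reference
n-gram credited at most its peer count), summed over references, divided
by total reference n-grams; no jackknifing.  `rouge_su` uses skip-bigrams
— ordered pairs with at most `skip` (default 4) intervening words — plus
unigrams, the standard "SU" unit set; the unigram component can be
disabled.  Tokenization lowercases and splits on non-alphanumerics, with
optional stemming and stop-listing, off by default since the metrics'
preprocessing is not fixed by their definition.  References shorter than
the unit size are skipped with a warning; if none remain the metric is
undefined and an error is raised rather than a silent 0.

## The synthetic world

The generators produce, deterministically per seed: a knowledge base
with an `is_a` forest (default depth 4, level sizes growing with depth,
round-robin parents), six disjoint coded words per concept (two two-word
synonyms + a definition — coded tokens make separability exactly
controllable, which matters more here than surface realism), specific
semantic types cycling over UMLS-style labels, a few generic-typed
concepts to exercise the filter, `other_related` edges and type
associations; ambiguous terms attached to `senses_per_term` concepts;
WSD datasets; a planted-topic corpus with references; a pseudo-literature
corpus for AEC; and an orthogonal descriptor model (one descriptor per
type, supports disjoint by construction, one-hot type indexing).

Design points worth knowing:

* **Separability.**  A context word comes from the gold sense's
  vocabulary with probability $s$, otherwise from the confusion pool —
  the union of all the term's sense vocabularies.  At $s=0$ contexts
  confuse the senses symmetrically, so accuracy equals chance ($1/k$)
  exactly in expectation; at $s=1$ contexts are pure gold vocabulary and
  the context-aware methods are perfect.  Because all word draws are
  made under one seed regardless of $s$, datasets across an $s$-grid are
  coupled: raising $s$ flips pool words to gold words at fixed positions,
  which makes accuracy-versus-$s$ monotone in practice rather than only
  in expectation.
* **Adversarial first sense.**  Each term's lexicographically smallest
  candidate is a shallow decoy — no hypernyms, generic semantic type —
  so `first_mapping` resolves planted topic terms to a concept that the
  generic filter (or the two-level trim) removes from the graph, while
  MRD/AEC/JDI can recover the deep gold sense from context.  With
  `type_overlap = TRUE` all senses share one specific type instead,
  making every term JDI-ineligible.
* **Planted topics.**  A document's topic is a connected subgraph (deep
  gold sense, its parent, the parent's other children).  Topic sentences
  (30% of the document) carry the ambiguous term, two topic synonyms and
  scattered gold-vocabulary words; *imposter* fillers repeat the topic
  synonyms without the ambiguous term, so they tie with a topic sentence
  exactly when the disambiguated sense is lost; noise fillers mention
  shallow off-topic and generic-typed concepts whose trimmed chains stay
  isolated.  All sentences have equal token counts, so at compression
  0.30 a perfect system recovers exactly the topic sentences and the
  reference summary equals their concatenation.

What the fixtures do **not** emulate: lexical variation (inflection,
spelling variants, nested phrases), MetaMap-style candidate scoring,
realistic MEDLINE word statistics, citation-scale contexts with topical
drift, or reference summaries written in different words than the
document (synthetic references are extracts, so ROUGE values near 1 are
attainable by construction).  Passing tests therefore demonstrate the
algorithms' contracts and their interaction — not field performance on
real corpora, which requires the licensed resources.

## Problem sizes and numerical choices

The test suite and the acceptance script run the package at sizes chosen
to make sampling error negligible relative to the effects measured: 500
instances per WSD accuracy estimate (3σ of a chance-level estimate
≈ 0.067), a grid $s \in \{0, 0.25, 0.5, 0.75, 1\}$, 20 planted-topic
documents of 10 sentences, 500 random instances against the sense-choice
oracle and 200 random token pairs against the ROUGE counting oracle,
and ~100 generated document graphs for the structural invariants.  A full
run completes in well under a minute on one core.

Tie-breaks are lexicographic (smallest CUI, earliest sentence, first
cluster) at every decision point, making the entire pipeline a pure
function of its inputs.  Degenerate inputs are defined, not special-cased
away: empty contexts give zero vectors, concept-free documents give
all-zero sentence scores and fall back to document order, an empty graph
clusters to nothing.

## Known limitations

* Dictionary matching is exact after normalization; morphological
  variants of a synonym are missed (by design — the mapper's stand-in is
  not a contribution of this package).
* The AEC offline searcher evaluates the structured query object rather
  than parsing its serialized string form; the serialization exists for
  interoperability with E-utilities-style services.
* JDI depends entirely on the quality of the supplied descriptor model;
  the synthetic one is deliberately orthogonal and says nothing about
  real descriptor granularity.
* The RRF reader is a convenience for license holders and is untested
  against full releases.
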