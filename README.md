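# wsdsumm

Knowledge-based word sense disambiguation (WSD) and graph-based
extractive summarization for biomedical text, over a UMLS-like concept
knowledge base.

Biomedical terms are heavily ambiguous: *cold* alone maps to a disease, a
temperature and a sensation in a Metathesaurus-style vocabulary, each
with its own concept identifier (CUI).  Pipelines that map text onto
concepts must choose, and anything downstream — here, a summarizer that
reasons over a concept graph — inherits the choice.  `wsdsumm` is for
text-mining researchers and practitioners who want to study that
interaction end to end: three unsupervised disambiguation methods, a
concept-graph summarizer that consumes them, ROUGE evaluation, and
deterministic synthetic fixtures so the whole pipeline runs without any
licensed resource (UMLS, MetaMap, MEDLINE access).

## What is inside

**Disambiguation** — for an ambiguous word *w* with candidate concepts
*C_w* and context vector *cx*:

* **MRD** selects `argmax_{c in C_w} (c . cx) / (|c||cx|)`, where each
  candidate profile *c* is a tf×icf-weighted stemmed bag built from the
  concept's definitions, synonyms and directly related concepts
  (siblings excluded), with `icf(t) = log((1+N)/(1+n_t)) + 1`.
* **AEC** builds boolean queries from *monosemous relatives* (unique
  synonyms OR-ed as quoted phrases; the ambiguous term AND-ed with
  monosemous terms of related concepts; terms >50 chars, <3 chars,
  numbers and stop words filtered; `[tiab]` field; parenthesized
  fallback when quotes retrieve nothing), labels up to 100 retrieved
  documents per sense, and trains a multinomial naive Bayes classifier
  with add-one smoothing.  Retrieval sits behind a searcher interface
  with an offline boolean implementation.
* **JDI** indexes the context against journal-descriptor word vectors,
  scores each candidate's semantic types against pre-computed descriptor
  indexings, and picks the candidate with the top-ranked type.  It
  abstains when all candidates share one semantic-type set; accuracy is
  reported on the whole set and on the JDI-eligible subset,
  `accuracy = correct / all instances` with abstentions counted wrong.

**Summarization** — four steps: dictionary concept mapping with the
chosen WSD method (or the `first_mapping` no-WSD baseline); a document
graph of merged hypernym chains (two upper levels trimmed) with is_a
edge weight `depth(parent)/depth(child)` and weight-1 related/associated
edges; hub-vertex-set (HVS) clustering by salience; non-democratic
voting (1 per HVS vertex, 0.5 per other member) with sentence score
`sum_i similarity(C_i, S_j)/|C_i|`, selecting sentences until the
summary reaches 30% of the document words.

**Evaluation** — ROUGE-2 and ROUGE-SU4 (skip distance 4, unigrams
included) with clipped counts over one or more references, plus the
*common mapping agreement* between two disambiguation runs.

## Worked example

```r
library(wsdsumm)

spec <- fixture_spec(seed = 42)        # the deterministic synthetic world
kb   <- generate_kb(spec)
kb
#> <knowledge_base> 83 concepts, 64 is_a / 5 other_related relations, 3 semantic-type associations

# disambiguation accuracy at moderate sense separability (s = 0.5)
ds <- generate_wsd_dataset(kb, spec, n_instances = 400, separability = 0.5)
rep <- run_wsd_eval(kb, ds, methods = c("mrd", "aec", "jdi", "first_mapping"),
                    jd = generate_jd_model(kb, spec),
                    searcher = make_offline_searcher(generate_search_corpus(kb, spec)))
print(rep$summary, digits = 3)
#>          method   set subset
#> 1           mrd 0.975  0.975
#> 2           aec 0.990  0.990
#> 3           jdi 0.990  0.990
#> 4 first_mapping 0.490  0.490
```

With half the context words drawn from the gold sense's vocabulary, the
three context-aware methods recover nearly every instance while the
take-the-first-concept baseline sits at chance (two senses per term).
The `subset` column is accuracy after removing instances whose
candidates share a semantic-type set — here none, since the fixture
makes every term JDI-eligible.

```r
# does disambiguation matter for summarization?
corpus <- generate_corpus(kb, spec)    # 20 planted-topic documents
ev <- run_summarization_eval(kb, corpus, methods = c("mrd", "first_mapping"))
print(ev$summary, digits = 3)
#>          method mean_rouge2 mean_rouge_su4
#> 1           mrd       1.000          1.000
#> 2 first_mapping       0.662          0.631
print(ev$wins)
#>          method rouge2_wins
#> 1           mrd          20
#> 2 first_mapping           0
```

Every document plants a dominant topic behind an ambiguous term whose
lexicographically first candidate is a decoy.  Summaries built with MRD
recover the topic sentences exactly (ROUGE-2 = 1 against the reference);
the baseline loses the planted sense and with it roughly a third of the
reference bigrams, losing on all 20 documents.

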