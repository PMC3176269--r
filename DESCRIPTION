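Package: wsdsumm
Title: Knowledge-Based Word Sense Disambiguation and Graph-Based
    Biomedical Summarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for knowledge-based word sense disambiguation (WSD) over a
    UMLS-like concept knowledge base, and for graph-based extractive
    summarization of biomedical documents.  Implements three unsupervised
    disambiguation methods: a machine-readable-dictionary method (MRD) that
    compares tf-icf weighted concept profiles with the context by cosine
    similarity, an automatically-extracted-corpus method (AEC) that builds
    boolean queries from monosemous relatives, retrieves pseudo-labeled
    training documents and fits a multinomial naive Bayes classifier, and a
    journal-descriptor-indexing method (JDI) that scores candidate senses
    through the semantic types of their concepts.  The summarizer maps
    sentences to concepts, builds a weighted concept graph with hypernym
    hierarchies, clusters it into hub vertex sets and selects sentences by
    non-democratic voting.  ROUGE-2 and ROUGE-SU4 evaluation, deterministic
    synthetic fixture generators, and a small command-line interface are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
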