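# Deterministic synthetic fixtures: a UMLS-like knowledge base with an is_a
# forest, ambiguous terms with controllable sense separability, WSD
# instance sets, planted-topic document corpora with reference summaries, a
# pseudo-literature search corpus for AEC training, and an orthogonal
# journal-descriptor model.  Vocabularies are disjoint integer-coded tokens
# ("w0017"), so separability is exactly controllable; every generator is a
# pure function of (spec, seed).

.fixture_specific_types <- c(
  "Disease or Syndrome", "Body Part, Organ, or Organ Component",
  "Pharmacologic Substance", "Gene or Genome", "Bacterium", "Virus",
  "Cell", "Tissue", "Neoplastic Process",
  "Therapeutic or Preventive Procedure", "Laboratory Procedure",
  "Organic Chemical"
)

#' Fixture specification
#'
#' Parameters of the synthetic world every generator consumes.  Separability
#' `s` is the probability that a context word of a WSD instance is drawn
#' from the gold sense's vocabulary rather than from the confusion pool
#' shared by all senses of the term: `s = 1` gives fully separable senses,
#' `s = 0` uninformative contexts.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param n_concepts number of base concepts in the is_a forest.
#' @param hierarchy_depth depth of the forest (root depth 1); summarization
#'   fixtures assume at least 4 so planted topics survive the removal of
#'   the two upper hierarchy levels.
#' @param n_ambiguous_terms,senses_per_term ambiguous surface terms and the
#'   number of candidate concepts attached to each.
#' @param separability `s` in `[0, 1]`.
#' @param n_documents,sentences_per_document corpus dimensions.
#' @param planted_topic_size concepts in each document's planted topic
#'   subgraph (0 disables corpus generation).
#' @param vocabulary_size coded words available for concept vocabularies.
#' @param n_instances WSD instances per generated dataset.
#' @param context_length words per instance context.
#' @param type_overlap when TRUE all senses of a term share one semantic
#'   type (making the term ineligible for JDI); when FALSE sense types are
#'   pairwise distinct.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_concepts = 60L, hierarchy_depth = 4L,
                         n_ambiguous_terms = 10L, senses_per_term = 2L,
                         separability = 1, n_documents = 20L,
                         sentences_per_document = 10L, planted_topic_size = 4L,
                         vocabulary_size = 900L, n_instances = 100L,
                         context_length = 20L, type_overlap = FALSE) {
  spec <- list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
               hierarchy_depth = as.integer(hierarchy_depth),
               n_ambiguous_terms = as.integer(n_ambiguous_terms),
               senses_per_term = as.integer(senses_per_term),
               separability = separability,
               n_documents = as.integer(n_documents),
               sentences_per_document = as.integer(sentences_per_document),
               planted_topic_size = as.integer(planted_topic_size),
               vocabulary_size = as.integer(vocabulary_size),
               n_instances = as.integer(n_instances),
               context_length = as.integer(context_length),
               type_overlap = isTRUE(type_overlap))
  n_generic <- max(2L, spec$n_concepts %/% 20L)
  needed <- 6L * (spec$n_concepts + spec$n_ambiguous_terms * spec$senses_per_term +
                    n_generic)
  if (spec$separability < 0 || spec$separability > 1) stop("separability must be in [0, 1]")
  if (spec$hierarchy_depth < 2L) stop("hierarchy_depth must be >= 2")
  if (spec$senses_per_term < 2L) stop("senses_per_term must be >= 2")
  if (spec$planted_topic_size < 0L) stop("planted_topic_size must be >= 0")
  for (f in c("n_concepts", "n_ambiguous_terms", "n_documents",
              "sentences_per_document", "n_instances", "context_length")) {
    if (spec[[f]] < 1L) stop(f, " must be positive")
  }
  if (spec$vocabulary_size < needed) {
    stop("vocabulary_size too small: need at least ", needed, " words")
  }
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic knowledge base
#'
#' Builds an is_a forest of the requested depth (parents assigned
#' round-robin level by level), gives every concept a disjoint slice of six
#' coded words (two two-word synonyms and a definition), cycles specific
#' semantic types over the base concepts, and adds a handful of
#' generic-typed concepts so the summarizer's semantic-type filter is
#' exercised.  Each ambiguous term is attached as an extra synonym to
#' `senses_per_term` sense concepts: the lexicographically smallest sense
#' is a shallow generic-typed decoy (unless `type_overlap`), so baselines
#' that always take the first concept resolve planted topics incorrectly;
#' the remaining senses hang off deep forest nodes with distinct specific
#' types.  A designated distractor parent and its children provide
#' competing off-topic material for the corpus generator.  Some
#' other_related relations and semantic-type associations complete the
#' graph.  Deterministic per seed.
#'
#' @param spec a [fixture_spec()].
#' @return a [knowledge_base()]; generator bookkeeping (concept
#'   vocabularies, the ambiguous-sense table, the confusion pool) is kept
#'   in the `"fixture_meta"` attribute.
#' @export
generate_kb <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, .generate_kb_impl(spec))
}

.generate_kb_impl <- function(spec) {
  n <- spec$n_concepts
  d <- spec$hierarchy_depth
  n_generic <- max(2L, n %/% 20L)

  # level sizes proportional to depth, at least one node per level
  raw <- (1:d) / sum(1:d)
  counts <- pmax(1L, floor(raw * n))
  counts[d] <- counts[d] + (n - sum(counts))
  cuis <- sprintf("C%04d", seq_len(n))
  depth <- rep(seq_len(d), counts)
  parent <- rep(NA_character_, n)
  offset <- cumsum(c(0L, counts))
  for (l in 2:d) {
    prev <- cuis[(offset[l - 1L] + 1L):offset[l]]
    idx <- (offset[l] + 1L):offset[l + 1L]
    parent[idx] <- prev[((seq_along(idx) - 1L) %% length(prev)) + 1L]
  }

  word_counter <- 0L
  next_slice <- function() {
    w <- sprintf("w%04d", word_counter + 1:6)
    word_counter <<- word_counter + 6L
    w
  }
  concept_vocab <- list()
  mk_concept <- function(cui, types, extra_synonyms = character()) {
    w <- next_slice()
    concept_vocab[[cui]] <<- w
    new_concept(
      cui = cui,
      preferred_name = paste(w[1:2], collapse = " "),
      synonyms = c(paste(w[3:4], collapse = " "), extra_synonyms),
      semantic_types = types,
      definitions = paste(w, collapse = " ")
    )
  }

  concepts <- list()
  for (i in seq_len(n)) {
    tp <- .fixture_specific_types[((i - 1L) %% length(.fixture_specific_types)) + 1L]
    concepts[[cuis[i]]] <- mk_concept(cuis[i], tp)
  }
  generic_cuis <- sprintf("C7%03d", seq_len(n_generic))
  gtypes <- default_generic_types()
  for (j in seq_len(n_generic)) {
    concepts[[generic_cuis[j]]] <-
      mk_concept(generic_cuis[j], gtypes[((j - 1L) %% length(gtypes)) + 1L])
  }

  # deep parents (depth d-1) with at least two children carry the topics
  deep_parents <- cuis[depth == d - 1L]
  child_count <- vapply(deep_parents, function(p) sum(parent == p, na.rm = TRUE),
                        integer(1))
  eligible <- deep_parents[child_count >= 2L]
  if (length(eligible) < 2L) eligible <- deep_parents
  distractor_parent <- eligible[length(eligible)]
  topic_parents <- eligible[-length(eligible)]

  relations <- data.frame(source = parent[!is.na(parent)], kind = "is_a",
                          target = cuis[!is.na(parent)], stringsAsFactors = FALSE)

  ambiguous <- list()
  for (i in seq_len(spec$n_ambiguous_terms)) {
    term <- sprintf("ambterm%02d", i)
    sense_cuis <- sprintf("C8%02d%d", i, seq_len(spec$senses_per_term))
    shared_type <- .fixture_specific_types[((i - 1L) %% length(.fixture_specific_types)) + 1L]
    gp <- topic_parents[((i - 1L) %% length(topic_parents)) + 1L]
    for (j in seq_len(spec$senses_per_term)) {
      if (j == 1L) {
        # shallow decoy: smallest cui, no hypernyms, generic type unless the
        # fixture plants a shared-type (JDI-ineligible) term
        tp <- if (spec$type_overlap) shared_type else "Temporal concept"
        concepts[[sense_cuis[j]]] <- mk_concept(sense_cuis[j], tp, term)
      } else {
        tp <- if (spec$type_overlap) {
          shared_type
        } else {
          .fixture_specific_types[((i + j) %% length(.fixture_specific_types)) + 1L]
        }
        concepts[[sense_cuis[j]]] <- mk_concept(sense_cuis[j], tp, term)
        relations <- rbind(relations, data.frame(
          source = gp, kind = "is_a", target = sense_cuis[j],
          stringsAsFactors = FALSE))
      }
    }
    ambiguous[[term]] <- list(
      term = term, senses = sense_cuis, decoy = sense_cuis[1L],
      gold = sense_cuis[spec$senses_per_term], gold_parent = gp,
      siblings = cuis[!is.na(parent) & parent == gp]
    )
  }

  # other_related edges among deep base concepts
  deep <- cuis[depth >= 2L]
  n_or <- max(2L, n %/% 10L)
  pairs_a <- sample(deep, n_or, replace = TRUE)
  pairs_b <- sample(deep, n_or, replace = TRUE)
  keep <- pairs_a != pairs_b & parent[match(pairs_b, cuis)] != pairs_a &
    parent[match(pairs_a, cuis)] != pairs_b
  if (any(keep)) {
    relations <- rbind(relations, unique(data.frame(
      source = pmin(pairs_a[keep], pairs_b[keep]), kind = "other_related",
      target = pmax(pairs_a[keep], pairs_b[keep]), stringsAsFactors = FALSE)))
  }

  used_types <- .fixture_specific_types[seq_len(min(6L, length(.fixture_specific_types)))]
  st_assoc <- data.frame(type_a = used_types[c(1L, 3L, 5L)],
                         type_b = used_types[c(2L, 4L, 6L)],
                         stringsAsFactors = FALSE)

  kb <- knowledge_base(concepts, relations, st_assoc)
  attr(kb, "fixture_meta") <- list(
    spec = spec,
    concept_vocab = concept_vocab,
    pool = sprintf("p%04d", 1:200),
    ambiguous = ambiguous,
    generic_cuis = generic_cuis,
    base_cuis = cuis,
    base_depth = setNames(depth, cuis),
    distractor = list(parent = distractor_parent,
                      children = cuis[!is.na(parent) & parent == distractor_parent])
  )
  kb
}

.fixture_meta <- function(kb) {
  meta <- attr(kb, "fixture_meta")
  if (is.null(meta)) stop("knowledge base was not produced by generate_kb()")
  meta
}

#' Generate a synthetic WSD dataset
#'
#' Instances emulate evaluation collections of ambiguous-term occurrences:
#' the gold sense is drawn uniformly, and each context word comes from the
#' gold sense's vocabulary with probability `separability` and otherwise
#' from the confusion pool — the union of the vocabularies of all the
#' term's senses, so uninformative contexts confuse the senses
#' symmetrically and accuracy degrades to chance at separability 0.
#'
#' @param kb a knowledge base from [generate_kb()].
#' @param spec the [fixture_spec()] used to build it.
#' @param n_instances,separability override the spec values.
#' @return a [wsd_dataset()].
#' @export
generate_wsd_dataset <- function(kb, spec, n_instances = spec$n_instances,
                                 separability = spec$separability) {
  meta <- .fixture_meta(kb)
  stopifnot(separability >= 0, separability <= 1)
  with_seed(spec$seed + 1L, {
    terms <- names(meta$ambiguous)
    instances <- lapply(seq_len(n_instances), function(i) {
      entry <- meta$ambiguous[[sample(terms, 1L)]]
      gold <- sample(entry$senses, 1L)
      gold_vocab <- meta$concept_vocab[[gold]]
      pool <- unique(unlist(meta$concept_vocab[entry$senses]))
      from_gold <- stats::runif(spec$context_length) < separability
      words <- ifelse(from_gold,
                      sample(gold_vocab, spec$context_length, replace = TRUE),
                      sample(pool, spec$context_length, replace = TRUE))
      wsd_instance(entry$term, paste(words, collapse = " "), entry$senses, gold)
    })
    wsd_dataset(instances, name = sprintf("synthetic_s%g", separability))
  })
}

#' Generate a pseudo-literature search corpus for AEC training
#'
#' Emulates the title/abstract corpus a retrieval service would search:
#' each concept contributes `docs_per_concept` short documents containing
#' one of its synonym phrases plus words from its own vocabulary, so
#' monosemous-relative queries retrieve correctly labeled documents.
#'
#' @inheritParams generate_wsd_dataset
#' @param docs_per_concept documents generated per concept.
#' @return data frame with columns `id`, `text`, usable with
#'   [make_offline_searcher()].
#' @export
generate_search_corpus <- function(kb, spec, docs_per_concept = 5L) {
  meta <- .fixture_meta(kb)
  with_seed(spec$seed + 2L, {
    rows <- list()
    for (cui in names(meta$concept_vocab)) {
      syns <- kb$concepts[[cui]]$synonyms
      syns <- syns[!grepl("^ambterm", syns)]
      vocab <- meta$concept_vocab[[cui]]
      for (k in seq_len(docs_per_concept)) {
        txt <- paste(c(syns[((k - 1L) %% length(syns)) + 1L],
                       sample(vocab, 8L, replace = TRUE)), collapse = " ")
        rows[[length(rows) + 1L]] <- txt
      }
    }
    data.frame(id = sprintf("D%05d", seq_along(rows)),
               text = unlist(rows), stringsAsFactors = FALSE)
  })
}

#' Generate an orthogonal journal-descriptor model
#'
#' One synthetic descriptor per semantic type in the knowledge base; its
#' word vector covers the vocabularies of the concepts carrying that type
#' (disjoint across types by construction, hence near-orthogonal), and the
#' per-type descriptor indexing is one-hot.  Contexts drawn from a sense's
#' vocabulary therefore load exclusively on that sense's type.
#'
#' @inheritParams generate_wsd_dataset
#' @return a [jd_model()].
#' @export
generate_jd_model <- function(kb, spec) {
  meta <- .fixture_meta(kb)
  types <- sort(unique(unlist(lapply(kb$concepts, `[[`, "semantic_types"))))
  jds <- paste0("jd:", types)
  jd_vectors <- lapply(types, function(tp) {
    carriers <- names(kb$concepts)[vapply(kb$concepts, function(co) {
      tp %in% co$semantic_types
    }, logical(1))]
    words <- sort(unique(unlist(meta$concept_vocab[carriers])))
    setNames(rep(0.9, length(words)), words)
  })
  names(jd_vectors) <- jds
  st_jd_index <- lapply(types, function(tp) {
    setNames(as.numeric(jds == paste0("jd:", tp)), jds)
  })
  names(st_jd_index) <- types
  jd_model(jd_vectors, st_jd_index)
}

# fixed token budget per sentence keeps the word-count compression
# threshold aligned with the sentence count
.fixture_sentence_len <- 16L

.pad_tokens <- function(tokens, pool, len = .fixture_sentence_len) {
  if (length(tokens) < len) {
    tokens <- c(tokens, sample(pool, len - length(tokens), replace = TRUE))
  }
  head(tokens, len)
}

#' Generate a planted-topic document corpus with reference summaries
#'
#' Each document carries a dominant topic: a connected subgraph made of an
#' ambiguous term's deep gold sense, its parent and the parent's other
#' children.  Topic sentences (30% of the document) mention the ambiguous
#' term, two topic synonyms and scattered words from the gold sense's
#' vocabulary.  The remaining sentences are fillers of two kinds: imposter
#' fillers repeating the topic synonyms without the ambiguous term (they
#' tie with a topic sentence exactly when the disambiguated sense is lost
#' from the graph), and noise fillers mentioning shallow off-topic and
#' generic-typed concepts.  The reference summary is the concatenation of
#' the topic sentences.  Because the smallest candidate CUI of every
#' ambiguous term is the shallow decoy, a first-mapping baseline resolves
#' the topic term incorrectly in every topic sentence, while a
#' context-aware method can recover the planted sense.
#'
#' All sentences have the same token count, so at compression 0.3 a
#' perfect system recovers exactly the topic sentences.
#'
#' @inheritParams generate_wsd_dataset
#' @return list of documents, each
#'   `list(id, sentences, reference, topic_term, topic_cuis,
#'   topic_positions)` (`topic_positions` 0-based); empty when
#'   `planted_topic_size` is 0.
#' @export
generate_corpus <- function(kb, spec) {
  meta <- .fixture_meta(kb)
  if (spec$planted_topic_size == 0L) return(list())
  with_seed(spec$seed + 3L, {
    S <- spec$sentences_per_document
    n_topic <- max(1L, round(0.3 * S))
    terms <- names(meta$ambiguous)

    lapply(seq_len(spec$n_documents), function(di) {
      entry <- meta$ambiguous[[terms[((di - 1L) %% length(terms)) + 1L]]]
      sibs <- setdiff(entry$siblings, entry$gold)
      topic_cuis <- unique(c(entry$gold, entry$gold_parent,
                             head(sibs, max(0L, spec$planted_topic_size - 2L))))
      phrase_pool <- setdiff(topic_cuis, entry$gold)
      # two fixed companion phrases per sentence: siblings first, parent if short
      phrase_cuis <- head(c(setdiff(phrase_pool, entry$gold_parent),
                            entry$gold_parent), 2L)
      topic_phrases <- vapply(phrase_cuis, function(k) {
        kb$concepts[[k]]$preferred_name
      }, character(1))
      gold_vocab <- meta$concept_vocab[[entry$gold]]
      # scattered off-topic concepts at depth 3: their trimmed hypernym
      # chains stay isolated, so they never form a competing cluster
      shallow <- meta$base_cuis[meta$base_depth[meta$base_cuis] == 3L]
      off_set <- sample(setdiff(shallow, topic_cuis), min(3L, length(shallow)))

      topic_sentence <- function(k) {
        gw <- sample(gold_vocab, 3L)
        body <- c(entry$term, unlist(strsplit(topic_phrases, " ")),
                  rbind(gw, sample(meta$pool, 3L)))
        paste0(paste(.pad_tokens(body, meta$pool), collapse = " "), ".")
      }
      imposter_sentence <- function(k) {
        body <- unlist(strsplit(topic_phrases, " "))
        paste0(paste(.pad_tokens(body, meta$pool), collapse = " "), ".")
      }
      noise_sentence <- function(k) {
        off <- off_set[((k - 1L) %% length(off_set)) + 1L]
        body <- c(strsplit(kb$concepts[[off]]$preferred_name, " ")[[1L]],
                  strsplit(kb$concepts[[sample(meta$generic_cuis, 1L)]]$preferred_name,
                           " ")[[1L]])
        paste0(paste(.pad_tokens(body, meta$pool), collapse = " "), ".")
      }

      n_imp <- min(2L, S - n_topic)
      n_noise <- S - n_topic - n_imp
      kinds <- sample(c(rep("topic", n_topic), rep("imposter", n_imp),
                        rep("noise", n_noise)))
      sentences <- character(S)
      ki <- c(topic = 0L, imposter = 0L, noise = 0L)
      for (si in seq_len(S)) {
        kind <- kinds[si]
        ki[kind] <- ki[kind] + 1L
        sentences[si] <- switch(kind,
                                topic = topic_sentence(ki[kind]),
                                imposter = imposter_sentence(ki[kind]),
                                noise = noise_sentence(ki[kind]))
      }
      topic_positions <- which(kinds == "topic") - 1L
      list(id = sprintf("doc%03d", di),
           sentences = sentences,
           reference = paste(sentences[topic_positions + 1L], collapse = " "),
           topic_term = entry$term,
           topic_cuis = topic_cuis,
           topic_positions = topic_positions)
    })
  })
}

#' Write a generated corpus to disk
#'
#' One sentence-per-line document file and one reference file per document.
#'
#' @param corpus list from [generate_corpus()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus) {
    writeLines(doc$sentences, file.path(path, paste0(doc$id, ".txt")))
    writeLines(doc$reference, file.path(path, paste0(doc$id, ".ref.txt")))
  }
  invisible(path)
}
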