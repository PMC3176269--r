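# Graph-based extractive summarizer, four steps: (1) concept
# identification with a longest-match dictionary mapper plus a WSD method
# for ambiguous phrases, filtering overly generic semantic types; (2) a
# document graph from merged hypernym hierarchies (two upper levels
# removed) extended with other_related and associated_with edges,
# depth-ratio weights on is_a edges; (3) hub-vertex-set clustering by
# salience; (4) non-democratic sentence voting and selection up to the
# compression threshold.

#' Semantic types excluded from summarization
#'
#' Concepts all of whose semantic types fall in this list are discarded
#' during concept identification: these categories are too broad to
#' contribute to the topical structure of a document.
#'
#' @return character vector of semantic-type labels.
#' @export
default_generic_types <- function() {
  c("Quantitative concept", "Qualitative concept", "Temporal concept",
    "Functional concept", "Idea or concept", "Intellectual product",
    "Mental process", "Spatial concept", "Language")
}

#' Split plain text into sentences
#'
#' Minimal rule-based splitter: sentence boundaries at `.`, `!` or `?`
#' followed by whitespace.  Documents can also be supplied pre-segmented
#' (one sentence per line) anywhere a document is accepted.
#'
#' @param text a character string.
#' @return character vector of sentences.
#' @export
split_sentences <- function(text) {
  s <- unlist(strsplit(text, "(?<=[.!?])\\s+", perl = TRUE))
  s <- trimws(s)
  s[nzchar(s)]
}

# greedy longest-match of normalized token n-grams against the term index
.match_phrases <- function(kb, sentence) {
  toks <- strsplit(normalize_term(sentence), " ", fixed = TRUE)[[1L]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(list())
  max_len <- max(c(1L, lengths(strsplit(ls(kb$term_index), " ", fixed = TRUE))))
  out <- list()
  i <- 1L
  while (i <= length(toks)) {
    hit <- NULL
    for (L in seq(min(max_len, length(toks) - i + 1L), 1L)) {
      phrase <- paste(toks[i:(i + L - 1L)], collapse = " ")
      cands <- kb$term_index[[phrase]]
      if (!is.null(cands)) {
        hit <- list(phrase = phrase, candidates = cands, token_start = i, len = L)
        break
      }
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      out[[length(out) + 1L]] <- hit
      i <- i + hit$len
    }
  }
  out
}

#' Map document sentences to disambiguated concepts
#'
#' Step 1 of the summarizer.  Each sentence is scanned with a greedy
#' longest-match dictionary mapper over the knowledge-base term index
#' (standing in for a full lexical mapper, which emits candidate concept
#' sets per phrase); unambiguous phrases are accepted directly and
#' ambiguous ones are resolved by the chosen WSD method with the sentence
#' as context.  `"first_mapping"` takes the lexicographically smallest
#' candidate CUI — the no-WSD baseline.  Concepts whose semantic types all
#' fall in `generic_types` are then discarded.
#'
#' When a WSD method abstains or cannot be trained for a phrase, the
#' first-mapping choice is used for that phrase so every ambiguous phrase
#' receives a decision.
#'
#' @param kb a [knowledge_base()].
#' @param document character vector of sentences, or a single string that
#'   is passed through [split_sentences()].
#' @param wsd one of `"mrd"`, `"aec"`, `"jdi"`, `"first_mapping"`.
#' @param profiles concept profiles for `"mrd"` (built on demand if NULL).
#' @param jd a [jd_model()], required for `"jdi"`.
#' @param searcher searcher function, required for `"aec"`.
#' @param aec_limit per-concept document cap for AEC training.
#' @param precomputed optional list of precomputed candidate mappings keyed
#'   by sentence index (as produced by [read_mapping_file()]); replaces the
#'   dictionary mapper where present.
#' @param generic_types semantic types to filter out.
#' @param stopwords stop list used throughout.
#' @return list with `sentences` — per sentence a list
#'   `(sentence_index, text, concepts)` (`sentence_index` 0-based) — and
#'   `mappings`, a data frame of every phrase decision
#'   (`sentence_index`, `token_start`, `phrase`, `candidates` pipe-joined,
#'   `chosen`, `ambiguous`).
#' @export
identify_concepts <- function(kb, document,
                              wsd = c("mrd", "aec", "jdi", "first_mapping"),
                              profiles = NULL, jd = NULL, searcher = NULL,
                              aec_limit = 100L, precomputed = NULL,
                              generic_types = default_generic_types(),
                              stopwords = default_stopwords()) {
  wsd <- match.arg(wsd)
  if (length(document) == 1L && !grepl("\n", document, fixed = TRUE)) {
    sentences <- split_sentences(document)
  } else {
    sentences <- trimws(unlist(strsplit(document, "\n", fixed = TRUE)))
    sentences <- sentences[nzchar(sentences)]
  }
  if (length(sentences) == 0L) stop("document has no sentences")
  if (wsd == "jdi" && is.null(jd)) stop("wsd = 'jdi' requires a jd model")
  if (wsd == "aec" && is.null(searcher)) stop("wsd = 'aec' requires a searcher")
  if (wsd == "mrd" && is.null(profiles)) profiles <- build_concept_profiles(kb)

  aec_models <- new.env(parent = emptyenv())
  resolve <- function(phrase, cands, context) {
    first <- sort(cands)[1L]
    if (wsd == "first_mapping") return(first)
    inst <- wsd_instance(phrase, context, cands)
    pred <- switch(wsd,
      mrd = mrd_disambiguate(kb, inst, profiles, stopwords),
      jdi = jdi_disambiguate(inst, kb, jd, stopwords),
      aec = {
        m <- aec_models[[phrase]] %||% {
          fit <- withCallingHandlers(
            train_aec(kb, phrase, searcher, aec_limit, stopwords),
            warning = function(w) invokeRestart("muffleWarning")
          )
          aec_models[[phrase]] <- if (is.null(fit)) NA else fit
          aec_models[[phrase]]
        }
        if (identical(m, NA)) NA_character_ else {
          withCallingHandlers(aec_disambiguate(m, inst, stopwords),
                              warning = function(w) invokeRestart("muffleWarning"))
        }
      }
    )
    if (is.na(pred)) first else pred
  }

  maps <- list()
  sent_concepts <- vector("list", length(sentences))
  for (si in seq_along(sentences)) {
    hits <- if (!is.null(precomputed) && !is.null(precomputed[[as.character(si - 1L)]])) {
      precomputed[[as.character(si - 1L)]]
    } else {
      .match_phrases(kb, sentences[si])
    }
    chosen <- character(0)
    for (h in hits) {
      cands <- sort(unique(h$candidates))
      pick <- if (length(cands) == 1L) cands else resolve(h$phrase, cands, sentences[si])
      maps[[length(maps) + 1L]] <- data.frame(
        sentence_index = si - 1L,
        token_start = h$token_start %||% NA_integer_,
        phrase = h$phrase,
        candidates = paste(cands, collapse = "|"),
        chosen = pick,
        ambiguous = length(cands) > 1L,
        stringsAsFactors = FALSE
      )
      chosen <- c(chosen, pick)
    }
    keep <- vapply(unique(chosen), function(k) {
      !all(kb$concepts[[k]]$semantic_types %in% generic_types)
    }, logical(1))
    sent_concepts[[si]] <- list(
      sentence_index = si - 1L,
      text = sentences[si],
      concepts = sort(unique(chosen)[keep])
    )
  }
  mappings <- if (length(maps)) do.call(rbind, maps) else {
    data.frame(sentence_index = integer(), token_start = integer(),
               phrase = character(), candidates = character(),
               chosen = character(), ambiguous = logical(),
               stringsAsFactors = FALSE)
  }
  list(sentences = sent_concepts, mappings = mappings)
}

#' Read a precomputed candidate-mapping file
#'
#' JSON object keyed by 0-based sentence index; each value is an array of
#' `{phrase, candidates}` objects.  Lets externally produced candidate
#' mappings (e.g. from a full lexical mapper) be injected in place of the
#' built-in dictionary matcher.
#'
#' @param path JSON file.
#' @return nested list usable as `precomputed` in [identify_concepts()].
#' @export
read_mapping_file <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(hits) {
    lapply(hits, function(h) {
      list(phrase = h$phrase, candidates = unlist(h$candidates))
    })
  })
}

#' Build the concept graph of one sentence
#'
#' Step 2, per sentence: every identified concept is extended with its full
#' hypernym chain; the chains are merged, then the two upper levels of the
#' hierarchy (depths 1 and 2) are removed with their incident edges —
#' retained vertices keep their original depths.
#'
#' @param kb a [knowledge_base()].
#' @param concepts character vector of CUIs in the sentence.
#' @return list with `vertices` (data frame `cui`, `depth`) and `edges`
#'   (data frame `from`, `to`, `kind`; `from` is the is_a parent).
#' @export
build_sentence_graph <- function(kb, concepts) {
  vertices <- data.frame(cui = character(), depth = integer(),
                         stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(), kind = character(),
                      stringsAsFactors = FALSE)
  for (cui in concepts) {
    chain <- hypernym_chain(kb, cui)
    vertices <- rbind(vertices,
                      data.frame(cui = chain, depth = seq_along(chain),
                                 stringsAsFactors = FALSE))
    if (length(chain) > 1L) {
      edges <- rbind(edges, data.frame(from = chain[-length(chain)],
                                       to = chain[-1L], kind = "is_a",
                                       stringsAsFactors = FALSE))
    }
  }
  vertices <- unique(vertices)
  edges <- unique(edges)
  keep <- vertices$depth > 2L
  kept <- vertices$cui[keep]
  list(
    vertices = vertices[keep, , drop = FALSE],
    edges = edges[edges$from %in% kept & edges$to %in% kept, , drop = FALSE]
  )
}

#' Merge sentence graphs into the weighted document graph
#'
#' Step 2, document level: vertex and edge union of the sentence graphs,
#' extended with `other_related` edges between vertex pairs so related in
#' the knowledge base, and `associated_with` edges between leaf vertices
#' whose semantic types are associated in the semantic network.  An is_a
#' edge between a parent at depth d_p and child at depth d_c gets weight
#' d_p / d_c (in `(0, 1]` under the root-depth-1 convention); all other
#' edges weigh 1.  Vertex salience is the sum of incident edge weights.
#'
#' @param kb a [knowledge_base()].
#' @param sentence_graphs list from [build_sentence_graph()].
#' @return a `document_graph`: `vertices` (`cui`, `depth`, `salience`) and
#'   `edges` (`from`, `to`, `kind`, `weight`).
#' @export
build_document_graph <- function(kb, sentence_graphs) {
  stopifnot(length(sentence_graphs) >= 1L)
  vertices <- unique(do.call(rbind, lapply(sentence_graphs, `[[`, "vertices")))
  edges <- unique(do.call(rbind, lapply(sentence_graphs, `[[`, "edges")))
  if (is.null(vertices) || nrow(vertices) == 0L) {
    return(structure(list(
      vertices = data.frame(cui = character(), depth = integer(),
                            salience = numeric(), stringsAsFactors = FALSE),
      edges = data.frame(from = character(), to = character(),
                         kind = character(), weight = numeric(),
                         stringsAsFactors = FALSE)),
      class = "document_graph"))
  }
  vset <- vertices$cui
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- if (nrow(edges)) pair_key(edges$from, edges$to) else character(0)

  # other_related edges between co-present vertices
  rel <- kb$relations
  or <- rel[rel$kind == "other_related" & rel$source %in% vset & rel$target %in% vset, ,
            drop = FALSE]
  if (nrow(or)) {
    k <- pair_key(or$source, or$target)
    new <- !duplicated(k) & !(k %in% have)
    if (any(new)) {
      edges <- rbind(edges, data.frame(from = or$source[new], to = or$target[new],
                                       kind = "other_related", stringsAsFactors = FALSE))
      have <- c(have, k[new])
    }
  }

  # associated_with edges between leaf vertices with associated types
  leaves <- setdiff(vset, edges$from[edges$kind == "is_a"])
  if (length(leaves) >= 2L && nrow(kb$st_associations)) {
    pairs <- t(utils::combn(sort(leaves), 2L))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1L]; b <- pairs[i, 2L]
      if (pair_key(a, b) %in% have) next
      ta <- kb$concepts[[a]]$semantic_types
      tb <- kb$concepts[[b]]$semantic_types
      assoc <- any(outer(ta, tb, Vectorize(function(x, y) st_associated(kb, x, y))))
      if (assoc) {
        edges <- rbind(edges, data.frame(from = a, to = b, kind = "associated_with",
                                         stringsAsFactors = FALSE))
        have <- c(have, pair_key(a, b))
      }
    }
  }

  depth_of <- setNames(vertices$depth, vertices$cui)
  edges$weight <- ifelse(edges$kind == "is_a",
                         depth_of[edges$from] / depth_of[edges$to], 1)
  sal <- setNames(numeric(length(vset)), vset)
  for (i in seq_len(nrow(edges))) {
    sal[edges$from[i]] <- sal[edges$from[i]] + edges$weight[i]
    sal[edges$to[i]] <- sal[edges$to[i]] + edges$weight[i]
  }
  vertices$salience <- as.numeric(sal[vertices$cui])
  rownames(vertices) <- rownames(edges) <- NULL
  structure(list(vertices = vertices, edges = edges), class = "document_graph")
}

#' @export
print.document_graph <- function(x, ...) {
  cat("<document_graph>", nrow(x$vertices), "vertices,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Cluster the document graph into hub vertex sets
#'
#' Step 3.  The `max(1, ceiling(hub_fraction * |V|))` vertices of highest
#' salience (ties to the smaller CUI) become hub vertices; the connected
#' components of the hub-induced subgraph are the hub vertex sets (HVS),
#' the centroids of the clusters.  Remaining vertices are attached in
#' descending salience order to the cluster to whose current members they
#' are most strongly connected (sum of edge weights), with live membership
#' updates; passes repeat until no vertex can be attached, and vertices
#' with no connection to any cluster stay unassigned.
#'
#' @param g a `document_graph`.
#' @param hub_fraction fraction of vertices labeled as hubs, in `(0, 1]`.
#' @return list of clusters, each `list(hvs, members)`; empty for an empty
#'   graph.
#' @export
cluster_concepts <- function(g, hub_fraction = 0.1) {
  stopifnot(hub_fraction > 0, hub_fraction <= 1)
  v <- g$vertices
  if (nrow(v) == 0L) return(list())
  ord <- order(-v$salience, v$cui)
  n_hub <- max(1L, ceiling(hub_fraction * nrow(v)))
  hubs <- v$cui[ord][seq_len(n_hub)]

  he <- g$edges[g$edges$from %in% hubs & g$edges$to %in% hubs, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(he[, c("from", "to")], directed = FALSE,
                                      vertices = data.frame(name = hubs))
  comp <- igraph::components(ig)$membership
  clusters <- lapply(split(names(comp), comp), function(hvs) {
    list(hvs = sort(hvs), members = sort(hvs))
  })
  clusters <- clusters[order(vapply(clusters, function(cl) cl$hvs[1L], character(1)))]

  rest <- setdiff(v$cui, hubs)
  sal <- setNames(v$salience, v$cui)
  rest <- rest[order(-sal[rest], rest)]
  repeat {
    attached <- character(0)
    for (u in rest) {
      conn <- vapply(clusters, function(cl) {
        e <- g$edges
        sum(e$weight[(e$from == u & e$to %in% cl$members) |
                     (e$to == u & e$from %in% cl$members)])
      }, numeric(1))
      if (max(conn) > 0) {
        ci <- which(conn >= max(conn) - 1e-12)[1L]
        clusters[[ci]]$members <- sort(c(clusters[[ci]]$members, u))
        attached <- c(attached, u)
      }
    }
    rest <- setdiff(rest, attached)
    if (length(attached) == 0L || length(rest) == 0L) break
  }
  clusters
}

#' Sentence-to-cluster similarity by non-democratic voting
#'
#' Step 4: each vertex of the sentence graph casts one vote if it belongs
#' to the cluster's HVS, half a vote if it is a non-HVS member, none
#' otherwise; the similarity is the vote total.
#'
#' @param sentence_graph a sentence graph from [build_sentence_graph()].
#' @param cluster one cluster from [cluster_concepts()].
#' @return non-negative vote total.
#' @export
sentence_similarity <- function(sentence_graph, cluster) {
  vs <- unique(sentence_graph$vertices$cui)
  sum(ifelse(vs %in% cluster$hvs, 1, ifelse(vs %in% cluster$members, 0.5, 0)))
}

#' Score sentences against all clusters
#'
#' A sentence's score is the sum over clusters of its vote similarity
#' divided by the cluster's member count, so large clusters do not dominate
#' by size alone.
#'
#' @param sentence_graphs list of sentence graphs, in document order.
#' @param clusters non-empty list from [cluster_concepts()].
#' @return data frame `sentence_index` (0-based), `score`.
#' @export
score_sentences <- function(sentence_graphs, clusters) {
  if (length(clusters) == 0L) stop("score_sentences needs at least one cluster")
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  if (any(sizes == 0L)) stop("zero-size cluster")
  score <- vapply(sentence_graphs, function(sg) {
    sum(vapply(seq_along(clusters), function(i) {
      sentence_similarity(sg, clusters[[i]]) / sizes[i]
    }, numeric(1)))
  }, numeric(1))
  data.frame(sentence_index = seq_along(sentence_graphs) - 1L, score = score)
}

#' Summarize a document
#'
#' Runs the full four-step pipeline and selects sentences in descending
#' score order (ties to the earlier sentence) until the summary first
#' reaches `compression` times the document size — word count by default,
#' sentence count with `size_unit = "sentences"`.  Selected sentences are
#' returned in document order.
#'
#' @inheritParams identify_concepts
#' @param compression target summary size as a fraction of the document,
#'   in `(0, 1]`.
#' @param hub_fraction passed to [cluster_concepts()].
#' @param size_unit `"words"` or `"sentences"`.
#' @return a `document_summary`: `selected` (0-based indices in document
#'   order), `summary` (text), `sentences`, `scores`, `clusters`, `graph`,
#'   `mappings`.
#' @export
summarize_document <- function(kb, document, wsd = c("mrd", "aec", "jdi", "first_mapping"),
                               compression = 0.30, hub_fraction = 0.1,
                               size_unit = c("words", "sentences"),
                               profiles = NULL, jd = NULL, searcher = NULL,
                               aec_limit = 100L, precomputed = NULL,
                               generic_types = default_generic_types(),
                               stopwords = default_stopwords()) {
  stopifnot(compression > 0, compression <= 1)
  size_unit <- match.arg(size_unit)
  ident <- identify_concepts(kb, document, wsd, profiles = profiles, jd = jd,
                             searcher = searcher, aec_limit = aec_limit,
                             precomputed = precomputed,
                             generic_types = generic_types, stopwords = stopwords)
  sentences <- vapply(ident$sentences, `[[`, character(1), "text")
  sgraphs <- lapply(ident$sentences, function(s) build_sentence_graph(kb, s$concepts))
  g <- build_document_graph(kb, sgraphs)
  clusters <- cluster_concepts(g, hub_fraction)
  scores <- if (length(clusters)) {
    score_sentences(sgraphs, clusters)
  } else {
    data.frame(sentence_index = seq_along(sentences) - 1L, score = 0)
  }

  sizes <- if (size_unit == "words") {
    vapply(sentences, function(s) length(tokenize_words(s)), integer(1))
  } else {
    rep(1L, length(sentences))
  }
  target <- compression * sum(sizes)
  ord <- order(-scores$score, scores$sentence_index)
  selected <- integer(0)
  total <- 0
  for (i in ord) {
    selected <- c(selected, scores$sentence_index[i])
    total <- total + sizes[i]
    if (total >= target) break
  }
  selected <- sort(selected)
  structure(
    list(selected = selected,
         summary = paste(sentences[selected + 1L], collapse = " "),
         sentences = sentences,
         scores = scores,
         clusters = clusters,
         graph = g,
         mappings = ident$mappings),
    class = "document_summary"
  )
}

#' @export
print.document_summary <- function(x, ...) {
  cat("<document_summary>", length(x$selected), "of", length(x$sentences),
      "sentences selected\n")
  cat(strwrap(x$summary, width = 76), sep = "\n")
  invisible(x)
}

#' Agreement of two disambiguation runs on their common mappings
#'
#' A "common mapping" is a phrase occurrence for which the mapper returned
#' several candidate concepts; the agreement is the fraction of such
#' occurrences where the two methods chose the same concept.  Both mapping
#' tables must cover the same occurrences (same document, same mapper).
#'
#' @param mappings_a,mappings_b `mappings` data frames from
#'   [identify_concepts()] or [summarize_document()] over the same
#'   document.
#' @return proportion in `[0, 1]`.
#' @export
common_mapping_agreement <- function(mappings_a, mappings_b) {
  a <- mappings_a[mappings_a$ambiguous, , drop = FALSE]
  b <- mappings_b[mappings_b$ambiguous, , drop = FALSE]
  key <- function(m) paste(m$sentence_index, m$token_start, m$phrase, m$candidates)
  ka <- key(a); kb_ <- key(b)
  if (!identical(sort(ka), sort(kb_))) {
    stop("mapping tables do not cover the same ambiguous phrase occurrences")
  }
  if (nrow(a) == 0L) return(1)
  b <- b[match(ka, kb_), , drop = FALSE]
  mean(a$chosen == b$chosen)
}
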