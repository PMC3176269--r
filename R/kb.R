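# Knowledge-base data model: concepts with synonyms, semantic types and
# definitions; typed relations (is_a hierarchy + other_related); symmetric
# semantic-type associations; and a normalized term index for lookup.

.kb_relation_kinds <- c("is_a", "other_related")

stop_integrity <- function(...) {
  stop(errorCondition(paste0(...), class = c("wsdsumm_integrity_error", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("wsdsumm_parse_error", "error")))
}

new_concept <- function(cui, preferred_name, synonyms = character(),
                        semantic_types, definitions = character()) {
  synonyms <- sort(unique(c(preferred_name, synonyms)))
  list(
    cui = cui,
    preferred_name = preferred_name,
    synonyms = synonyms,
    semantic_types = sort(unique(semantic_types)),
    definitions = as.character(definitions)
  )
}

# canonical ordering for symmetric semantic-type pairs
canonical_st_pairs <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(type_a = character(), type_b = character(),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(df$type_a, df$type_b)
  b <- pmax(df$type_a, df$type_b)
  out <- unique(data.frame(type_a = a, type_b = b, stringsAsFactors = FALSE))
  out <- out[order(out$type_a, out$type_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a knowledge base
#'
#' Assembles concepts, relations and semantic-type associations into a
#' validated `knowledge_base` object with a case-insensitive term index.
#' Every synonym (after [normalize_term()]) is indexed to its concept.
#'
#' @param concepts list of concepts, each a list with fields `cui`,
#'   `preferred_name`, `synonyms`, `semantic_types`, `definitions`.
#' @param relations data frame with columns `source`, `kind`
#'   (`"is_a"` with source = parent, or `"other_related"`), `target`.
#' @param st_associations data frame with columns `type_a`, `type_b`;
#'   symmetric pairs, stored once in canonical order.
#' @return an object of class `knowledge_base`.
#' @export
knowledge_base <- function(concepts,
                           relations = NULL,
                           st_associations = NULL) {
  if (is.null(relations)) {
    relations <- data.frame(source = character(), kind = character(),
                            target = character(), stringsAsFactors = FALSE)
  }
  cuis <- vapply(concepts, `[[`, character(1), "cui")
  if (anyDuplicated(cuis)) {
    stop_integrity("duplicate cui: ", paste(unique(cuis[duplicated(cuis)]), collapse = ", "))
  }
  concepts <- lapply(concepts, function(co) {
    new_concept(co$cui, co$preferred_name, co$synonyms %||% character(),
                co$semantic_types, co$definitions %||% character())
  })
  names(concepts) <- cuis
  for (co in concepts) {
    if (length(co$semantic_types) == 0L || all(!nzchar(co$semantic_types))) {
      stop_integrity("concept ", co$cui, " has no semantic types")
    }
  }

  relations <- unique(relations[, c("source", "kind", "target")])
  relations <- relations[order(relations$kind, relations$source, relations$target), ,
                         drop = FALSE]
  rownames(relations) <- NULL
  bad_kind <- setdiff(unique(relations$kind), .kb_relation_kinds)
  if (length(bad_kind)) {
    stop_integrity("unknown relation kind: ", paste(bad_kind, collapse = ", "))
  }
  dangling <- setdiff(c(relations$source, relations$target), cuis)
  if (length(dangling)) {
    stop_integrity("relation endpoint not in concepts: ",
                   paste(sort(dangling), collapse = ", "))
  }
  if (any(relations$source == relations$target)) {
    stop_integrity("self-loop relation on ",
                   relations$source[relations$source == relations$target][1L])
  }
  .check_isa_acyclic(relations)

  term_index <- new.env(parent = emptyenv())
  for (co in concepts) {
    for (s in unique(normalize_term(co$synonyms))) {
      if (!nzchar(s)) next
      term_index[[s]] <- sort(unique(c(term_index[[s]], co$cui)))
    }
  }

  structure(
    list(concepts = concepts,
         relations = relations,
         st_associations = canonical_st_pairs(st_associations),
         term_index = term_index),
    class = "knowledge_base"
  )
}

# reject cycles in the is_a hierarchy by iterated leaf-stripping
.check_isa_acyclic <- function(relations) {
  isa <- relations[relations$kind == "is_a", , drop = FALSE]
  if (nrow(isa) == 0L) return(invisible(TRUE))
  edges <- isa[, c("source", "target")]
  repeat {
    if (nrow(edges) == 0L) return(invisible(TRUE))
    sinks <- setdiff(edges$target, edges$source)
    if (length(sinks) == 0L) stop_integrity("is_a relations contain a cycle")
    edges <- edges[!(edges$target %in% sinks), , drop = FALSE]
  }
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>", length(x$concepts), "concepts,",
      sum(x$relations$kind == "is_a"), "is_a /",
      sum(x$relations$kind == "other_related"), "other_related relations,",
      nrow(x$st_associations), "semantic-type associations\n")
  invisible(x)
}

#' Candidate concepts of a surface term
#'
#' Looks a term up in the normalized term index and returns every concept
#' whose synonym set contains it.  Unknown terms give an empty set.
#'
#' @param kb a [knowledge_base()].
#' @param term surface string, normalized internally.
#' @return sorted character vector of CUIs (possibly empty).
#' @export
candidate_concepts <- function(kb, term) {
  stopifnot(inherits(kb, "knowledge_base"), nzchar(term))
  kb$term_index[[normalize_term(term)]] %||% character(0)
}

#' Is a term monosemous?
#'
#' A term is monosemous when it is linked to exactly one concept in the
#' knowledge base; such terms can stand as unambiguous search proxies for
#' their concept.
#'
#' @inheritParams candidate_concepts
#' @return TRUE iff exactly one candidate concept exists.
#' @export
is_monosemous <- function(kb, term) {
  length(candidate_concepts(kb, term)) == 1L
}

# parent of a concept in the is_a hierarchy; lexicographically smallest cui
# when several parents exist, NA at a root
.isa_parent <- function(kb, cui) {
  isa <- kb$relations
  p <- isa$source[isa$kind == "is_a" & isa$target == cui]
  if (length(p) == 0L) NA_character_ else sort(p)[1L]
}

.isa_children <- function(kb, cui) {
  isa <- kb$relations
  sort(isa$target[isa$kind == "is_a" & isa$source == cui])
}

#' Hypernym chain of a concept
#'
#' Walks the is_a hierarchy from the concept up to its root and returns the
#' chain root-first, so the root has depth 1 and the concept itself depth
#' `length(chain)`.  When a concept has several is_a parents the chain
#' follows the lexicographically smallest parent CUI.
#'
#' @param kb a [knowledge_base()].
#' @param cui concept identifier present in `kb`.
#' @return character vector of CUIs, root first, ending at `cui`.
#' @export
hypernym_chain <- function(kb, cui) {
  if (is.null(kb$concepts[[cui]])) stop_integrity("unknown cui: ", cui)
  chain <- cui
  cur <- cui
  repeat {
    p <- .isa_parent(kb, cur)
    if (is.na(p)) break
    if (p %in% chain) stop_integrity("is_a cycle at ", p)
    chain <- c(p, chain)
    cur <- p
  }
  chain
}

#' Raw text sources of a concept profile
#'
#' Collects the strings from which a concept's profile vector is built: its
#' definitions and synonyms, plus the synonyms and definitions of directly
#' related concepts — is_a parents and children and other_related
#' neighbours.  Siblings (concepts sharing a parent but not directly
#' related) are excluded.
#'
#' @inheritParams hypernym_chain
#' @return character vector (a bag; duplicates meaningful).
#' @export
profile_sources <- function(kb, cui) {
  co <- kb$concepts[[cui]]
  if (is.null(co)) stop_integrity("unknown cui: ", cui)
  rel <- kb$relations
  parents <- rel$source[rel$kind == "is_a" & rel$target == cui]
  children <- rel$target[rel$kind == "is_a" & rel$source == cui]
  other <- c(rel$target[rel$kind == "other_related" & rel$source == cui],
             rel$source[rel$kind == "other_related" & rel$target == cui])
  related <- setdiff(unique(c(parents, children, other)), cui)
  bag <- c(co$definitions, co$synonyms)
  for (r in sort(related)) {
    rc <- kb$concepts[[r]]
    bag <- c(bag, rc$synonyms, rc$definitions)
  }
  bag
}

#' Are two semantic types associated?
#'
#' @param kb a [knowledge_base()].
#' @param type_a,type_b semantic-type labels.
#' @return TRUE iff the (unordered) pair is in the association table.
#' @export
st_associated <- function(kb, type_a, type_b) {
  a <- pmin(type_a, type_b)
  b <- pmax(type_a, type_b)
  any(kb$st_associations$type_a == a & kb$st_associations$type_b == b)
}
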