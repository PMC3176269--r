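# WSD instances and datasets: occurrences of an ambiguous term with its
# candidate senses and (optionally) a gold label, plus TSV I/O and the
# accuracy metric.

#' A word-sense-disambiguation instance
#'
#' @param term ambiguous surface string.
#' @param context text surrounding the occurrence (for the summarizer this
#'   is the sentence; evaluation collections provide citation-scale text).
#' @param candidates character vector of >= 2 candidate CUIs.
#' @param gold the correct CUI, or `NA` when unknown.
#' @return an object of class `wsd_instance`.
#' @export
wsd_instance <- function(term, context, candidates, gold = NA_character_) {
  candidates <- sort(unique(as.character(candidates)))
  if (length(candidates) < 2L) {
    stop("a wsd instance needs at least 2 candidate concepts")
  }
  if (!is.na(gold) && !(gold %in% candidates)) {
    stop("gold concept ", gold, " is not among the candidates")
  }
  structure(list(term = term, context = context,
                 candidates = candidates, gold = gold),
            class = "wsd_instance")
}

#' A named collection of WSD instances
#'
#' @param instances list of [wsd_instance()] objects.
#' @param name dataset label.
#' @return an object of class `wsd_dataset`.
#' @export
wsd_dataset <- function(instances, name = "dataset") {
  stopifnot(all(vapply(instances, inherits, logical(1), "wsd_instance")))
  structure(list(instances = instances, name = name), class = "wsd_dataset")
}

#' @export
print.wsd_dataset <- function(x, ...) {
  cat("<wsd_dataset>", x$name, "-", length(x$instances), "instances,",
      length(unique(vapply(x$instances, `[[`, character(1), "term"))), "terms\n")
  invisible(x)
}

#' @export
length.wsd_dataset <- function(x) length(x$instances)

#' Read / write WSD datasets as TSV
#'
#' Columns: `term`, `context`, `candidates` (pipe-joined CUIs), `gold`
#' (empty = no appropriate sense).  Instances without a gold label are
#' dropped at load time, mirroring the usual exclusion of
#' none-of-the-above cases from evaluation.
#'
#' @param path TSV file.
#' @param name dataset label.
#' @return [load_wsd_dataset()]: a [wsd_dataset()].
#' @export
load_wsd_dataset <- function(path, name = basename(path)) {
  df <- .read_tsv_strict(path, c("term", "context", "candidates", "gold"))
  keep <- nzchar(df$gold)
  inst <- lapply(which(keep), function(i) {
    wsd_instance(df$term[i], df$context[i], .split_pipe(df$candidates[i]), df$gold[i])
  })
  wsd_dataset(inst, name = name)
}

#' @rdname load_wsd_dataset
#' @param dataset a [wsd_dataset()].
#' @export
write_wsd_dataset <- function(dataset, path) {
  df <- data.frame(
    term = vapply(dataset$instances, `[[`, character(1), "term"),
    context = vapply(dataset$instances, `[[`, character(1), "context"),
    candidates = vapply(dataset$instances, function(i) paste(i$candidates, collapse = "|"), character(1)),
    gold = vapply(dataset$instances, function(i) if (is.na(i$gold)) "" else i$gold, character(1)),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# TRUE when all candidates of the instance carry identical semantic-type sets
.shared_type_sets <- function(kb, inst) {
  sets <- lapply(inst$candidates, function(k) kb$concepts[[k]]$semantic_types)
  all(vapply(sets[-1L], identical, logical(1), sets[[1L]]))
}

#' Disambiguation accuracy
#'
#' Fraction of instances whose prediction equals the gold concept.
#' Abstentions (`NA` predictions) count as incorrect, since the denominator
#' is all instances.  With `subset_mode = "jdi_subset"` the instances whose
#' candidates all share an identical semantic-type set are removed first —
#' the subset on which journal-descriptor indexing can act at all.
#'
#' @param predictions character vector of predicted CUIs (NA = abstain),
#'   aligned with `dataset$instances`.
#' @param dataset a [wsd_dataset()] whose instances carry gold labels.
#' @param subset_mode `"all"` or `"jdi_subset"`.
#' @param kb required for `"jdi_subset"` (to read semantic types).
#' @return accuracy in `[0, 1]`.
#' @export
wsd_accuracy <- function(predictions, dataset, subset_mode = c("all", "jdi_subset"),
                         kb = NULL) {
  subset_mode <- match.arg(subset_mode)
  if (length(predictions) != length(dataset$instances)) {
    stop("predictions must cover every instance of the dataset")
  }
  keep <- rep(TRUE, length(predictions))
  if (subset_mode == "jdi_subset") {
    if (is.null(kb)) stop("jdi_subset needs the knowledge base for semantic types")
    keep <- !vapply(dataset$instances, function(i) .shared_type_sets(kb, i), logical(1))
  }
  if (!any(keep)) stop("no instances left after subset filtering; accuracy undefined")
  gold <- vapply(dataset$instances, `[[`, character(1), "gold")[keep]
  pred <- predictions[keep]
  mean(!is.na(pred) & pred == gold)
}
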