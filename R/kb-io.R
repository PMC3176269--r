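# Knowledge-base I/O.  The native format is a four-file TSV dialect
# (concepts.tsv, terms.tsv, relations.tsv, st_associations.tsv); a
# best-effort reader for UMLS RRF releases (MRCONSO/MRSTY/MRDEF/MRREL) is
# provided for users holding a UMLS license.

.read_tsv_strict <- function(file, columns) {
  if (!file.exists(file)) stop_parse("missing file: ", file)
  lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) stop_parse(file, ": empty, header row required")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  if (!identical(header, columns)) {
    stop_parse(file, " line 1: expected header ", paste(columns, collapse = "\t"))
  }
  n <- length(columns)
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    p <- parts[[i + 1L]]
    # strsplit drops trailing empty fields; the tab count is authoritative
    nf <- lengths(regmatches(lines[i + 1L], gregexpr("\t", lines[i + 1L], fixed = TRUE))) + 1L
    if (nf != n) {
      stop_parse(file, " line ", i + 1L, ": expected ", n, " fields, got ", nf)
    }
    if (length(p) < n) p <- c(p, rep("", n - length(p)))
    rows[[i]] <- p
  }
  out <- as.data.frame(do.call(rbind, c(rows, list(matrix(character(), 0, n)))),
                       stringsAsFactors = FALSE)
  names(out) <- columns
  out
}

.split_pipe <- function(x) {
  if (!nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1L]]
}

#' Load a knowledge base from disk
#'
#' The `"tsv"` dialect (authoritative, written by [write_kb()]) is a
#' directory with four UTF-8 tab-separated files with header rows:
#' `concepts.tsv` (`cui`, `preferred_name`, `semantic_types`, `definitions`;
#' the last two pipe-joined), `terms.tsv` (`term`, `cui`), `relations.tsv`
#' (`source_cui`, `kind`, `target_cui`) and `st_associations.tsv`
#' (`type_a`, `type_b`).  The `"rrf"` dialect reads UMLS
#' MRCONSO/MRSTY/MRDEF/MRREL pipe-delimited files from the directory, as a
#' convenience for license holders.
#'
#' Malformed lines raise a parse error naming file and line; dangling
#' relation endpoints and is_a cycles raise integrity errors.
#'
#' @param path directory containing the files.
#' @param dialect `"tsv"` or `"rrf"`.
#' @return a [knowledge_base()].
#' @export
load_kb <- function(path, dialect = c("tsv", "rrf")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(path)) stop_parse("no such directory: ", path)
  if (dialect == "rrf") return(.load_kb_rrf(path))

  con <- .read_tsv_strict(file.path(path, "concepts.tsv"),
                          c("cui", "preferred_name", "semantic_types", "definitions"))
  trm <- .read_tsv_strict(file.path(path, "terms.tsv"), c("term", "cui"))
  rel <- .read_tsv_strict(file.path(path, "relations.tsv"),
                          c("source_cui", "kind", "target_cui"))
  sta <- .read_tsv_strict(file.path(path, "st_associations.tsv"),
                          c("type_a", "type_b"))

  unknown <- setdiff(trm$cui, con$cui)
  if (length(unknown)) {
    stop_parse("terms.tsv references unknown cui: ", paste(sort(unknown), collapse = ", "))
  }
  concepts <- lapply(seq_len(nrow(con)), function(i) {
    cui <- con$cui[i]
    new_concept(
      cui = cui,
      preferred_name = con$preferred_name[i],
      synonyms = trm$term[trm$cui == cui],
      semantic_types = .split_pipe(con$semantic_types[i]),
      definitions = .split_pipe(con$definitions[i])
    )
  })
  knowledge_base(
    concepts,
    relations = data.frame(source = rel$source_cui, kind = rel$kind,
                           target = rel$target_cui, stringsAsFactors = FALSE),
    st_associations = sta
  )
}

#' Write a knowledge base in the TSV dialect
#'
#' Writes the four files read back by [load_kb()]; loading the result yields
#' a knowledge base equal to the input (set-wise round trip).
#'
#' @param kb a [knowledge_base()].
#' @param path output directory, created if needed.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cuis <- sort(names(kb$concepts))
  con <- data.frame(
    cui = cuis,
    preferred_name = vapply(cuis, function(k) kb$concepts[[k]]$preferred_name, character(1)),
    semantic_types = vapply(cuis, function(k) paste(kb$concepts[[k]]$semantic_types, collapse = "|"), character(1)),
    definitions = vapply(cuis, function(k) paste(kb$concepts[[k]]$definitions, collapse = "|"), character(1)),
    stringsAsFactors = FALSE
  )
  trm <- do.call(rbind, lapply(cuis, function(k) {
    data.frame(term = kb$concepts[[k]]$synonyms, cui = k, stringsAsFactors = FALSE)
  }))
  trm <- trm[order(trm$term, trm$cui), , drop = FALSE]
  rel <- data.frame(source_cui = kb$relations$source, kind = kb$relations$kind,
                    target_cui = kb$relations$target, stringsAsFactors = FALSE)

  .write_tsv <- function(df, file) {
    write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  .write_tsv(con, "concepts.tsv")
  .write_tsv(trm, "terms.tsv")
  .write_tsv(rel, "relations.tsv")
  .write_tsv(kb$st_associations, "st_associations.tsv")
  invisible(path)
}

# Best-effort UMLS RRF reader; field positions follow the standard column
# layouts of MRCONSO/MRSTY/MRDEF/MRREL.  English terms only.
.load_kb_rrf <- function(path) {
  rrf <- function(name) {
    f <- file.path(path, name)
    if (!file.exists(f)) stop_parse("missing file: ", f)
    lines <- readLines(f, warn = FALSE, encoding = "UTF-8")
    strsplit(lines, "|", fixed = TRUE)
  }
  conso <- rrf("MRCONSO.RRF")
  conso <- Filter(function(p) length(p) >= 15L && p[[2L]] == "ENG", conso)
  cui <- vapply(conso, `[[`, character(1), 1L)
  str <- vapply(conso, `[[`, character(1), 15L)
  ispref <- vapply(conso, function(p) p[[7L]] == "Y", logical(1))

  sty <- rrf("MRSTY.RRF")
  sty_cui <- vapply(sty, `[[`, character(1), 1L)
  sty_lab <- vapply(sty, `[[`, character(1), 4L)

  defs <- tryCatch(rrf("MRDEF.RRF"), error = function(e) list())
  def_cui <- vapply(defs, `[[`, character(1), 1L)
  def_txt <- vapply(defs, function(p) if (length(p) >= 6L) p[[6L]] else "", character(1))

  concepts <- lapply(unique(cui), function(k) {
    sel <- cui == k
    pref <- str[sel & ispref]
    new_concept(
      cui = k,
      preferred_name = if (length(pref)) pref[1L] else str[sel][1L],
      synonyms = str[sel],
      semantic_types = unique(sty_lab[sty_cui == k]),
      definitions = def_txt[def_cui == k]
    )
  })

  rels <- tryCatch(rrf("MRREL.RRF"), error = function(e) list())
  rel_df <- data.frame(source = character(), kind = character(),
                       target = character(), stringsAsFactors = FALSE)
  if (length(rels)) {
    c1 <- vapply(rels, `[[`, character(1), 1L)
    rl <- vapply(rels, `[[`, character(1), 4L)
    c2 <- vapply(rels, `[[`, character(1), 5L)
    keep <- c1 != c2 & c1 %in% cui & c2 %in% cui
    c1 <- c1[keep]; rl <- rl[keep]; c2 <- c2[keep]
    rel_df <- rbind(
      data.frame(source = c2[rl == "PAR"], kind = "is_a", target = c1[rl == "PAR"],
                 stringsAsFactors = FALSE),
      data.frame(source = c1[rl == "CHD"], kind = "is_a", target = c2[rl == "CHD"],
                 stringsAsFactors = FALSE),
      data.frame(source = c1[rl == "RO"], kind = "other_related", target = c2[rl == "RO"],
                 stringsAsFactors = FALSE)
    )
  }
  knowledge_base(concepts, relations = rel_df)
}
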