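test_that("a degenerate knowledge base of one concept and no relations loads", {
  kb <- knowledge_base(list(list(cui = "C1", preferred_name = "thing",
                                 semantic_types = "Cell")))
  expect_s3_class(kb, "knowledge_base")
  expect_length(kb$concepts, 1)
  expect_equal(nrow(kb$relations), 0)
  expect_equal(candidate_concepts(kb, "thing"), "C1")
})

test_that("every leaf of a 10-concept tree reaches the root through its chain", {
  kb <- toy_kb()
  expect_length(kb$concepts, 10)
  expect_equal(sum(kb$relations$kind == "is_a"), 9)
  leaves <- setdiff(names(kb$concepts), kb$relations$source[kb$relations$kind == "is_a"])
  for (leaf in leaves) {
    chain <- hypernym_chain(kb, leaf)
    expect_equal(chain[1], "C001")
    expect_equal(chain[length(chain)], leaf)
  }
  # hand-traced third-level chain
  expect_equal(hypernym_chain(kb, "C003"), c("C001", "C002", "C003"))
  expect_equal(hypernym_chain(kb, "C001"), "C001")
})

test_that("a concept with two parents follows the smallest parent cui", {
  kb <- knowledge_base(
    list(list(cui = "P1", preferred_name = "first parent", semantic_types = "Cell"),
         list(cui = "P2", preferred_name = "second parent", semantic_types = "Cell"),
         list(cui = "X9", preferred_name = "child node", semantic_types = "Cell")),
    data.frame(source = c("P1", "P2"), kind = "is_a", target = c("X9", "X9"),
               stringsAsFactors = FALSE)
  )
  expect_equal(hypernym_chain(kb, "X9"), c("P1", "X9"))
})

test_that("term lookup is case-insensitive and returns all senses", {
  kb <- toy_kb()
  expect_setequal(candidate_concepts(kb, "cold"), c("C003", "C006", "C008"))
  expect_setequal(candidate_concepts(kb, "COLD"), c("C003", "C006", "C008"))
  expect_equal(candidate_concepts(kb, "no such term"), character(0))
  expect_true(is_monosemous(kb, "cold storage"))
  expect_false(is_monosemous(kb, "cold"))
  expect_false(is_monosemous(kb, "unknown"))
  # every synonym of every concept indexes back to its cui
  for (co in kb$concepts) {
    for (s in co$synonyms) {
      expect_true(co$cui %in% candidate_concepts(kb, s))
    }
  }
})

test_that("profile sources include parents and exclude siblings", {
  kb <- toy_kb()
  bag <- profile_sources(kb, "C003")  # parent C002, sibling C004
  expect_true("disorder" %in% bag)
  expect_true(any(grepl("disorder of the body", bag)))
  expect_false("influenza" %in% bag)
  expect_false("flu" %in% bag)
  expect_true("common cold" %in% bag)
  # other_related endpoints contribute both ways
  expect_true("cold storage" %in% profile_sources(kb, "C006"))
  expect_true("cold temperature" %in% profile_sources(kb, "C009"))
  # concept with one synonym, no definitions, no relations
  kb1 <- knowledge_base(list(list(cui = "Z1", preferred_name = "lonely node",
                                  semantic_types = "Cell")))
  expect_equal(profile_sources(kb1, "Z1"), "lonely node")
})

test_that("integrity violations are rejected at construction", {
  base <- list(list(cui = "C1", preferred_name = "one", semantic_types = "Cell"),
               list(cui = "C2", preferred_name = "two", semantic_types = "Cell"))
  expect_error(
    knowledge_base(base, data.frame(source = "C1", kind = "is_a", target = "C9")),
    class = "wsdsumm_integrity_error")
  expect_error(
    knowledge_base(base, data.frame(source = "C1", kind = "is_a", target = "C1")),
    class = "wsdsumm_integrity_error")
  expect_error(
    knowledge_base(base, data.frame(source = c("C1", "C2"), kind = "is_a",
                                    target = c("C2", "C1"))),
    class = "wsdsumm_integrity_error")
  expect_error(
    knowledge_base(list(list(cui = "C1", preferred_name = "x",
                             semantic_types = character(0)))),
    class = "wsdsumm_integrity_error")
  expect_error(
    knowledge_base(c(base, list(list(cui = "C1", preferred_name = "dup",
                                     semantic_types = "Cell")))),
    class = "wsdsumm_integrity_error")
})

test_that("the TSV dialect round-trips a knowledge base identically", {
  kb <- toy_kb()
  dir <- withr::local_tempdir()
  write_kb(kb, dir)
  kb2 <- load_kb(dir, "tsv")
  expect_identical(names(kb$concepts)[order(names(kb$concepts))],
                   names(kb2$concepts)[order(names(kb2$concepts))])
  for (cui in names(kb$concepts)) {
    expect_identical(kb$concepts[[cui]], kb2$concepts[[cui]])
  }
  expect_identical(kb$relations, kb2$relations)
  expect_identical(kb$st_associations, kb2$st_associations)
  # and the index behaves the same
  expect_setequal(candidate_concepts(kb2, "cold"), c("C003", "C006", "C008"))
})

test_that("malformed TSV input names the file and line", {
  dir <- withr::local_tempdir()
  write_kb(toy_kb(), dir)
  cat("C999\tonly two fields\n", file = file.path(dir, "concepts.tsv"), append = TRUE)
  err <- tryCatch(load_kb(dir, "tsv"), error = function(e) e)
  expect_s3_class(err, "wsdsumm_parse_error")
  expect_match(conditionMessage(err), "concepts.tsv line 12")
})

test_that("relations referencing unknown concepts fail to load", {
  dir <- withr::local_tempdir()
  write_kb(toy_kb(), dir)
  cat("C001\tis_a\tC999\n", file = file.path(dir, "relations.tsv"), append = TRUE)
  expect_error(load_kb(dir, "tsv"), class = "wsdsumm_integrity_error")
})

test_that("hypernym depths increase by one along generated forests", {
  spec <- default_fixture_spec(seed = 11)
  kb <- generate_kb(spec)
  for (cui in sample(names(kb$concepts), 20)) {
    chain <- hypernym_chain(kb, cui)
    expect_lte(length(chain), spec$hierarchy_depth)
    for (k in seq_along(chain)) {
      expect_equal(length(hypernym_chain(kb, chain[k])), k)
    }
  }
})
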