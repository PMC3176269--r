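test_that("concept identification respects ambiguity resolution and the type filter", {
  kb <- toy_kb()
  profiles <- build_concept_profiles(kb)
  doc <- c("The cold with runny nose sneezing viral infection.",
           "Influenza spreads in winter.",
           "Cold storage keeps goods fresh.")
  got <- identify_concepts(kb, doc, wsd = "mrd", profiles = profiles)
  expect_true("C003" %in% got$sentences[[1]]$concepts)   # context-resolved sense
  expect_equal(got$sentences[[2]]$concepts, "C004")
  expect_true("C009" %in% got$sentences[[3]]$concepts)   # longest match, not "cold"
  # first-mapping baseline takes the smallest cui instead
  first <- identify_concepts(kb, doc, wsd = "first_mapping")
  amb <- first$mappings[first$mappings$ambiguous, ]
  expect_equal(amb$chosen, "C003")
  # concepts typed only with generic categories are filtered
  kbg <- knowledge_base(list(
    list(cui = "G1", preferred_name = "january timeframe",
         semantic_types = "Temporal concept"),
    list(cui = "K1", preferred_name = "heart muscle",
         semantic_types = "Body Part, Organ, or Organ Component")
  ))
  got2 <- identify_concepts(kbg, "The january timeframe for the heart muscle.",
                            wsd = "first_mapping")
  expect_equal(got2$sentences[[1]]$concepts, "K1")
  expect_error(identify_concepts(kb, doc, wsd = "jdi"), "jd model")
})

test_that("sentence graphs merge hypernym chains and drop the two upper levels", {
  kb <- chain_kb()
  g <- build_sentence_graph(kb, "D")  # chain A(1) B(2) C(3) D(4)
  expect_setequal(g$vertices$cui, c("C", "D"))
  expect_equal(g$vertices$depth[g$vertices$cui == "C"], 3)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$from, "C")
  expect_equal(g$edges$to, "D")
  # a concept living at depth 2 is trimmed away entirely
  g2 <- build_sentence_graph(kb, "B")
  expect_equal(nrow(g2$vertices), 0)
  # shared ancestors appear once
  g3 <- build_sentence_graph(kb, c("D", "E"))
  expect_setequal(g3$vertices$cui, c("C", "D", "E"))
  expect_equal(sum(g3$vertices$cui == "C"), 1)
  expect_equal(nrow(build_sentence_graph(kb, character(0))$vertices), 0)
})

test_that("document graph weights follow the depth-ratio rule", {
  kb <- chain_kb()
  sg <- list(build_sentence_graph(kb, c("D", "E", "F")))
  g <- build_document_graph(kb, sg)
  isa <- g$edges[g$edges$kind == "is_a", ]
  expect_equal(isa$weight[isa$from == "C" & isa$to == "D"], 3 / 4)
  expect_true(all(g$edges$weight >= 0 & g$edges$weight <= 1))
  # leaf vertices D and E have associated semantic types -> weight-1 edge
  aw <- g$edges[g$edges$kind == "associated_with", ]
  expect_true(nrow(aw) >= 1)
  expect_true(all(aw$weight == 1))
  # salience conservation
  expect_equal(sum(g$vertices$salience), 2 * sum(g$edges$weight))
})

test_that("other_related edges get weight 1 and isolated vertices salience 0", {
  kb <- toy_kb()
  sgs <- lapply(list("C003", "C006", "C009"),
                function(cc) build_sentence_graph(kb, cc))
  g <- build_document_graph(kb, sgs)
  orl <- g$edges[g$edges$kind == "other_related", ]
  expect_equal(nrow(orl), 1)   # C006 - C009 from the kb
  expect_equal(orl$weight, 1)
  iso <- setdiff(g$vertices$cui, c(g$edges$from, g$edges$to))
  expect_true(all(g$vertices$salience[g$vertices$cui %in% iso] == 0))
})

test_that("clustering splits disconnected hub regions and unifies connected ones", {
  tri <- function(a, b, c) {
    data.frame(from = c(a, b, a), to = c(b, c, c), kind = "other_related",
               weight = 1, stringsAsFactors = FALSE)
  }
  g <- structure(list(
    vertices = data.frame(cui = c("A1", "A2", "A3", "B1", "B2", "B3"),
                          depth = 3L, salience = c(2, 2, 2, 2, 2, 2)),
    edges = rbind(tri("A1", "A2", "A3"), tri("B1", "B2", "B3"))
  ), class = "document_graph")
  cl <- cluster_concepts(g, hub_fraction = 0.35)  # top 3 by tie-break: A1 A2 A3
  # hubs A1..A3 form one component; B-triangle attaches nowhere
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$hvs, c("A1", "A2", "A3"))
  expect_setequal(cl[[1]]$members, c("A1", "A2", "A3"))
  # raising the fraction far enough seeds both triangles
  cl2 <- cluster_concepts(g, hub_fraction = 0.67)
  expect_length(cl2, 2)
  expect_setequal(cl2[[1]]$members, c("A1", "A2", "A3"))
  expect_setequal(cl2[[2]]$members, c("B1", "B2", "B3"))
  # fully connected graph collapses to one cluster containing everything
  gc <- structure(list(
    vertices = data.frame(cui = c("X", "Y", "Z"), depth = 3L,
                          salience = c(2, 2, 2)),
    edges = tri("X", "Y", "Z")
  ), class = "document_graph")
  cl3 <- cluster_concepts(gc, hub_fraction = 0.4)
  expect_length(cl3, 1)
  expect_setequal(cl3[[1]]$members, c("X", "Y", "Z"))
  # singleton graph
  g1 <- structure(list(
    vertices = data.frame(cui = "V", depth = 3L, salience = 0),
    edges = data.frame(from = character(), to = character(),
                       kind = character(), weight = numeric())
  ), class = "document_graph")
  cl4 <- cluster_concepts(g1)
  expect_equal(cl4[[1]]$hvs, "V")
  expect_equal(cl4[[1]]$members, "V")
  expect_length(cluster_concepts(structure(list(
    vertices = data.frame(cui = character(), depth = integer(),
                          salience = numeric()),
    edges = data.frame(from = character(), to = character(),
                       kind = character(), weight = numeric())
  ), class = "document_graph")), 0)
})

test_that("non-democratic votes weight hvs membership double", {
  cluster <- list(hvs = c("H1", "H2"), members = c("H1", "H2", "M1", "M2"))
  sg <- list(vertices = data.frame(cui = c("H1", "H2", "M1"), depth = 3L))
  expect_equal(sentence_similarity(sg, cluster), 2.5)
  sg0 <- list(vertices = data.frame(cui = c("Q1", "Q2"), depth = 3L))
  expect_equal(sentence_similarity(sg0, cluster), 0)
  sgh <- list(vertices = data.frame(cui = c("H1", "H2"), depth = 3L))
  expect_equal(sentence_similarity(sgh, cluster), 2)
})

test_that("sentence scores divide votes by cluster size and sum over clusters", {
  c1 <- list(hvs = c("H1", "H2"), members = c("H1", "H2", "M1", "M2"))
  sg <- list(vertices = data.frame(cui = c("H1", "H2"), depth = 3L))
  expect_equal(score_sentences(list(sg), list(c1))$score, 0.5)
  c2 <- list(hvs = "K1", members = c("K1", "K2", "K3", "K4", "K5"))
  sg2 <- list(vertices = data.frame(cui = c("H1", "K1", "K2", "K3"), depth = 3L))
  # votes: 1 to c1 (size 4), 1 + 0.5 + 0.5 = 2 to c2 (size 5)
  expect_equal(score_sentences(list(sg2), list(c1, c2))$score, 1 / 4 + 2 / 5)
  sg0 <- list(vertices = data.frame(cui = "Q9", depth = 3L))
  expect_equal(score_sentences(list(sg0), list(c1, c2))$score, 0)
  expect_error(score_sentences(list(sg), list()), "cluster")
  expect_error(score_sentences(list(sg), list(list(hvs = "a", members = character(0)))),
               "zero-size")
})

test_that("selection fills the compression budget in score order, output in document order", {
  spec <- default_fixture_spec(seed = 13)
  kb <- generate_kb(spec)
  prof <- build_concept_profiles(kb)
  doc <- generate_corpus(kb, spec)[[1]]
  sm <- summarize_document(kb, doc$sentences, wsd = "mrd", profiles = prof,
                           compression = 0.3)
  # equal-length sentences: 30% of 10 sentences -> exactly 3, sorted
  expect_length(sm$selected, 3)
  expect_equal(sm$selected, sort(sm$selected))
  expect_equal(sm$selected, doc$topic_positions)
  all_s <- summarize_document(kb, doc$sentences, wsd = "mrd", profiles = prof,
                              compression = 1)
  expect_equal(all_s$selected, 0:(length(doc$sentences) - 1))
  one <- summarize_document(kb, doc$sentences[1], wsd = "first_mapping")
  expect_equal(one$selected, 0)
  expect_error(summarize_document(kb, character(0)), "no sentences")
})

test_that("summarization is deterministic for identical inputs", {
  spec <- default_fixture_spec(seed = 17)
  kb <- generate_kb(spec)
  prof <- build_concept_profiles(kb)
  doc <- generate_corpus(kb, spec)[[3]]
  a <- summarize_document(kb, doc$sentences, wsd = "mrd", profiles = prof)
  b <- summarize_document(kb, doc$sentences, wsd = "mrd", profiles = prof)
  expect_identical(a$selected, b$selected)
  expect_identical(a$scores, b$scores)
})

test_that("common-mapping agreement counts identical decisions on ambiguous phrases", {
  mk <- function(chosen) data.frame(
    sentence_index = c(0L, 0L, 1L, 2L, 3L),
    token_start = 1L,
    phrase = c("cold", "unique phrase", "cold", "cold", "cold"),
    candidates = c("C1|C2", "C9", "C1|C2", "C1|C2", "C1|C2"),
    chosen = chosen,
    ambiguous = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  a <- mk(c("C1", "C9", "C1", "C2", "C1"))
  b <- mk(c("C1", "C9", "C1", "C1", "C1"))
  expect_equal(common_mapping_agreement(a, a), 1)
  expect_equal(common_mapping_agreement(a, b), 0.75)
  expect_equal(common_mapping_agreement(mk(c("C1", "C9", "C1", "C1", "C1")),
                                        mk(c("C2", "C9", "C2", "C2", "C2"))), 0)
  bad <- b[-1, ]
  expect_error(common_mapping_agreement(a, bad), "same ambiguous")
})

test_that("plain text splits into sentences at terminal punctuation", {
  s <- split_sentences("First sentence here. Second one! And a third? Done.")
  expect_length(s, 4)
  expect_equal(s[2], "Second one!")
})
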