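# Knowledge base mirroring a two-sense ambiguous term with monosemous
# synonyms and related concepts, for query-construction tests.
aec_kb <- function(extra = list()) {
  concepts <- c(list(
    list(cui = "C100", preferred_name = "surgical repair",
         synonyms = c("repair", "operative repair"),
         semantic_types = "Therapeutic or Preventive Procedure",
         definitions = "operative restoration procedure suturing"),
    list(cui = "C200", preferred_name = "wound healing",
         synonyms = c("repair", "tissue repair"),
         semantic_types = "Organism Function",
         definitions = "biological process closing wounds granulation"),
    list(cui = "C101", preferred_name = "suture technique",
         semantic_types = "Therapeutic or Preventive Procedure",
         definitions = "stitching tissue together"),
    list(cui = "C201", preferred_name = "granulation tissue",
         semantic_types = "Tissue",
         definitions = "new connective tissue in healing")
  ), extra)
  relations <- data.frame(
    source = c("C100", "C200"), kind = "other_related",
    target = c("C101", "C201"), stringsAsFactors = FALSE
  )
  knowledge_base(concepts, relations)
}

test_that("queries mix monosemous synonyms and term+relative conjunctions", {
  kb <- aec_kb()
  qs <- build_aec_queries(kb, "repair")
  expect_length(qs, 2)
  expect_equal(vapply(qs, `[[`, character(1), "cui"), c("C100", "C200"))
  q1 <- qs[[1]]
  expect_setequal(q1$synonyms, c("operative repair", "surgical repair"))
  expect_true("suture technique" %in% q1$relatives)
  expect_match(q1$expression, "\"surgical repair\"\\[tiab\\]")
  expect_match(q1$expression, "\\(\"repair\"\\[tiab\\] AND \"suture technique\"\\[tiab\\]\\)")
  # fallback swaps quotes for parentheses
  expect_match(q1$fallback_expression, "\\(surgical repair\\)\\[tiab\\]", )
  expect_false(grepl('"', q1$fallback_expression))
  q2 <- qs[[2]]
  expect_true("tissue repair" %in% q2$synonyms)
  expect_true("granulation tissue" %in% q2$relatives)
})

test_that("retrieval term filters drop long, short, numeric and stop-word terms", {
  long_syn <- paste(rep("verylongword", 5), collapse = " ")  # > 50 characters
  kb <- aec_kb(list(
    list(cui = "C300", preferred_name = "third sense of repair",
         synonyms = c("repair", "mg", "1234", "very", long_syn),
         semantic_types = "Cell", definitions = character())
  ))
  qs <- build_aec_queries(kb, "repair")
  q3 <- qs[[which(vapply(qs, `[[`, character(1), "cui") == "C300")]]
  expect_false(long_syn %in% q3$synonyms)     # > 50 chars
  expect_false("mg" %in% q3$synonyms)          # < 3 chars
  expect_false("1234" %in% q3$synonyms)        # pure number
  expect_false("very" %in% q3$synonyms)        # stop word
  expect_true("third sense of repair" %in% q3$synonyms)
})

test_that("the offline searcher matches phrases strictly and loosely", {
  corpus <- data.frame(
    id = paste0("d", 1:4),
    text = c("a case of surgical repair of the hernia",
             "repair was achieved by suture technique applied twice",
             "the repair by technique of suture",   # words present, phrase not
             "nothing relevant here"),
    stringsAsFactors = FALSE
  )
  kb <- aec_kb()
  qs <- build_aec_queries(kb, "repair")
  searcher <- make_offline_searcher(corpus)
  hits <- searcher(qs[[1]], mode = "primary")
  expect_setequal(hits$id, c("d1", "d2"))
  loose <- searcher(qs[[1]], mode = "fallback")
  expect_setequal(loose$id, c("d1", "d2", "d3"))
})

test_that("corpus collection caps documents, falls back, and flags untrainable senses", {
  kb <- aec_kb()
  qs <- build_aec_queries(kb, "repair")
  mk_doc <- function(i, text) data.frame(id = paste0("m", i), text = text,
                                         stringsAsFactors = FALSE)
  corpus <- do.call(rbind, c(
    lapply(1:5, function(i) mk_doc(i, "surgical repair of the hernia")),
    list(mk_doc(6, "healing wound granulation observed"))  # loose words only
  ))
  searcher <- make_offline_searcher(corpus)
  got <- collect_training_corpus(qs, searcher, limit = 3)
  expect_equal(sum(got$cui == "C100"), 3)  # capped at limit, searcher order
  expect_equal(got$id[got$cui == "C100"], paste0("m", 1:3))
  # "wound healing" phrase absent -> fallback finds the loose-word doc
  expect_equal(got$id[got$cui == "C200"], "m6")
  # a query with no usable relatives warns and is skipped
  empty_q <- qs[[1]]
  empty_q$synonyms <- character(0)
  empty_q$relatives <- character(0)
  empty_q$empty <- TRUE
  expect_warning(out <- collect_training_corpus(list(empty_q), searcher),
                 "untrainable")
  expect_equal(nrow(out), 0)
})

test_that("naive Bayes satisfies its normalization invariants", {
  corpus <- data.frame(
    cui = c("C1", "C1", "C2"),
    id = paste0("d", 1:3),
    text = c("alpha beta beta", "alpha gamma", "delta delta epsilon"),
    stringsAsFactors = FALSE
  )
  m <- train_nb(corpus, stopwords = character(0))
  expect_equal(sum(exp(m$class_log_priors)), 1, tolerance = 1e-9)
  for (cl in rownames(m$word_log_likelihoods)) {
    expect_equal(sum(exp(m$word_log_likelihoods[cl, ])), 1, tolerance = 1e-9)
  }
})

test_that("naive Bayes matches a hand-computed smoothed posterior", {
  # two classes, overlapping vocabulary {alpha, beta, gamma}
  corpus <- data.frame(
    cui = c("CA", "CB"), id = c("d1", "d2"),
    text = c("alpha alpha beta", "beta gamma"),
    stringsAsFactors = FALSE
  )
  m <- train_nb(corpus, stopwords = character(0))
  # class CA: counts alpha=2, beta=1, gamma=0, total 3, V=3
  expect_equal(m$word_log_likelihoods["CA", "alpha"], log(3 / 6))
  expect_equal(m$word_log_likelihoods["CA", "gamma"], log(1 / 6))
  expect_equal(m$word_log_likelihoods["CB", "beta"], log(2 / 5))
  inst <- wsd_instance("w", "beta gamma gamma", c("CA", "CB"))
  # log posterior CA: log(1/2) + log(2/6) + 2*log(1/6)
  # log posterior CB: log(1/2) + log(2/5) + 2*log(2/5)
  expect_equal(aec_disambiguate(m, inst, stopwords = character(0)), "CB")
  inst2 <- wsd_instance("w", "alpha alpha", c("CA", "CB"))
  expect_equal(aec_disambiguate(m, inst2, stopwords = character(0)), "CA")
})

test_that("disjoint training vocabularies give a separable classifier", {
  corpus <- data.frame(
    cui = rep(c("CA", "CB"), each = 2),
    id = paste0("d", 1:4),
    text = c("heart valve muscle", "valve muscle pump",
             "kidney filter nephron", "filter nephron tubule"),
    stringsAsFactors = FALSE
  )
  m <- train_nb(corpus)
  inst <- wsd_instance("organ", "the muscle pump with a valve", c("CA", "CB"))
  expect_equal(aec_disambiguate(m, inst), "CA")
  inst2 <- wsd_instance("organ", "nephron and tubule in the kidney", c("CA", "CB"))
  expect_equal(aec_disambiguate(m, inst2), "CB")
  # candidate without training data is excluded with a warning
  inst3 <- wsd_instance("organ", "muscle pump", c("CA", "CB", "CZ"))
  expect_warning(pred <- aec_disambiguate(m, inst3), "CZ")
  expect_equal(pred, "CA")
})

test_that("end-to-end aec training on the synthetic world is accurate when separable", {
  spec <- default_fixture_spec(seed = 5)
  kb <- generate_kb(spec)
  ds <- generate_wsd_dataset(kb, spec, n_instances = 60, separability = 1)
  searcher <- make_offline_searcher(generate_search_corpus(kb, spec))
  pred <- predict_wsd(kb, ds, "aec", searcher = searcher)
  expect_gte(wsd_accuracy(pred, ds), 0.95)
})
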