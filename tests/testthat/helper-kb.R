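# Hand-built miniature knowledge bases used across the unit tests.

# A 10-concept tree (9 is_a edges), one three-way ambiguous term ("cold"),
# a monosemous multiword term ("cold storage"), a sibling pair, one
# other_related edge and one semantic-type association.
toy_kb <- function() {
  concepts <- list(
    list(cui = "C001", preferred_name = "entity",
         semantic_types = "Idea or concept",
         definitions = "top node of the toy hierarchy"),
    list(cui = "C002", preferred_name = "disorder",
         semantic_types = "Disease or Syndrome",
         definitions = "any disorder of the body"),
    list(cui = "C003", preferred_name = "common cold",
         synonyms = c("cold", "acute coryza"),
         semantic_types = "Disease or Syndrome",
         definitions = "viral infection runny nose sneezing"),
    list(cui = "C004", preferred_name = "influenza",
         synonyms = "flu",
         semantic_types = "Disease or Syndrome",
         definitions = "viral infection fever aches"),
    list(cui = "C005", preferred_name = "physical phenomenon",
         semantic_types = "Natural Phenomenon or Process",
         definitions = character()),
    list(cui = "C006", preferred_name = "cold temperature",
         synonyms = "cold",
         semantic_types = "Natural Phenomenon or Process",
         definitions = "low temperature of the environment"),
    list(cui = "C007", preferred_name = "perception",
         semantic_types = "Organism Function",
         definitions = character()),
    list(cui = "C008", preferred_name = "cold sensation",
         synonyms = "cold",
         semantic_types = "Organism Function",
         definitions = "feeling of being cold shivering"),
    list(cui = "C009", preferred_name = "cold storage",
         semantic_types = "Manufactured Object",
         definitions = "refrigerated storage of goods"),
    list(cui = "C010", preferred_name = "storage facility",
         semantic_types = "Manufactured Object",
         definitions = character())
  )
  relations <- data.frame(
    source = c("C001", "C002", "C002", "C001", "C005", "C001", "C007", "C001", "C010"),
    kind = "is_a",
    target = c("C002", "C003", "C004", "C005", "C006", "C007", "C008", "C010", "C009"),
    stringsAsFactors = FALSE
  )
  relations <- rbind(relations, data.frame(
    source = "C006", kind = "other_related", target = "C009",
    stringsAsFactors = FALSE))
  knowledge_base(concepts, relations,
                 st_associations = data.frame(
                   type_a = "Disease or Syndrome",
                   type_b = "Natural Phenomenon or Process",
                   stringsAsFactors = FALSE))
}

# deeper chain fixture for graph-construction tests:
# A(1) -> B(2) -> C(3) -> D(4), plus E(3) under B and F(1) isolated
chain_kb <- function() {
  mk <- function(cui, name, type = "Disease or Syndrome", def = character()) {
    list(cui = cui, preferred_name = name, semantic_types = type,
         definitions = def)
  }
  concepts <- list(
    mk("A", "alpha node"), mk("B", "beta node"), mk("C", "gamma node"),
    mk("D", "delta node"), mk("E", "epsilon node", "Cell"),
    mk("F", "zeta node", "Cell")
  )
  relations <- data.frame(
    source = c("A", "B", "C", "B"), kind = "is_a",
    target = c("B", "C", "D", "E"), stringsAsFactors = FALSE
  )
  knowledge_base(concepts, relations,
                 st_associations = data.frame(
                   type_a = "Disease or Syndrome", type_b = "Cell",
                   stringsAsFactors = FALSE))
}

default_fixture_spec <- function(seed = 1L, ...) fixture_spec(seed = seed, ...)
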