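test_that("term ids parse from both CURIE dialects to one canonical form", {
  expect_equal(parse_term_id("HP:0001943"), "HP:0001943")
  expect_equal(parse_term_id("MP_0003951"), "MP:0003951")
  expect_equal(parse_term_id(c("GO:1", "GO_1")), c("GO:1", "GO:1"))
  # prefixes containing underscores split at the last underscore
  expect_equal(parse_term_id("OBO_REL_0000001"), "OBO_REL:0000001")
  expect_equal(term_prefix(c("PATO:0001163", "CHEBI:17234")),
               c("PATO", "CHEBI"))
})

test_that("term id parsing is idempotent on canonical ids", {
  withr::with_seed(11, {
    ids <- sprintf("%s:%07d",
                   sample(c("GO", "MP", "PATO", "CHEBI"), 50, replace = TRUE),
                   sample.int(10^7, 50))
    expect_identical(parse_term_id(ids), ids)
    expect_identical(parse_term_id(gsub(":", "_", ids)), ids)
  })
})

test_that("malformed identifiers and relations are rejected", {
  expect_error(parse_term_id(""), "empty")
  expect_error(parse_term_id("nodelimiter"), "malformed")
  expect_error(parse_term_id(":0001"), "malformed")
  expect_error(parse_term_id("GO:"), "malformed")
  expect_equal(parse_relation("OBO_REL:inheres_in"), "inheres_in")
  expect_equal(parse_relation("towards"), "towards")
  expect_error(parse_relation("is_a"), "structural")
})

test_that("validation reports cycles, dangling endpoints and obsolete parents", {
  expect_equal(nrow(validate_ontology(ontology_graph())), 0L)

  cyc <- ontology_graph(c("X:1", "X:2"),
                        isa = tibble::tibble(child = c("X:1", "X:2"),
                                             parent = c("X:2", "X:1")))
  f <- validate_ontology(cyc)
  expect_equal(f$type, "isa_cycle")
  expect_setequal(f$terms[[1]], c("X:1", "X:2"))

  dang <- ontology_graph(c("X:1"),
                         isa = tibble::tibble(child = "X:1", parent = "X:9"))
  expect_equal(validate_ontology(dang)$type, "dangling_edge")

  obs <- ontology_graph(
    terms = tibble::tibble(id = c("X:1", "X:2"), label = c("a", "b"),
                           obsolete = c(FALSE, TRUE)),
    isa = tibble::tibble(child = "X:1", parent = "X:2"))
  expect_true("obsolete_with_children" %in% validate_ontology(obs)$type)
  pruned <- drop_obsolete(obs)
  expect_equal(pruned$terms$id, "X:1")
  expect_equal(nrow(pruned$isa), 0L)
})

test_that("cycle detection agrees with an independent DFS on random graphs", {
  for (s in 1:20) {
    g <- random_graph(s, n = 30, m = 50)
    got_cycle <- any(validate_ontology(g)$type == "isa_cycle")
    expect_identical(got_cycle, dfs_has_cycle(g$isa), info = paste("seed", s))
    expect_false(got_cycle) # rank-ordered construction is acyclic
  }
  # plant a back edge and both detectors must fire
  withr::with_seed(99, {
    g <- random_graph(3, n = 10, m = 15)
    e <- g$isa[1, ]
    broken <- ontology_graph(g$terms,
                             isa = dplyr::bind_rows(
                               g$isa, tibble::tibble(child = e$parent,
                                                     parent = e$child)))
    expect_true(any(validate_ontology(broken)$type == "isa_cycle"))
    expect_true(dfs_has_cycle(broken$isa))
  })
})

test_that("validation is pure and idempotent", {
  g <- random_graph(7)
  before <- g
  f1 <- validate_ontology(g)
  f2 <- validate_ontology(g)
  expect_identical(f1, f2)
  expect_identical(g, before)
})

test_that("definitions reject self-reference, missing genus and duplicates", {
  expect_error(xp_definition("X:1", "X:1"), "itself")
  d1 <- xp_definition("X:1", "Q:1", list(c("towards", "F:1")))
  expect_error(validate_definitions(dplyr::bind_rows(d1, d1)),
               "more than one")
  no_genus <- tibble::tibble(defined = "X:1", role = "differentia",
                             relation = "towards", filler = "F:1", pos = 1L)
  expect_error(validate_definitions(no_genus), "genus")
  expect_silent(validate_definitions(d1))
})

test_that("referenced terms by prefix match an exhaustive scan", {
  hypo <- example_corpus("hypoglycemia_parse")$expected_definition
  expect_setequal(referenced_terms(hypo, "PATO"),
                  c("PATO:0001163", "PATO:0000460"))
  expect_equal(referenced_terms(hypo, "GO"), character())
  expect_setequal(referenced_prefixes(hypo),
                  c("PATO", "CHEBI", "FMA"))

  withr::with_seed(5, {
    defs <- dplyr::bind_rows(lapply(1:100, function(i) {
      xp_definition(
        sprintf("MP:%07d", i),
        sprintf("%s:%04d", sample(c("PQ", "GO"), 1), sample.int(50, 1)),
        tibble::tibble(relation = "towards",
                       filler = sprintf("%s:%04d", sample(c("GO", "CL"), 1),
                                        sample.int(50, 1))))
    }))
    for (p in c("PQ", "GO", "CL", "XX")) {
      scan <- unique(defs$filler[startsWith(defs$filler, paste0(p, ":"))])
      expect_setequal(referenced_terms(defs, p), scan)
    }
  })
})
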