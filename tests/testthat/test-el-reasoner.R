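test_that("normalizing a four-conjunct definition yields the stated forms", {
  fx <- example_corpus("hypoglycemia_parse")
  comp <- suppressWarnings(build_composite(list(), fx$expected_definition))
  ax <- normalize_axioms(comp)
  # one genus inclusion, three existential inclusions
  expect_equal(nrow(ax$type1), 1L)
  expect_equal(ax$type1$sub, "HP:0001943")
  expect_equal(ax$type1$sup, "PATO:0001163")
  expect_equal(nrow(ax$type3), 3L)
  # converse direction: three filler names, three chain conjunctions
  expect_equal(nrow(ax$type4), 3L)
  expect_equal(nrow(ax$type2), 3L)
  expect_equal(ax$type2$sup[3], "HP:0001943")
  expect_equal(length(ax$fresh), 5L) # 3 differentia names + 2 chain names
})

test_that("a single-genus definition is a plain equivalence", {
  d <- xp_definition("X:1", "Q:1")
  comp <- suppressWarnings(build_composite(list(ontology_graph("Q:1")), d))
  ax <- normalize_axioms(comp)
  expect_equal(nrow(ax$type2) + nrow(ax$type3) + nrow(ax$type4), 0L)
  expect_setequal(paste(ax$type1$sub, ax$type1$sup),
                  c("X:1 Q:1", "Q:1 X:1"))
  cl <- el_classify(ax)
  expect_true(any(vapply(cl$equiv_classes,
                         function(x) setequal(x, c("Q:1", "X:1")),
                         logical(1))))
})

test_that("an empty axiom set classifies to the reflexive closure", {
  cl <- el_classify(normalize_axioms(build_composite(list())))
  expect_equal(length(cl$names), 0L)
  comp <- build_composite(list(ontology_graph(c("A:1", "A:2"))))
  cl <- el_classify(normalize_axioms(comp))
  expect_identical(unname(cl$subsumes), diag(2) > 0)
})

test_that("entity-quality definitions over a subsumed process entail the
           subsumption of the phenotypes", {
  cx <- example_corpus("copper_homeostasis")
  rep <- validate_corpus(cx)
  cl <- attr(rep, "closure")
  expect_true(is_subsumed(cl, "MP:0003951", "MP:0001765"))
  expect_false(is_subsumed(cl, "MP:0001765", "MP:0003951"))
})

test_that("symbol-identical definitions land in one equivalence class", {
  cx <- example_corpus("uric_acid_equivalence")
  rep <- validate_corpus(cx)
  expect_equal(rep$equivalences, list(c("MP:0005561", "MP:0009356")))
})

test_that("completion-rule classification matches the canonical-model
           oracle on random EL composites", {
  for (s in 1:60) {
    comp <- random_el_composite(s)
    c1 <- el_classify(normalize_axioms(comp))
    c2 <- el_classify_canonical(comp)
    expect_true(closures_agree(c1, c2), info = paste("seed", s))
  }
})

test_that("classification is monotone under added axioms", {
  for (s in 1:10) {
    comp <- random_el_composite(s)
    cl <- el_classify(normalize_axioms(comp))
    ids <- comp$graph$terms$id
    extra <- withr::with_seed(s + 500, sample(ids, 2))
    comp2 <- build_composite(
      list(merge_graphs(list(comp$graph, ontology_graph(
        extra, isa = tibble::tibble(child = extra[1], parent = extra[2]))))),
      comp$definitions, comp$bridges)
    cl2 <- el_classify(normalize_axioms(comp2))
    nm <- sort(cl$names)
    expect_true(all(cl2$subsumes[nm, nm] >= cl$subsumes[nm, nm]),
                info = paste("seed", s))
  }
})

test_that("classification does not depend on axiom iteration order", {
  comp <- random_el_composite(17)
  cl <- el_classify(normalize_axioms(comp))
  ax <- normalize_axioms(comp)
  perm <- withr::with_seed(1, {
    ax$type1 <- ax$type1[sample.int(nrow(ax$type1)), ]
    ax$type2 <- ax$type2[sample.int(nrow(ax$type2)), ]
    ax$type3 <- ax$type3[sample.int(nrow(ax$type3)), ]
    ax$type4 <- ax$type4[sample.int(nrow(ax$type4)), ]
    ax
  })
  cl2 <- el_classify(perm)
  expect_true(closures_agree(cl, cl2))
})

test_that("closure is reflexive and transitive", {
  for (s in c(2, 9, 23)) {
    cl <- el_classify(normalize_axioms(random_el_composite(s)))
    S <- cl$subsumes
    expect_true(all(diag(S)))
    expect_true(all(((S %*% S) > 0) <= S), info = paste("seed", s))
  }
})

test_that("the inferred target hierarchy is the transitive reduction", {
  # a pure chain reduces to its two covers
  defs <- dplyr::bind_rows(
    xp_definition("MP:1", "Q:1"),
    xp_definition("MP:2", "Q:2"),
    xp_definition("MP:3", "Q:3"))
  g <- ontology_graph(c("Q:1", "Q:2", "Q:3"),
                      isa = tibble::tibble(child = c("Q:1", "Q:2"),
                                           parent = c("Q:2", "Q:3")))
  comp <- build_composite(list(g), defs)
  cl <- el_classify(normalize_axioms(comp))
  inf <- inferred_target_axioms(cl, "MP", c("MP:1", "MP:2", "MP:3"))
  expect_equal(inf$direct_edges,
               tibble::tibble(child = c("MP:1", "MP:2"),
                              parent = c("MP:2", "MP:3")))

  # reduction preserves reachability of the strict order (random corpora)
  for (s in 1:8) {
    cx <- generate_corpus(corpus_spec(seed = s))
    comp <- build_composite(unname(cx$blocks), cx$definitions)
    cl <- el_classify(normalize_axioms(comp))
    defined <- unique(cx$definitions$defined)
    inf <- inferred_target_axioms(cl, "MP", defined)
    reps <- unique(inf$classes$representative)
    for (a in reps) {
      for (b in setdiff(reps, a)) {
        strict <- is_subsumed(cl, a, b) && !is_subsumed(cl, b, a)
        via_direct <- nrow(inf$direct_edges) > 0 &&
          brute_reachable(inf$direct_edges, a, b)
        expect_identical(via_direct, strict,
                         info = paste(s, a, b))
      }
    }
  }
})

test_that("fresh names and self-subsumptions never surface in target axioms", {
  for (s in c(4, 12)) {
    comp <- random_el_composite(s)
    ax <- normalize_axioms(comp)
    cl <- el_classify(ax)
    expect_false(any(ax$fresh %in% cl$names))
    defined <- unique(comp$definitions$defined)
    inf <- inferred_target_axioms(cl, "A", defined)
    expect_false(any(inf$direct_edges$child == inf$direct_edges$parent))
    expect_false(any(grepl("^~", c(inf$direct_edges$child,
                                   inf$direct_edges$parent))))
  }
})
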