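test_that("inferred edges are classified direct / indirect / new correctly", {
  # target asserts A [= B [= C; definitions entail A [= C (and the chain)
  defs <- dplyr::bind_rows(
    xp_definition("MP:1", "Q:1"),
    xp_definition("MP:2", "Q:2"),
    xp_definition("MP:3", "Q:3"))
  q <- ontology_graph(c("Q:1", "Q:2", "Q:3"),
                      isa = tibble::tibble(child = c("Q:1", "Q:2"),
                                           parent = c("Q:2", "Q:3")))
  target <- ontology_graph(
    c("MP:1", "MP:2", "MP:3"),
    isa = tibble::tibble(child = c("MP:1", "MP:2"),
                         parent = c("MP:2", "MP:3")))
  rep <- validate_corpus(list(blocks = list(Q = q), definitions = defs,
                              target = target))
  expect_equal(rep$inferred$category, c("direct", "direct"))
  expect_true(all(rep$asserted$found))

  # drop the asserted chain bottom edge: the entailed (MP:1, MP:2) is new,
  # and an entailed long link over an asserted path is indirect
  target2 <- ontology_graph(
    c("MP:1", "MP:2", "MP:3"),
    isa = tibble::tibble(child = "MP:2", parent = "MP:3"))
  rep2 <- validate_corpus(list(blocks = list(Q = q), definitions = defs,
                               target = target2))
  expect_equal(new_edges_of(rep2),
               tibble::tibble(child = "MP:1", parent = "MP:2"))

  # asserted A->X->C path makes an inferred (A, C) edge indirect
  defs3 <- dplyr::bind_rows(
    xp_definition("MP:1", "Q:1"),
    xp_definition("MP:3", "Q:3"))
  target3 <- ontology_graph(
    c("MP:1", "MP:3", "MP:9"),
    isa = tibble::tibble(child = c("MP:1", "MP:9"),
                         parent = c("MP:9", "MP:3")))
  rep3 <- validate_corpus(list(blocks = list(Q = q), definitions = defs3,
                               target = target3))
  edge <- rep3$inferred[rep3$inferred$child == "MP:1" &
                          rep3$inferred$parent == "MP:3", ]
  expect_equal(edge$category, "indirect")
  # cross-check with the brute-force reachability oracle
  expect_true(brute_reachable(target3$isa, "MP:1", "MP:3"))
})

test_that("asserted links the definitions do not entail are flagged", {
  cx <- example_corpus("sperm_motility")
  rep <- validate_corpus(cx)
  expect_equal(not_found_of(rep),
               tibble::tibble(child = "MP:0002674", parent = "MP:0005389"))
  expect_equal(new_edges_of(rep),
               tibble::tibble(child = "MP:0002674", parent = "MP:0001392"))
})

test_that("report partition laws hold on generated corpora", {
  for (s in 1:8) {
    cx <- generate_corpus(corpus_spec(
      n_missing_links = s %% 3, n_spurious_links = s %% 2,
      n_duplicate_defs = s %% 2, seed = s))
    rep <- validate_corpus(cx)
    # the three categories partition the inferred direct edges
    expect_true(all(rep$inferred$category %in%
                      c("direct", "indirect", "new")))
    # found/not-found partition the asserted defined-term edges
    both_defined <- cx$target$isa$child %in% cx$definitions$defined &
      cx$target$isa$parent %in% cx$definitions$defined
    expect_equal(nrow(rep$asserted), sum(both_defined))
    expect_equal(rep$n_asserted_excluded, sum(!both_defined))
    # a directly-found inferred edge is an entailed asserted edge
    dir_edges <- rep$inferred[rep$inferred$category == "direct", ]
    if (nrow(dir_edges) > 0) {
      key <- paste(rep$asserted$child, rep$asserted$parent)
      hit <- match(paste(dir_edges$child, dir_edges$parent), key)
      expect_true(all(rep$asserted$found[hit]))
    }
    g <- glance(rep)
    expect_equal(g$n_inferred,
                 g$n_direct_found + g$n_indirect_found + g$n_new)
    expect_equal(g$n_asserted, g$n_asserted_found + g$n_asserted_not_found)
  }
})

test_that("comparison is a pure function of its inputs", {
  cx <- generate_corpus(corpus_spec(n_missing_links = 2, seed = 3))
  rep1 <- validate_corpus(cx)
  # permute every input table; the report must not change
  cx2 <- cx
  cx2$definitions <- cx$definitions[order(-seq_len(nrow(cx$definitions))), ]
  cx2$definitions <- dplyr::arrange(cx2$definitions, defined, pos)
  cx2$blocks <- rev(cx$blocks)
  rep2 <- validate_corpus(cx2)
  expect_identical(rep1$inferred, rep2$inferred)
  expect_identical(rep1$asserted, rep2$asserted)
  expect_identical(rep1$equivalences, rep2$equivalences)
})

test_that("a corpus without planted disagreements reports none", {
  for (s in c(1, 6)) {
    rep <- validate_corpus(generate_corpus(corpus_spec(seed = s)))
    expect_equal(nrow(new_edges_of(rep)), 0L)
    expect_equal(nrow(not_found_of(rep)), 0L)
    expect_equal(length(rep$equivalences), 0L)
  }
})

test_that("traces name the building-block axioms behind an inference", {
  cx <- example_corpus("copper_homeostasis")
  rep <- validate_corpus(cx)
  tr <- trace_explanation(rep, "MP:0003951", "MP:0001765")
  expect_false(tr$identical_definitions)
  chains <- dplyr::bind_rows(tr$support$chain)
  expect_true(any(chains$from == "GO:0006878" & chains$to == "GO:0050801"))
  expect_error(trace_explanation(rep, "MP:0001765", "MP:0003951"),
               "not inferred")

  # identical definitions are called out as such
  cxu <- example_corpus("uric_acid_equivalence")
  # force an inferred edge by making one term's def strictly more specific:
  # here instead both are identical, so no direct edge exists between them;
  # check the trace path on a generated corpus instead
  cg <- generate_corpus(corpus_spec(n_missing_links = 1, seed = 2))
  repg <- validate_corpus(cg)
  e <- repg$inferred[1, ]
  trg <- trace_explanation(repg, e$child, e$parent)
  expect_s3_class(trg, "axiom_trace")
  expect_false(any(is.na(trg$support$child_conjunct)))

  # replaying only the cited axioms re-derives the edge
  sub_edges <- dplyr::bind_rows(trg$support$chain)
  sub_ids <- unique(c(trg$child_definition$filler,
                      trg$parent_definition$filler,
                      sub_edges$from, sub_edges$to))
  mini <- suppressWarnings(build_composite(
    list(ontology_graph(sub_ids,
                        isa = tibble::tibble(
                          child = sub_edges$from[sub_edges$kind == "is_a"],
                          parent = sub_edges$to[sub_edges$kind == "is_a"]))),
    dplyr::bind_rows(trg$child_definition, trg$parent_definition)))
  cl <- el_classify(normalize_axioms(mini))
  expect_true(is_subsumed(cl, e$child, e$parent))
})

test_that("tidy, glance and autoplot summarize a report coherently", {
  cx <- example_corpus("sperm_motility")
  rep <- validate_corpus(cx)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_setequal(names(td), c("direction", "child", "child_label",
                               "parent", "parent_label", "category"))
  expect_equal(nrow(td), nrow(rep$inferred) + nrow(rep$asserted))
  expect_true("abnormal sperm motility" %in% td$child_label)
  g <- glance(rep)
  expect_equal(g$n_new, 1L)
  expect_equal(g$n_asserted_not_found, 1L)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")

  # a report with an empty asserted direction still tidies cleanly
  td0 <- tidy(validate_corpus(example_corpus("copper_homeostasis")))
  expect_equal(nrow(td0), 1L)
  expect_type(td0$category, "character")
})
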