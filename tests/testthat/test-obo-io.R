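test_that("the four-conjunct hypoglycemia stanza parses to its definition", {
  fx <- example_corpus("hypoglycemia_parse")
  parsed <- read_obo(fx$obo_text)
  expect_identical(parsed$definitions, fx$expected_definition)
  expect_equal(parsed$graph$terms$id, "HP:0001943")
  expect_equal(parsed$graph$terms$label, "Hypoglycemia")
})

test_that("empty documents and single-conjunct stanzas yield no definitions", {
  empty <- read_obo("format-version: 1.2\n")
  expect_equal(nrow(empty$graph$terms), 0L)
  expect_equal(nrow(empty$definitions), 0L)
  # one intersection_of line is not an intersection
  one <- read_obo("[Term]\nid: X:1\nintersection_of: Q:1\n")
  expect_equal(nrow(one$definitions), 0L)
  expect_equal(one$graph$terms$id, "X:1")
})

test_that("parser handles comments, unknown tags, duplicates and errors", {
  txt <- paste(
    "[Term]",
    "id: GO:0000001 ! some label",
    "name: first",
    "def: \"ignored free text\" [PMID:1]",
    "synonym: also ignored",
    "is_a: GO:0000002 ! parent comment",
    "relationship: OBO_REL:part_of GO:0000003",
    "xref: EC:1.1.1.1",
    "",
    "[Typedef]",
    "id: part_of",
    "", sep = "\n")
  p <- read_obo(txt)
  expect_equal(p$graph$isa,
               tibble::tibble(child = "GO:0000001", parent = "GO:0000002"))
  expect_equal(p$graph$rel$relation, "part_of")
  expect_equal(p$graph$xref$xref, "EC:1.1.1.1")

  dup <- paste("[Term]", "id: X:1", "name: old", "",
               "[Term]", "id: X:1", "name: new", "", sep = "\n")
  expect_warning(pd <- read_obo(dup), "duplicate")
  expect_equal(pd$graph$terms$label, "new")

  expect_error(read_obo("[Term]\nid: X:1\nnot a tag line\n"), ":3:")
  expect_error(read_obo("/no/such/file.obo"), "cannot read")
})

test_that("serialization round-trips random graphs and is deterministic", {
  for (s in 1:30) {
    g <- random_graph(s)
    txt <- write_obo(g)
    expect_identical(read_obo(txt)$graph, g, info = paste("seed", s))
    expect_identical(write_obo(g), txt) # byte-stable
  }
})

test_that("distinct validated graphs serialize to distinct text", {
  for (s in 1:10) {
    g1 <- random_graph(s)
    g2 <- random_graph(s + 100)
    if (!identical(g1, g2)) {
      expect_false(identical(write_obo(g1), write_obo(g2)),
                   info = paste("seed", s))
    }
  }
})

test_that("definitions serialize as ordered intersection_of lines", {
  fx <- example_corpus("hypoglycemia_parse")
  g <- ontology_graph(tibble::tibble(id = "HP:0001943",
                                     label = "Hypoglycemia",
                                     obsolete = FALSE))
  txt <- write_obo(g, fx$expected_definition)
  expect_equal(sum(grepl("^intersection_of:", strsplit(txt, "\n")[[1]])), 4L)
  reparsed <- read_obo(txt)
  expect_identical(reparsed$definitions, fx$expected_definition)
})

test_that("report writing produces the five files, sorted and byte-stable", {
  empty_comp <- build_composite(list())
  empty_closure <- el_classify(normalize_axioms(empty_comp))
  empty_inf <- inferred_target_axioms(empty_closure, "MP", character())
  rep0 <- compare_hierarchies(empty_inf, empty_closure, ontology_graph(),
                              character())
  d0 <- withr::local_tempdir()
  written <- write_reports(rep0, d0)
  expect_setequal(written, report_files)
  for (f in report_files) {
    expect_equal(length(readLines(file.path(d0, f))), 1L, info = f)
  }

  cx <- example_corpus("copper_homeostasis")
  rep <- validate_corpus(cx)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reports(rep, d1)
  write_reports(rep, d2)
  expect_true(files_identical(d1, d2, report_files))
  nf <- readLines(file.path(d1, "inf_ax_not_found.txt"))
  expect_true(any(grepl("^MP:0003951\t.*\tMP:0001765\t", nf)))
  expect_equal(sum(grepl("^\tdef ", nf)), 2L) # both definitions listed

  expect_error(write_reports(rep, file.path(d1, "does-not-exist")),
               "not writable")
})
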