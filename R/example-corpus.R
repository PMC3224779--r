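mini_graph <- function(terms, isa = NULL) {
  ontology_graph(
    terms = tibble::tibble(id = names(terms), label = unname(terms),
                           obsolete = FALSE),
    isa = if (is.null(isa)) tibble::tibble(child = character(),
                                           parent = character()) else isa
  )
}

eq_def <- function(defined, quality, entity, genus = "PATO:0000001",
                   relation = "inheres_in") {
  xp_definition(defined, genus,
                tibble::tibble(relation = c("qualifier", relation),
                               filler = c(quality, entity)))
}

#' Curated miniature corpora for known disagreement patterns
#'
#' Hand-built fixtures, each a few terms, reproducing a classic curation
#' finding between a mammalian-phenotype-style target and its building
#' blocks:
#'
#' * `"copper_homeostasis"` — abnormal copper homeostasis (MP:0003951) is
#'   inferred a subclass of abnormal ion homeostasis (MP:0001765) because
#'   copper ion homeostasis sits below ion homeostasis in the process
#'   ontology; the target asserts no such link, so the axiom is *new*.
#' * `"inguinal_lymph_node"` — enlarged inguinal lymph nodes (MP:0009623)
#'   under enlarged lymph nodes (MP:0000702), driven by the anatomy
#'   ontology; again a *new* axiom.
#' * `"uric_acid_equivalence"` — two distinct target terms (urine vs blood
#'   uric acid level) accidentally defined with the *same* anatomical
#'   filler (blood), so the reasoner proves them equivalent.
#' * `"sperm_motility"` — abnormal sperm motility (MP:0002674) inferred
#'   under abnormal locomotor activity (MP:0001392) because sperm motility
#'   (GO:0030317) sits under locomotion (GO:0040011); meanwhile the
#'   asserted placement of MP:0002674 under a reproductive-system term is
#'   not entailed by the definitions.
#' * `"hypoglycemia_parse"` — the canonical four-conjunct OBO stanza
#'   (decreased concentration of glucose in blood, qualified abnormal) as
#'   raw OBO text, with the definition table its parse must produce.
#'
#' Except for the parse fixture, each corpus carries its ground truth in
#' `truth` (`expected_new`, `expected_not_found`, `expected_equivalences`).
#' Term identifiers follow the published vocabularies where the source
#' examples name them; surrounding scaffold terms are synthetic.
#'
#' @param name One of the five fixture names above.
#' @return A corpus list shaped like [generate_corpus()] output (or, for
#'   `"hypoglycemia_parse"`, a list with `obo_text` and
#'   `expected_definition`).
#' @export
example_corpus <- function(name) {
  pato <- mini_graph(
    c("PATO:0000001" = "quality", "PATO:0000460" = "abnormal",
      "PATO:0000586" = "increased size"),
    tibble::tibble(child = c("PATO:0000460", "PATO:0000586"),
                   parent = c("PATO:0000001", "PATO:0000001")))
  mp_root <- c("MP:0000001" = "mammalian phenotype")
  under_root <- function(ids) {
    tibble::tibble(child = ids, parent = "MP:0000001")
  }
  no_edges <- tibble::tibble(child = character(), parent = character())
  truth0 <- function(new = no_edges, not_found = no_edges, eq = list()) {
    list(expected_new = new, expected_not_found = not_found,
         expected_equivalences = eq)
  }

  switch(
    name,
    copper_homeostasis = {
      go <- mini_graph(
        c("GO:0050801" = "ion homeostasis",
          "GO:0006878" = "copper ion homeostasis"),
        tibble::tibble(child = "GO:0006878", parent = "GO:0050801"))
      defs <- dplyr::bind_rows(
        eq_def("MP:0003951", "PATO:0000460", "GO:0006878"),
        eq_def("MP:0001765", "PATO:0000460", "GO:0050801"))
      target <- mini_graph(
        c(mp_root, "MP:0003951" = "abnormal copper homeostasis",
          "MP:0001765" = "abnormal ion homeostasis"),
        under_root(c("MP:0003951", "MP:0001765")))
      list(name = name, blocks = list(PATO = pato, GO = go),
           definitions = defs, target = target,
           truth = truth0(new = tibble::tibble(child = "MP:0003951",
                                               parent = "MP:0001765")))
    },
    inguinal_lymph_node = {
      ma <- mini_graph(
        c("MA:0000139" = "lymph node",
          "MA:0000738" = "inguinal lymph node"),
        tibble::tibble(child = "MA:0000738", parent = "MA:0000139"))
      defs <- dplyr::bind_rows(
        eq_def("MP:0009623", "PATO:0000460", "MA:0000738",
               genus = "PATO:0000586"),
        eq_def("MP:0000702", "PATO:0000460", "MA:0000139",
               genus = "PATO:0000586"))
      target <- mini_graph(
        c(mp_root, "MP:0009623" = "enlarged inguinal lymph nodes",
          "MP:0000702" = "enlarged lymph nodes"),
        under_root(c("MP:0009623", "MP:0000702")))
      list(name = name, blocks = list(PATO = pato, MA = ma),
           definitions = defs, target = target,
           truth = truth0(new = tibble::tibble(child = "MP:0009623",
                                               parent = "MP:0000702")))
    },
    uric_acid_equivalence = {
      ma <- mini_graph(
        c("MA:0000001" = "anatomical structure", "MA:0000059" = "blood",
          "MA:0002546" = "urine"),
        tibble::tibble(child = c("MA:0000059", "MA:0002546"),
                       parent = c("MA:0000001", "MA:0000001")))
      chebi <- mini_graph(c("CHEBI:17775" = "urate"))
      mk <- function(defined) {
        xp_definition(defined, "PATO:0000001", tibble::tibble(
          relation = c("qualifier", "towards", "inheres_in"),
          # both definitions use the blood filler: the planted curation slip
          filler = c("PATO:0000460", "CHEBI:17775", "MA:0000059")))
      }
      defs <- dplyr::bind_rows(mk("MP:0009356"), mk("MP:0005561"))
      target <- mini_graph(
        c(mp_root, "MP:0009356" = "abnormal urine uric acid level",
          "MP:0005561" = "abnormal blood uric acid level"),
        under_root(c("MP:0009356", "MP:0005561")))
      list(name = name, blocks = list(PATO = pato, MA = ma, CHEBI = chebi),
           definitions = defs, target = target,
           truth = truth0(eq = list(c("MP:0005561", "MP:0009356"))))
    },
    sperm_motility = {
      go <- mini_graph(
        c("GO:0040011" = "locomotion", "GO:0030317" = "sperm motility",
          "GO:0000003" = "reproduction"),
        tibble::tibble(child = "GO:0030317", parent = "GO:0040011"))
      defs <- dplyr::bind_rows(
        eq_def("MP:0002674", "PATO:0000460", "GO:0030317"),
        eq_def("MP:0001392", "PATO:0000460", "GO:0040011"),
        eq_def("MP:0005389", "PATO:0000460", "GO:0000003"))
      target <- mini_graph(
        c(mp_root, "MP:0002674" = "abnormal sperm motility",
          "MP:0001392" = "abnormal locomotor activity",
          "MP:0005389" = "reproductive system phenotype"),
        dplyr::bind_rows(
          under_root(c("MP:0001392", "MP:0005389")),
          tibble::tibble(child = "MP:0002674", parent = "MP:0005389")))
      list(name = name, blocks = list(PATO = pato, GO = go),
           definitions = defs, target = target,
           truth = truth0(
             new = tibble::tibble(child = "MP:0002674",
                                  parent = "MP:0001392"),
             not_found = tibble::tibble(child = "MP:0002674",
                                        parent = "MP:0005389")))
    },
    hypoglycemia_parse = {
      obo_text <- paste(
        "format-version: 1.2", "",
        "[Term]",
        "id: HP:0001943 ! Hypoglycemia",
        "name: Hypoglycemia",
        "intersection_of: PATO:0001163 ! decreased concentration",
        "intersection_of: qualifier PATO:0000460 ! abnormal",
        "intersection_of: towards CHEBI:17234 ! glucose",
        "intersection_of: inheres_in FMA:9670 ! Portion of blood",
        "", sep = "\n")
      expected <- xp_definition(
        "HP:0001943", "PATO:0001163",
        tibble::tibble(relation = c("qualifier", "towards", "inheres_in"),
                       filler = c("PATO:0000460", "CHEBI:17234",
                                  "FMA:9670")))
      list(name = name, obo_text = obo_text, expected_definition = expected)
    },
    stop("unknown example corpus: ", name, call. = FALSE)
  )
}

#' Names of the curated example corpora
#' @return Character vector accepted by [example_corpus()].
#' @export
example_corpus_names <- function() {
  c("copper_homeostasis", "inguinal_lymph_node", "uric_acid_equivalence",
    "sperm_motility", "hypoglycemia_parse")
}
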