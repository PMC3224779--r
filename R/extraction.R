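#' Induced ancestral graph of a building-block ontology
#'
#' Reasoning over cross-product definitions only needs the terms they
#' reference plus all ancestors of those terms on every path back to the
#' root(s); classification over this subset yields exactly the same target
#' inferences as classification over the full ontology, at a fraction of the
#' cost. The retained node set is the upward closure of the seeds under the
#' `closure_relations` edges (by default subsumption only), and the retained
#' edge set is *every* `is_a` and relationship edge of the input whose two
#' endpoints are both retained. Labels and cross-references carry over.
#'
#' Seeds missing from the ontology are dropped with a warning — a stale
#' definition referencing a removed term is exactly what a curator needs to
#' see; downstream they behave as fresh atomic classes.
#'
#' @param ontology A validated (acyclic) [ontology_graph()].
#' @param seeds Character vector of term ids to extract.
#' @param closure_relations Relations (besides `is_a`, always included) whose
#'   edges also drive the upward traversal, e.g. `"part_of"`. Default: none.
#' @return An `ontology_graph` restricted to the ancestral closure.
#' @examples
#' g <- ontology_graph(c("A:1", "A:2", "A:3"),
#'   isa = tibble::tibble(child = c("A:1", "A:2"), parent = c("A:2", "A:3")))
#' induced_ancestral_graph(g, "A:1")
#' @export
induced_ancestral_graph <- function(ontology, seeds,
                                    closure_relations = character()) {
  stopifnot(inherits(ontology, "ontology_graph"))
  seeds <- unique(seeds)
  missing <- setdiff(seeds, ontology$terms$id)
  if (length(missing) > 0) {
    warning("seed term(s) absent from ontology, skipped: ",
            paste(sort(missing, method = "radix"), collapse = ", "),
            call. = FALSE)
    seeds <- setdiff(seeds, missing)
  }
  if (length(seeds) == 0) {
    out <- ontology_graph()
    attr(out, "missing_seeds") <- missing
    return(out)
  }
  ig <- graph_igraph(ontology, relations = closure_relations)
  keep <- unique(unlist(lapply(seeds, function(s) {
    names(igraph::subcomponent(ig, s, mode = "out"))
  })))
  out <- ontology_graph(
    terms = ontology$terms[ontology$terms$id %in% keep, ],
    isa = ontology$isa[ontology$isa$child %in% keep &
                         ontology$isa$parent %in% keep, ],
    rel = ontology$rel[ontology$rel$subject %in% keep &
                         ontology$rel$object %in% keep, ],
    xref = ontology$xref[ontology$xref$id %in% keep, ]
  )
  attr(out, "missing_seeds") <- missing
  out
}

#' Per-ontology subset sizes
#'
#' Summarizes how much of each building-block ontology the definitions
#' actually reference — the quantity that makes subset reasoning worthwhile.
#'
#' @param ontologies Named list of full [ontology_graph()] objects.
#' @param subsets Named list of extracted subsets (same names).
#' @return Tibble with columns `ontology`, `n_terms`, `n_subset`,
#'   `fraction_referenced`.
#' @export
subset_sizes <- function(ontologies, subsets) {
  stopifnot(identical(names(ontologies), names(subsets)))
  tibble::tibble(
    ontology = names(ontologies),
    n_terms = unname(purrr::map_int(ontologies, ~ nrow(.x$terms))),
    n_subset = unname(purrr::map_int(subsets, ~ nrow(.x$terms)))
  ) |>
    dplyr::mutate(fraction_referenced = ifelse(.data$n_terms > 0,
                                               .data$n_subset / .data$n_terms,
                                               NA_real_))
}
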