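empty_bridges <- function() tibble::tibble(a = character(), b = character())

normalize_bridges <- function(bridges) {
  if (nrow(bridges) == 0) return(empty_bridges())
  tibble::tibble(a = pmin(bridges$a, bridges$b),
                 b = pmax(bridges$a, bridges$b)) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$a, .data$b)
}

#' Build the composite ontology handed to the reasoner
#'
#' Takes the union of the building-block subsets (set semantics: the result
#' is independent of subset order), attaches the logical definitions keyed
#' by defined term, and records equivalence bridges. Every defined term and
#' every genus/filler a definition references becomes a node of the
#' composite; referenced terms missing from all subsets are added as fresh
#' isolated atomic classes with a warning — a stale reference should
#' suppress inferences, not abort the run, and the curator must see it.
#'
#' @param subsets List of [ontology_graph()] objects (building-block
#'   subsets; the target ontology's asserted hierarchy is *not* included).
#' @param definitions Long-form definition tibble.
#' @param bridges Tibble with columns `a`, `b`: unordered equivalence pairs,
#'   typically from [build_xref_bridge()].
#' @return A `composite_ontology`: list with `graph`, `definitions`,
#'   `bridges`; attribute `n_unresolved` counts fresh fallback nodes.
#' @export
build_composite <- function(subsets, definitions = empty_definitions(),
                            bridges = empty_bridges()) {
  if (is.null(definitions) || nrow(definitions) == 0) {
    definitions <- empty_definitions()
  }
  validate_definitions(definitions)
  graph <- merge_graphs(subsets)
  needed <- unique(c(definitions$defined, definitions$filler,
                     bridges$a, bridges$b))
  unresolved <- sort(setdiff(needed, graph$terms$id), method = "radix")
  # defined target terms are expected to be absent from the building blocks;
  # only missing genera/fillers indicate stale definitions
  stale <- setdiff(intersect(unresolved, definitions$filler),
                   definitions$defined)
  if (length(stale) > 0) {
    warning("definition references unresolved in any subset (kept as fresh ",
            "atomic classes): ", paste(stale, collapse = ", "),
            call. = FALSE)
  }
  if (length(unresolved) > 0) {
    graph <- merge_graphs(list(graph, ontology_graph(unresolved)))
  }
  structure(
    list(graph = graph,
         definitions = definitions,
         bridges = normalize_bridges(bridges)),
    class = "composite_ontology",
    n_unresolved = length(stale)
  )
}

#' @export
print.composite_ontology <- function(x, ...) {
  cat(sprintf(
    "<composite_ontology> %d classes, %d is_a edges, %d definitions, %d bridge equivalences\n",
    nrow(x$graph$terms), nrow(x$graph$isa),
    length(unique(x$definitions$defined)), nrow(x$bridges)
  ))
  invisible(x)
}

#' Derive equivalence bridges from a bridging ontology
#'
#' Species-neutral bridging ontologies (UBERON-style) relate their own
#' generic classes to species-specific anatomy classes in two ways: an
#' asserted subclass edge from a specific class up to the generic class, and
#' cross-references on the generic class pointing at the specific ones. Both
#' readings are supported: every subclass edge `X is_a U` with `X` in a
#' bridged namespace and `U` in the bridging ontology's own namespace, and
#' every xref of such a `U` into a bridged namespace, is turned into the
#' unordered equivalence pair `{X, U}` (the specific cochlear duct *is* the
#' generic cochlear duct).
#'
#' @param bridging_ontology A validated [ontology_graph()].
#' @param bridged_prefixes Character vector of namespaces to bridge
#'   (e.g. `c("MA", "FMA")`).
#' @param bridge_prefix The bridging ontology's own namespace. Default: the
#'   most frequent term prefix outside `bridged_prefixes`.
#' @param use Which evidence to convert: `"both"` (default), `"xref"`, or
#'   `"subclass"`.
#' @return Tibble with columns `a`, `b` (each pair sorted, deduplicated).
#' @export
build_xref_bridge <- function(bridging_ontology, bridged_prefixes,
                              bridge_prefix = NULL,
                              use = c("both", "xref", "subclass")) {
  use <- match.arg(use)
  pref <- term_prefix(bridging_ontology$terms$id)
  if (is.null(bridge_prefix)) {
    own <- pref[!pref %in% bridged_prefixes]
    if (length(own) == 0) return(empty_bridges())
    bridge_prefix <- names(sort(table(own), decreasing = TRUE))[1]
  }
  pairs <- empty_bridges()
  if (use %in% c("both", "subclass") && nrow(bridging_ontology$isa) > 0) {
    e <- bridging_ontology$isa
    keep <- term_prefix(e$child) %in% bridged_prefixes &
      term_prefix(e$parent) == bridge_prefix
    pairs <- dplyr::bind_rows(pairs,
                              tibble::tibble(a = e$child[keep],
                                             b = e$parent[keep]))
  }
  if (use %in% c("both", "xref") && nrow(bridging_ontology$xref) > 0) {
    x <- bridging_ontology$xref
    keep <- term_prefix(x$id) == bridge_prefix &
      term_prefix(x$xref) %in% bridged_prefixes
    pairs <- dplyr::bind_rows(pairs,
                              tibble::tibble(a = x$xref[keep],
                                             b = x$id[keep]))
  }
  normalize_bridges(pairs)
}
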