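#' Construct an ontology graph
#'
#' The in-memory model of one OBO ontology: a term table, the asserted
#' `is_a` (subsumption) edges, typed relationship edges (e.g. `part_of`),
#' and cross-references. Edge endpoints are normally keys of the term table;
#' [validate_ontology()] reports dangling endpoints, `is_a` cycles and
#' obsolete terms that still have children as findings rather than errors,
#' so that a curator-facing pipeline can name them.
#'
#' @param terms Tibble with columns `id`, `label`, `obsolete` (or a character
#'   vector of ids, in which case labels default to the id and nothing is
#'   obsolete).
#' @param isa Tibble with columns `child`, `parent` (asserted subsumptions).
#' @param rel Tibble with columns `subject`, `relation`, `object`.
#' @param xref Tibble with columns `id`, `xref` (cross-referenced term ids).
#' @return An `ontology_graph` object (a list of four tibbles).
#' @examples
#' g <- ontology_graph(
#'   terms = c("GO:0006878", "GO:0050801"),
#'   isa = tibble::tibble(child = "GO:0006878", parent = "GO:0050801")
#' )
#' g
#' @export
ontology_graph <- function(terms = tibble::tibble(id = character(),
                                                  label = character(),
                                                  obsolete = logical()),
                           isa = tibble::tibble(child = character(),
                                                parent = character()),
                           rel = tibble::tibble(subject = character(),
                                                relation = character(),
                                                object = character()),
                           xref = tibble::tibble(id = character(),
                                                 xref = character())) {
  if (is.character(terms)) {
    terms <- tibble::tibble(id = terms, label = terms, obsolete = FALSE)
  }
  terms <- tibble::as_tibble(terms)
  if (!"label" %in% names(terms)) terms$label <- terms$id
  if (!"obsolete" %in% names(terms)) terms$obsolete <- FALSE
  terms$label <- dplyr::coalesce(as.character(terms$label), terms$id)
  if (anyDuplicated(terms$id)) {
    terms <- dplyr::distinct(terms, .data$id, .keep_all = TRUE)
  }
  structure(
    list(
      terms = dplyr::arrange(terms[, c("id", "label", "obsolete")], .data$id),
      isa = dplyr::arrange(dplyr::distinct(tibble::as_tibble(isa)),
                           .data$child, .data$parent),
      rel = dplyr::arrange(dplyr::distinct(tibble::as_tibble(rel)),
                           .data$subject, .data$relation, .data$object),
      xref = dplyr::arrange(dplyr::distinct(tibble::as_tibble(xref)),
                            .data$id, .data$xref)
    ),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf(
    "<ontology_graph> %d terms (%d obsolete), %d is_a edges, %d relationship edges, %d xrefs\n",
    nrow(x$terms), sum(x$terms$obsolete), nrow(x$isa), nrow(x$rel), nrow(x$xref)
  ))
  invisible(x)
}

#' Term labels as a named lookup vector
#' @param graph An `ontology_graph`.
#' @return Named character vector mapping id to label.
#' @export
term_labels <- function(graph) {
  stats::setNames(graph$terms$label, graph$terms$id)
}

graph_igraph <- function(graph, relations = character()) {
  edges <- graph$isa
  names(edges) <- c("from", "to")
  if (length(relations) > 0 && nrow(graph$rel) > 0) {
    extra <- graph$rel[graph$rel$relation %in% relations, c("subject", "object")]
    names(extra) <- c("from", "to")
    edges <- dplyr::bind_rows(edges, extra)
  }
  verts <- union(graph$terms$id, unlist(edges, use.names = FALSE))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Structural validation of an ontology graph
#'
#' Checks the invariants reasoning depends on and returns findings instead of
#' throwing: edge endpoints that are not in the term table, `is_a` cycles
#' (with their member terms), and obsolete terms that still have children.
#' The input graph is never modified; calling twice yields identical output.
#'
#' @param graph An [ontology_graph()].
#' @return Tibble with columns `type` (`"dangling_edge"`, `"isa_cycle"`,
#'   `"obsolete_with_children"`), `detail` (human-readable message) and
#'   `terms` (list-column of the ids involved).
#' @export
validate_ontology <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  findings <- list()
  known <- graph$terms$id

  ends <- unique(c(graph$isa$child, graph$isa$parent,
                   graph$rel$subject, graph$rel$object))
  dangling <- sort(setdiff(ends, known), method = "radix")
  if (length(dangling) > 0) {
    findings <- c(findings, list(tibble::tibble(
      type = "dangling_edge",
      detail = paste0("edge endpoint not declared as a term: ",
                      paste(dangling, collapse = ", ")),
      terms = list(dangling)
    )))
  }

  if (nrow(graph$isa) > 0) {
    ig <- igraph::graph_from_data_frame(
      stats::setNames(graph$isa, c("from", "to")), directed = TRUE)
    comp <- igraph::components(ig, mode = "strong")
    cyc_ids <- which(comp$csize >= 2)
    self <- graph$isa$child[graph$isa$child == graph$isa$parent]
    for (cid in cyc_ids) {
      members <- sort(names(comp$membership)[comp$membership == cid],
                      method = "radix")
      findings <- c(findings, list(tibble::tibble(
        type = "isa_cycle",
        detail = paste0("is_a cycle: ", paste(members, collapse = " -> ")),
        terms = list(members)
      )))
    }
    for (s in unique(self)) {
      findings <- c(findings, list(tibble::tibble(
        type = "isa_cycle",
        detail = paste0("is_a self-loop: ", s),
        terms = list(s)
      )))
    }
  }

  obs <- graph$terms$id[graph$terms$obsolete]
  bad_obs <- sort(intersect(obs, unique(graph$isa$parent)), method = "radix")
  for (o in bad_obs) {
    kids <- sort(graph$isa$child[graph$isa$parent == o], method = "radix")
    findings <- c(findings, list(tibble::tibble(
      type = "obsolete_with_children",
      detail = paste0("obsolete term ", o, " has is_a children"),
      terms = list(c(o, kids))
    )))
  }

  if (length(findings) == 0) {
    return(tibble::tibble(type = character(), detail = character(),
                          terms = list()))
  }
  dplyr::bind_rows(findings)
}

#' Drop obsolete terms and their incident edges
#'
#' Obsolete terms are retained in the model so validation findings can name
#' them, but they take no part in reasoning or comparison.
#'
#' @param graph An [ontology_graph()].
#' @return The graph without obsolete terms.
#' @export
drop_obsolete <- function(graph) {
  keep <- graph$terms$id[!graph$terms$obsolete]
  ontology_graph(
    terms = graph$terms[!graph$terms$obsolete, ],
    isa = graph$isa[graph$isa$child %in% keep & graph$isa$parent %in% keep, ],
    rel = graph$rel[graph$rel$subject %in% keep & graph$rel$object %in% keep, ],
    xref = graph$xref[graph$xref$id %in% keep, ]
  )
}

#' Merge ontology graphs by set union
#'
#' Node and edge sets are united; when two graphs label one id differently
#' the first label is kept and a warning names the id.
#'
#' @param graphs List of [ontology_graph()] objects.
#' @return A single merged `ontology_graph`.
#' @export
merge_graphs <- function(graphs) {
  stopifnot(is.list(graphs))
  if (length(graphs) == 0) return(ontology_graph())
  terms <- dplyr::bind_rows(purrr::map(graphs, "terms"))
  # conflicting labels: keep first occurrence, warn
  conf <- terms |>
    dplyr::distinct(.data$id, .data$label) |>
    dplyr::count(.data$id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conf) > 0) {
    warning("conflicting labels for: ", paste(conf$id, collapse = ", "),
            "; keeping the first seen", call. = FALSE)
  }
  terms <- terms |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(label = dplyr::first(.data$label),
                     obsolete = any(.data$obsolete), .groups = "drop")
  ontology_graph(
    terms = terms,
    isa = dplyr::bind_rows(purrr::map(graphs, "isa")),
    rel = dplyr::bind_rows(purrr::map(graphs, "rel")),
    xref = dplyr::bind_rows(purrr::map(graphs, "xref"))
  )
}
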