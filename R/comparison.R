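#' Compare the reasoned hierarchy against the asserted target hierarchy
#'
#' The bidirectional diff at the heart of the validation workflow. Three
#' kinds of disagreement are surfaced:
#'
#' 1. an inferred subclass edge not asserted in the target (`category =
#'    "new"`): the definitions imply a link the curators have not placed;
#' 2. an asserted target edge the definitions do not entail
#'    (`found = FALSE`): either the definitions are incomplete or the
#'    asserted link encodes knowledge the building blocks lack;
#' 3. two distinct target terms inferred equivalent: duplicates, or a
#'    copy-paste error in the definitions.
#'
#' Each inferred direct edge is classified `"direct"` (asserted as an edge),
#' `"indirect"` (the parent is reachable from the child through a chain of
#' two or more asserted edges) or `"new"`. In the other direction, every
#' asserted edge between two *defined* terms is checked for entailment
#' against the closure; edges touching an undefined term are excluded and
#' counted in `n_asserted_excluded`.
#'
#' @param inferred Result of [inferred_target_axioms()].
#' @param closure The `el_closure` of the same run.
#' @param target The target [ontology_graph()] (asserted hierarchy).
#' @param defined_terms Terms carrying logical definitions.
#' @param definitions Long-form definition tibble (carried into the report
#'   so the `*_not_found` files can print debugging hints).
#' @param composite Optional [build_composite()] result; if supplied,
#'   [trace_explanation()] can reconstruct why an edge was inferred.
#' @param extra_labels Named character vector of labels for ids outside the
#'   target ontology (building-block terms appearing in definitions).
#' @return A `comparison_report`; see [tidy.comparison_report()] and
#'   [glance.comparison_report()].
#' @export
compare_hierarchies <- function(inferred, closure, target, defined_terms,
                                definitions = empty_definitions(),
                                composite = NULL,
                                extra_labels = character()) {
  stopifnot(inherits(closure, "el_closure"),
            inherits(target, "ontology_graph"))
  asserted_key <- paste(target$isa$child, target$isa$parent)

  ig <- if (nrow(target$isa) > 0) {
    igraph::graph_from_data_frame(stats::setNames(target$isa, c("from", "to")),
                                  directed = TRUE)
  } else NULL
  reachable <- function(a, b) {
    if (is.null(ig)) return(FALSE)
    vs <- igraph::V(ig)$name
    if (!(a %in% vs) || !(b %in% vs)) return(FALSE)
    b %in% names(igraph::subcomponent(ig, a, mode = "out"))
  }

  inf <- inferred$direct_edges
  category <- character(nrow(inf))
  if (nrow(inf) > 0) {
    for (i in seq_len(nrow(inf))) {
      key <- paste(inf$child[i], inf$parent[i])
      category[i] <- if (key %in% asserted_key) {
        "direct"
      } else if (reachable(inf$child[i], inf$parent[i])) {
        "indirect"
      } else {
        "new"
      }
    }
  }
  inf$category <- category

  both_defined <- target$isa$child %in% defined_terms &
    target$isa$parent %in% defined_terms
  asserted <- target$isa[both_defined, ]
  found <- logical(nrow(asserted))
  if (nrow(asserted) > 0) {
    for (i in seq_len(nrow(asserted))) {
      found[i] <- is_subsumed(closure, asserted$child[i], asserted$parent[i])
    }
  }
  asserted$found <- found

  labels <- c(term_labels(target), extra_labels)
  labels <- labels[!duplicated(names(labels))]

  structure(
    list(
      inferred = dplyr::arrange(inf, .data$child, .data$parent),
      asserted = dplyr::arrange(asserted, .data$child, .data$parent),
      equivalences = inferred$equivalences,
      labels = labels,
      definitions = definitions,
      n_asserted_excluded = sum(!both_defined)
    ),
    class = "comparison_report",
    closure = closure,
    composite = composite
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  g <- glance(x)
  cat("<comparison_report>\n")
  cat(sprintf("  inferred direct edges: %d (found directly %d, indirectly %d, new %d)\n",
              g$n_inferred, g$n_direct_found, g$n_indirect_found, g$n_new))
  cat(sprintf("  asserted edges between defined terms: %d (entailed %d, not entailed %d; %d excluded, endpoint undefined)\n",
              g$n_asserted, g$n_asserted_found, g$n_asserted_not_found,
              x$n_asserted_excluded))
  cat(sprintf("  inferred equivalence classes: %d\n", g$n_equivalence_classes))
  invisible(x)
}

#' Tidy and summarize comparison reports
#'
#' `tidy()` returns one row per compared axiom (both directions of the
#' diff), `glance()` a one-row count summary, mirroring the category counts
#' a curator scans first.
#'
#' @param x A `comparison_report` (or, for the closure method, an
#'   `el_closure`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_ontodiff
#' @exportS3Method generics::tidy
tidy.comparison_report <- function(x, ...) {
  lab <- function(id) unname(ifelse(id %in% names(x$labels),
                                    x$labels[id], id))
  inf <- tibble::tibble(
    direction = "reasoned_to_target",
    child = x$inferred$child, parent = x$inferred$parent,
    category = paste0(ifelse(x$inferred$category == "new", "",
                             "found_"), x$inferred$category)
  )
  ass <- tibble::tibble(
    direction = "target_to_reasoned",
    child = x$asserted$child, parent = x$asserted$parent,
    category = dplyr::if_else(x$asserted$found, "found", "not_found")
  )
  dplyr::bind_rows(inf, ass) |>
    dplyr::mutate(child_label = lab(.data$child),
                  parent_label = lab(.data$parent)) |>
    dplyr::select("direction", "child", "child_label",
                  "parent", "parent_label", "category")
}

#' @rdname tidy_ontodiff
#' @exportS3Method generics::glance
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    n_inferred = nrow(x$inferred),
    n_direct_found = sum(x$inferred$category == "direct"),
    n_indirect_found = sum(x$inferred$category == "indirect"),
    n_new = sum(x$inferred$category == "new"),
    n_asserted = nrow(x$asserted),
    n_asserted_found = sum(x$asserted$found),
    n_asserted_not_found = sum(!x$asserted$found),
    n_asserted_excluded = x$n_asserted_excluded,
    n_equivalence_classes = length(x$equivalences)
  )
}

#' Category counts as a bar chart
#'
#' @param object A `comparison_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.comparison_report <- function(object, ...) {
  g <- glance(object)
  df <- tibble::tibble(
    category = factor(
      c("inferred: found directly", "inferred: found indirectly",
        "inferred: new", "asserted: entailed", "asserted: not entailed",
        "equivalence classes"),
      levels = c("inferred: found directly", "inferred: found indirectly",
                 "inferred: new", "asserted: entailed",
                 "asserted: not entailed", "equivalence classes")),
    n = c(g$n_direct_found, g$n_indirect_found, g$n_new,
          g$n_asserted_found, g$n_asserted_not_found,
          g$n_equivalence_classes),
    direction = c("reasoned → target", "reasoned → target",
                  "reasoned → target", "target → reasoned",
                  "target → reasoned", "equivalence")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "axioms",
                  title = "Asserted vs inferred hierarchy disagreements") +
    ggplot2::theme_minimal()
}

#' Explain an inferred subclass edge
#'
#' Reconstructs why the reasoner derived `child [= parent`: the two
#' logical definitions, and for each conjunct of the parent's definition
#' the supporting conjunct of the child's definition together with the
#' chain of building-block subsumptions (and bridge equivalences) that
#' connects them. If the two definitions are conjunct-for-conjunct
#' identical the trace says so — the signature of a duplicated definition.
#'
#' @param report A `comparison_report` built with `composite` supplied.
#' @param child,parent The inferred edge to explain.
#' @return An `axiom_trace` object.
#' @export
trace_explanation <- function(report, child, parent) {
  stopifnot(inherits(report, "comparison_report"))
  closure <- attr(report, "closure")
  composite <- attr(report, "composite")
  key <- paste(report$inferred$child, report$inferred$parent)
  if (!(paste(child, parent) %in% key)) {
    stop("edge ", child, " [= ", parent, " was not inferred in this run",
         call. = FALSE)
  }
  if (is.null(composite)) {
    stop("report was built without the composite ontology; no trace available",
         call. = FALSE)
  }
  defs <- definitions_by_term(composite$definitions)
  cd <- defs[[child]]
  pd <- defs[[parent]]
  if (is.null(cd) || is.null(pd)) {
    stop("no logical definition recorded for ", child, " or ", parent,
         call. = FALSE)
  }
  same <- identical(
    cd[order(cd$role, cd$relation, cd$filler), c("role", "relation", "filler")],
    pd[order(pd$role, pd$relation, pd$filler), c("role", "relation", "filler")]
  )

  # path graph over building-block is_a edges plus (bidirectional) bridges
  g <- composite$graph
  edges <- dplyr::bind_rows(
    tibble::tibble(from = g$isa$child, to = g$isa$parent, kind = "is_a"),
    tibble::tibble(from = composite$bridges$a, to = composite$bridges$b,
                   kind = "bridge"),
    tibble::tibble(from = composite$bridges$b, to = composite$bridges$a,
                   kind = "bridge")
  )
  ig <- if (nrow(edges) > 0) {
    igraph::graph_from_data_frame(edges, directed = TRUE,
                                  vertices = union(g$terms$id,
                                                   c(edges$from, edges$to)))
  } else NULL
  chain_between <- function(from, to) {
    if (from == to || is.null(ig)) {
      return(tibble::tibble(from = character(), to = character(),
                            kind = character()))
    }
    sp <- suppressWarnings(igraph::shortest_paths(ig, from, to, mode = "out",
                                                  output = "epath"))
    ep <- sp$epath[[1]]
    if (length(ep) == 0) {
      return(tibble::tibble(from = character(), to = character(),
                            kind = character()))
    }
    ends <- igraph::ends(ig, ep)
    tibble::tibble(from = ends[, 1], to = ends[, 2],
                   kind = igraph::edge_attr(ig, "kind", ep))
  }

  support <- purrr::map(seq_len(nrow(pd)), function(i) {
    role <- pd$role[i]
    relation <- pd$relation[i]
    goal <- pd$filler[i]
    cands <- if (role == "genus") {
      cd$filler[cd$role == "genus"]
    } else {
      cd$filler[cd$role == "differentia" & cd$relation == relation]
    }
    hit <- cands[vapply(cands, function(f) is_subsumed(closure, f, goal),
                        logical(1))]
    if (length(hit) == 0) {
      return(tibble::tibble(role = role, relation = relation,
                            parent_conjunct = goal,
                            child_conjunct = NA_character_,
                            chain = list(tibble::tibble(from = character(),
                                                        to = character(),
                                                        kind = character()))))
    }
    hit <- sort(hit, method = "radix")[1]
    tibble::tibble(role = role, relation = relation, parent_conjunct = goal,
                   child_conjunct = hit, chain = list(chain_between(hit, goal)))
  }) |> dplyr::bind_rows()

  structure(
    list(edge = c(child = child, parent = parent),
         identical_definitions = same,
         child_definition = cd,
         parent_definition = pd,
         support = support),
    class = "axiom_trace"
  )
}

#' @export
print.axiom_trace <- function(x, ...) {
  cat(sprintf("<axiom_trace> %s [= %s\n", x$edge[["child"]],
              x$edge[["parent"]]))
  cat("  ", x$edge[["child"]], " := ",
      render_definition(x$child_definition), "\n", sep = "")
  cat("  ", x$edge[["parent"]], " := ",
      render_definition(x$parent_definition), "\n", sep = "")
  if (x$identical_definitions) {
    cat("  definitions syntactically identical\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$support))) {
    s <- x$support[i, ]
    ch <- s$chain[[1]]
    via <- if (nrow(ch) == 0) "" else
      paste0(" via ", paste(paste0(ch$from, " ->(", ch$kind, ") ", ch$to),
                            collapse = ", "))
    cat(sprintf("  %s supported by %s%s\n", s$parent_conjunct,
                ifelse(is.na(s$child_conjunct), "(unresolved)",
                       s$child_conjunct), via))
  }
  invisible(x)
}
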