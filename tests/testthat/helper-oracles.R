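# Independent oracles and random-input generators used across the suite.
# These deliberately avoid the package's own graph/reasoner code paths.

# plain recursive DFS cycle detector over an edge table
dfs_has_cycle <- function(edges) {
  nodes <- unique(c(edges$child, edges$parent))
  adj <- split(edges$parent, edges$child)
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new 1 open 2 done
  found <- FALSE
  visit <- function(v) {
    if (found || state[[v]] == 2L) return()
    if (state[[v]] == 1L) { found <<- TRUE; return() }
    state[[v]] <<- 1L
    for (w in adj[[v]]) visit(w)
    state[[v]] <<- 2L
  }
  for (v in nodes) visit(v)
  found
}

# brute-force reachability: iterate edge relaxation to fixpoint
brute_reachable <- function(edges, from, to) {
  reach <- from
  repeat {
    nxt <- unique(c(reach, edges$parent[edges$child %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  to %in% reach
}

# random DAG edge table by rank-ordered parent sampling (acyclic by build)
random_dag_edges <- function(n, m, prefix = "T") {
  ids <- sprintf("%s:%04d", prefix, seq_len(n))
  child <- character(m); parent <- character(m)
  for (k in seq_len(m)) {
    i <- sample(2:n, 1)
    child[k] <- ids[i]
    parent[k] <- ids[sample.int(i - 1L, 1)]
  }
  list(ids = ids, edges = dplyr::distinct(tibble::tibble(child = child,
                                                         parent = parent)))
}

random_graph <- function(seed, n = 12, m = 18) {
  withr::with_seed(seed, {
    d <- random_dag_edges(n, m)
    obs <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.1, 0.9))
    # obsolete leaves only, so validation stays clean
    obs[d$ids %in% d$edges$parent] <- FALSE
    ontology_graph(
      terms = tibble::tibble(id = d$ids,
                             label = paste("term", seq_len(n)),
                             obsolete = obs),
      isa = d$edges
    )
  })
}

# random EL composite: two namespaces, arbitrary (possibly cyclic) subclass
# edges, relationship edges, genus+differentia definitions, bridges
random_el_composite <- function(seed) {
  withr::with_seed(seed, {
    na <- sample(3:20, 1)
    nb <- sample(2:20, 1)
    a_ids <- sprintf("A:%03d", seq_len(na))
    b_ids <- sprintf("B:%03d", seq_len(nb))
    ids <- c(a_ids, b_ids)
    rels <- paste0("r", seq_len(sample(1:5, 1)))
    n_isa <- sample(0:25, 1)
    isa <- tibble::tibble(child = sample(ids, n_isa, replace = TRUE),
                          parent = sample(ids, n_isa, replace = TRUE))
    isa <- dplyr::distinct(isa[isa$child != isa$parent, ])
    n_rel <- sample(0:10, 1)
    rel <- dplyr::distinct(tibble::tibble(
      subject = sample(ids, n_rel, replace = TRUE),
      relation = sample(rels, n_rel, replace = TRUE),
      object = sample(ids, n_rel, replace = TRUE)))
    def_terms <- sample(ids, sample(0:6, 1))
    defs <- if (length(def_terms) > 0) {
      dplyr::bind_rows(lapply(def_terms, function(d) {
        others <- setdiff(ids, d)
        nd <- sample(0:2, 1)
        xp_definition(d, sample(others, sample(1:2, 1)),
                      tibble::tibble(relation = sample(rels, nd,
                                                       replace = TRUE),
                                     filler = sample(others, nd,
                                                     replace = TRUE)))
      }))
    } else NULL
    n_br <- sample(0:3, 1)
    br <- tibble::tibble(a = sample(a_ids, n_br, replace = TRUE),
                         b = sample(b_ids, n_br, replace = TRUE))
    args <- list(list(ontology_graph(ids, isa = isa, rel = rel)))
    if (!is.null(defs)) args <- c(args, list(defs)) else
      args <- c(args, list(ontodiff:::empty_definitions()))
    suppressWarnings(build_composite(args[[1]], args[[2]], br))
  })
}

# compare two closures over identical name sets
closures_agree <- function(c1, c2) {
  if (!identical(sort(c1$names), sort(c2$names))) return(FALSE)
  nm <- sort(c1$names)
  identical(unname(c1$subsumes[nm, nm, drop = FALSE]),
            unname(c2$subsumes[nm, nm, drop = FALSE]))
}

report_files <- c("inf_ax_found.txt", "inf_ax_not_found.txt",
                  "assert_ax_found.txt", "assert_ax_not_found.txt",
                  "equivalence_ax.txt")

files_identical <- function(dir1, dir2, files) {
  all(vapply(files, function(f) {
    identical(readBin(file.path(dir1, f), "raw", n = 10^7),
              readBin(file.path(dir2, f), "raw", n = 10^7))
  }, logical(1)))
}

new_edges_of <- function(report) {
  dplyr::arrange(report$inferred[report$inferred$category == "new",
                                 c("child", "parent")],
                 child, parent)
}

not_found_of <- function(report) {
  dplyr::arrange(tibble::as_tibble(
    report$asserted[!report$asserted$found, c("child", "parent")]),
    child, parent)
}
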