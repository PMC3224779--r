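#' Specify a synthetic validation corpus
#'
#' Parameters of the generator in [generate_corpus()]: how many
#' building-block ontologies to simulate, their size and DAG density, how
#' many target terms get entity-quality definitions, and how many
#' disagreements of each kind to plant (missing asserted links, spurious
#' asserted links, duplicated definitions).
#'
#' @param n_blocks Number of building-block ontologies (entity namespaces).
#' @param terms_per_block Terms per building block.
#' @param dag_density Expected number of parents per non-root term.
#' @param n_defined Number of defined target terms.
#' @param n_missing_links Asserted edges deleted from the true hierarchy
#'   (each must surface as an inferred-but-new axiom).
#' @param n_spurious_links Non-entailed asserted edges inserted (each must
#'   surface as asserted-but-not-found).
#' @param n_duplicate_defs Definitions duplicated under fresh target ids
#'   (each must surface as an inferred equivalence pair).
#' @param seed Integer seed; the corpus is a pure function of this
#'   specification object.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_blocks = 2, terms_per_block = 15, dag_density = 1.5,
                        n_defined = 12, n_missing_links = 0,
                        n_spurious_links = 0, n_duplicate_defs = 0,
                        seed = 1L) {
  counts <- c(n_blocks, terms_per_block, n_defined, n_missing_links,
              n_spurious_links, n_duplicate_defs)
  stopifnot(all(counts >= 0), dag_density > 0,
            n_defined >= 2 * n_duplicate_defs,
            n_blocks >= 1, terms_per_block >= 2)
  structure(list(n_blocks = n_blocks, terms_per_block = terms_per_block,
                 dag_density = dag_density, n_defined = n_defined,
                 n_missing_links = n_missing_links,
                 n_spurious_links = n_spurious_links,
                 n_duplicate_defs = n_duplicate_defs,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

random_block <- function(prefix, n, density, part_of_prob = 0.1) {
  ids <- sprintf("%s:%07d", prefix, seq_len(n))
  terms <- tibble::tibble(id = ids,
                          label = paste(tolower(prefix), "term", seq_len(n)),
                          obsolete = FALSE)
  child <- character(); parent <- character()
  for (i in seq_len(n)[-1]) {
    k <- min(i - 1L, 1L + stats::rpois(1, max(density - 1, 0)))
    ps <- sample.int(i - 1L, k)
    child <- c(child, rep(ids[i], k))
    parent <- c(parent, ids[ps])
  }
  rel <- tibble::tibble(subject = character(), relation = character(),
                        object = character())
  if (n >= 3) {
    for (i in seq_len(n)[-1]) {
      if (stats::runif(1) < part_of_prob) {
        j <- sample.int(i - 1L, 1)
        rel <- dplyr::bind_rows(rel, tibble::tibble(
          subject = ids[i], relation = "part_of", object = ids[j]))
      }
    }
  }
  ontology_graph(terms = terms,
                 isa = tibble::tibble(child = child, parent = parent),
                 rel = rel)
}

ancestor_sets <- function(graph) {
  ig <- graph_igraph(graph)
  ids <- graph$terms$id
  stats::setNames(lapply(ids, function(s) {
    names(igraph::subcomponent(ig, s, mode = "out"))
  }), ids)
}

#' Generate a synthetic corpus with planted disagreements
#'
#' Emulates the data a curator-facing validation run sees: random rooted
#' DAG building blocks (one quality namespace `PQ` plus `n_blocks` entity
#' namespaces `B1`, `B2`, ...), entity-quality definitions for the target
#' terms (one quality genus plus one existential filler per entity block,
#' `inheres_in` for odd blocks and `towards` for even ones), and a target
#' ontology whose asserted hierarchy is the *true* entailed hierarchy —
#' after which disagreements are planted with known ground truth:
#'
#' * `n_missing_links` asserted edges are deleted such that the parent
#'   becomes unreachable (these must come back as inferred `"new"` axioms);
#' * `n_spurious_links` acyclicity-preserving non-entailed edges are
#'   inserted (these must come back as asserted-not-found);
#' * `n_duplicate_defs` definitions are copied under fresh target ids
#'   (these must come back as equivalence classes).
#'
#' Everything is a deterministic function of `spec$seed`.
#'
#' @param spec A [corpus_spec()].
#' @return List with `blocks` (named list of [ontology_graph()]s, quality
#'   block first), `definitions`, `target`, and `truth` (tibbles
#'   `expected_new`, `expected_not_found`; list `expected_equivalences`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  # planting is stochastic: a draw may admit no deletable edge. Retry with
  # derived sub-seeds (deterministic in spec$seed) before declaring the
  # spec infeasible.
  base <- spec$seed %% 1000000000L
  err <- NULL
  for (attempt in 0:24) {
    res <- tryCatch(
      withr::with_seed(base + attempt * 7919L, generate_corpus_impl(spec)),
      error = function(e) e)
    if (!inherits(res, "error")) return(res)
    err <- res
  }
  stop("corpus generation infeasible for this spec: ",
       conditionMessage(err), call. = FALSE)
}

generate_corpus_impl <- function(spec) {
  prefixes <- sprintf("B%d", seq_len(spec$n_blocks))
  blocks <- c(
    list(PQ = random_block("PQ", max(6, ceiling(spec$terms_per_block / 2)),
                           1.2, part_of_prob = 0)),
    stats::setNames(
      lapply(prefixes, function(p)
        random_block(p, spec$terms_per_block, spec$dag_density)),
      prefixes)
  )
  block_rel <- ifelse(seq_len(spec$n_blocks) %% 2 == 1,
                      "inheres_in", "towards")
  anc <- lapply(blocks, ancestor_sets)
  strict_desc <- lapply(anc, function(as) {
    ids <- names(as)
    stats::setNames(lapply(ids, function(v) {
      setdiff(ids[vapply(as, function(x) v %in% x, logical(1))], v)
    }), ids)
  })

  # unique (genus, fillers) tuples; roughly half the definitions specialize
  # an earlier one in a single coordinate, so the true hierarchy is non-trivial
  keys <- character(0)
  defs <- vector("list", spec$n_defined)
  genus_of <- character(spec$n_defined)
  fillers_of <- matrix(NA_character_, spec$n_defined, spec$n_blocks)
  for (d in seq_len(spec$n_defined)) {
    for (try in 1:200) {
      if (d > 1 && stats::runif(1) < 0.6) {
        e <- sample.int(d - 1L, 1)
        genus <- genus_of[e]
        fills <- fillers_of[e, ]
        coord <- sample.int(spec$n_blocks + 1L, 1)
        if (coord == 1L) {
          below <- strict_desc$PQ[[genus]]
          if (length(below) > 0) genus <- sample(below, 1)
        } else {
          below <- strict_desc[[prefixes[coord - 1L]]][[fills[coord - 1L]]]
          if (length(below) > 0) fills[coord - 1L] <- sample(below, 1)
        }
      } else {
        genus <- sample(blocks$PQ$terms$id, 1)
        fills <- vapply(prefixes, function(p) sample(blocks[[p]]$terms$id, 1),
                        character(1))
      }
      key <- paste(genus, paste(fills, collapse = "|"))
      if (!key %in% keys) break
      if (try == 200) stop("cannot generate distinct definitions",
                           call. = FALSE)
    }
    keys <- c(keys, key)
    genus_of[d] <- genus
    fillers_of[d, ] <- fills
    defs[[d]] <- xp_definition(
      sprintf("MP:%07d", d), genus,
      tibble::tibble(relation = block_rel, filler = unname(fills)))
  }
  definitions <- dplyr::bind_rows(defs)
  originals <- sprintf("MP:%07d", seq_len(spec$n_defined))

  # true entailed order among defined terms, computed combinationally from
  # per-block ancestor sets (independent of the reasoner)
  nd <- spec$n_defined
  S <- matrix(FALSE, nd, nd)
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      ok <- genus_of[j] %in% anc$PQ[[genus_of[i]]]
      b <- 1
      while (ok && b <= spec$n_blocks) {
        ok <- fillers_of[j, b] %in% anc[[prefixes[b]]][[fillers_of[i, b]]]
        b <- b + 1
      }
      S[i, j] <- ok
    }
  }
  strict <- S & !t(S)
  direct <- strict & !((strict %*% strict) > 0)

  # duplicates under fresh ids sorting after every original
  dup_src <- if (spec$n_duplicate_defs > 0) {
    sample(seq_len(nd), spec$n_duplicate_defs)
  } else integer(0)
  dup_ids <- sprintf("MP:9%06d", seq_along(dup_src))
  for (k in seq_along(dup_src)) {
    definitions <- dplyr::bind_rows(definitions, xp_definition(
      dup_ids[k], genus_of[dup_src[k]],
      tibble::tibble(relation = block_rel,
                     filler = unname(fillers_of[dup_src[k], ]))))
  }
  expected_equivalences <- lapply(seq_along(dup_src), function(k) {
    sort(c(originals[dup_src[k]], dup_ids[k]), method = "radix")
  })

  # target ontology: true direct edges, roots attached under a common root
  root <- "MP:0000000"
  idx <- which(direct, arr.ind = TRUE)
  asserted <- tibble::tibble(child = originals[idx[, 1]],
                             parent = originals[idx[, 2]])
  orphans <- originals[!originals %in% asserted$child]
  asserted <- dplyr::bind_rows(
    asserted,
    tibble::tibble(child = c(orphans, dup_ids), parent = root))

  # spurious links first (so deletions are checked on the final edge set)
  reach_asserted <- function(edges, a, b) {
    ig <- igraph::graph_from_data_frame(
      stats::setNames(edges, c("from", "to")), directed = TRUE,
      vertices = c(originals, dup_ids, root))
    b %in% names(igraph::subcomponent(ig, a, mode = "out"))
  }
  spurious <- tibble::tibble(child = character(), parent = character())
  if (spec$n_spurious_links > 0) {
    for (try in 1:500) {
      ij <- sample(seq_len(nd), 2)
      a <- originals[ij[1]]; b <- originals[ij[2]]
      if (S[ij[1], ij[2]]) next                       # entailed: not spurious
      if (paste(a, b) %in% paste(asserted$child, asserted$parent)) next
      if (reach_asserted(asserted, b, a)) next        # would create a cycle
      spurious <- dplyr::bind_rows(spurious,
                                   tibble::tibble(child = a, parent = b))
      asserted <- dplyr::bind_rows(asserted,
                                   tibble::tibble(child = a, parent = b))
      if (nrow(spurious) == spec$n_spurious_links) break
    }
    if (nrow(spurious) < spec$n_spurious_links) {
      stop("cannot plant the requested spurious links acyclically",
           call. = FALSE)
    }
  }

  # missing links: delete true direct edges whose parent then becomes
  # unreachable, so the pipeline must classify them "new"
  missing <- tibble::tibble(child = character(), parent = character())
  if (spec$n_missing_links > 0) {
    cand <- tibble::tibble(child = originals[idx[, 1]],
                           parent = originals[idx[, 2]])
    cand <- cand[sample.int(nrow(cand)), ]
    for (i in seq_len(nrow(cand))) {
      if (nrow(missing) == spec$n_missing_links) break
      a <- cand$child[i]; b <- cand$parent[i]
      keep <- !(asserted$child == a & asserted$parent == b)
      if (!reach_asserted(asserted[keep, ], a, b)) {
        asserted <- asserted[keep, ]
        missing <- dplyr::bind_rows(missing,
                                    tibble::tibble(child = a, parent = b))
      }
    }
    if (nrow(missing) < spec$n_missing_links) {
      stop("cannot plant the requested missing links: every candidate edge ",
           "stays reachable", call. = FALSE)
    }
  }

  target <- ontology_graph(
    terms = tibble::tibble(
      id = c(root, originals, dup_ids),
      label = c("phenotype root",
                sprintf("target phenotype %d", seq_len(nd)),
                sprintf("duplicated phenotype %d", seq_along(dup_src))),
      obsolete = FALSE),
    isa = asserted
  )

  list(
    blocks = blocks,
    definitions = definitions,
    target = target,
    truth = list(
      expected_new = dplyr::arrange(missing, .data$child, .data$parent),
      expected_not_found = dplyr::arrange(spurious, .data$child,
                                          .data$parent),
      expected_equivalences = expected_equivalences[
        order(purrr::map_chr(expected_equivalences, 1))]
    ),
    spec = spec
  )
}

#' Write a corpus to a directory as OBO files
#'
#' One file per building block (`<prefix>.obo`), the definitions as
#' `definitions.obo` (stanzas for the defined terms with their
#' `intersection_of` conjuncts), and the target as `target.obo`. The
#' on-disk corpus is what [run_pipeline()] consumes, so generated corpora
#' double as end-to-end command-line tests.
#'
#' @param corpus A [generate_corpus()] or [example_corpus()] result.
#' @param dir Directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(corpus$blocks)) {
    p <- file.path(dir, paste0(nm, ".obo"))
    writeLines(write_obo(corpus$blocks[[nm]]), p, sep = "")
    paths$externals <- c(paths$externals, p)
  }
  def_terms <- unique(corpus$definitions$defined)
  lab <- term_labels(corpus$target)
  def_graph <- ontology_graph(tibble::tibble(
    id = def_terms,
    label = unname(ifelse(def_terms %in% names(lab), lab[def_terms],
                          def_terms)),
    obsolete = FALSE))
  p <- file.path(dir, "definitions.obo")
  writeLines(write_obo(def_graph, corpus$definitions), p, sep = "")
  paths$definitions <- p
  p <- file.path(dir, "target.obo")
  writeLines(write_obo(corpus$target), p, sep = "")
  paths$target <- p
  if (!is.null(corpus$bridge)) {
    p <- file.path(dir, "bridge.obo")
    writeLines(write_obo(corpus$bridge), p, sep = "")
    paths$bridge <- p
  }
  invisible(paths)
}
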