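#' Read an OBO flat file
#'
#' Parses the OBO 1.2/1.4 tag-value subset the validation pipeline needs:
#' `id`, `name`, `is_a`, `relationship`, `intersection_of`, `xref` and
#' `is_obsolete` inside `[Term]` stanzas. Trailing `! label` comments are
#' stripped; unrecognized tags and non-`[Term]` stanzas are ignored.
#'
#' An `intersection_of` line with a single token contributes a genus, one
#' with two tokens a `(relation, filler)` differentium. A stanza with fewer
#' than two `intersection_of` lines yields no logical definition (a single
#' conjunct is not an intersection). Duplicate stanzas for one id follow
#' last-writer-wins with a warning.
#'
#' @param file Path to an OBO file, or a single string containing OBO text
#'   (detected by the presence of a newline).
#' @return List with elements `graph` (an [ontology_graph()]),
#'   `definitions` (long-form tibble, see [xp_definition()]) and `source`.
#' @export
read_obo <- function(file) {
  if (length(file) == 1L && grepl("\n", file, fixed = TRUE)) {
    lines <- strsplit(file, "\n", fixed = TRUE)[[1]]
    src <- "<text>"
  } else {
    if (!file.exists(file)) stop("cannot read OBO file: ", file, call. = FALSE)
    lines <- readLines(file, warn = FALSE)
    src <- file
  }
  parse_obo_lines(lines, src)
}

strip_obo_comment <- function(value) {
  stringr::str_trim(stringr::str_replace(value, "\\s*!.*$", ""))
}

parse_obo_lines <- function(lines, src = "<text>") {
  terms <- list()      # id -> list(label, obsolete)
  isa <- list()
  rel <- list()
  xref <- list()
  defs <- list()       # id -> list of conjunct rows

  in_term <- FALSE
  cur_id <- NA_character_
  cur <- NULL
  flush_stanza <- function() {
    if (!in_term || is.na(cur_id)) return()
    if (cur_id %in% names(terms)) {
      warning("duplicate [Term] stanza for ", cur_id,
              "; keeping the later one", call. = FALSE)
      isa[names(isa) == cur_id] <<- NULL
      rel[names(rel) == cur_id] <<- NULL
      xref[names(xref) == cur_id] <<- NULL
      defs[names(defs) == cur_id] <<- NULL
    }
    terms[[cur_id]] <<- cur$term
    if (length(cur$isa)) {
      isa[[length(isa) + 1L]] <<- cur$isa
      names(isa)[length(isa)] <<- cur_id
    }
    if (length(cur$rel)) {
      rel[[length(rel) + 1L]] <<- cur$rel
      names(rel)[length(rel)] <<- cur_id
    }
    if (length(cur$xref)) {
      xref[[length(xref) + 1L]] <<- cur$xref
      names(xref)[length(xref)] <<- cur_id
    }
    if (length(cur$def) >= 2L) {
      defs[[cur_id]] <<- cur$def
    }
  }

  new_stanza <- function() list(term = list(label = NA_character_,
                                            obsolete = FALSE),
                                isa = list(), rel = list(), xref = list(),
                                def = list())

  for (i in seq_along(lines)) {
    raw <- stringr::str_trim(lines[i])
    if (!nzchar(raw)) next
    if (stringr::str_starts(raw, stringr::fixed("["))) {
      flush_stanza()
      in_term <- identical(raw, "[Term]")
      cur_id <- NA_character_
      cur <- new_stanza()
      next
    }
    if (!in_term) next
    m <- stringr::str_match(raw, "^([A-Za-z_][A-Za-z0-9_-]*):\\s*(.*)$")
    if (is.na(m[1, 1])) {
      stop(src, ":", i, ": malformed OBO line: ", raw, call. = FALSE)
    }
    tag <- m[1, 2]
    value <- strip_obo_comment(m[1, 3])
    if (tag == "id") {
      cur_id <- tryCatch(parse_term_id(value), error = function(e) {
        stop(src, ":", i, ": ", conditionMessage(e), call. = FALSE)
      })
    } else if (tag == "name") {
      cur$term$label <- value
    } else if (tag == "is_obsolete") {
      cur$term$obsolete <- identical(tolower(value), "true")
    } else if (tag == "is_a") {
      cur$isa[[length(cur$isa) + 1L]] <- parse_term_id(value)
    } else if (tag == "relationship") {
      tok <- strsplit(value, "\\s+")[[1]]
      if (length(tok) != 2L) {
        stop(src, ":", i, ": malformed relationship line: ", raw,
             call. = FALSE)
      }
      cur$rel[[length(cur$rel) + 1L]] <-
        c(parse_relation(tok[1]), parse_term_id(tok[2]))
    } else if (tag == "intersection_of") {
      tok <- strsplit(value, "\\s+")[[1]]
      if (length(tok) == 1L) {
        cur$def[[length(cur$def) + 1L]] <-
          list(role = "genus", relation = NA_character_,
               filler = parse_term_id(tok[1]))
      } else if (length(tok) == 2L) {
        cur$def[[length(cur$def) + 1L]] <-
          list(role = "differentia", relation = parse_relation(tok[1]),
               filler = parse_term_id(tok[2]))
      } else {
        stop(src, ":", i, ": malformed intersection_of line: ", raw,
             call. = FALSE)
      }
    } else if (tag == "xref") {
      tok <- strsplit(value, "\\s+")[[1]][1]
      xid <- tryCatch(parse_term_id(tok), error = function(e) NULL)
      if (!is.null(xid)) {
        cur$xref[[length(cur$xref) + 1L]] <- xid
      }
    }
    # other tags: ignored (synonyms, def text, subsets, ...)
  }
  flush_stanza()

  term_tbl <- tibble::tibble(
    id = as.character(names(terms)),
    label = unname(purrr::map_chr(terms, "label")),
    obsolete = unname(purrr::map_lgl(terms, "obsolete"))
  )
  isa_tbl <- if (length(isa)) {
    tibble::tibble(
      child = rep(names(isa), lengths(isa)),
      parent = unlist(isa, use.names = FALSE)
    )
  } else tibble::tibble(child = character(), parent = character())
  rel_tbl <- if (length(rel)) {
    dplyr::bind_rows(purrr::imap(rel, function(edges, id) {
      tibble::tibble(subject = id,
                     relation = purrr::map_chr(edges, 1),
                     object = purrr::map_chr(edges, 2))
    }))
  } else tibble::tibble(subject = character(), relation = character(),
                        object = character())
  xref_tbl <- if (length(xref)) {
    dplyr::bind_rows(purrr::imap(xref, function(ids, id) {
      tibble::tibble(id = id, xref = unlist(ids, use.names = FALSE))
    }))
  } else tibble::tibble(id = character(), xref = character())

  def_tbl <- if (length(defs)) {
    dplyr::bind_rows(purrr::imap(defs, function(conj, id) {
      tibble::tibble(
        defined = id,
        role = purrr::map_chr(conj, "role"),
        relation = purrr::map_chr(conj, "relation"),
        filler = purrr::map_chr(conj, "filler"),
        pos = seq_along(conj)
      )
    }))
  } else empty_definitions()

  list(graph = ontology_graph(terms = term_tbl, isa = isa_tbl,
                              rel = rel_tbl, xref = xref_tbl),
       definitions = def_tbl,
       source = src)
}

#' Serialize an ontology graph (and optional definitions) to OBO text
#'
#' Output is deterministic: stanzas sorted by term id, fixed tag order
#' (`id`, `name`, `is_obsolete`, `is_a`, `relationship`, `intersection_of`,
#' `xref`), edges sorted bytewise — so the same graph always yields
#' byte-identical text.
#'
#' @param graph An [ontology_graph()].
#' @param definitions Optional long-form definition tibble; each defined
#'   term's conjuncts are written as `intersection_of` lines in stored order.
#' @return A single string of OBO text.
#' @export
write_obo <- function(graph, definitions = empty_definitions()) {
  labels <- term_labels(graph)
  obs <- stats::setNames(graph$terms$obsolete, graph$terms$id)
  def_list <- definitions_by_term(definitions)
  ids <- sort(union(graph$terms$id, names(def_list)), method = "radix")

  isa_by <- split(graph$isa$parent, graph$isa$child)
  rel_by <- split(graph$rel[, c("relation", "object")], graph$rel$subject)
  xref_by <- split(graph$xref$xref, graph$xref$id)

  out <- c("format-version: 1.2", "")
  for (id in ids) {
    stanza <- c("[Term]", paste0("id: ", id))
    if (id %in% names(labels)) stanza <- c(stanza, paste0("name: ", labels[[id]]))
    if (isTRUE(obs[[id]])) stanza <- c(stanza, "is_obsolete: true")
    for (p in sort(as.character(isa_by[[id]]), method = "radix")) {
      stanza <- c(stanza, paste0("is_a: ", p))
    }
    if (id %in% names(rel_by)) {
      r <- rel_by[[id]]
      r <- r[order(r$relation, r$object, method = "radix"), ]
      stanza <- c(stanza, paste0("relationship: ", r$relation, " ", r$object))
    }
    if (id %in% names(def_list)) {
      d <- def_list[[id]]
      stanza <- c(stanza, purrr::map_chr(seq_len(nrow(d)), function(i) {
        if (d$role[i] == "genus") {
          paste0("intersection_of: ", d$filler[i])
        } else {
          paste0("intersection_of: ", d$relation[i], " ", d$filler[i])
        }
      }))
    }
    for (x in sort(as.character(xref_by[[id]]), method = "radix")) {
      stanza <- c(stanza, paste0("xref: ", x))
    }
    out <- c(out, stanza, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

axiom_lines <- function(edges, labels) {
  if (nrow(edges) == 0) return(character())
  edges <- edges[order(edges$child, edges$parent, method = "radix"), ]
  lab <- function(id) ifelse(id %in% names(labels), labels[id], id)
  paste(edges$child, lab(edges$child), edges$parent, lab(edges$parent),
        sep = "\t")
}

definition_footnotes <- function(edges, definitions, labels) {
  if (nrow(edges) == 0) return(character())
  edges <- edges[order(edges$child, edges$parent, method = "radix"), ]
  def_list <- definitions_by_term(definitions)
  lab <- function(id) ifelse(id %in% names(labels), labels[id], id)
  unlist(purrr::map(seq_len(nrow(edges)), function(i) {
    a <- edges$child[i]; b <- edges$parent[i]
    line <- paste(a, lab(a), b, lab(b), sep = "\t")
    foot <- purrr::map_chr(c(a, b), function(t) {
      if (t %in% names(def_list)) {
        paste0("\tdef ", t, " := ", render_definition(def_list[[t]], labels))
      } else {
        paste0("\tdef ", t, " := (no logical definition)")
      }
    })
    c(line, foot)
  }))
}

#' Write the five disagreement report files
#'
#' Writes exactly `inf_ax_found.txt`, `inf_ax_not_found.txt`,
#' `assert_ax_found.txt`, `assert_ax_not_found.txt` and
#' `equivalence_ax.txt` into `outdir`. Axiom lines are tab-separated
#' `child_id  child_label  parent_id  parent_label`, sorted by child then
#' parent id. In the two `*_not_found` files each axiom is followed by the
#' logical definitions of both terms, indented — the debugging hints a
#' curator needs. Output is byte-identical across re-runs.
#'
#' @param report A `comparison_report` from [compare_hierarchies()].
#' @param outdir Existing writable directory.
#' @return Invisibly, the five file names written.
#' @export
write_reports <- function(report, outdir) {
  stopifnot(inherits(report, "comparison_report"))
  if (!dir.exists(outdir) || file.access(outdir, 2) != 0) {
    stop("output directory not writable: ", outdir, call. = FALSE)
  }
  labels <- report$labels
  defs <- report$definitions
  header <- "child_id\tchild_label\tparent_id\tparent_label"

  inf_found <- report$inferred[report$inferred$category %in%
                                 c("direct", "indirect"), c("child", "parent")]
  inf_new <- report$inferred[report$inferred$category == "new",
                             c("child", "parent")]
  as_found <- report$asserted[report$asserted$found, c("child", "parent")]
  as_not <- report$asserted[!report$asserted$found, c("child", "parent")]

  eq_lines <- purrr::map_chr(report$equivalences, function(cl) {
    cl <- sort(cl, method = "radix")
    lab <- ifelse(cl %in% names(labels), labels[cl], cl)
    paste(as.vector(rbind(cl, lab)), collapse = "\t")
  })
  eq_lines <- sort(eq_lines, method = "radix")

  contents <- list(
    "inf_ax_found.txt" = c(header, axiom_lines(inf_found, labels)),
    "inf_ax_not_found.txt" = c(header,
                               definition_footnotes(inf_new, defs, labels)),
    "assert_ax_found.txt" = c(header, axiom_lines(as_found, labels)),
    "assert_ax_not_found.txt" = c(header,
                                  definition_footnotes(as_not, defs, labels)),
    "equivalence_ax.txt" = c("equivalent_terms", eq_lines)
  )
  for (fn in names(contents)) {
    con <- file(file.path(outdir, fn), open = "wb")
    writeLines(contents[[fn]], con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  invisible(names(contents))
}
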