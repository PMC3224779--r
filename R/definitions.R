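#' Build a cross-product logical definition
#'
#' A logical definition states that a defined term is *equivalent to* the
#' intersection of one or more genus classes and zero or more existential
#' differentia `(relation, filler)` — the entity-quality pattern used to
#' decompose phenotype terms, e.g. Hypoglycemia as a decreased concentration,
#' qualified abnormal, towards glucose, inhering in blood.
#'
#' Definitions are kept in a long (tidy) table: one row per conjunct, with
#' `role = "genus"` rows carrying `relation = NA`. Conjunct order is
#' preserved in `pos`.
#'
#' @param defined Term id of the defined class.
#' @param genera Character vector of genus term ids (length >= 1).
#' @param differentia Tibble with columns `relation`, `filler` (may be empty),
#'   or a list of two-element character vectors.
#' @return Tibble with columns `defined`, `role`, `relation`, `filler`, `pos`.
#' @examples
#' xp_definition("HP:0001943", "PATO:0001163",
#'   tibble::tibble(relation = c("qualifier", "towards", "inheres_in"),
#'                  filler = c("PATO:0000460", "CHEBI:17234", "FMA:9670")))
#' @export
xp_definition <- function(defined, genera,
                          differentia = tibble::tibble(relation = character(),
                                                       filler = character())) {
  stopifnot(length(defined) == 1L, length(genera) >= 1L)
  defined <- parse_term_id(defined)
  genera <- parse_term_id(genera)
  if (is.list(differentia) && !is.data.frame(differentia)) {
    differentia <- tibble::tibble(
      relation = purrr::map_chr(differentia, 1),
      filler = purrr::map_chr(differentia, 2)
    )
  }
  differentia <- tibble::as_tibble(differentia)
  if (nrow(differentia) > 0) {
    differentia$relation <- parse_relation(differentia$relation)
    differentia$filler <- parse_term_id(differentia$filler)
  }
  if (defined %in% c(genera, differentia$filler)) {
    stop("definition of ", defined, " refers to itself", call. = FALSE)
  }
  dplyr::bind_rows(
    tibble::tibble(defined = defined, role = "genus",
                   relation = NA_character_, filler = genera),
    tibble::tibble(defined = defined, role = "differentia",
                   relation = differentia$relation,
                   filler = differentia$filler)
  ) |>
    dplyr::mutate(pos = dplyr::row_number())
}

empty_definitions <- function() {
  tibble::tibble(defined = character(), role = character(),
                 relation = character(), filler = character(), pos = integer())
}

#' Check a definition table for structural problems
#'
#' Enforces: at most one definition per defined term (a defined term's rows
#' must be contiguous in intent, i.e. no term defined twice), every
#' definition has at least one genus, and no definition mentions its own
#' defined term.
#'
#' @param definitions Long-form definition tibble (rows from
#'   [xp_definition()], possibly concatenated across files).
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_definitions <- function(definitions) {
  if (nrow(definitions) == 0) return(invisible(definitions))
  dup <- definitions |>
    dplyr::count(.data$defined, .data$pos) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("more than one logical definition for: ",
         paste(unique(dup$defined), collapse = ", "), call. = FALSE)
  }
  selfref <- definitions$defined == definitions$filler
  if (any(selfref)) {
    stop("self-referential definition: ",
         paste(unique(definitions$defined[selfref]), collapse = ", "),
         call. = FALSE)
  }
  no_genus <- definitions |>
    dplyr::group_by(.data$defined) |>
    dplyr::summarise(g = sum(.data$role == "genus"), .groups = "drop") |>
    dplyr::filter(.data$g == 0)
  if (nrow(no_genus) > 0) {
    stop("definition without a genus: ",
         paste(no_genus$defined, collapse = ", "), call. = FALSE)
  }
  invisible(definitions)
}

#' Terms of one namespace referenced by a set of definitions
#'
#' The union of all genus and filler identifiers carrying the given prefix.
#' Defined terms themselves are excluded: they belong to the target ontology,
#' not to the building blocks being subset.
#'
#' @param definitions Long-form definition tibble.
#' @param prefix Namespace token, e.g. `"PATO"`.
#' @return Sorted character vector of term ids.
#' @examples
#' d <- xp_definition("HP:0001943", "PATO:0001163",
#'   list(c("towards", "CHEBI:17234")))
#' referenced_terms(d, "PATO")
#' @export
referenced_terms <- function(definitions, prefix) {
  if (nrow(definitions) == 0) return(character())
  ids <- setdiff(unique(definitions$filler), unique(definitions$defined))
  sort(ids[term_prefix(ids) == prefix], method = "radix")
}

#' Namespace prefixes referenced by a set of definitions
#' @param definitions Long-form definition tibble.
#' @return Sorted character vector of prefixes appearing among genera/fillers.
#' @export
referenced_prefixes <- function(definitions) {
  if (nrow(definitions) == 0) return(character())
  ids <- setdiff(unique(definitions$filler), unique(definitions$defined))
  sort(unique(term_prefix(ids)), method = "radix")
}

# split a long definition table into a named list of per-term tables,
# preserving conjunct order
definitions_by_term <- function(definitions) {
  if (nrow(definitions) == 0) return(list())
  split(definitions, definitions$defined)
}

# render one term's definition as a single human-readable line
render_definition <- function(def_rows, labels = character()) {
  lab <- function(id) {
    if (id %in% names(labels) && labels[[id]] != id) {
      paste0(id, " '", labels[[id]], "'")
    } else id
  }
  parts <- purrr::map_chr(seq_len(nrow(def_rows)), function(i) {
    if (def_rows$role[i] == "genus") {
      lab(def_rows$filler[i])
    } else {
      paste0(def_rows$relation[i], " some ", lab(def_rows$filler[i]))
    }
  })
  paste(parts, collapse = " and ")
}
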