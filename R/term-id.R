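#' Parse CURIE-style term identifiers
#'
#' Ontology terms are identified by compact URIs such as `"GO:0006878"` or
#' `"PATO:0001163"`. Two spelling dialects circulate in the wild: the colon
#' form (`"HP:0001943"`) and the underscore form (`"MP_0003951"`). Both parse
#' to the same identifier; the colon form is canonical on output, so that all
#' serialized reports are bit-stable regardless of the input dialect.
#'
#' @param token Character vector of identifier tokens in either dialect.
#' @return Character vector of canonical `"PREFIX:LOCAL"` identifiers.
#' @examples
#' parse_term_id(c("HP:0001943", "MP_0003951"))
#' @export
parse_term_id <- function(token) {
  stopifnot(is.character(token))
  if (length(token) == 0L) return(character())
  bad <- is.na(token) | !nzchar(token)
  if (any(bad)) {
    stop("cannot parse empty term identifier", call. = FALSE)
  }
  # Split on the FIRST ":" if present, otherwise on the LAST "_" (underscore
  # dialect; prefixes like "OBO_REL" may themselves contain underscores).
  has_colon <- stringr::str_detect(token, stringr::fixed(":"))
  prefix <- character(length(token))
  local <- character(length(token))
  prefix[has_colon] <- stringr::str_replace(token[has_colon], ":.*$", "")
  local[has_colon] <- stringr::str_replace(token[has_colon], "^[^:]*:", "")
  if (any(!has_colon)) {
    m <- stringr::str_match(token[!has_colon], "^(.*)_([^_]+)$")
    prefix[!has_colon] <- m[, 2]
    local[!has_colon] <- m[, 3]
  }
  bad <- is.na(prefix) | !nzchar(prefix) | is.na(local) | !nzchar(local)
  if (any(bad)) {
    stop("malformed term identifier: ", paste(unique(token[bad]), collapse = ", "),
         call. = FALSE)
  }
  paste0(prefix, ":", local)
}

#' Namespace prefix of a term identifier
#'
#' @param id Character vector of canonical term identifiers.
#' @return Character vector of namespace prefixes (e.g. `"GO"`).
#' @export
term_prefix <- function(id) {
  stringr::str_replace(id, ":.*$", "")
}

#' Normalize an object-property token
#'
#' Relation names (e.g. `inheres_in`, `towards`, `part_of`) are case-sensitive
#' tokens; an optional `OBO_REL:` prefix is trimmed. The subsumption relation
#' `is_a` is structural, never a relation token.
#'
#' @param name Character vector of relation tokens.
#' @return Normalized character vector.
#' @export
parse_relation <- function(name) {
  stopifnot(is.character(name))
  out <- stringr::str_remove(name, "^OBO_REL:")
  if (any(!nzchar(out) | is.na(out))) {
    stop("malformed relation token", call. = FALSE)
  }
  if (any(out == "is_a")) {
    stop("'is_a' is the structural subsumption relation, not an object property",
         call. = FALSE)
  }
  out
}
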