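fresh_diff_name <- function(defined, relation, filler) {
  paste0("~X|", defined, "|", relation, "|", filler)
}
fresh_chain_name <- function(defined, j) {
  paste0("~C|", defined, "|", j)
}

#' Normalize a composite ontology into EL axiom normal forms
#'
#' Rewrites the composite (subsumption edges, relationship edges, logical
#' definitions, bridge equivalences) into the four EL normal forms over
#' named classes only:
#'
#' * type 1: `A [= B`
#' * type 2: `A n B [= C` (binary conjunction)
#' * type 3: `A [= Er.B`
#' * type 4: `Er.A [= B`
#'
#' Each definition `D == g1 n ... n Er1.f1 n ...` contributes (a) one
#' type-1/type-3 axiom `D [= conjunct` per conjunct, and (b) the converse
#' direction through deterministic fresh names: `Eri.fi [= Ni` (type 4)
#' and a left-associated chain of type-2 axioms over the genera and the
#' `Ni`, ending in `[= D`. Fresh names are synthesized from the defining
#' term, relation and filler, so normalization is reproducible and
#' order-independent. Bridge pairs become the two type-1 inclusions.
#'
#' @param composite A [build_composite()] result.
#' @param translate_relationships Should relationship edges `(S, r, O)` of
#'   the building blocks be read as `S [= Er.O`? Default `TRUE`, the
#'   standard OBO-to-OWL reading.
#' @return A `normalized_axioms` object: tibbles `type1` (`sub`, `sup`),
#'   `type2` (`a`, `b`, `sup`), `type3` (`sub`, `rel`, `filler`), `type4`
#'   (`rel`, `filler`, `sup`); character vectors `names` (all class names)
#'   and `fresh` (synthesized ones).
#' @export
normalize_axioms <- function(composite, translate_relationships = TRUE) {
  stopifnot(inherits(composite, "composite_ontology"))
  g <- composite$graph
  t1 <- list(tibble::tibble(sub = g$isa$child, sup = g$isa$parent))
  t2 <- list()
  t3 <- list()
  t4 <- list()
  if (translate_relationships && nrow(g$rel) > 0) {
    t3 <- c(t3, list(tibble::tibble(sub = g$rel$subject, rel = g$rel$relation,
                                    filler = g$rel$object)))
  }
  fresh <- character()
  for (def in definitions_by_term(composite$definitions)) {
    d <- def$defined[1]
    genera <- def$filler[def$role == "genus"]
    diffs <- def[def$role == "differentia", c("relation", "filler")]
    # (a) defined [= each conjunct
    t1 <- c(t1, list(tibble::tibble(sub = d, sup = genera)))
    if (nrow(diffs) > 0) {
      t3 <- c(t3, list(tibble::tibble(sub = d, rel = diffs$relation,
                                      filler = diffs$filler)))
    }
    # (b) conjunction of all conjuncts [= defined, via fresh names
    nn <- character(0)
    if (nrow(diffs) > 0) {
      nn <- fresh_diff_name(d, diffs$relation, diffs$filler)
      t4 <- c(t4, list(tibble::tibble(rel = diffs$relation,
                                      filler = diffs$filler, sup = nn)))
    }
    conj <- c(genera, nn)
    fresh <- c(fresh, nn)
    if (length(conj) == 1L) {
      t1 <- c(t1, list(tibble::tibble(sub = conj, sup = d)))
    } else {
      acc <- conj[1]
      for (j in 2:length(conj)) {
        nxt <- if (j == length(conj)) d else fresh_chain_name(d, j)
        t2 <- c(t2, list(tibble::tibble(a = acc, b = conj[j], sup = nxt)))
        if (nxt != d) fresh <- c(fresh, nxt)
        acc <- nxt
      }
    }
  }
  if (nrow(composite$bridges) > 0) {
    t1 <- c(t1, list(tibble::tibble(sub = composite$bridges$a,
                                    sup = composite$bridges$b)),
            list(tibble::tibble(sub = composite$bridges$b,
                                sup = composite$bridges$a)))
  }
  t1 <- dplyr::distinct(dplyr::bind_rows(t1))
  t2 <- if (length(t2)) dplyr::distinct(dplyr::bind_rows(t2)) else
    tibble::tibble(a = character(), b = character(), sup = character())
  t3 <- if (length(t3)) dplyr::distinct(dplyr::bind_rows(t3)) else
    tibble::tibble(sub = character(), rel = character(), filler = character())
  t4 <- if (length(t4)) dplyr::distinct(dplyr::bind_rows(t4)) else
    tibble::tibble(rel = character(), filler = character(), sup = character())
  fresh <- sort(unique(fresh), method = "radix")
  nms <- sort(unique(c(g$terms$id, composite$definitions$defined,
                       composite$definitions$filler,
                       t1$sub, t1$sup, t2$a, t2$b, t2$sup,
                       t3$sub, t3$filler, t4$filler, t4$sup)),
              method = "radix")
  structure(list(type1 = t1, type2 = t2, type3 = t3, type4 = t4,
                 names = nms, fresh = fresh),
            class = "normalized_axioms")
}

#' @export
print.normalized_axioms <- function(x, ...) {
  cat(sprintf(
    "<normalized_axioms> %d names (%d fresh); type1 %d, type2 %d, type3 %d, type4 %d\n",
    length(x$names), length(x$fresh), nrow(x$type1), nrow(x$type2),
    nrow(x$type3), nrow(x$type4)))
  invisible(x)
}

new_el_closure <- function(S, names, method) {
  dimnames(S) <- list(names, names)
  if (length(names) > 0) {
    mutual <- S & t(S)
    rep_of <- vapply(seq_along(names),
                     function(i) min(names[mutual[i, ]]), character(1))
    classes <- unname(lapply(split(names, rep_of), sort, method = "radix"))
  } else {
    classes <- list()
  }
  structure(list(subsumes = S, names = names, equiv_classes = classes),
            class = "el_closure", method = method)
}

#' Classify a normalized axiom set by EL completion rules
#'
#' Computes the least fixpoint of the standard EL completion rules over
#' subsumer sets `S(A)` and role successors `R(r)`:
#'
#' * CR1: `B in S(A)`, `B [= C` gives `C in S(A)`
#' * CR2: `B1, B2 in S(A)`, `B1 n B2 [= C` gives `C in S(A)`
#' * CR3: `B in S(A)`, `B [= Er.C` gives `(A, C) in R(r)`
#' * CR4: `(A, B) in R(r)`, `B' in S(B)`, `Er.B' [= C` gives `C in S(A)`
#'
#' This is sound and complete for the fragment the cross-product pattern
#' uses (conjunction and existential restriction; no negation, so the set
#' can never be inconsistent). The result is restricted to non-fresh names
#' and, being a unique fixpoint, does not depend on axiom iteration order.
#'
#' @param axioms A [normalize_axioms()] result.
#' @return An `el_closure`: logical matrix `subsumes` (`subsumes[A, B]`
#'   means `A [= B` is entailed; reflexive and transitive), the class
#'   `names`, and `equiv_classes`, the partition into mutually subsuming
#'   classes.
#' @export
el_classify <- function(axioms) {
  stopifnot(inherits(axioms, "normalized_axioms"))
  nm <- axioms$names
  n <- length(nm)
  if (n == 0) {
    return(new_el_closure(matrix(FALSE, 0, 0), character(), "completion"))
  }
  ix <- stats::setNames(seq_len(n), nm)
  S <- diag(n) > 0
  M1 <- matrix(FALSE, n, n)
  if (nrow(axioms$type1) > 0) {
    M1[cbind(ix[axioms$type1$sub], ix[axioms$type1$sup])] <- TRUE
  }
  t2 <- axioms$type2
  t3 <- axioms$type3
  t4 <- axioms$type4
  rels <- sort(unique(c(t3$rel, t4$rel)), method = "radix")
  R <- lapply(rels, function(r) matrix(FALSE, n, n))
  names(R) <- rels

  repeat {
    before <- sum(S) + sum(vapply(R, sum, numeric(1)))
    # CR1
    S <- S | ((S %*% M1) > 0)
    # CR2
    if (nrow(t2) > 0) {
      for (k in seq_len(nrow(t2))) {
        rows <- S[, ix[t2$a[k]]] & S[, ix[t2$b[k]]]
        if (any(rows)) S[rows, ix[t2$sup[k]]] <- TRUE
      }
    }
    # CR3
    if (nrow(t3) > 0) {
      for (k in seq_len(nrow(t3))) {
        rows <- S[, ix[t3$sub[k]]]
        if (any(rows)) R[[t3$rel[k]]][rows, ix[t3$filler[k]]] <- TRUE
      }
    }
    # CR4
    if (nrow(t4) > 0) {
      for (r in unique(t4$rel)) {
        M <- (R[[r]] %*% S) > 0   # M[A, B'] : A has an r-successor below B'
        rows4 <- which(t4$rel == r)
        for (k in rows4) {
          rows <- M[, ix[t4$filler[k]]]
          if (any(rows)) S[rows, ix[t4$sup[k]]] <- TRUE
        }
      }
    }
    after <- sum(S) + sum(vapply(R, sum, numeric(1)))
    if (after == before) break
  }

  keep <- !(nm %in% axioms$fresh)
  new_el_closure(S[keep, keep, drop = FALSE], nm[keep], "completion")
}

#' @export
print.el_closure <- function(x, ...) {
  n <- length(x$names)
  cat(sprintf(
    "<el_closure> %d classes, %d entailed subsumptions (non-reflexive), %d equivalence classes of size >= 2 [%s]\n",
    n, sum(x$subsumes) - n,
    sum(lengths(x$equiv_classes) >= 2),
    attr(x, "method")))
  invisible(x)
}

#' Is a subsumption entailed?
#' @param closure An `el_closure`.
#' @param sub,sup Term ids.
#' @return Logical: `TRUE` iff `sub [= sup` is entailed (unknown names
#'   subsume only themselves).
#' @export
is_subsumed <- function(closure, sub, sup) {
  if (!(sub %in% closure$names) || !(sup %in% closure$names)) {
    return(sub == sup)
  }
  closure$subsumes[sub, sup]
}

#' Classify a composite ontology via its canonical (least) model
#'
#' An independent verification path for [el_classify()]: instead of
#' saturating subsumer sets, this materializes the least model of the
#' composite — one domain element per named class, class extensions and
#' role extensions grown to the smallest fixpoint satisfying every axiom
#' (subsumption edges, relationship edges, both directions of each
#' definition's equivalence, bridge equivalences). In this fragment the
#' canonical-model property holds: `A [= B` is entailed exactly when the
#' element introduced for `A` lies in the extension of `B`. No
#' normalization and no fresh names are involved, so the two routes share
#' no code.
#'
#' @param composite A [build_composite()] result.
#' @param translate_relationships As in [normalize_axioms()].
#' @return An `el_closure` over the composite's named classes.
#' @export
el_classify_canonical <- function(composite, translate_relationships = TRUE) {
  stopifnot(inherits(composite, "composite_ontology"))
  g <- composite$graph
  nm <- sort(unique(c(g$terms$id, composite$definitions$defined,
                      composite$definitions$filler,
                      composite$bridges$a, composite$bridges$b)),
             method = "radix")
  n <- length(nm)
  if (n == 0) return(new_el_closure(matrix(FALSE, 0, 0), character(),
                                    "canonical"))
  ix <- stats::setNames(seq_len(n), nm)
  # E[d, C]: element d belongs to the extension of class C
  E <- diag(n) > 0
  rels <- unique(c(if (translate_relationships) g$rel$relation,
                   composite$definitions$relation))
  rels <- sort(rels[!is.na(rels)], method = "radix")
  RM <- lapply(rels, function(r) matrix(FALSE, n, n))
  names(RM) <- rels

  defs <- definitions_by_term(composite$definitions)
  isa <- g$isa
  rel_edges <- if (translate_relationships) g$rel else g$rel[0, ]
  br <- composite$bridges

  repeat {
    before <- sum(E) + sum(vapply(RM, sum, numeric(1)))
    # asserted subsumptions: ext(A) subset of ext(B)
    if (nrow(isa) > 0) {
      for (k in seq_len(nrow(isa))) {
        a <- ix[isa$child[k]]; b <- ix[isa$parent[k]]
        E[, b] <- E[, b] | E[, a]
      }
    }
    # relationship edges: d in ext(A) forces the edge (d, d_B) in r
    if (nrow(rel_edges) > 0) {
      for (k in seq_len(nrow(rel_edges))) {
        RM[[rel_edges$relation[k]]][E[, ix[rel_edges$subject[k]]],
                                    ix[rel_edges$object[k]]] <- TRUE
      }
    }
    # bridges: extensions coincide
    if (nrow(br) > 0) {
      for (k in seq_len(nrow(br))) {
        u <- E[, ix[br$a[k]]] | E[, ix[br$b[k]]]
        E[, ix[br$a[k]]] <- u
        E[, ix[br$b[k]]] <- u
      }
    }
    for (def in defs) {
      d <- ix[def$defined[1]]
      genera <- ix[def$filler[def$role == "genus"]]
      diffs <- def[def$role == "differentia", ]
      # necessary direction: members of D satisfy every conjunct
      for (gix in genera) E[, gix] <- E[, gix] | E[, d]
      if (nrow(diffs) > 0) {
        for (k in seq_len(nrow(diffs))) {
          RM[[diffs$relation[k]]][E[, d], ix[diffs$filler[k]]] <- TRUE
        }
      }
      # sufficient direction: anything satisfying all conjuncts is a D
      cand <- rep(TRUE, n)
      for (gix in genera) cand <- cand & E[, gix]
      if (nrow(diffs) > 0) {
        for (k in seq_len(nrow(diffs))) {
          wit <- (RM[[diffs$relation[k]]] %*% E[, ix[diffs$filler[k]]]) > 0
          cand <- cand & as.vector(wit)
        }
      }
      E[cand, d] <- TRUE
    }
    after <- sum(E) + sum(vapply(RM, sum, numeric(1)))
    if (after == before) break
  }
  new_el_closure(E, nm, "canonical")
}

#' Inferred hierarchy over the defined target terms
#'
#' Restricts a subsumption closure to the defined terms of the target
#' namespace, collapses equivalence classes onto their lexicographically
#' smallest representative, and takes the transitive reduction of the
#' remaining strict order: the result is the set of *direct* inferred
#' subclass edges, i.e. the reasoned hierarchy a curator compares against
#' the asserted one. Fresh names and reflexive subsumptions never appear.
#'
#' @param closure An `el_closure`.
#' @param target_prefix Namespace of the target ontology (e.g. `"MP"`).
#' @param defined_terms Character vector of terms that carry definitions.
#' @return List with `direct_edges` (tibble `child`, `parent`, on
#'   representatives), `equivalences` (list of classes of size >= 2) and
#'   `classes` (tibble `id`, `representative`).
#' @export
inferred_target_axioms <- function(closure, target_prefix, defined_terms) {
  cand <- sort(intersect(defined_terms, closure$names), method = "radix")
  cand <- cand[term_prefix(cand) == target_prefix]
  if (length(cand) == 0) {
    return(list(direct_edges = tibble::tibble(child = character(),
                                              parent = character()),
                equivalences = list(),
                classes = tibble::tibble(id = character(),
                                         representative = character())))
  }
  S <- closure$subsumes[cand, cand, drop = FALSE]
  mutual <- S & t(S)
  rep_of <- vapply(seq_along(cand), function(i) min(cand[mutual[i, ]]),
                   character(1))
  classes <- tibble::tibble(id = cand, representative = rep_of)
  eqs <- unname(split(cand, rep_of))
  eqs <- lapply(eqs[lengths(eqs) >= 2], sort, method = "radix")
  reps <- sort(unique(rep_of), method = "radix")
  Sr <- S[reps, reps, drop = FALSE]
  strict <- Sr & !t(Sr)
  direct <- strict & !((strict %*% strict) > 0)
  idx <- which(direct, arr.ind = TRUE)
  edges <- tibble::tibble(child = reps[idx[, 1]], parent = reps[idx[, 2]]) |>
    dplyr::arrange(.data$child, .data$parent)
  list(direct_edges = edges, equivalences = eqs, classes = classes)
}

#' @rdname tidy_ontodiff
#' @exportS3Method generics::tidy
tidy.el_closure <- function(x, ...) {
  idx <- which(x$subsumes & !diag(length(x$names)), arr.ind = TRUE)
  tibble::tibble(sub = x$names[idx[, 1]], sup = x$names[idx[, 2]]) |>
    dplyr::arrange(.data$sub, .data$sup)
}
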