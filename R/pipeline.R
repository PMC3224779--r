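#' Assemble a pipeline run configuration
#'
#' @param definition_files Paths to OBO files carrying the cross-product
#'   logical definitions (at least one).
#' @param target_path Path to the target ontology (asserted hierarchy).
#' @param output_dir Directory for the report files; created if missing.
#' @param external_ontologies Paths to the building-block ontologies.
#' @param full_import Import the building blocks in their entirety instead
#'   of their induced ancestral subsets. The reports are identical either
#'   way; subsets are simply cheaper.
#' @param backend Reasoner backend; only `"internal"` (the bundled EL
#'   engine) is available. The argument exists as the integration point for
#'   an external OWL reasoner.
#' @param bridge_path Optional OBO file whose cross-namespace subclass
#'   axioms and xrefs are converted into equivalence bridges.
#' @param bridged_prefixes Namespaces to bridge (see [build_xref_bridge()]).
#' @param closure_relations Relations besides `is_a` that drive the upward
#'   closure during subset extraction.
#' @param translate_relationships Read relationship edges as existential
#'   axioms (see [normalize_axioms()]).
#' @param target_prefix Namespace of the target ontology; default: the most
#'   frequent prefix among defined terms.
#' @param quiet Suppress progress messages.
#' @return A `run_config` list.
#' @export
run_config <- function(definition_files, target_path, output_dir,
                       external_ontologies = character(),
                       full_import = FALSE, backend = "internal",
                       bridge_path = NULL, bridged_prefixes = character(),
                       closure_relations = character(),
                       translate_relationships = TRUE,
                       target_prefix = NULL, quiet = FALSE) {
  structure(list(
    definition_files = definition_files, target_path = target_path,
    output_dir = output_dir, external_ontologies = external_ontologies,
    full_import = isTRUE(full_import), backend = backend,
    bridge_path = bridge_path, bridged_prefixes = bridged_prefixes,
    closure_relations = closure_relations,
    translate_relationships = isTRUE(translate_relationships),
    target_prefix = target_prefix, quiet = isTRUE(quiet)
  ), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with keys matching the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  bad <- setdiff(names(y), allowed)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
                 class = "ontodiff_input_error")
  }
  do.call(run_config, y)
}

check_inputs <- function(config) {
  files <- c(config$definition_files, config$target_path,
             config$external_ontologies, config$bridge_path)
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    rlang::abort(paste0("input file(s) not found: ",
                        paste(missing, collapse = ", ")),
                 class = "ontodiff_input_error")
  }
  if (length(config$definition_files) < 1) {
    rlang::abort("at least one definition file is required",
                 class = "ontodiff_input_error")
  }
  if (!identical(config$backend, "internal")) {
    rlang::abort(paste0("reasoner backend '", config$backend,
                        "' is not bundled; use 'internal'"),
                 class = "ontodiff_input_error")
  }
}

stop_on_cycles <- function(graph, what) {
  findings <- validate_ontology(graph)
  cyc <- findings[findings$type == "isa_cycle", ]
  if (nrow(cyc) > 0) {
    rlang::abort(paste0("is_a cycle(s) in ", what, ": ",
                        paste(cyc$detail, collapse = "; "),
                        " — refusing to reason over a cyclic hierarchy"),
                 class = "ontodiff_cycle_error")
  }
  invisible(findings)
}

#' Validate an in-memory corpus
#'
#' The same extract/merge/classify/compare chain as [run_pipeline()], but
#' over graphs already in memory (e.g. a [generate_corpus()] or
#' [example_corpus()] result) and without touching the file system.
#'
#' @param corpus List with `blocks` (named list of [ontology_graph()]),
#'   `definitions`, `target`, and optionally `bridges`.
#' @param extract Use induced ancestral subsets (`TRUE`, default) or the
#'   full building blocks.
#' @param closure_relations,translate_relationships See [run_pipeline()].
#' @param target_prefix Defaults to the majority prefix of defined terms.
#' @return A `comparison_report`.
#' @export
validate_corpus <- function(corpus, extract = TRUE,
                            closure_relations = character(),
                            translate_relationships = TRUE,
                            target_prefix = NULL) {
  defs <- corpus$definitions
  validate_definitions(defs)
  defined <- sort(unique(defs$defined), method = "radix")
  bridges <- corpus$bridges
  if (is.null(bridges)) bridges <- empty_bridges()
  blocks <- corpus$blocks
  subsets <- if (extract) {
    bridge_seeds <- c(bridges$a, bridges$b)
    lapply(blocks, function(g) {
      prefixes <- unique(term_prefix(g$terms$id))
      seeds <- unique(c(
        unlist(lapply(prefixes, function(p) referenced_terms(defs, p))),
        bridge_seeds[term_prefix(bridge_seeds) %in% prefixes]))
      induced_ancestral_graph(g, seeds, closure_relations)
    })
  } else blocks
  composite <- build_composite(unname(subsets), defs, bridges)
  closure <- el_classify(normalize_axioms(composite,
                                          translate_relationships))
  if (is.null(target_prefix)) {
    target_prefix <- if (length(defined) == 0) "" else
      names(sort(table(term_prefix(defined)), decreasing = TRUE))[1]
  }
  inferred <- inferred_target_axioms(closure, target_prefix, defined)
  compare_hierarchies(inferred, closure, corpus$target, defined, defs,
                      composite,
                      extra_labels = term_labels(composite$graph))
}

#' Run the full validation pipeline
#'
#' Parse definitions, building blocks, target and optional bridge; extract
#' the induced ancestral subsets (unless `full_import`); build the
#' composite ontology; classify it; restrict to the defined target terms;
#' diff against the asserted hierarchy; and write the five report files
#' plus `composite.obo`, `reasoned.obo` and a machine-readable
#' `summary.tsv` into the output directory. All outputs are byte-stable
#' under re-runs of an unchanged configuration.
#'
#' @param config A [run_config()], or the path of a YAML config file.
#' @return The `comparison_report`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  stopifnot(inherits(config, "run_config"))
  check_inputs(config)
  say <- function(...) if (!config$quiet) message(...)

  defs <- empty_definitions()
  def_labels <- character()
  for (f in config$definition_files) {
    parsed <- read_obo(f)
    defs <- dplyr::bind_rows(defs, parsed$definitions)
    def_labels <- c(def_labels, term_labels(parsed$graph))
  }
  validate_definitions(defs)
  defined <- sort(unique(defs$defined), method = "radix")
  say(length(defined), " defined terms across ",
      length(config$definition_files), " definition file(s)")

  target_parsed <- read_obo(config$target_path)
  stop_on_cycles(target_parsed$graph, "target ontology")
  target <- drop_obsolete(target_parsed$graph)

  externals <- lapply(config$external_ontologies, function(f) {
    parsed <- read_obo(f)
    stop_on_cycles(parsed$graph, f)
    drop_obsolete(parsed$graph)
  })
  names(externals) <- config$external_ontologies

  bridges <- empty_bridges()
  if (!is.null(config$bridge_path)) {
    bparsed <- read_obo(config$bridge_path)
    stop_on_cycles(bparsed$graph, "bridging ontology")
    bridges <- build_xref_bridge(drop_obsolete(bparsed$graph),
                                 config$bridged_prefixes)
    say(nrow(bridges), " bridge equivalence pairs")
  }

  if (config$full_import) {
    subsets <- externals
  } else {
    bridge_seeds <- c(bridges$a, bridges$b)
    subsets <- lapply(externals, function(g) {
      prefixes <- unique(term_prefix(g$terms$id))
      seeds <- unique(c(
        unlist(lapply(prefixes, function(p) referenced_terms(defs, p))),
        bridge_seeds[term_prefix(bridge_seeds) %in% prefixes]
      ))
      induced_ancestral_graph(g, seeds, config$closure_relations)
    })
    sizes <- subset_sizes(externals, subsets)
    for (i in seq_len(nrow(sizes))) {
      say(sprintf("subset %s: %d of %d terms (%.1f%%)", sizes$ontology[i],
                  sizes$n_subset[i], sizes$n_terms[i],
                  100 * sizes$fraction_referenced[i]))
    }
  }

  composite <- build_composite(unname(subsets), defs, bridges)
  axioms <- normalize_axioms(composite, config$translate_relationships)
  closure <- el_classify(axioms)

  target_prefix <- config$target_prefix
  if (is.null(target_prefix)) {
    target_prefix <- if (length(defined) == 0) "" else
      names(sort(table(term_prefix(defined)), decreasing = TRUE))[1]
  }
  inferred <- inferred_target_axioms(closure, target_prefix, defined)

  report <- compare_hierarchies(
    inferred, closure, target, defined, defs, composite,
    extra_labels = c(term_labels(composite$graph), def_labels))
  g <- glance(report)
  say(sprintf(paste0("inferred %d direct axioms: %d found directly, ",
                     "%d indirectly, %d new; asserted %d: %d entailed, ",
                     "%d not; %d equivalence classes"),
              g$n_inferred, g$n_direct_found, g$n_indirect_found, g$n_new,
              g$n_asserted, g$n_asserted_found, g$n_asserted_not_found,
              g$n_equivalence_classes))

  outdir <- config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir) || file.access(outdir, 2) != 0) {
    rlang::abort(paste0("cannot write to output directory: ", outdir),
                 class = "ontodiff_output_error")
  }
  write_reports(report, outdir)

  out_bin <- function(path, text) {
    con <- file(path, open = "wb")
    writeLines(text, con, sep = "", useBytes = TRUE)
    close(con)
  }
  out_bin(file.path(outdir, "composite.obo"),
          write_obo(composite$graph, defs))

  reasoned_terms <- sort(unique(c(inferred$classes$id,
                                  inferred$direct_edges$child,
                                  inferred$direct_edges$parent)),
                         method = "radix")
  lab <- report$labels
  reasoned <- ontology_graph(
    terms = tibble::tibble(
      id = reasoned_terms,
      label = unname(ifelse(reasoned_terms %in% names(lab),
                            lab[reasoned_terms], reasoned_terms)),
      obsolete = FALSE),
    isa = inferred$direct_edges)
  out_bin(file.path(outdir, "reasoned.obo"), write_obo(reasoned))

  summary_lines <- c(
    paste0("n_defined_terms\t", length(defined)),
    paste0(names(g), "\t", unlist(g[1, ]))
  )
  if (!config$full_import) {
    summary_lines <- c(summary_lines, sprintf(
      "subset_size\t%s\t%d\t%d", basename(sizes$ontology),
      sizes$n_subset, sizes$n_terms))
  }
  con <- file(file.path(outdir, "summary.tsv"), open = "wb")
  writeLines(summary_lines, con, sep = "\n", useBytes = TRUE)
  close(con)

  invisible(report)
}
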