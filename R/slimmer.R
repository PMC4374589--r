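# The slimming procedure: compute the keep set from the instructions,
# strip everything else, rewire orphaned subclass links to the nearest
# kept ancestor, assert instruction-specified parents, and stamp
# provenance on the result.
#
# By default every class in the source ontology is excluded; only classes
# covered by a keep directive (optionally closed downward over all
# descendants or upward along every superclass path) survive. Remove
# directives prune a whole branch out of a kept set and are applied after
# all keeps, so instruction files are order-independent.

#' Compute the keep set for a set of instructions
#'
#' Keeps are the union over keep-mode instructions of the target plus its
#' closure (`KEEP`: the class alone; `KEEP_WITH_DESCENDANTS`: all
#' transitive subclasses; `KEEP_WITH_ANCESTORS`: every class on every
#' superclass path to the roots), minus the union over `EXCLUDE`
#' instructions of the target plus its descendants.
#'
#' @param ont an [ontology()] — typically the merged import closure.
#' @param instructions tibble from [parse_instructions()].
#' @return object of class `keep_set`: list with `kept` (character),
#'   `excluded` (character), `reparent_map` (named character:
#'   target IRI -> asserted new parent IRI).
#' @export
compute_keep_set <- function(ont, instructions) {
  unknown <- setdiff(instructions$target, ont$classes)
  if (length(unknown) > 0) {
    lineno <- which(instructions$target %in% unknown)[[1]]
    stop(sprintf("instruction %d targets unknown class IRI %s",
                 lineno, instructions$target[[lineno]]), call. = FALSE)
  }
  keeps <- character()
  for (i in seq_len(nrow(instructions))) {
    mode <- instructions$mode[[i]]
    target <- instructions$target[[i]]
    if (mode == "EXCLUDE") next
    closure <- switch(mode,
      KEEP = character(),
      KEEP_WITH_DESCENDANTS = class_neighborhood(ont, target, "descendants"),
      KEEP_WITH_ANCESTORS = class_neighborhood(ont, target, "ancestors")
    )
    keeps <- union(keeps, c(target, closure))
  }
  excluded <- character()
  for (target in instructions$target[instructions$mode == "EXCLUDE"]) {
    excluded <- union(excluded, c(target, class_neighborhood(ont, target, "descendants")))
  }
  if (length(intersect(excluded, keeps)) == 0 && length(excluded) > 0) {
    warning("remove instruction(s) matched no kept class; no-op", call. = FALSE)
  }
  kept <- sort(setdiff(keeps, excluded))
  rp <- instructions[!is.na(instructions$new_parent) & instructions$mode != "EXCLUDE", ,
                     drop = FALSE]
  rp <- rp[rp$target %in% kept, , drop = FALSE]
  reparent_map <- stats::setNames(rp$new_parent, rp$target)
  structure(list(kept = kept, excluded = sort(excluded), reparent_map = reparent_map),
            class = "keep_set")
}

#' Nearest kept ancestors of a class
#'
#' For each upward superclass path leaving `iri`, the first class
#' encountered that belongs to `kept`. Used to rewire the children of
#' removed classes so that reachability among kept classes is preserved
#' exactly.
#'
#' @param ont an [ontology()].
#' @param kept character vector of kept class IRIs.
#' @param iri class IRI (itself kept).
#' @return character vector of kept ancestor IRIs (possibly empty).
#' @export
nearest_kept_ancestors <- function(ont, kept, iri) {
  pm <- parent_map(ont)
  found <- character()
  visited <- character()
  frontier <- setdiff(unique(unlist(pm[iri], use.names = FALSE)), iri)
  while (length(frontier) > 0) {
    hits <- intersect(frontier, kept)
    found <- union(found, hits)
    expand <- setdiff(frontier, c(kept, visited))
    visited <- c(visited, frontier)
    frontier <- setdiff(unique(unlist(pm[expand], use.names = FALSE)), c(visited, iri))
  }
  sort(found)
}

#' Apply a slim to a merged ontology
#'
#' Removes all classes outside the keep set while preserving the original
#' IRIs of everything retained. Subclass links whose parent was removed
#' are rewired to each nearest kept ancestor along every superclass path;
#' instruction-specified new parents are asserted as additional subclass
#' edges (they need not be declared in the processed ontology — such
#' dangling parents are recorded, to be resolved at assembly). Entity
#' annotations survive for kept entities only, subject to the
#' configuration's annotation property include/exclude filter; opaque
#' axioms survive iff every entity they reference is kept. The output
#' receives the configured slim ontology IRI, retains the source's
#' ontology-level annotations and is stamped with provenance.
#'
#' @param ont merged [ontology()] (see [merge_ontologies()]).
#' @param instructions tibble from [parse_instructions()].
#' @param config a [slim_config()].
#' @param timestamp ISO-8601 instant recorded as `dcterms:created`;
#'   injected rather than read from the wall clock so builds reproduce.
#' @param publisher recorded as `dcterms:publisher`.
#' @return object of class `slim_result`: list with `ontology` (the slim),
#'   `keep_set`, `dropped_axioms` (count), `rewired_edges` (tibble
#'   `child`/`parent`), `dangling_parents` (character).
#' @export
apply_slim <- function(ont, instructions, config,
                       timestamp = "1970-01-01T00:00:00Z",
                       publisher = "eNanoMapper") {
  stopifnot(is_ontology(ont), inherits(config, "slim_config"))
  ks <- compute_keep_set(ont, instructions)
  kept <- ks$kept

  # original edges among kept classes, plus rewiring through removed ones
  keep_edges <- ont$edges[ont$edges$child %in% kept & ont$edges$parent %in% kept, ,
                          drop = FALSE]
  rewired <- list()
  for (cls in kept) {
    parents <- ont$edges$parent[ont$edges$child == cls]
    lost <- setdiff(parents, kept)
    if (length(lost) == 0) next
    nka <- nearest_kept_ancestors(ont, kept, cls)
    nka <- setdiff(nka, keep_edges$parent[keep_edges$child == cls])
    if (length(nka) > 0) {
      rewired[[length(rewired) + 1]] <- tibble::tibble(child = cls, parent = nka)
    }
  }
  rewired <- if (length(rewired) > 0) dplyr::distinct(dplyr::bind_rows(rewired)) else empty_edges()

  reparent_edges <- if (length(ks$reparent_map) > 0) {
    tibble::tibble(child = names(ks$reparent_map), parent = unname(ks$reparent_map))
  } else empty_edges()
  dangling <- sort(setdiff(unique(reparent_edges$parent), kept))

  # annotations: kept entities only, filtered by property
  ann <- ont$annotations[ont$annotations$subject %in% kept, , drop = FALSE]
  ann <- filter_annotation_properties(ann, config$annotation_include, config$annotation_exclude)

  # opaque axioms: all referenced entities must be kept
  ax <- ont$opaque_axioms
  ax_keep <- vapply(ax$entities, function(e) all(e %in% kept), logical(1))
  dropped_axioms <- sum(!ax_keep)

  # properties survive iff still referenced by retained content
  used <- unique(c(ann$property, unlist(ax$entities[ax_keep], use.names = FALSE)))
  out <- ontology(
    ontology_iri = config$output_ontology_iri,
    classes = kept,
    edges = dplyr::bind_rows(keep_edges, rewired, reparent_edges),
    annotations = ann,
    ontology_annotations = ont$ontology_annotations,
    annotation_properties = intersect(ont$annotation_properties, used),
    object_properties = intersect(ont$object_properties, used),
    opaque_axioms = ax[ax_keep, , drop = FALSE]
  )
  src <- source_iri_of(ont, config)
  if (identical(ont$ontology_iri, config$output_ontology_iri)) {
    # re-slimming an existing slim: keep pointing at the original source
    prev <- ont$ontology_annotations$value[ont$ontology_annotations$property == IRI_SOURCE]
    if (length(prev) > 0) src <- prev[[1]]
  }
  out <- add_provenance(out, publisher = publisher, timestamp = timestamp,
                        tool = ontoslim_tool_string(), source_iri = src)
  structure(list(ontology = out, keep_set = ks, dropped_axioms = dropped_axioms,
                 rewired_edges = rewired, dangling_parents = dangling),
            class = "slim_result")
}

filter_annotation_properties <- function(ann, include, exclude) {
  if (length(include) > 0) {
    ann[ann$property %in% normalize_xref_property(include), , drop = FALSE]
  } else if (length(exclude) > 0) {
    ann[!ann$property %in% normalize_xref_property(exclude), , drop = FALSE]
  } else {
    ann
  }
}

ontoslim_tool_string <- function() {
  paste0("ontoslim ", as.character(utils::packageVersion("ontoslim")))
}

source_iri_of <- function(ont, config) {
  if (!is.null(ont$ontology_iri)) return(ont$ontology_iri)
  if (is_valid_iri(config$input_location)) return(config$input_location)
  paste0("file://", config$input_location)
}

#' Stamp provenance annotations on an ontology
#'
#' Adds ontology-level annotations identifying the publisher of the slim
#' (`dcterms:publisher`), when it was made (`dcterms:created`, ISO-8601),
#' the source ontology (`dcterms:source`) and the tool used
#' (`rdfs:comment`). Existing ontology annotations are untouched; set
#' semantics make repeated stamping with identical arguments a no-op.
#'
#' @param ont an [ontology()].
#' @param publisher publisher text.
#' @param timestamp ISO-8601 instant (injected, never the wall clock).
#' @param tool tool name and version text.
#' @param source_iri IRI of the source ontology.
#' @return the annotated [ontology()].
#' @export
add_provenance <- function(ont, publisher, timestamp, tool, source_iri) {
  extra <- tibble::tibble(
    property = c(IRI_PUBLISHER, IRI_CREATED, IRI_SOURCE, IRI_COMMENT),
    value = c(publisher, as.character(timestamp), source_iri,
              paste0("Slimmed with ", tool)),
    lang = NA_character_
  )
  ontology(
    ontology_iri = ont$ontology_iri, version_iri = ont$version_iri,
    imports = ont$imports, classes = ont$classes, edges = ont$edges,
    annotations = ont$annotations,
    ontology_annotations = dplyr::bind_rows(ont$ontology_annotations, extra),
    annotation_properties = ont$annotation_properties,
    object_properties = ont$object_properties,
    opaque_axioms = ont$opaque_axioms
  )
}

#' Run the whole slim step from a configuration
#'
#' Reads the input ontology, resolves and merges its import closure,
#' parses the instruction file, applies the slim and writes the output to
#' the configured path.
#'
#' @param config a [slim_config()] (or path to a properties file).
#' @param resolver import resolver mapping (see [resolve_imports()]);
#'   defaults to empty.
#' @param format serialization format for input and output.
#' @param timestamp,publisher passed to [apply_slim()].
#' @param write whether to write the result to `config$output_path`.
#' @return the `slim_result`, invisibly when `write = TRUE`.
#' @export
run_slim <- function(config, resolver = list(), format = c("rdfxml", "turtle"),
                     timestamp = "1970-01-01T00:00:00Z",
                     publisher = "eNanoMapper", write = TRUE) {
  format <- match.arg(format)
  if (is.character(config)) config <- parse_properties(config)
  ont <- read_ontology(config$input_location, format = format)
  closure <- resolve_imports(ont, resolver, format = format)
  merged <- merge_ontologies(ont, closure)
  instructions <- parse_instructions(config$instructions_location)
  res <- apply_slim(merged, instructions, config, timestamp = timestamp,
                    publisher = publisher)
  if (write) {
    write_ontology(res$ontology, format = format, path = config$output_path)
    return(invisible(res))
  }
  res
}

#' @export
print.slim_result <- function(x, ...) {
  cat("<slim_result> ", x$ontology$ontology_iri %||% "(anonymous)", "\n", sep = "")
  cat("  kept classes: ", length(x$keep_set$kept),
      "  rewired edges: ", nrow(x$rewired_edges),
      "  dropped axioms: ", x$dropped_axioms, "\n", sep = "")
  if (length(x$dangling_parents) > 0) {
    cat("  dangling parents: ", paste(x$dangling_parents, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
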