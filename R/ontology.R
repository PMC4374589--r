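# In-memory model of the OWL subset the slimming pipeline manipulates:
# named classes, asserted subclass edges, annotation assertions, imports,
# and an opaque store for any axiom outside that subset.


#' Validate an absolute IRI
#'
#' An IRI is accepted when it is a non-empty string containing a
#' `scheme://` separator and no surrounding whitespace.
#'
#' @param x character vector of candidate IRIs.
#' @return logical vector, one element per input.
#' @export
is_valid_iri <- function(x) {
  !is.na(x) & nzchar(x) & grepl("://", x, fixed = TRUE) & x == trimws(x)
}

assert_iri <- function(x, what = "IRI") {
  bad <- x[!is_valid_iri(x)]
  if (length(bad) > 0) {
    stop(sprintf("invalid %s: %s (must be absolute, contain '://', no surrounding whitespace)",
                 what, paste(utils::head(bad, 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

empty_annotations <- function() {
  tibble::tibble(subject = character(), property = character(),
                 value = character(), lang = character())
}

empty_edges <- function() {
  tibble::tibble(child = character(), parent = character())
}

empty_axioms <- function() {
  tibble::tibble(payload = character(), entities = list())
}

#' Construct an ontology object
#'
#' The container holds the structural OWL subset the pipeline operates on.
#' All components use set semantics: duplicate edges, annotation
#' assertions and opaque axioms are collapsed on construction.
#'
#' @param ontology_iri optional ontology IRI.
#' @param version_iri optional version IRI.
#' @param imports character vector of imported ontology IRIs.
#' @param classes character vector of class IRIs.
#' @param edges tibble with columns `child`, `parent` (IRIs); asserted
#'   `rdfs:subClassOf` between named classes. Parents may be undeclared
#'   ("dangling"); QA reports them.
#' @param annotations tibble with columns `subject`, `property`, `value`,
#'   `lang` (`NA` when untagged).
#' @param ontology_annotations tibble with columns `property`, `value`,
#'   `lang`; annotations on the ontology header itself.
#' @param annotation_properties,object_properties character vectors of
#'   declared property IRIs.
#' @param opaque_axioms tibble with columns `payload` (canonical serialized
#'   axiom text) and `entities` (list column of referenced IRIs).
#' @return an object of class `ontology`.
#' @export
ontology <- function(ontology_iri = NULL, version_iri = NULL,
                     imports = character(), classes = character(),
                     edges = empty_edges(),
                     annotations = empty_annotations(),
                     ontology_annotations = NULL,
                     annotation_properties = character(),
                     object_properties = character(),
                     opaque_axioms = empty_axioms()) {
  if (!is.null(ontology_iri)) assert_iri(ontology_iri, "ontology IRI")
  classes <- sort(unique(as.character(classes)))
  assert_iri(classes, "class IRI")
  edges <- dplyr::distinct(tibble::as_tibble(edges)[, c("child", "parent")])
  annotations <- normalize_annotations(annotations)
  if (is.null(ontology_annotations)) {
    ontology_annotations <- tibble::tibble(property = character(),
                                           value = character(), lang = character())
  }
  ontology_annotations <- tibble::as_tibble(ontology_annotations)
  if (!"lang" %in% names(ontology_annotations)) ontology_annotations$lang <- NA_character_
  ontology_annotations <- dplyr::distinct(ontology_annotations[, c("property", "value", "lang")])
  opaque_axioms <- tibble::as_tibble(opaque_axioms)
  if (nrow(opaque_axioms) > 0) {
    keep <- !duplicated(opaque_axioms$payload)
    opaque_axioms <- opaque_axioms[keep, , drop = FALSE]
  }
  structure(list(
    ontology_iri = ontology_iri,
    version_iri = version_iri,
    imports = sort(unique(imports)),
    classes = classes,
    edges = dplyr::arrange(edges, .data$child, .data$parent),
    annotations = annotations,
    ontology_annotations = dplyr::arrange(ontology_annotations, .data$property, .data$value),
    annotation_properties = sort(unique(annotation_properties)),
    object_properties = sort(unique(object_properties)),
    opaque_axioms = opaque_axioms[order(opaque_axioms$payload), , drop = FALSE]
  ), class = "ontology")
}

# Canonical form for annotation tables: required columns, NA lang for
# untagged literals, bare "dbXref" dialect folded into oboInOwl:hasDbXref,
# duplicates collapsed, stable sort.
normalize_annotations <- function(ann) {
  ann <- tibble::as_tibble(ann)
  if (nrow(ann) == 0 && ncol(ann) == 0) return(empty_annotations())
  if (!"lang" %in% names(ann)) ann$lang <- NA_character_
  ann <- ann[, c("subject", "property", "value", "lang")]
  ann$property <- normalize_xref_property(ann$property)
  ann <- dplyr::distinct(ann)
  dplyr::arrange(ann, .data$subject, .data$property, .data$value)
}

# NPO and some legacy ontologies use a bare "dbXref" annotation property;
# both dialects are read, the oboInOwl IRI is used internally and written.
normalize_xref_property <- function(p) {
  bare <- grepl("[#/]dbXref$", p) & p != IRI_DBXREF
  p[bare] <- IRI_DBXREF
  p
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology> ", if (is.null(x$ontology_iri)) "(anonymous)" else x$ontology_iri, "\n", sep = "")
  cat("  classes: ", length(x$classes),
      "  subclass edges: ", nrow(x$edges),
      "  annotations: ", nrow(x$annotations), "\n", sep = "")
  cat("  imports: ", length(x$imports),
      "  opaque axioms: ", nrow(x$opaque_axioms), "\n", sep = "")
  invisible(x)
}

is_ontology <- function(x) inherits(x, "ontology")

# Adjacency maps (child -> parents, parent -> children) as named lists.
parent_map <- function(ont) {
  split(ont$edges$parent, ont$edges$child)
}

child_map <- function(ont) {
  split(ont$edges$child, ont$edges$parent)
}

#' Transitive subclass neighborhood of a class
#'
#' Walks asserted subclass edges from `iri`, downward to collect all
#' descendants or upward along every superclass path to collect all
#' ancestors. The class itself is excluded. A visited-set guard makes the
#' traversal terminate on cyclic hierarchies.
#'
#' @param ont an [ontology()].
#' @param iri class IRI; must be declared in `ont`.
#' @param direction `"descendants"` or `"ancestors"`.
#' @return character vector of class IRIs (sorted).
#' @export
class_neighborhood <- function(ont, iri, direction = c("descendants", "ancestors")) {
  direction <- match.arg(direction)
  if (!iri %in% ont$classes) {
    stop(sprintf("unknown class IRI: %s", iri), call. = FALSE)
  }
  adj <- if (direction == "descendants") child_map(ont) else parent_map(ont)
  reachable_from(iri, adj, restrict = ont$classes)
}

# BFS over an adjacency list with a visited-set guard; the start node is
# always excluded from the result (even on cyclic graphs).
reachable_from <- function(start, adj, restrict = NULL) {
  visited <- character()
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(visited, start))
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  if (!is.null(restrict)) visited <- intersect(visited, restrict)
  sort(visited)
}

#' Collected annotations of one entity
#'
#' Gathers the entity's `rdfs:label` values, its first definition
#' (IAO_0000115), synonyms (oboInOwl exact/related) and cross-references
#' (oboInOwl `hasDbXref`; the bare `dbXref` dialect is folded in at load
#' time). Unknown entities yield all-empty collections.
#'
#' @param ont an [ontology()].
#' @param iri entity IRI.
#' @return list with elements `labels`, `definition` (single string or
#'   `NA`), `synonyms`, `xrefs`.
#' @export
entity_annotations <- function(ont, iri) {
  ann <- ont$annotations[ont$annotations$subject == iri, , drop = FALSE]
  defs <- ann$value[ann$property == IRI_DEFINITION]
  list(
    labels = ann$value[ann$property == IRI_LABEL],
    definition = if (length(defs) > 0) defs[[1]] else NA_character_,
    synonyms = ann$value[ann$property %in% SYNONYM_PROPERTIES],
    xrefs = ann$value[ann$property == IRI_DBXREF]
  )
}

#' Merge ontologies with strict deduplication
#'
#' Takes the set union of classes, subclass edges, annotation assertions,
#' property declarations and opaque axioms across the primary ontology and
#' any number of others. An assertion present in several inputs appears
#' exactly once in the result — merging an import closure never multiplies
#' annotations or axioms. The primary's ontology IRI, version IRI, imports
#' list and ontology-level annotations are retained.
#'
#' @param primary an [ontology()]; identity of the result.
#' @param others list of further [ontology()] objects.
#' @return merged [ontology()].
#' @export
merge_ontologies <- function(primary, others = list()) {
  stopifnot(is_ontology(primary))
  if (is_ontology(others)) others <- list(others)
  all_onts <- c(list(primary), others)
  ontology(
    ontology_iri = primary$ontology_iri,
    version_iri = primary$version_iri,
    imports = primary$imports,
    classes = unique(unlist(lapply(all_onts, `[[`, "classes"))),
    edges = dplyr::bind_rows(lapply(all_onts, `[[`, "edges")),
    annotations = dplyr::bind_rows(lapply(all_onts, `[[`, "annotations")),
    ontology_annotations = primary$ontology_annotations,
    annotation_properties = unlist(lapply(all_onts, `[[`, "annotation_properties")),
    object_properties = unlist(lapply(all_onts, `[[`, "object_properties")),
    opaque_axioms = dplyr::bind_rows(lapply(all_onts, `[[`, "opaque_axioms"))
  )
}

#' Resolve the import closure of an ontology
#'
#' Follows `owl:imports` transitively through an injected resolver (no
#' network access). The closure is returned breadth-first with IRIs sorted
#' within each level; every ontology is loaded exactly once even when it is
#' reachable through several import chains.
#'
#' @param ont an [ontology()].
#' @param resolver named list or character vector mapping import IRIs to a
#'   file path, to serialized ontology text, or to an [ontology()] object.
#'   See [read_catalog()] for the file format.
#' @param format serialization format assumed for paths/text.
#' @return list of [ontology()] objects (the closure, excluding `ont`).
#' @export
resolve_imports <- function(ont, resolver = list(), format = c("rdfxml", "turtle")) {
  format <- match.arg(format)
  resolver <- as.list(resolver)
  loaded <- list()
  seen <- character()
  frontier <- sort(ont$imports)
  chain <- character()
  while (length(frontier) > 0) {
    level_new <- list()
    for (iri in frontier) {
      if (iri %in% seen) next
      src <- resolver[[iri]]
      if (is.null(src)) {
        stop(sprintf("unresolvable import IRI: %s (chain: %s)", iri,
                     paste(c(chain, iri), collapse = " -> ")), call. = FALSE)
      }
      o <- if (is_ontology(src)) src else read_ontology(src, format = format)
      seen <- c(seen, iri)
      loaded[[iri]] <- o
      level_new[[iri]] <- o
    }
    chain <- c(chain, frontier)
    frontier <- sort(setdiff(unique(unlist(lapply(level_new, `[[`, "imports"))), seen))
  }
  unname(loaded)
}

#' Detect subclass cycles
#'
#' Enumerates every elementary cycle in the subclass graph (Johnson-style
#' search restricted to non-trivial strongly connected components). A
#' well-formed hierarchy returns an empty list.
#'
#' @param ont an [ontology()].
#' @return list of cycles, each a character vector of class IRIs in path
#'   order, canonically rotated to start at the lexicographically smallest
#'   member.
#' @export
detect_cycles <- function(ont) {
  edges <- ont$edges
  if (nrow(edges) == 0) return(list())
  nodes <- sort(unique(c(edges$child, edges$parent)))
  adj <- split(edges$parent, edges$child)
  sccs <- strong_components(nodes, adj)
  cycles <- list()
  for (comp in sccs) {
    if (length(comp) < 2) {
      # self-loop check
      if (comp %in% names(adj) && comp %in% adj[[comp]]) {
        cycles[[length(cycles) + 1]] <- comp
      }
      next
    }
    sub_adj <- lapply(adj[intersect(names(adj), comp)], intersect, comp)
    cycles <- c(cycles, elementary_cycles(sort(comp), sub_adj))
  }
  cycles[order(vapply(cycles, function(cy) paste(cy, collapse = "|"), character(1)))]
}

# Tarjan strongly connected components over an adjacency list.
strong_components <- function(nodes, adj) {
  index <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  low <- index
  onstack <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  stack <- character()
  counter <- 0L
  comps <- list()
  # iterative Tarjan to avoid deep recursion
  for (root in nodes) {
    if (!is.na(index[[root]])) next
    work <- list(list(node = root, succ = adj[[root]] %||% character(), i = 1L))
    repeat {
      if (length(work) == 0) break
      frame <- work[[length(work)]]
      v <- frame$node
      if (frame$i == 1L && is.na(index[[v]])) {
        counter <- counter + 1L
        index[[v]] <- counter
        low[[v]] <- counter
        stack <- c(stack, v)
        onstack[[v]] <- TRUE
      }
      advanced <- FALSE
      while (frame$i <= length(frame$succ)) {
        w <- frame$succ[[frame$i]]
        frame$i <- frame$i + 1L
        if (is.na(index[[w]])) {
          work[[length(work)]] <- frame
          work[[length(work) + 1]] <- list(node = w, succ = adj[[w]] %||% character(), i = 1L)
          advanced <- TRUE
          break
        } else if (onstack[[w]]) {
          low[[v]] <- min(low[[v]], index[[w]])
        }
      }
      if (advanced) next
      work[[length(work)]] <- NULL
      if (low[[v]] == index[[v]]) {
        comp <- character()
        repeat {
          w <- stack[[length(stack)]]
          stack <- stack[-length(stack)]
          onstack[[w]] <- FALSE
          comp <- c(comp, w)
          if (w == v) break
        }
        comps[[length(comps) + 1]] <- comp
      }
      if (length(work) > 0) {
        parent <- work[[length(work)]]
        low[[parent$node]] <- min(low[[parent$node]], low[[v]])
        work[[length(work)]] <- parent
      }
    }
  }
  comps
}

# Enumerate elementary cycles within one SCC by DFS from each node,
# only visiting nodes >= the start node (canonical start), which yields
# each cycle exactly once.
elementary_cycles <- function(nodes, adj) {
  out <- list()
  for (start in nodes) {
    path <- start
    blocked <- character()
    dfs <- function(v) {
      for (w in sort(adj[[v]] %||% character())) {
        if (w == start) {
          out[[length(out) + 1]] <<- path
        } else if (w > start && !w %in% path) {
          path <<- c(path, w)
          dfs(w)
          path <<- path[-length(path)]
        }
      }
    }
    dfs(start)
  }
  out
}

# Canonical comparable representation, used by isomorphism checks.
canonical_form <- function(ont) {
  list(
    ontology_iri = ont$ontology_iri %||% NA_character_,
    imports = sort(ont$imports),
    classes = sort(ont$classes),
    edges = dplyr::arrange(ont$edges, .data$child, .data$parent),
    annotations = dplyr::arrange(ont$annotations, .data$subject, .data$property,
                                 .data$value, .data$lang),
    ontology_annotations = dplyr::arrange(ont$ontology_annotations,
                                          .data$property, .data$value),
    annotation_properties = sort(ont$annotation_properties),
    object_properties = sort(ont$object_properties),
    axiom_payloads = sort(ont$opaque_axioms$payload)
  )
}

#' Test two ontologies for structural identity
#'
#' Compares canonical forms: same classes, edges, annotations, imports,
#' property declarations and opaque axiom payloads, ignoring order.
#'
#' @param a,b [ontology()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
ontology_isomorphic <- function(a, b) {
  isTRUE(all.equal(canonical_form(a), canonical_form(b), check.attributes = FALSE))
}
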