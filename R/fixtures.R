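# Seeded synthetic ontology generation. Emulates OBO-style inputs — DAG
# subclass hierarchies over numeric-ID PURLs with labels, textual
# definitions, synonyms and dbXrefs — so every pipeline stage can be
# exercised without downloading a real ontology. Generation is a pure
# function of its parameters: the RNG state is scoped locally and restored.

# Word pool for multi-token labels; composed phrases make composite term
# matching exercisable.
FIXTURE_WORDS <- c(
  "gold", "silver", "silica", "carbon", "titanium", "zinc", "iron", "copper",
  "nanoparticle", "nanotube", "nanorod", "nanowire", "quantum", "dot",
  "coating", "surface", "charge", "diameter", "hydrodynamic", "average",
  "zeta", "potential", "assay", "endpoint", "toxicity", "viability",
  "cellular", "uptake", "aggregation", "dispersion", "solvent", "buffer",
  "oxide", "sulfide", "polymer", "dendrimer", "liposome", "micelle",
  "crystalline", "amorphous", "spherical", "cubic", "porous", "hollow",
  "functionalized", "pegylated", "labeled", "fluorescent", "magnetic",
  "radius", "area", "volume", "density", "mobility", "index", "unit",
  "concentration", "dose", "exposure", "medium", "matrix", "protein",
  "corona", "membrane", "receptor", "pathway", "response", "stress"
)

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

obo_iri <- function(prefix, ids) sprintf("%s%07d", prefix, ids)

random_labels <- function(n, min_words = 1, max_words = 3) {
  out <- character(0)
  while (length(out) < n) {
    k <- sample(min_words:max_words, n, replace = TRUE)
    cand <- vapply(k, function(kk) {
      paste(sample(FIXTURE_WORDS, kk), collapse = " ")
    }, character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Generate a seeded synthetic taxonomy
#'
#' Builds a rooted subclass DAG over `n_classes` classes with OBO-style
#' numeric-ID IRIs, multi-token labels, textual definitions, synonyms and
#' optional planted defects. The ground-truth record states exactly which
#' defects were planted, so QA results can be verified against it.
#'
#' @param n_classes number of classes (>= 1).
#' @param seed RNG seed; identical arguments give identical output.
#' @param iri_prefix OBO-style PURL prefix; IRIs are
#'   `prefix` + zero-padded 7-digit ID.
#' @param max_parents maximum number of parents per non-root class.
#' @param missing_label_fraction,missing_definition_fraction proportions
#'   of classes generated without a label / definition.
#' @param planted_cycles number of back-edges planted to create exactly
#'   this many subclass cycles (node-disjoint).
#' @param n_dangling number of subclass edges pointing at undeclared
#'   parent IRIs.
#' @param synonym_rate proportion of classes given an exact synonym.
#' @param xref_rate proportion of classes given a dbXref.
#' @return list with `ontology` (an [ontology()]) and `truth`, a list
#'   recording `missing_labels`, `missing_definitions`, `cycle_edges`
#'   (tibble), `n_cycles`, `dangling_parents`.
#' @export
generate_taxonomy <- function(n_classes, seed = 1,
                              iri_prefix = "http://purl.example.org/obo/ENM_",
                              max_parents = 3,
                              missing_label_fraction = 0,
                              missing_definition_fraction = 0,
                              planted_cycles = 0, n_dangling = 0,
                              synonym_rate = 0.3, xref_rate = 0.2) {
  stopifnot(n_classes >= 1, max_parents >= 1,
            missing_label_fraction >= 0, missing_label_fraction <= 1,
            missing_definition_fraction >= 0, missing_definition_fraction <= 1)
  if (planted_cycles > floor((n_classes - 1) / 2)) {
    stop("planted_cycles too large for this taxonomy size", call. = FALSE)
  }
  with_local_seed(seed, {
    iris <- obo_iri(iri_prefix, seq_len(n_classes))
    # DAG: node 1 is the root; node i > 1 links to 1..max_parents earlier nodes
    edges <- list()
    for (i in seq_len(n_classes)[-1]) {
      k <- sample(seq_len(min(max_parents, i - 1)), 1)
      parents <- sample(seq_len(i - 1), k)
      edges[[length(edges) + 1]] <- tibble::tibble(child = iris[[i]],
                                                   parent = iris[parents])
    }
    edges <- if (length(edges) > 0) dplyr::bind_rows(edges) else empty_edges()

    labels <- random_labels(n_classes)
    no_label <- sort(sample(n_classes, round(missing_label_fraction * n_classes)))
    no_def <- sort(sample(n_classes, round(missing_definition_fraction * n_classes)))

    ann <- list()
    for (i in seq_len(n_classes)) {
      if (!i %in% no_label) {
        ann[[length(ann) + 1]] <- tibble::tibble(
          subject = iris[[i]], property = IRI_LABEL, value = labels[[i]],
          lang = NA_character_)
      }
      if (!i %in% no_def) {
        ann[[length(ann) + 1]] <- tibble::tibble(
          subject = iris[[i]], property = IRI_DEFINITION,
          value = sprintf("A %s in the synthetic nanosafety taxonomy.", labels[[i]]),
          lang = NA_character_)
      }
      if (stats::runif(1) < synonym_rate && !i %in% no_label) {
        ann[[length(ann) + 1]] <- tibble::tibble(
          subject = iris[[i]], property = IRI_EXACT_SYN,
          value = paste(labels[[i]], "synonym"), lang = NA_character_)
      }
      if (stats::runif(1) < xref_rate) {
        ann[[length(ann) + 1]] <- tibble::tibble(
          subject = iris[[i]], property = IRI_DBXREF,
          value = sprintf("XREF:%07d", sample(9999999, 1)), lang = NA_character_)
      }
    }
    ann <- if (length(ann) > 0) dplyr::bind_rows(ann) else empty_annotations()

    # planted cycles: reverse edges that are the *only* upward path
    # between their endpoints, on node-disjoint pairs, so each back-edge
    # yields exactly one elementary 2-cycle
    cycle_edges <- empty_edges()
    if (planted_cycles > 0) {
      used <- character()
      planted <- 0L
      for (ei in sample(nrow(edges))) {
        if (planted == planted_cycles) break
        ch <- edges$child[[ei]]; pa <- edges$parent[[ei]]
        if (ch %in% used || pa %in% used) next
        rest <- dplyr::bind_rows(edges[-ei, , drop = FALSE], cycle_edges)
        still_anc <- pa %in% reachable_from(ch, split(rest$parent, rest$child))
        if (still_anc) next
        cycle_edges <- dplyr::bind_rows(cycle_edges,
                                        tibble::tibble(child = pa, parent = ch))
        used <- c(used, ch, pa)
        planted <- planted + 1L
      }
      if (planted < planted_cycles) {
        stop("could not plant the requested number of disjoint cycles", call. = FALSE)
      }
      edges <- dplyr::bind_rows(edges, cycle_edges)
    }

    dangling_parents <- character()
    if (n_dangling > 0) {
      dangling_parents <- sprintf("%sX%06d", iri_prefix, seq_len(n_dangling))
      src <- sample(n_classes, n_dangling, replace = TRUE)
      edges <- dplyr::bind_rows(edges, tibble::tibble(child = iris[src],
                                                      parent = dangling_parents))
    }

    ont <- ontology(
      ontology_iri = paste0(iri_prefix, "fixture.owl"),
      classes = iris,
      edges = edges,
      annotations = ann,
      annotation_properties = c(IRI_DEFINITION, IRI_EXACT_SYN, IRI_DBXREF)
    )
    list(ontology = ont,
         truth = list(
           missing_labels = iris[no_label],
           missing_definitions = iris[no_def],
           cycle_edges = cycle_edges,
           n_cycles = planted_cycles,
           dangling_parents = sort(dangling_parents)
         ))
  })
}

#' Generate a pair of ontologies with controlled label overlap
#'
#' Emulates the situation where two source ontologies describe overlapping
#' content: exactly `n_shared_labels` labels occur on both sides, of which
#' `n_shared_iris` are MIREOT-style re-imports (identical IRI on both
#' sides) and the rest are genuine conflicts (same label, different IRIs).
#'
#' @param n_a,n_b class counts of the two sides.
#' @param n_shared_labels number of labels present on both sides
#'   (`<= min(n_a, n_b)`).
#' @param n_shared_iris of those, how many share the IRI too
#'   (`<= n_shared_labels`).
#' @param n_xref_links how many of the conflicting shared labels get a
#'   dbXref from the A-side class to the B-side class.
#' @param seed RNG seed.
#' @param prefix_a,prefix_b IRI prefixes of the two sides.
#' @return list with `a`, `b` (ontologies) and `truth` (shared labels,
#'   shared IRIs, conflicting label -> (iri_a, iri_b) table).
#' @export
generate_overlap_pair <- function(n_a, n_b, n_shared_labels, n_shared_iris = 0,
                                  n_xref_links = 0, seed = 1,
                                  prefix_a = "http://purl.example.org/obo/NPO_",
                                  prefix_b = "http://purl.example.org/obo/CHEBI_") {
  if (n_shared_labels > min(n_a, n_b)) {
    stop("n_shared_labels exceeds the size of a side", call. = FALSE)
  }
  if (n_shared_iris > n_shared_labels) {
    stop("n_shared_iris exceeds n_shared_labels", call. = FALSE)
  }
  if (n_xref_links > n_shared_labels - n_shared_iris) {
    stop("n_xref_links exceeds the number of conflicting shared labels", call. = FALSE)
  }
  with_local_seed(seed, {
    labels <- random_labels(n_a + n_b - n_shared_labels)
    lab_a <- labels[seq_len(n_a)]
    shared <- lab_a[seq_len(n_shared_labels)]
    lab_b <- c(shared, labels[n_a + seq_len(n_b - n_shared_labels)])

    iris_a <- obo_iri(prefix_a, seq_len(n_a))
    iris_b <- obo_iri(prefix_b, 1000 + seq_len(n_b))
    # MIREOT-style: the first n_shared_iris shared labels reuse the A IRI on B
    if (n_shared_iris > 0) iris_b[seq_len(n_shared_iris)] <- iris_a[seq_len(n_shared_iris)]

    conflict_idx <- if (n_shared_labels > n_shared_iris) {
      (n_shared_iris + 1):n_shared_labels
    } else integer()

    build_side <- function(iris, labels, ontology_iri, extra_ann = empty_annotations()) {
      n <- length(iris)
      edges <- if (n > 1) {
        tibble::tibble(child = iris[-1],
                       parent = iris[vapply(2:n, function(i) sample(i - 1, 1), integer(1))])
      } else empty_edges()
      ann <- dplyr::bind_rows(
        tibble::tibble(subject = iris, property = IRI_LABEL, value = labels,
                       lang = NA_character_),
        tibble::tibble(subject = iris, property = IRI_DEFINITION,
                       value = sprintf("A %s.", labels), lang = NA_character_),
        extra_ann
      )
      ontology(ontology_iri = ontology_iri, classes = iris, edges = edges,
               annotations = ann,
               annotation_properties = c(IRI_DEFINITION, IRI_DBXREF))
    }

    xref_ann <- empty_annotations()
    if (n_xref_links > 0) {
      link_idx <- conflict_idx[seq_len(n_xref_links)]
      xref_ann <- tibble::tibble(subject = iris_a[link_idx], property = IRI_DBXREF,
                                 value = iri_to_curie(iris_b[link_idx]),
                                 lang = NA_character_)
    }

    a <- build_side(iris_a, lab_a, paste0(prefix_a, "fixture-a.owl"), xref_ann)
    b <- build_side(iris_b, lab_b, paste0(prefix_b, "fixture-b.owl"))
    list(a = a, b = b,
         truth = list(
           shared_labels = sort(shared),
           shared_iris = iris_a[seq_len(n_shared_iris)],
           conflicts = tibble::tibble(label = shared[conflict_idx],
                                      iri_a = iris_a[conflict_idx],
                                      iri_b = iris_b[conflict_idx]),
           n_xref_links = n_xref_links
         ))
  })
}
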