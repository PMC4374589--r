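# Shared fixture builders and independent brute-force oracles. The
# oracles never call the package's traversal code: reachability is
# computed by fixed-point set expansion over the raw edge table, upward
# paths by exhaustive enumeration.

iri_of <- function(x) paste0("http://example.org/onto/", x, recycle0 = TRUE)

# Small ontology from a compact edge spec: c("C>B", "B>A") means C sub B.
mini_ontology <- function(edge_spec, classes = NULL, labels = NULL, ...) {
  if (length(edge_spec) > 0) {
    parts <- strsplit(edge_spec, ">", fixed = TRUE)
    edges <- tibble::tibble(child = iri_of(vapply(parts, `[[`, "", 1)),
                            parent = iri_of(vapply(parts, `[[`, "", 2)))
  } else {
    edges <- tibble::tibble(child = character(), parent = character())
  }
  if (is.null(classes)) classes <- unique(c(edges$child, edges$parent))
  else classes <- iri_of(classes)
  ann <- if (!is.null(labels)) {
    tibble::tibble(subject = iri_of(names(labels)),
                   property = "http://www.w3.org/2000/01/rdf-schema#label",
                   value = unname(labels), lang = NA_character_)
  } else NULL
  args <- list(classes = classes, edges = edges, ...)
  if (!is.null(ann)) args$annotations <- ann
  do.call(ontology, args)
}

# Fixed-point transitive closure over an edge table; direction "down"
# follows parent -> child, "up" follows child -> parent. Excludes start.
oracle_reach <- function(edges, start, direction = c("down", "up")) {
  direction <- match.arg(direction)
  out <- character()
  repeat {
    from <- c(start, out)
    step <- if (direction == "down") {
      edges$child[edges$parent %in% from]
    } else {
      edges$parent[edges$child %in% from]
    }
    new <- setdiff(unique(step), c(out, start))
    if (length(new) == 0) break
    out <- c(out, new)
  }
  sort(out)
}

# Direct application of the keep-set formula: union over keep directives
# of target + closure, minus union over removes of target + descendants.
oracle_keep_set <- function(ont, instructions) {
  keeps <- character()
  for (i in seq_len(nrow(instructions))) {
    t <- instructions$target[[i]]
    keeps <- switch(instructions$mode[[i]],
      KEEP = union(keeps, t),
      KEEP_WITH_DESCENDANTS = union(keeps, c(t, oracle_reach(ont$edges, t, "down"))),
      KEEP_WITH_ANCESTORS = union(keeps, c(t, oracle_reach(ont$edges, t, "up"))),
      keeps)
  }
  drops <- character()
  for (t in instructions$target[instructions$mode == "EXCLUDE"]) {
    drops <- union(drops, c(t, oracle_reach(ont$edges, t, "down")))
  }
  sort(intersect(setdiff(keeps, drops), ont$classes))
}

# Exhaustive upward path enumeration: the first kept node on each simple
# path from iri to any root.
oracle_nearest_kept <- function(ont, kept, iri) {
  found <- character()
  walk <- function(node, path) {
    parents <- ont$edges$parent[ont$edges$child == node]
    for (p in setdiff(parents, path)) {
      if (p %in% kept) {
        found <<- union(found, p)
      } else {
        walk(p, c(path, p))
      }
    }
  }
  walk(iri, iri)
  sort(found)
}

# Reachability relation among a set of classes, as a sorted key set.
reach_relation <- function(edges, classes) {
  pairs <- character()
  for (cls in classes) {
    anc <- intersect(oracle_reach(edges, cls, "up"), classes)
    if (length(anc) > 0) pairs <- c(pairs, paste(cls, anc, sep = " -> "))
  }
  sort(pairs)
}

# Random instruction set over a fixture's classes.
random_instructions <- function(ont, n, modes = c("KEEP", "KEEP_WITH_DESCENDANTS",
                                                  "KEEP_WITH_ANCESTORS", "EXCLUDE")) {
  tibble::tibble(
    mode = sample(modes, n, replace = TRUE),
    target = sample(ont$classes, n, replace = TRUE),
    new_parent = NA_character_,
    comment = NA_character_
  )
}

default_config <- function() {
  slim_config("in.owl", "in.iris", "http://purl.example.net/onto/external/test-slim.owl",
              output_path = "test-slim.owl")
}
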