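# Ontology model, RDF/XML and Turtle I/O, merging, traversal.

test_that("RDF/XML with a small labelled chain is transcribed structurally", {
  txt <- '<?xml version="1.0"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <owl:Ontology rdf:about="http://example.org/onto/chain.owl"/>
  <owl:Class rdf:about="http://example.org/onto/A"><rdfs:label>alpha</rdfs:label></owl:Class>
  <owl:Class rdf:about="http://example.org/onto/B">
    <rdfs:subClassOf rdf:resource="http://example.org/onto/A"/>
    <rdfs:label>beta</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/onto/C">
    <rdfs:subClassOf rdf:resource="http://example.org/onto/B"/>
    <rdfs:label>gamma</rdfs:label>
  </owl:Class>
</rdf:RDF>'
  o <- read_ontology(txt)
  expect_length(o$classes, 3)
  expect_equal(nrow(o$edges), 2)
  expect_equal(sort(o$annotations$value), c("alpha", "beta", "gamma"))
  expect_equal(o$ontology_iri, "http://example.org/onto/chain.owl")
})

test_that("parse failures and relative IRIs are rejected with informative errors", {
  expect_error(read_ontology("<rdf:RDF"), "parse failure")
  bad <- '<?xml version="1.0"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <owl:Class rdf:about="relative/iri"/>
</rdf:RDF>'
  expect_error(read_ontology(bad), "relative or malformed IRI")
})

test_that("restriction axioms are captured opaquely with an exact entity index", {
  txt <- '<?xml version="1.0"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <owl:Class rdf:about="http://example.org/onto/A">
    <rdfs:subClassOf>
      <owl:Restriction>
        <owl:onProperty rdf:resource="http://example.org/onto/hasPart"/>
        <owl:someValuesFrom rdf:resource="http://example.org/onto/B"/>
      </owl:Restriction>
    </rdfs:subClassOf>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/onto/B"/>
</rdf:RDF>'
  o <- read_ontology(txt)
  expect_equal(nrow(o$opaque_axioms), 1)
  # independent oracle: raw scan of the source text for entity IRIs
  scanned <- regmatches(txt, gregexpr('rdf:(about|resource)="([^"]+)"', txt))[[1]]
  scanned <- sort(unique(sub('.*"([^"]+)"$', "\\1", scanned)))
  expect_equal(o$opaque_axioms$entities[[1]], scanned)
  # structural subclass table is untouched by the opaque capture
  expect_equal(nrow(o$edges), 0)
})

test_that("serialization is deterministic and read-write is the identity up to isomorphism", {
  for (seed in 1:5) {
    fx <- generate_taxonomy(50, seed = seed, missing_label_fraction = 0.1,
                            synonym_rate = 0.4, xref_rate = 0.3)
    txt1 <- write_ontology(fx$ontology)
    txt2 <- write_ontology(fx$ontology)
    expect_identical(txt1, txt2)
    expect_true(ontology_isomorphic(fx$ontology, read_ontology(txt1)))
    ttl <- write_ontology(fx$ontology, format = "turtle")
    expect_true(ontology_isomorphic(fx$ontology, read_ontology(ttl, format = "turtle")))
  }
})

test_that("an empty ontology serializes to a bare header and reads back", {
  o <- ontology(ontology_iri = iri_of("empty.owl"))
  txt <- write_ontology(o)
  expect_match(txt, "owl:Ontology")
  o2 <- read_ontology(txt)
  expect_length(o2$classes, 0)
  expect_true(ontology_isomorphic(o, o2))
})

test_that("written RDF/XML agrees with an independent triple-level parser", {
  fx <- generate_taxonomy(20, seed = 11, synonym_rate = 0.5, xref_rate = 0.5)
  path <- withr::local_tempfile(fileext = ".owl")
  write_ontology(fx$ontology, path = path)
  script <- paste(
    "import sys, rdflib",
    "g = rdflib.Graph(); g.parse(sys.argv[1], format='xml')",
    "OWL = rdflib.OWL; RDF = rdflib.RDF; RDFS = rdflib.RDFS",
    "print(len(list(g.subjects(RDF.type, OWL.Class))))",
    "print(len(list(g.triples((None, RDFS.subClassOf, None)))))",
    "print(len(list(g.triples((None, RDFS.label, None)))))",
    sep = "\n")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script), shQuote(path)),
                                  stdout = TRUE, stderr = FALSE))
  if (is.null(attr(out, "status"))) {
    counts <- as.integer(out)
    expect_equal(counts[[1]], length(fx$ontology$classes))
    expect_equal(counts[[2]], nrow(fx$ontology$edges))
    expect_equal(counts[[3]],
                 sum(fx$ontology$annotations$property ==
                       "http://www.w3.org/2000/01/rdf-schema#label"))
  } else {
    succeed("rdflib cross-check unavailable; covered by round-trip tests")
  }
})

test_that("merging is a set union: self-merge changes no counts", {
  for (seed in 1:5) {
    fx <- generate_taxonomy(30, seed = seed, synonym_rate = 0.5)
    o <- fx$ontology
    m <- merge_ontologies(o, list(o))
    expect_equal(nrow(m$annotations), nrow(o$annotations))
    expect_equal(nrow(m$edges), nrow(o$edges))
    expect_equal(nrow(m$opaque_axioms), nrow(o$opaque_axioms))
    expect_true(ontology_isomorphic(m, o))
  }
  # identity merge
  fx <- generate_taxonomy(15, seed = 99)
  expect_true(ontology_isomorphic(merge_ontologies(fx$ontology, list()), fx$ontology))
})

test_that("merging overlapping ontologies equals an independent canonical union", {
  shared <- mini_ontology(sprintf("S%d>S0", 1:10))
  extra_a <- mini_ontology(c("A1>S0", "A2>A1"))
  extra_b <- mini_ontology(c("B1>S0"))
  a <- merge_ontologies(shared, list(extra_a))
  b <- merge_ontologies(shared, list(extra_b))
  m <- merge_ontologies(a, list(b))
  # oracle: canonicalize-and-dedupe on the raw component tables
  expect_equal(m$classes, sort(unique(c(a$classes, b$classes))))
  expect_equal(nrow(m$edges),
               nrow(dplyr::distinct(dplyr::bind_rows(a$edges, b$edges))))
  expect_equal(nrow(m$annotations),
               nrow(dplyr::distinct(dplyr::bind_rows(a$annotations, b$annotations))))
})

test_that("neighborhood traversal matches brute-force reachability on random DAGs", {
  set.seed(401)
  for (rep in 1:5) {
    fx <- generate_taxonomy(40, seed = 500 + rep)
    o <- fx$ontology
    for (iri in sample(o$classes, 20, replace = TRUE)) {
      expect_equal(class_neighborhood(o, iri, "descendants"),
                   oracle_reach(o$edges, iri, "down"))
      expect_equal(class_neighborhood(o, iri, "ancestors"),
                   oracle_reach(o$edges, iri, "up"))
    }
  }
})

test_that("descendant/ancestor duality holds on acyclic fixtures", {
  fx <- generate_taxonomy(25, seed = 42)
  o <- fx$ontology
  for (a in o$classes) {
    for (b in class_neighborhood(o, a, "descendants")) {
      expect_true(a %in% class_neighborhood(o, b, "ancestors"))
    }
  }
})

test_that("chain and leaf neighborhoods behave as stated", {
  o <- mini_ontology(c("C>B", "B>A"))
  expect_equal(class_neighborhood(o, iri_of("A"), "descendants"),
               sort(iri_of(c("B", "C"))))
  expect_equal(class_neighborhood(o, iri_of("C"), "ancestors"),
               sort(iri_of(c("A", "B"))))
  expect_length(class_neighborhood(o, iri_of("C"), "descendants"), 0)
  expect_error(class_neighborhood(o, iri_of("nope")), "unknown class IRI")
})

test_that("entity_annotations collects labels, definition, synonyms and both xref dialects", {
  obo <- "http://purl.obolibrary.org/obo/"
  ann <- tibble::tibble(
    subject = rep(paste0(obo, "UO_0000000"), 5),
    property = c("http://www.w3.org/2000/01/rdf-schema#label",
                 paste0(obo, "IAO_0000115"),
                 "http://www.geneontology.org/formats/oboInOwl#hasExactSynonym",
                 "http://www.geneontology.org/formats/oboInOwl#hasDbXref",
                 "http://purl.bioontology.org/ontology/npo#dbXref"),
    value = c("unit", "A standard of measurement.", "measurement unit",
              "UO:0000000", "NPO_ref"),
    lang = NA_character_)
  o <- ontology(classes = paste0(obo, "UO_0000000"), annotations = ann)
  rec <- entity_annotations(o, paste0(obo, "UO_0000000"))
  expect_equal(rec$labels, "unit")
  expect_equal(rec$definition, "A standard of measurement.")
  expect_equal(rec$synonyms, "measurement unit")
  expect_length(rec$xrefs, 2) # oboInOwl + bare-dbXref dialect
  # absent entity: all empty
  rec0 <- entity_annotations(o, "http://example.org/none")
  expect_length(rec0$labels, 0)
  expect_true(is.na(rec0$definition))
})

test_that("import closure is breadth-first, deduplicated, and matches set reachability", {
  onts <- list()
  make <- function(name, imports) {
    ontology(ontology_iri = iri_of(name), imports = iri_of(imports),
             classes = iri_of(paste0(name, "_c")))
  }
  # A imports B and C; B imports C: C loaded once
  a <- make("A", c("B", "C"))
  resolver <- list(make("B", "C"), make("C", character()))
  names(resolver) <- iri_of(c("B", "C"))
  closure <- resolve_imports(a, resolver)
  expect_equal(vapply(closure, `[[`, "", "ontology_iri"), iri_of(c("B", "C")))

  # random import DAG of 8 ontologies vs transitive-closure oracle
  set.seed(77)
  for (rep in 1:5) {
    nms <- paste0("O", 1:8)
    imp <- lapply(seq_along(nms), function(i) {
      if (i == 8) character() else sample(nms[(i + 1):8], sample(0:min(3, 8 - i), 1))
    })
    onts <- Map(make, nms, imp)
    resolver <- stats::setNames(onts, iri_of(nms))
    closure <- resolve_imports(onts[[1]], resolver)
    got <- sort(vapply(closure, `[[`, "", "ontology_iri"))
    imp_edges <- dplyr::bind_rows(Map(function(n, is) {
      if (length(is) == 0) return(tibble::tibble(child = character(), parent = character()))
      tibble::tibble(child = iri_of(n), parent = iri_of(is))
    }, nms, imp))
    expected <- oracle_reach(imp_edges, iri_of("O1"), "up")
    expect_equal(got, expected)
    expect_false(any(duplicated(got)))
  }
  expect_error(resolve_imports(a, list()), "unresolvable import")
  expect_length(resolve_imports(make("Z", character()), list()), 0)
})

test_that("cycle detection finds planted cycles and nothing on DAGs", {
  o <- mini_ontology(c("A>B", "B>A"))
  cyc <- detect_cycles(o)
  expect_length(cyc, 1)
  expect_equal(sort(cyc[[1]]), sort(iri_of(c("A", "B"))))
  expect_length(detect_cycles(mini_ontology(c("B>A", "C>A", "D>B"))), 0)
  # planted back-edges: count equals an independent SCC oracle (igraph)
  for (seed in 1:5) {
    fx <- generate_taxonomy(40, seed = 600 + seed, planted_cycles = 3)
    got <- detect_cycles(fx$ontology)
    g <- igraph::graph_from_data_frame(fx$ontology$edges)
    scc <- igraph::components(g, mode = "strong")
    expect_equal(length(got), sum(scc$csize > 1))
    expect_equal(length(got), 3)
  }
})
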