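# Keep-set computation, slimming, rewiring, provenance.

test_that("keep set closures behave on simple chains", {
  o <- mini_ontology(c("C>B", "B>A"))
  expect_equal(compute_keep_set(o, parse_instructions(paste0("+D:", iri_of("B"))))$kept,
               sort(iri_of(c("B", "C"))))
  expect_equal(compute_keep_set(o, parse_instructions(paste0("+U:", iri_of("C"))))$kept,
               sort(iri_of(c("A", "B", "C"))))
  expect_error(compute_keep_set(o, parse_instructions("+:http://example.org/onto/nope")),
               "unknown class IRI")
})

test_that("keep set equals the brute-force set-formula oracle on random fixtures", {
  set.seed(303)
  for (rep in 1:30) {
    fx <- generate_taxonomy(sample(10:50, 1), seed = 700 + rep)
    o <- fx$ontology
    ins <- random_instructions(o, sample(1:6, 1))
    got <- suppressWarnings(compute_keep_set(o, ins))
    expect_equal(got$kept, oracle_keep_set(o, ins))
  }
})

test_that("keeps and removes are order-independent", {
  fx <- generate_taxonomy(30, seed = 17)
  o <- fx$ontology
  set.seed(18)
  ins <- random_instructions(o, 6)
  base <- suppressWarnings(compute_keep_set(o, ins))$kept
  for (rep in 1:5) {
    perm <- ins[sample(nrow(ins)), ]
    expect_equal(suppressWarnings(compute_keep_set(o, perm))$kept, base)
  }
})

test_that("adding a keep instruction never shrinks the kept set", {
  fx <- generate_taxonomy(30, seed = 21)
  o <- fx$ontology
  set.seed(22)
  ins <- random_instructions(o, 4)
  base <- suppressWarnings(compute_keep_set(o, ins))$kept
  for (mode in c("KEEP", "KEEP_WITH_DESCENDANTS")) {
    more <- dplyr::bind_rows(ins, tibble::tibble(
      mode = mode, target = sample(o$classes, 1),
      new_parent = NA_character_, comment = NA_character_))
    expect_true(all(base %in% suppressWarnings(compute_keep_set(o, more))$kept))
  }
})

test_that("nearest kept ancestors match exhaustive path enumeration", {
  o <- mini_ontology(c("C>B", "B>A"))
  expect_equal(nearest_kept_ancestors(o, iri_of(c("B", "C")), iri_of("C")), iri_of("B"))
  expect_length(nearest_kept_ancestors(o, iri_of("A"), iri_of("A")), 0)
  set.seed(404)
  for (rep in 1:10) {
    fx <- generate_taxonomy(30, seed = 800 + rep)
    o <- fx$ontology
    kept <- sample(o$classes, sample(5:20, 1))
    for (iri in sample(kept, 5)) {
      expect_equal(nearest_kept_ancestors(o, kept, iri),
                   oracle_nearest_kept(o, kept, iri))
    }
  }
})

test_that("the unit-ontology worked example yields 11 reparented classes", {
  obo <- "http://purl.obolibrary.org/obo/"
  uo <- paste0(obo, c("UO_0000000", sprintf("UO_%07d", 1:10)))
  other <- paste0(obo, sprintf("ZZ_%07d", 1:6))
  edges <- tibble::tibble(
    child = c(uo[2:6], uo[7:11], uo[1], other[2:6]),
    parent = c(rep(uo[1], 5), uo[2:6], other[1], rep(other[1], 5)))
  ont <- ontology(ontology_iri = paste0(obo, "uo.owl"), classes = c(uo, other),
                  edges = edges,
                  annotations = tibble::tibble(
                    subject = uo[1], property = "http://www.w3.org/2000/01/rdf-schema#label",
                    value = "unit", lang = NA_character_))
  ins <- parse_instructions(paste0(
    "+D(", obo, "IAO_0000030):", obo, "UO_0000000 unit"))
  cfg <- slim_config("uo.owl", "uo.iris",
                     "http://purl.enanomapper.net/onto/external/uo-slim.owl")
  res <- apply_slim(ont, ins, cfg, timestamp = "2015-03-01T00:00:00Z")
  expect_length(res$ontology$classes, 11)
  expect_setequal(res$ontology$classes, uo)  # IRIs unchanged
  expect_true(any(res$ontology$edges$child == uo[1] &
                    res$ontology$edges$parent == paste0(obo, "IAO_0000030")))
  expect_equal(res$dangling_parents, paste0(obo, "IAO_0000030"))
  expect_equal(res$ontology$ontology_iri,
               "http://purl.enanomapper.net/onto/external/uo-slim.owl")
})

test_that("an empty instruction list excludes every class", {
  for (seed in 1:3) {
    fx <- generate_taxonomy(20, seed = seed)
    res <- apply_slim(fx$ontology, parse_instructions(""), default_config())
    expect_length(res$ontology$classes, 0)
  }
})

test_that("orphan rewiring links each child to every nearest kept ancestor exactly once", {
  # diamond: A below B and C, both below D; B and C removed
  o <- mini_ontology(c("A>B", "A>C", "B>D", "C>D"))
  ins <- parse_instructions(paste0("+:", iri_of("A"), "\n+:", iri_of("D")))
  res <- apply_slim(o, ins, default_config())
  hit <- res$ontology$edges[res$ontology$edges$child == iri_of("A"), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$parent, iri_of("D"))
})

test_that("reachability among kept classes is preserved exactly", {
  set.seed(505)
  for (rep in 1:10) {
    fx <- generate_taxonomy(sample(15:40, 1), seed = 900 + rep)
    o <- fx$ontology
    ins <- random_instructions(o, sample(2:6, 1))
    res <- suppressWarnings(apply_slim(o, ins, default_config()))
    kept <- res$ontology$classes
    expect_equal(reach_relation(res$ontology$edges, kept),
                 reach_relation(o$edges, kept))
  }
})

test_that("slimming a slim with the same instructions is idempotent", {
  fx <- generate_taxonomy(30, seed = 31)
  o <- fx$ontology
  target <- o$classes[[5]]
  ins <- parse_instructions(paste0("+D:", target))
  cfg <- default_config()
  once <- apply_slim(o, ins, cfg, timestamp = "2015-01-01T00:00:00Z")
  if (target %in% once$ontology$classes && length(once$ontology$classes) > 0) {
    twice <- apply_slim(once$ontology, ins, cfg, timestamp = "2015-01-01T00:00:00Z")
    expect_true(ontology_isomorphic(once$ontology, twice$ontology))
  }
})

test_that("retained content references only kept entities or instruction parents", {
  set.seed(606)
  for (rep in 1:5) {
    fx <- generate_taxonomy(30, seed = 1000 + rep)
    o <- fx$ontology
    ins <- random_instructions(o, 4)
    ins$new_parent[[1]] <- if (ins$mode[[1]] != "EXCLUDE") iri_of("foreign_parent") else NA
    res <- suppressWarnings(apply_slim(o, ins, default_config()))
    allowed <- c(res$ontology$classes, unname(res$keep_set$reparent_map))
    expect_true(all(res$ontology$edges$parent %in% allowed))
    expect_true(all(res$ontology$edges$child %in% res$ontology$classes))
  }
})

test_that("annotation include/exclude filters restrict kept annotations", {
  fx <- generate_taxonomy(20, seed = 8, synonym_rate = 1)
  o <- fx$ontology
  label_iri <- "http://www.w3.org/2000/01/rdf-schema#label"
  ins <- parse_instructions(paste0("+D:", o$classes[[1]]))
  cfg_inc <- slim_config("a", "b", "http://x.org/slim.owl",
                         annotation_include = label_iri)
  res <- apply_slim(o, ins, cfg_inc)
  expect_true(all(res$ontology$annotations$property == label_iri))
  cfg_exc <- slim_config("a", "b", "http://x.org/slim.owl",
                         annotation_exclude = label_iri)
  res2 <- apply_slim(o, ins, cfg_exc)
  expect_false(any(res2$ontology$annotations$property == label_iri))
})

test_that("axioms referencing dropped entities are dropped and counted", {
  o <- mini_ontology(c("B>A", "C>A"))
  o$opaque_axioms <- tibble::tibble(
    payload = c("<ax1/>", "<ax2/>"),
    entities = list(iri_of(c("A", "B")), iri_of(c("A", "C"))))
  ins <- parse_instructions(paste0("+:", iri_of("A"), "\n+:", iri_of("B")))
  res <- apply_slim(o, ins, default_config())
  expect_equal(nrow(res$ontology$opaque_axioms), 1)
  expect_equal(res$dropped_axioms, 1)
})

test_that("provenance stamping is idempotent under set semantics and injectable", {
  o <- ontology(ontology_iri = iri_of("x.owl"))
  p1 <- add_provenance(o, "eNanoMapper", "2015-01-01T00:00:00Z", "slimmer 1.0",
                       iri_of("src.owl"))
  expect_equal(nrow(p1$ontology_annotations), 4)
  p2 <- add_provenance(p1, "eNanoMapper", "2015-01-01T00:00:00Z", "slimmer 1.0",
                       iri_of("src.owl"))
  expect_equal(p2$ontology_annotations, p1$ontology_annotations)
  expect_identical(write_ontology(p1), write_ontology(p2))
})
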