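# ontoslim

Ontology slimming, assembly and quality control for OWL class hierarchies.

Application ontologies in nanosafety and neighbouring fields are assembled
from many sources — chemical entities, assays, units, anatomy — but
importing each source ontology in full causes real damage: the same label
arrives under different IRIs from different providers, chained
`owl:imports` multiply every annotation and axiom of shared upper-level
classes, and the composite breaks each time an upstream source changes.
`ontoslim` implements the alternative working practice:

1. **Slim** — extract a declared subset from each source with a
   line-oriented instruction language. One directive per line:

   ```
   op [ "(" new-parent-iri ")" ] ":" target-iri [ comment ]
   ```

   with `+` (keep the class), `+D` (keep with all descendants), `+U`
   (keep with every superclass path to the root), `-` (remove a branch
   from a kept set). By default *all* classes are excluded; IRIs of kept
   classes are never rewritten. The optional parenthesized IRI asserts a
   new superclass — which need not exist in the processed ontology — so
   extracted branches cross-link into the assembled whole. Subclass links
   that would dangle after removal are rewired to each nearest kept
   ancestor along every superclass path, which preserves reachability
   among kept classes exactly.
2. **Assemble** — merge slims and manually curated content with set
   semantics (a re-imported MIREOT-style class, same IRI, collapses to
   one copy with one set of annotations).
3. **Reconcile** — detect labels borne by distinct IRIs and prune them
   under an ordered primary-provider policy (e.g. nanoparticle classes to
   NPO-style IRIs, chemical classes to ChEBI-style IRIs); children of a
   removed class are re-linked to the kept one.
4. **Check** — structural QA on every rebuild: missing labels, missing
   definitions, duplicate labels, subclass cycles, dangling parents.
5. **Audit** — cross-ontology exact-label overlap reports, and matching
   of free-text terms against labels/synonyms with exact and *composite*
   matches (several classes jointly covering one term).

A seeded generator of OBO-style synthetic taxonomies makes the whole
pipeline testable offline; no real ontology is downloaded.

## Worked example

```r
library(ontoslim)

# a unit-ontology-like fixture: a root "unit" class with descendants,
# embedded in a larger upper-level tree
obo <- "http://purl.obolibrary.org/obo/"
uo    <- paste0(obo, c("UO_0000000", sprintf("UO_%07d", 1:10)))
upper <- paste0(obo, sprintf("BFO_%07d", 1:4))
ont <- ontology(
  ontology_iri = paste0(obo, "uo.owl"), classes = c(uo, upper),
  edges = tibble::tibble(
    child  = c(uo[2:5], uo[6:9], uo[10:11], uo[1], upper[2:4]),
    parent = c(rep(uo[1], 4), uo[2:5], uo[6:7], upper[1], rep(upper[1], 3))))

ins <- parse_instructions(
  "+D(http://purl.obolibrary.org/obo/IAO_0000030):http://purl.obolibrary.org/obo/UO_0000000 unit")
cfg <- slim_config("uo.owl", "uo.iris",
                   "http://purl.enanomapper.net/onto/external/uo-slim.owl")
res <- apply_slim(ont, ins, cfg, timestamp = "2015-03-01T00:00:00Z")
res
#> <slim_result> http://purl.enanomapper.net/onto/external/uo-slim.owl
#>   kept classes: 11  rewired edges: 0  dropped axioms: 0
#>   dangling parents: http://purl.obolibrary.org/obo/IAO_0000030
```

The single `+D` directive keeps `UO_0000000` plus its 10 descendants (11
classes, original IRIs untouched); the rest of the tree is gone. The root
is asserted below `IAO_0000030`, which is not declared here — it stays a
recorded *dangling parent* until assembly, where any input that declares
it resolves the link:

```r
qa_check(res$ontology)
#> <qa_report> FAIL (11 classes)
#>   missing labels:      11
#>   missing definitions: 11
#>   duplicate labels:    0
#>   subclass cycles:     0
#>   dangling parents:    1
```

(The fixture above carries no definitions, so QA reports exactly that.)
Term matching reproduces composite annotation: with classes labelled
`"z-average"` and `"hydrodynamic diameter"`,

```r
match_term("z-average hydrodynamic diameter", zont)
#> <term_match> 'z-average hydrodynamic diameter': composite
#> # A tibble: 2 × 2
#>   iri                                     matched
#>   <chr>                                   <chr>
#> 1 http://purl.obolibrary.org/obo/NPO_1916 z-average
#> 2 http://purl.obolibrary.org/obo/NPO_1915 hydrodynamic diameter
```

A command-line front end covers the same ground
(`slim`, `assemble`, `check`, `overlap`, `match`, `gen` subcommands):

```sh
Rscript -e 'quit(status = ontoslim::run_cli(commandArgs(TRUE)))' \
  slim --config uo.props --timestamp 2015-03-01T00:00:00Z
```

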