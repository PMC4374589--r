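---
title: "Slimming, assembling and checking OWL class hierarchies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slimming, assembling and checking OWL class hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoslim)
```

## The problem

Application ontologies are assembled from parts of many sources. Importing
each source in full is tempting but costly in three specific ways. First,
neighbouring ontologies genuinely overlap: the same label appears under
different identifiers from different providers, sometimes with different
definitions. Second, OWL's import semantics duplicate content along
chained imports — when two inputs both re-import the same upper-level or
unit classes, every annotation and axiom of those classes arrives once
per chain. Third, a composite built by full imports must be rebuilt by
hand whenever a source updates. The working practice `ontoslim`
implements extracts *declared subsets* (slims) instead, stitches them
together below a small upper level, prunes residual duplication by an
explicit provider policy, and re-checks the structural health of the
whole on every rebuild, so that source updates flow through mechanically.

## The model

An ontology here is the structural OWL subset the procedure manipulates:
a set of class IRIs, asserted subclass edges between named classes,
annotation assertions (label, textual definition `IAO_0000115`, oboInOwl
synonyms and `hasDbXref`, plus the bare `dbXref` dialect some legacy
sources use, folded into the oboInOwl IRI at load time), `owl:imports`,
the ontology header, and declared annotation/object properties.
Everything else — restrictions, equivalences, reified axiom blocks — is
retained as an *opaque axiom*: a canonical serialized payload plus the
set of entity IRIs it references. This split matches what slimming
actually needs: the procedure reasons over the class hierarchy and
metadata, and opaque axioms only need an entity index to decide whether
they survive a slim (they do iff every referenced entity is kept).

Two deliberate consequences: the package never interprets complex class
expressions (a description-logic reasoner is out of scope; "coherence"
means structural coherence — acyclicity, no dangling references, labels
and definitions present), and blank-node fidelity inside opaque payloads
is only canonical-form-deep, which is sufficient for byte-stable round
trips of files the package itself writes.

## The slimming procedure

Instructions are one directive per line,
`op ["(" parent ")"] ":" target [comment]`, with four operators: `+`
keeps the single class, `+D` closes downward over all transitive
subclasses, `+U` closes upward along **every** superclass path (the
hierarchy is a DAG, not a tree, and a class's context is all of its
ancestry), `-` removes a class *and its descendant branch* from a kept
set. The keep set is

> (union of keep closures) minus (union of remove closures),

computed after all keeps, so instruction files are order-independent and
a `-` line never depends on its position. A remove that touches nothing
kept is a no-op with a warning. By default everything is excluded: an
empty instruction file yields an empty slim.

After the keep set is fixed, edges are reconstructed. An edge between two
kept classes survives as-is. Where a kept class's parent was removed, the
class is re-linked to each *nearest kept ancestor* along every upward
path — the first kept class encountered on that path. This choice (rather
than dropping orphaned edges) preserves reachability among kept classes
exactly: a kept class is above another in the slim iff it was above it in
the source. Instruction-specified parents are then asserted as additional
edges; they may be undeclared in the processed ontology ("dangling
parents"), which is the mechanism that links an extracted branch below a
class that will arrive from another slim at assembly time.

Slims are stamped with provenance as ontology-level annotations:
publisher (`dcterms:publisher`), creation instant (`dcterms:created`,
ISO-8601), source ontology (`dcterms:source`) and the tool
(`rdfs:comment`). The timestamp is always injected by the caller — the
library never reads a wall clock — so a fixed configuration and timestamp
reproduce byte-identical output. One boundary case needed a decision:
re-slimming a slim with its own configuration would flip `dcterms:source`
to the slim's own IRI and so break idempotence; when the input's ontology
IRI already equals the configured output IRI, the existing source
annotation is carried forward instead.

## Assembly and duplicate pruning

Merging is a set union on every component — classes, edges, annotation
assertions, opaque axiom payloads. This is what neutralizes the
multiplied-metadata problem: a class re-imported under its original IRI
(MIREOT practice) collapses to one copy, and merging an ontology with
itself changes no counts. Such same-IRI re-imports are *never* treated as
duplicates.

Genuine duplicates — one label, several distinct IRIs — are resolved by
an ordered provider policy. Each rule names a preferred IRI prefix and
optionally restricts its scope by a label regular expression or a member
prefix; the first matching rule decides which class of the group is kept.
This encodes the domain reality that no single source wins everywhere:
chemical classes resolve to the chemistry provider's IRIs, nanoparticle
classes to the nanotechnology provider's. Children of removed classes are
re-linked to the kept class; the removed class's annotations are
discarded (pruning means removing — `merge_annotations = TRUE` offers the
transfer alternative); opaque axioms referencing a removed class are
dropped and counted. Groups no rule covers fall back deterministically to
the lexicographically smallest IRI and are reported as unresolved, so a
policy gap is visible rather than silent.

## QA and audits

`qa_check()` inventories missing labels, missing definitions (deprecated
classes exempt), duplicate labels, subclass cycles (every elementary
cycle, enumerated by Tarjan components plus a canonical-start DFS) and
dangling parents, with per-check whitelists. `label_overlap()` reports
labels shared between two ontologies, flagging same-IRI records and
pairs already linked by cross-references. `match_term()` reproduces the
annotation-coverage methodology: a term matches exactly when it equals a
label or synonym, and otherwise a composite match is attempted by greedy
longest-first covering of the term's whitespace tokens with label/synonym
spans (ties: earlier start, then longer span; overlaps disallowed; the
cover must span the whole term with at least two components). Greedy
covering is deterministic and reproduces the canonical worked example —
"z-average hydrodynamic diameter" decomposing into "z-average" plus
"hydrodynamic diameter" — at the cost of missing rare covers a full
search would find; term matching is an audit aid, not an inference
procedure, so determinism won.

Defaults differ by audit on purpose: label overlap compares trimmed
strings case-sensitively (with a casefold flag), because cross-provider
label comparison is an *exact*-match analysis; term matching casefolds by
default, because free-text inputs vary in capitalization. Synonyms
participate in term matching but not in label overlap.

## The synthetic generator

`generate_taxonomy()` emulates the inputs the pipeline consumes:
a rooted subclass DAG (each class under up to 3 earlier classes) over
OBO-style PURLs (prefix + zero-padded 7-digit ID), 1–3-token labels drawn
from a fixed nanosafety word pool (multi-token labels make composite
matching exercisable), definitions, exact synonyms at rate 0.3 and xrefs
at rate 0.2. Defects are planted on request and recorded as ground truth:
fractions of missing labels/definitions, dangling-parent edges, and
subclass cycles. Cycles are planted as node-disjoint 2-cycles created by
reversing an edge that is the *unique* upward path between its endpoints
— this guarantees the planted count equals the elementary-cycle count
exactly, which is what lets QA recovery be tested for equality rather
than approximately. `generate_overlap_pair()` plants a controlled number
of shared labels across two prefixes, a subset of them as same-IRI
re-imports, optionally with cross-references on the conflicting pairs.

Generation is a pure function of its parameters; the RNG state is scoped
and restored. What the generator does *not* emulate: realistic branching
factors and depth distributions of production ontologies, complex logical
axioms, multilingual labels, or label noise (near-duplicates,
punctuation variants). Passing tests therefore demonstrate the
correctness of the set-theoretic and structural contracts on OBO-shaped
inputs, not robustness to the full messiness of real curation.

## Numerical and format choices

* Serialization is deterministic: classes, properties, annotations and
  axiom payloads are ordered lexicographically (IRI, then property, then
  value), so equal ontologies serialize byte-identically and pipeline
  outputs diff cleanly under version control.
* RDF/XML is the primary format. Turtle output covers the structural
  subset and refuses ontologies carrying opaque axioms rather than
  silently dropping them.
* Annotation values shaped like absolute IRIs serialize as resources,
  other values as (optionally language-tagged) literals.
* Import resolution is injected as an IRI-to-source mapping (two-column
  catalog file at the CLI); the library performs no network access. The
  closure is loaded breadth-first, IRI-sorted within levels, each
  ontology exactly once.
* Cyclic hierarchies are legal inputs — every traversal carries a
  visited-set guard — and are reported by QA rather than rejected.
* Relative IRIs are rejected at parse time; IRIs are taken as opaque
  strings otherwise (no normalization of case or escaping).

## Problem sizes

The bundled tests and the acceptance script run entirely on generated
fixtures: taxonomies of 10–60 classes, 100-fixture oracle-agreement
sweeps for keep sets and QA recovery, 50-fixture hierarchy-preservation
sweeps, and 25+25-class overlap pairs with 7 shared labels. These sizes
keep each property readable and the whole suite fast while exercising
every code path; the algorithms themselves are linear to near-linear in
edges and pose no obstacle to ontologies of tens of thousands of classes.

## Known limitations

Opaque axioms are never rewritten: a slim or prune either keeps an axiom
verbatim or drops it (counted), so axioms referencing removed duplicates
are lost rather than redirected. Equivalence axioms do not participate in
closure computation. The duplicate audit is label-based; synonym- or
definition-based duplicate detection is reported by the overlap module
only as far as labels go, and no fuzzy string matching is attempted.
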