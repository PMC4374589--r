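# Composite assembly: merge generated slims and manually curated content
# into one ontology, then reconcile duplicate labels by a primary-provider
# policy. A class re-imported under its original IRI (MIREOT practice) is
# the same class everywhere — set-semantics merging collapses it and it is
# never pruned. Distinct IRIs bearing the same label are genuine
# duplicates: for each content domain one ontology is designated primary
# provider, its class is kept, and the others are removed with their
# children re-linked to the survivor.

#' Assemble a composite ontology from slims and curated content
#'
#' Set-semantics union of all inputs under a fresh composite ontology IRI.
#' Parents asserted by slim instructions but undeclared in their own slim
#' ("dangling") are resolved automatically when any other input declares
#' them; whatever remains dangling is recorded in the
#' `dangling_parents` attribute of the result.
#'
#' @param slims list of [ontology()] objects (generated slims).
#' @param manual list of [ontology()] objects (manually curated content).
#' @param composite_iri ontology IRI for the assembled whole.
#' @return the composite [ontology()], with attribute `dangling_parents`.
#' @export
assemble_composite <- function(slims, manual = list(), composite_iri) {
  assert_iri(composite_iri, "composite ontology IRI")
  if (is_ontology(slims)) slims <- list(slims)
  if (is_ontology(manual)) manual <- list(manual)
  inputs <- c(slims, manual)
  stopifnot(length(inputs) > 0)
  shell <- ontology(ontology_iri = composite_iri)
  out <- merge_ontologies(shell, inputs)
  dangling <- sort(setdiff(unique(out$edges$parent), out$classes))
  attr(out, "dangling_parents") <- dangling
  out
}

#' Find labels shared by distinct classes
#'
#' @param ont an [ontology()].
#' @param normalize `"exact"` (whitespace-trimmed string equality) or
#'   `"casefold"` (additionally case-insensitive).
#' @return tibble with columns `label` (normalized), `iris` (list column
#'   of the distinct class IRIs bearing it), `n`; only labels with `n >= 2`
#'   appear, sorted by label.
#' @export
find_label_duplicates <- function(ont, normalize = c("exact", "casefold")) {
  normalize <- match.arg(normalize)
  lab <- ont$annotations[ont$annotations$property == IRI_LABEL &
                           ont$annotations$subject %in% ont$classes, , drop = FALSE]
  if (nrow(lab) == 0) {
    return(tibble::tibble(label = character(), iris = list(), n = integer()))
  }
  key <- normalize_label(lab$value, normalize)
  tab <- tibble::tibble(label = key, iri = lab$subject)
  tab <- dplyr::distinct(tab)
  out <- tab |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(iris = list(sort(unique(.data$iri))), n = dplyr::n_distinct(.data$iri)) |>
    dplyr::filter(.data$n >= 2L) |>
    dplyr::arrange(.data$label)
  out
}

normalize_label <- function(x, normalize) {
  x <- trimws(x)
  if (normalize == "casefold") tolower(x) else x
}

#' Define a primary-provider policy
#'
#' An ordered rule list deciding, for each duplicate-label group, which
#' source ontology's class to keep. A rule matches a group when some
#' member IRI starts with `preferred_prefix` and (if given) the label
#' matches `label_regex` or some member IRI starts with `scope_prefix`.
#' The first matching rule wins; groups no rule covers fall back to the
#' deterministic default (lexicographically smallest IRI) and are listed
#' as unresolved.
#'
#' @param rules tibble (or data frame) with columns `preferred_prefix`
#'   (required), and optionally `label_regex` and `scope_prefix` (`NA` =
#'   unconstrained).
#' @return object of class `provider_policy`.
#' @export
provider_policy <- function(rules) {
  rules <- tibble::as_tibble(rules)
  stopifnot("preferred_prefix" %in% names(rules))
  if (!"label_regex" %in% names(rules)) rules$label_regex <- NA_character_
  if (!"scope_prefix" %in% names(rules)) rules$scope_prefix <- NA_character_
  structure(list(rules = rules[, c("scope_prefix", "label_regex", "preferred_prefix")]),
            class = "provider_policy")
}

#' Read a provider policy file
#'
#' Accepts either a YAML list of rule mappings (`preferred_prefix`,
#' optional `label_regex` / `scope_prefix`) or a headerless TSV with
#' columns scope-prefix, label-regex, preferred-prefix (empty field =
#' unconstrained).
#'
#' @param path policy file path.
#' @return a [provider_policy()].
#' @export
read_policy <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    rules <- dplyr::bind_rows(lapply(raw, function(r) {
      tibble::tibble(scope_prefix = r$scope_prefix %||% NA_character_,
                     label_regex = r$label_regex %||% NA_character_,
                     preferred_prefix = r$preferred_prefix)
    }))
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    rules <- dplyr::bind_rows(lapply(parts, function(p) {
      p <- c(p, rep("", 3))[1:3]
      tibble::tibble(scope_prefix = if (nzchar(p[[1]])) p[[1]] else NA_character_,
                     label_regex = if (nzchar(p[[2]])) p[[2]] else NA_character_,
                     preferred_prefix = p[[3]])
    }))
  }
  provider_policy(rules)
}

# First rule index matching a duplicate group, or NA.
match_rule <- function(policy, label, iris) {
  rules <- policy$rules
  for (i in seq_len(nrow(rules))) {
    if (!any(startsWith(iris, rules$preferred_prefix[[i]]))) next
    scope_ok <- TRUE
    if (!is.na(rules$scope_prefix[[i]])) {
      scope_ok <- any(startsWith(iris, rules$scope_prefix[[i]]))
    }
    if (scope_ok && !is.na(rules$label_regex[[i]])) {
      scope_ok <- grepl(rules$label_regex[[i]], label)
    }
    if (scope_ok) return(i)
  }
  NA_integer_
}

#' Prune duplicate-label classes under a provider policy
#'
#' For every label borne by two or more distinct class IRIs, keeps the
#' class from the primary provider (first matching policy rule) and
#' removes the rest: their children are re-linked to the kept class, their
#' other subclass edges are dropped, their annotations are discarded
#' (unless `merge_annotations`), and opaque axioms referencing them are
#' dropped and counted. Same-IRI re-imports are never duplicates — set
#' merging already collapsed them.
#'
#' @param ont the composite [ontology()].
#' @param policy a [provider_policy()].
#' @param normalize label normalization, as in [find_label_duplicates()].
#' @param merge_annotations when `TRUE`, annotations of removed classes
#'   are transferred to the kept class instead of discarded.
#' @param whitelist labels (normalized) allowed to stay duplicated.
#' @return list with `ontology` (pruned) and `report`, an object of class
#'   `duplicate_report`: tibble `removals` (`removed_iri`, `kept_iri`,
#'   `label`, `rule`), character `unresolved`, tibble `counts` per removed
#'   IRI prefix.
#' @export
prune_duplicates <- function(ont, policy, normalize = c("exact", "casefold"),
                             merge_annotations = FALSE, whitelist = character()) {
  normalize <- match.arg(normalize)
  dups <- find_label_duplicates(ont, normalize)
  dups <- dups[!dups$label %in% normalize_label(whitelist, normalize), , drop = FALSE]
  removals <- list()
  unresolved <- character()
  for (i in seq_len(nrow(dups))) {
    label <- dups$label[[i]]
    iris <- dups$iris[[i]]
    ridx <- match_rule(policy, label, iris)
    if (is.na(ridx)) {
      kept_iri <- min(iris)
      unresolved <- c(unresolved, label)
      rule <- "default:lexicographic"
    } else {
      pref <- policy$rules$preferred_prefix[[ridx]]
      kept_iri <- min(iris[startsWith(iris, pref)])
      rule <- sprintf("rule %d (%s)", ridx, pref)
    }
    removed <- setdiff(iris, kept_iri)
    removals[[length(removals) + 1]] <- tibble::tibble(
      removed_iri = removed, kept_iri = kept_iri, label = label, rule = rule)
  }
  removals <- if (length(removals) > 0) dplyr::bind_rows(removals) else {
    tibble::tibble(removed_iri = character(), kept_iri = character(),
                   label = character(), rule = character())
  }
  out <- drop_classes(ont, removals, merge_annotations = merge_annotations)
  counts <- if (nrow(removals) > 0) {
    tibble::tibble(prefix = iri_prefix(removals$removed_iri)) |>
      dplyr::count(.data$prefix, name = "removed")
  } else tibble::tibble(prefix = character(), removed = integer())
  report <- structure(list(removals = removals, unresolved = sort(unique(unresolved)),
                           counts = counts),
                      class = "duplicate_report")
  list(ontology = out, report = report)
}

iri_prefix <- function(iri) {
  sub("[^#/_]+$", "", iri)
}

# Remove classes, re-linking each removed class's children to its kept
# counterpart and dropping its other edges, annotations and axioms.
drop_classes <- function(ont, removals, merge_annotations = FALSE) {
  if (nrow(removals) == 0) return(ont)
  removed <- removals$removed_iri
  replacement <- stats::setNames(removals$kept_iri, removals$removed_iri)
  edges <- ont$edges
  # children of a removed class point to its kept counterpart
  hit <- edges$parent %in% removed
  edges$parent[hit] <- unname(replacement[edges$parent[hit]])
  # edges *from* removed classes are dropped
  edges <- edges[!edges$child %in% removed, , drop = FALSE]
  edges <- edges[edges$child != edges$parent, , drop = FALSE]

  ann <- ont$annotations
  if (merge_annotations) {
    hit <- ann$subject %in% removed
    ann$subject[hit] <- unname(replacement[ann$subject[hit]])
  } else {
    ann <- ann[!ann$subject %in% removed, , drop = FALSE]
  }

  ax <- ont$opaque_axioms
  if (nrow(ax) > 0) {
    ax_keep <- vapply(ax$entities, function(e) !any(e %in% removed), logical(1))
    ax <- ax[ax_keep, , drop = FALSE]
  }

  ontology(
    ontology_iri = ont$ontology_iri, version_iri = ont$version_iri,
    imports = ont$imports,
    classes = setdiff(ont$classes, removed),
    edges = edges, annotations = ann,
    ontology_annotations = ont$ontology_annotations,
    annotation_properties = ont$annotation_properties,
    object_properties = ont$object_properties,
    opaque_axioms = ax
  )
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat("<duplicate_report> ", nrow(x$removals), " removal(s), ",
      length(x$unresolved), " unresolved label(s)\n", sep = "")
  if (nrow(x$removals) > 0) print(x$removals, n = 10)
  invisible(x)
}

#' Write a duplicate report as TSV
#'
#' @param report a `duplicate_report` from [prune_duplicates()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_duplicate_report <- function(report, path) {
  tab <- report$removals
  lines <- c("removed_iri\tkept_iri\tlabel\trule",
             sprintf("%s\t%s\t%s\t%s", tab$removed_iri, tab$kept_iri, tab$label, tab$rule))
  write_atomic(paste(c(lines, ""), collapse = "\n"), path)
}
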