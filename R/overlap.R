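# Cross-ontology audits: exact-label overlap between two ontologies (the
# analysis that motivates primary-provider pruning) and matching of
# free-text terms against one ontology's labels and synonyms, reporting
# exact matches and composite matches (several classes whose labels
# jointly cover the term).

#' Exact-label overlap between two ontologies
#'
#' One record per normalized label borne by classes on both sides.
#' `shared_iri` marks labels where some IRI appears on both sides
#' (MIREOT-style re-import: same class, no conflict); `xref_linked` marks
#' labels where a class on one side cross-references (`hasDbXref`) a class
#' on the other, either by full IRI or by OBO-style CURIE.
#'
#' @param a,b [ontology()] objects.
#' @param normalize `"exact"` (trimmed) or `"casefold"`.
#' @return tibble sorted by label: `label`, `iris_a`, `iris_b` (list
#'   columns), `shared_iri`, `xref_linked`.
#' @export
label_overlap <- function(a, b, normalize = c("exact", "casefold")) {
  normalize <- match.arg(normalize)
  la <- class_labels(a, normalize)
  lb <- class_labels(b, normalize)
  shared <- sort(intersect(unique(la$label), unique(lb$label)))
  if (length(shared) == 0) {
    return(tibble::tibble(label = character(), iris_a = list(), iris_b = list(),
                          shared_iri = logical(), xref_linked = logical()))
  }
  xa <- xref_table(a)
  xb <- xref_table(b)
  rows <- lapply(shared, function(lbl) {
    ia <- sort(unique(la$iri[la$label == lbl]))
    ib <- sort(unique(lb$iri[lb$label == lbl]))
    tibble::tibble(
      label = lbl, iris_a = list(ia), iris_b = list(ib),
      shared_iri = length(intersect(ia, ib)) > 0,
      xref_linked = xref_links(xa, ia, ib) || xref_links(xb, ib, ia)
    )
  })
  dplyr::bind_rows(rows)
}

class_labels <- function(ont, normalize) {
  lab <- ont$annotations[ont$annotations$property == IRI_LABEL &
                           ont$annotations$subject %in% ont$classes, , drop = FALSE]
  tibble::tibble(iri = lab$subject, label = normalize_label(lab$value, normalize))
}

xref_table <- function(ont) {
  x <- ont$annotations[ont$annotations$property == IRI_DBXREF, , drop = FALSE]
  tibble::tibble(subject = x$subject, value = x$value)
}

# Does any class in `from` xref any class in `to`? Xref values may be the
# full IRI or a CURIE derived from an OBO-style PURL (PREFIX_ID -> PREFIX:ID).
xref_links <- function(xr, from, to) {
  if (nrow(xr) == 0) return(FALSE)
  vals <- xr$value[xr$subject %in% from]
  if (length(vals) == 0) return(FALSE)
  any(vals %in% c(to, iri_to_curie(to)))
}

iri_to_curie <- function(iri) {
  local <- sub(".*[#/]", "", iri)
  sub("_", ":", local, fixed = TRUE)
}

#' Match one free-text term against an ontology
#'
#' The term matches *exactly* when its normalized text equals a class
#' label or synonym. Otherwise a *composite* match is attempted: a greedy
#' longest-first covering of the term's whitespace tokens by spans that
#' each equal some label/synonym; the cover must span the whole term with
#' at least two components (ties broken by earlier start, then longer
#' span). Anything else is *none*.
#'
#' @param term non-empty text.
#' @param ont an [ontology()].
#' @param normalize `"exact"` or `"casefold"`.
#' @return object of class `term_match`: list with `term`, `kind`
#'   (`"exact"`, `"composite"`, `"none"`) and `components`, a tibble
#'   (`iri`, `matched`) ordered by position in the term.
#' @export
match_term <- function(term, ont, normalize = c("casefold", "exact")) {
  normalize <- match.arg(normalize)
  stopifnot(is.character(term), length(term) == 1, nzchar(trimws(term)))
  index <- term_index(ont, normalize)
  key <- normalize_label(term, normalize)
  hit <- index$iri[index$text == key]
  if (length(hit) > 0) {
    return(new_term_match(term, "exact",
                          tibble::tibble(iri = min(hit), matched = key)))
  }
  tokens <- strsplit(key, "\\s+")[[1]]
  n <- length(tokens)
  if (n < 2) return(new_term_match(term, "none", NULL))
  # candidate spans [i, j] whose joined tokens equal an indexed text
  spans <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      txt <- paste(tokens[i:j], collapse = " ")
      hit <- index$iri[index$text == txt]
      if (length(hit) > 0) {
        spans[[length(spans) + 1]] <- list(start = i, end = j, text = txt, iri = min(hit))
      }
    }
  }
  if (length(spans) == 0) return(new_term_match(term, "none", NULL))
  len <- vapply(spans, function(s) s$end - s$start + 1L, integer(1))
  start <- vapply(spans, `[[`, integer(1), "start")
  ord <- order(-len, start)
  covered <- rep(FALSE, n)
  chosen <- list()
  for (k in ord) {
    s <- spans[[k]]
    if (any(covered[s$start:s$end])) next
    covered[s$start:s$end] <- TRUE
    chosen[[length(chosen) + 1]] <- s
  }
  if (!all(covered) || length(chosen) < 2) {
    return(new_term_match(term, "none", NULL))
  }
  chosen <- chosen[order(vapply(chosen, `[[`, integer(1), "start"))]
  new_term_match(term, "composite", tibble::tibble(
    iri = vapply(chosen, `[[`, character(1), "iri"),
    matched = vapply(chosen, `[[`, character(1), "text")
  ))
}

new_term_match <- function(term, kind, components) {
  if (is.null(components)) components <- tibble::tibble(iri = character(), matched = character())
  structure(list(term = term, kind = kind, components = components), class = "term_match")
}

#' @export
print.term_match <- function(x, ...) {
  cat("<term_match> '", x$term, "': ", x$kind, "\n", sep = "")
  if (nrow(x$components) > 0) print(x$components)
  invisible(x)
}

# Label + synonym lookup table, normalized.
term_index <- function(ont, normalize) {
  ann <- ont$annotations[ont$annotations$property %in% c(IRI_LABEL, SYNONYM_PROPERTIES), ,
                         drop = FALSE]
  tibble::tibble(iri = ann$subject, text = normalize_label(ann$value, normalize))
}

#' Match a list of terms and tally the outcome
#'
#' @param terms character vector of free-text terms.
#' @param ont an [ontology()].
#' @param normalize passed to [match_term()].
#' @return object of class `match_summary`: list with `exact_count`,
#'   `composite_count`, `none_count` (partitioning `length(terms)`) and
#'   `per_term`, a tibble (`term`, `kind`, `n_components`, `components`
#'   list column of per-term component tibbles).
#' @export
summarize_matches <- function(terms, ont, normalize = c("casefold", "exact")) {
  normalize <- match.arg(normalize)
  matches <- lapply(terms, match_term, ont = ont, normalize = normalize)
  kinds <- vapply(matches, `[[`, character(1), "kind")
  per_term <- tibble::tibble(
    term = as.character(terms),
    kind = kinds,
    n_components = vapply(matches, function(m) nrow(m$components), integer(1)),
    components = lapply(matches, `[[`, "components")
  )
  structure(list(
    exact_count = sum(kinds == "exact"),
    composite_count = sum(kinds == "composite"),
    none_count = sum(kinds == "none"),
    per_term = per_term
  ), class = "match_summary")
}

#' @export
print.match_summary <- function(x, ...) {
  n <- nrow(x$per_term)
  cat("<match_summary> ", n, " term(s): ", x$exact_count, " exact, ",
      x$composite_count, " composite, ", x$none_count, " unmatched\n", sep = "")
  invisible(x)
}

#' Tidy per-term match results
#'
#' @param x a `match_summary`.
#' @param ... unused.
#' @return tibble `term`, `kind`, `n_components`.
#' @export
tidy.match_summary <- function(x, ...) {
  x$per_term[, c("term", "kind", "n_components")]
}

#' One-row match tallies
#'
#' @param x a `match_summary`.
#' @param ... unused.
#' @return one-row tibble with the three counts and coverage fraction.
#' @export
glance.match_summary <- function(x, ...) {
  n <- nrow(x$per_term)
  tibble::tibble(
    n_terms = n,
    exact = x$exact_count,
    composite = x$composite_count,
    none = x$none_count,
    coverage = if (n > 0) (x$exact_count + x$composite_count) / n else NA_real_
  )
}

#' Bar chart of match outcomes
#'
#' @param object a `match_summary`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.match_summary <- function(object, ...) {
  df <- tibble::tibble(kind = factor(c("exact", "composite", "none"),
                                     levels = c("exact", "composite", "none")),
                       count = c(object$exact_count, object$composite_count,
                                 object$none_count))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$count)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = NULL, y = "terms", title = "Term annotation coverage") +
    ggplot2::theme_minimal()
}

#' Write an overlap report as TSV
#'
#' @param overlap tibble from [label_overlap()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_overlap_report <- function(overlap, path) {
  lines <- c("label\tiris_a\tiris_b\tshared_iri\txref_linked",
             vapply(seq_len(nrow(overlap)), function(i) {
               sprintf("%s\t%s\t%s\t%s\t%s", overlap$label[[i]],
                       paste(overlap$iris_a[[i]], collapse = "|"),
                       paste(overlap$iris_b[[i]], collapse = "|"),
                       overlap$shared_iri[[i]], overlap$xref_linked[[i]])
             }, character(1)))
  write_atomic(paste(c(lines, ""), collapse = "\n"), path)
}
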