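# Structural quality checks run over every assembled resource: label and
# definition presence across all classes, duplicate labels, subclass
# cycles, and dangling parents. These stand in for the continuous
# coherence testing the pipeline runs on each rebuild; description-logic
# reasoning is deliberately out of scope.

#' Run structural quality checks
#'
#' * `missing_labels` — declared classes with no `rdfs:label`
#' * `missing_definitions` — classes with no definition (IAO_0000115);
#'   classes marked `owl:deprecated` are exempt
#' * `duplicate_labels` — via [find_label_duplicates()]
#' * `cycles` — via [detect_cycles()]
#' * `dangling_parents` — parent IRIs referenced by subclass edges but
#'   never declared as classes
#'
#' The report passes iff every defect collection is empty after
#' whitelist filtering.
#'
#' @param ont an [ontology()].
#' @param whitelist optional named list of exemptions: `labels`,
#'   `definitions` (class IRIs), `duplicate_labels` (label strings),
#'   `dangling_parents` (IRIs).
#' @param normalize label normalization for the duplicate check.
#' @return object of class `qa_report` with the fields above plus `pass`.
#' @export
qa_check <- function(ont, whitelist = list(), normalize = c("exact", "casefold")) {
  normalize <- match.arg(normalize)
  ann <- ont$annotations
  labeled <- unique(ann$subject[ann$property == IRI_LABEL])
  defined <- unique(ann$subject[ann$property == IRI_DEFINITION])
  deprecated <- unique(ann$subject[ann$property == IRI_DEPRECATED &
                                     tolower(ann$value) %in% c("true", "1")])

  missing_labels <- setdiff(ont$classes, labeled)
  missing_definitions <- setdiff(setdiff(ont$classes, defined), deprecated)
  dups <- find_label_duplicates(ont, normalize)
  cycles <- detect_cycles(ont)
  dangling <- setdiff(unique(ont$edges$parent), ont$classes)

  missing_labels <- sort(setdiff(missing_labels, whitelist$labels %||% character()))
  missing_definitions <- sort(setdiff(missing_definitions, whitelist$definitions %||% character()))
  dups <- dups[!dups$label %in% (whitelist$duplicate_labels %||% character()), , drop = FALSE]
  dangling <- sort(setdiff(dangling, whitelist$dangling_parents %||% character()))

  structure(list(
    missing_labels = missing_labels,
    missing_definitions = missing_definitions,
    duplicate_labels = dups,
    cycles = cycles,
    dangling_parents = dangling,
    n_classes = length(ont$classes),
    pass = length(missing_labels) == 0 && length(missing_definitions) == 0 &&
      nrow(dups) == 0 && length(cycles) == 0 && length(dangling) == 0
  ), class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report> ", if (x$pass) "PASS" else "FAIL", " (", x$n_classes, " classes)\n", sep = "")
  cat("  missing labels:      ", length(x$missing_labels), "\n", sep = "")
  cat("  missing definitions: ", length(x$missing_definitions), "\n", sep = "")
  cat("  duplicate labels:    ", nrow(x$duplicate_labels), "\n", sep = "")
  cat("  subclass cycles:     ", length(x$cycles), "\n", sep = "")
  cat("  dangling parents:    ", length(x$dangling_parents), "\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a QA report into one row per defect
#'
#' @param x a `qa_report`.
#' @param ... unused.
#' @return tibble with columns `check`, `item`.
#' @export
tidy.qa_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(check = "missing_label", item = x$missing_labels),
    tibble::tibble(check = "missing_definition", item = x$missing_definitions),
    tibble::tibble(check = "duplicate_label", item = x$duplicate_labels$label),
    tibble::tibble(check = "cycle",
                   item = vapply(x$cycles, paste, character(1), collapse = " -> ")),
    tibble::tibble(check = "dangling_parent", item = x$dangling_parents)
  )
}

#' One-row QA summary
#'
#' @param x a `qa_report`.
#' @param ... unused.
#' @return one-row tibble of defect counts and the pass flag.
#' @export
glance.qa_report <- function(x, ...) {
  tibble::tibble(
    n_classes = x$n_classes,
    missing_labels = length(x$missing_labels),
    missing_definitions = length(x$missing_definitions),
    duplicate_labels = nrow(x$duplicate_labels),
    cycles = length(x$cycles),
    dangling_parents = length(x$dangling_parents),
    pass = x$pass
  )
}

#' Bar chart of QA defect counts
#'
#' @param object a `qa_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.qa_report <- function(object, ...) {
  g <- glance.qa_report(object)
  df <- tidyr::pivot_longer(g[, c("missing_labels", "missing_definitions",
                                  "duplicate_labels", "cycles", "dangling_parents")],
                            dplyr::everything(),
                            names_to = "check", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$check, -.data$count),
                                   y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "defects",
                  title = sprintf("Structural QA: %s", if (object$pass) "pass" else "fail")) +
    ggplot2::theme_minimal()
}

#' Write a QA report to TSV or JSON
#'
#' @param report a `qa_report`.
#' @param path output path; format chosen by extension (`.json` or TSV).
#' @return the path, invisibly.
#' @export
write_qa_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      pass = report$pass,
      missing_labels = report$missing_labels,
      missing_definitions = report$missing_definitions,
      duplicate_labels = stats::setNames(report$duplicate_labels$iris,
                                         report$duplicate_labels$label),
      cycles = report$cycles,
      dangling_parents = report$dangling_parents
    )
    write_atomic(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE), path)
  } else {
    td <- tidy.qa_report(report)
    lines <- c("check\titem", sprintf("%s\t%s", td$check, td$item))
    write_atomic(paste(c(lines, ""), collapse = "\n"), path)
  }
  invisible(path)
}
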