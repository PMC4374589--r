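# The slimming instruction language and the properties-style
# configuration that binds an input ontology, an instruction file and the
# IRI/path of the resulting slim.
#
# One directive per line:
#
#   op [ "(" parent-iri ")" ] ":" target-iri [ whitespace comment ]
#
# with op one of:
#   +    keep the single class
#   +D   keep the class with all its descendants (downward branch)
#   +U   keep the class with its chain(s) of superclasses up to the root
#   -    remove the class (and its branch) from a kept set
#
# The optional parenthesized IRI asserts a new superclass for the target
# in the slim; it does not have to be defined in the processed ontology,
# which is how slims cross-link to branches imported from elsewhere.
# A trailing free-text comment (typically the class label) is ignored by
# the machinery.

MODE_TOKENS <- c("KEEP" = "+", "KEEP_WITH_DESCENDANTS" = "+D",
                 "KEEP_WITH_ANCESTORS" = "+U", "EXCLUDE" = "-")

empty_instructions <- function() {
  tibble::tibble(mode = character(), target = character(),
                 new_parent = character(), comment = character())
}

#' Parse slimming instructions
#'
#' @param text instruction file content (or path to a `.iris` file).
#' @return tibble with one row per directive, in file order: `mode`
#'   (`KEEP`, `KEEP_WITH_DESCENDANTS`, `KEEP_WITH_ANCESTORS`, `EXCLUDE`),
#'   `target` (IRI), `new_parent` (IRI or `NA`), `comment` (text or `NA`).
#' @export
#' @examples
#' parse_instructions(paste0(
#'   "+D(http://purl.obolibrary.org/obo/IAO_0000030):",
#'   "http://purl.obolibrary.org/obo/UO_0000000 unit"))
parse_instructions <- function(text) {
  if (length(text) == 1 && !grepl("[\n:]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  lines <- strsplit(paste(text, collapse = "\n"), "\r?\n")[[1]]
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec("^(\\+D|\\+U|\\+|-)(?:\\(([^)]*)\\))?:\\s*(\\S+)(?:\\s+(.*))?$", ln))[[1]]
    if (length(m) == 0) {
      stop(sprintf("malformed instruction at line %d: %s", i, ln), call. = FALSE)
    }
    op <- m[[2]]; parent <- m[[3]]; target <- m[[4]]; comment <- m[[5]]
    mode <- names(MODE_TOKENS)[MODE_TOKENS == op]
    if (op == "-" && nzchar(parent)) {
      stop(sprintf("line %d: a remove ('-') instruction cannot carry a new parent", i),
           call. = FALSE)
    }
    if (!is_valid_iri(target)) {
      stop(sprintf("line %d: invalid target IRI '%s'", i, target), call. = FALSE)
    }
    if (nzchar(parent) && !is_valid_iri(parent)) {
      stop(sprintf("line %d: invalid parent IRI '%s'", i, parent), call. = FALSE)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      mode = mode, target = target,
      new_parent = if (nzchar(parent)) parent else NA_character_,
      comment = if (nzchar(comment)) comment else NA_character_
    )
  }
  if (length(rows) == 0) return(empty_instructions())
  dplyr::bind_rows(rows)
}

#' Render instructions back to the file format
#'
#' Inverse of [parse_instructions()]: `parse_instructions(render_instructions(x))`
#' reproduces `x`.
#'
#' @param instructions tibble as returned by [parse_instructions()].
#' @return single string, one directive per line.
#' @export
render_instructions <- function(instructions) {
  if (nrow(instructions) == 0) return("")
  lines <- vapply(seq_len(nrow(instructions)), function(i) {
    op <- MODE_TOKENS[[instructions$mode[[i]]]]
    parent <- instructions$new_parent[[i]]
    comment <- instructions$comment[[i]]
    paste0(op,
           if (!is.na(parent)) sprintf("(%s)", parent) else "",
           ":", instructions$target[[i]],
           if (!is.na(comment)) paste0(" ", comment) else "")
  }, character(1))
  paste(lines, collapse = "\n")
}

#' Parse a slimming configuration
#'
#' Properties-style `key=value` file naming the input ontology, the
#' instruction file, the ontology IRI of the resulting slim and the
#' output path. Recognized keys:
#'
#' * `owl` — input ontology location (required)
#' * `iris` — instruction file location (required)
#' * `slim` — ontology IRI for the slimmed output (required)
#' * `out` — output file path (optional; defaults from `slim` basename)
#' * `anno.include`, `anno.exclude` — comma-separated annotation property
#'   IRIs to keep / drop (optional, mutually exclusive sets)
#'
#' Lines starting with `#` or `!` are comments.
#'
#' @param text configuration content (or path to a `.props` file).
#' @return object of class `slim_config`: a list with fields
#'   `input_location`, `instructions_location`, `output_ontology_iri`,
#'   `output_path`, `annotation_include`, `annotation_exclude`.
#' @export
parse_properties <- function(text) {
  if (length(text) == 1 && !grepl("[\n=]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  lines <- strsplit(paste(text, collapse = "\n"), "\r?\n")[[1]]
  kv <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "!")) next
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq == -1) {
      stop(sprintf("malformed property at line %d (no '='): %s", i, ln), call. = FALSE)
    }
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substring(ln, eq + 1))
    if (key %in% names(kv)) {
      stop(sprintf("duplicate configuration key '%s' at line %d", key, i), call. = FALSE)
    }
    kv[[key]] <- val
  }
  for (req in c("owl", "iris", "slim")) {
    if (is.null(kv[[req]]) || !nzchar(kv[[req]])) {
      stop(sprintf("configuration error: required key '%s' is missing", req), call. = FALSE)
    }
  }
  assert_iri(kv$slim, "slim output ontology IRI")
  split_iris <- function(x) {
    if (is.null(x)) return(character())
    out <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    out[nzchar(out)]
  }
  inc <- split_iris(kv$anno.include)
  exc <- split_iris(kv$anno.exclude)
  both <- intersect(inc, exc)
  if (length(both) > 0) {
    stop(sprintf("configuration error: anno.include and anno.exclude overlap: %s",
                 paste(both, collapse = ", ")), call. = FALSE)
  }
  structure(list(
    input_location = kv$owl,
    instructions_location = kv$iris,
    output_ontology_iri = kv$slim,
    output_path = kv$out %||% basename(kv$slim),
    annotation_include = inc,
    annotation_exclude = exc
  ), class = "slim_config")
}

#' Build a slim configuration in code
#'
#' Programmatic equivalent of [parse_properties()].
#'
#' @param input_location input ontology path or IRI.
#' @param instructions_location instruction file path.
#' @param output_ontology_iri ontology IRI of the slim.
#' @param output_path output file path.
#' @param annotation_include,annotation_exclude optional annotation
#'   property IRI filters (disjoint; the include list, when non-empty,
#'   wins).
#' @return a `slim_config` object.
#' @export
slim_config <- function(input_location, instructions_location,
                        output_ontology_iri, output_path = basename(output_ontology_iri),
                        annotation_include = character(),
                        annotation_exclude = character()) {
  assert_iri(output_ontology_iri, "slim output ontology IRI")
  if (length(intersect(annotation_include, annotation_exclude)) > 0) {
    stop("annotation_include and annotation_exclude must be disjoint", call. = FALSE)
  }
  structure(list(
    input_location = input_location,
    instructions_location = instructions_location,
    output_ontology_iri = output_ontology_iri,
    output_path = output_path,
    annotation_include = annotation_include,
    annotation_exclude = annotation_exclude
  ), class = "slim_config")
}

#' @export
print.slim_config <- function(x, ...) {
  cat("<slim_config>\n")
  cat("  input:        ", x$input_location, "\n", sep = "")
  cat("  instructions: ", x$instructions_location, "\n", sep = "")
  cat("  slim IRI:     ", x$output_ontology_iri, "\n", sep = "")
  cat("  output path:  ", x$output_path, "\n", sep = "")
  invisible(x)
}
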