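# Readers and writers for the OWL subset: RDF/XML (primary, as published
# by the OBO ecosystem) and a flat full-IRI Turtle dialect. Output is
# deterministic — entities sorted by IRI, then property, then value — so
# identical ontologies serialize to byte-identical text.


#' Read an ontology from RDF/XML or Turtle
#'
#' Captures `owl:Class` declarations, named-class `rdfs:subClassOf`
#' assertions, annotation assertions, `owl:imports` and the ontology
#' header structurally. Any other axiom (restrictions, equivalences,
#' reified `owl:Axiom` blocks, ...) is preserved as an opaque payload with
#' an index of the entity IRIs it references.
#'
#' @param source path to a file, or the serialized text itself.
#' @param format `"rdfxml"` or `"turtle"`.
#' @return an [ontology()].
#' @export
read_ontology <- function(source, format = c("rdfxml", "turtle")) {
  format <- match.arg(format)
  text <- read_source_text(source)
  if (format == "rdfxml") read_rdfxml(text) else read_turtle(text)
}

read_source_text <- function(source) {
  if (length(source) == 1 && !grepl("[<\n]", source) && file.exists(source)) {
    paste(readLines(source, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
}

#' Serialize an ontology
#'
#' Deterministic serialization: two calls on the same ontology produce
#' byte-identical text, and `read_ontology(write_ontology(o))` is
#' structurally isomorphic to `o`. Turtle output covers the structural
#' subset only; ontologies carrying opaque axioms must use RDF/XML.
#'
#' @param ont an [ontology()].
#' @param format `"rdfxml"` or `"turtle"`.
#' @param path optional file path; when given, text is written atomically
#'   (temporary file then rename) and returned invisibly.
#' @return the serialized text (invisibly when `path` is given).
#' @export
write_ontology <- function(ont, format = c("rdfxml", "turtle"), path = NULL) {
  format <- match.arg(format)
  stopifnot(is_ontology(ont))
  text <- if (format == "rdfxml") write_rdfxml(ont) else write_turtle(ont)
  if (!is.null(path)) {
    write_atomic(text, path)
    return(invisible(text))
  }
  text
}

write_atomic <- function(text, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  con <- file(tmp, open = "wb")
  writeLines(text, con, sep = "", useBytes = TRUE)
  close(con)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# ---- RDF/XML reading ---------------------------------------------------

read_rdfxml <- function(text) {
  doc <- tryCatch(suppressWarnings(xml2::read_xml(text)),
                  error = function(e) stop(sprintf("RDF/XML parse failure: %s",
                                                   conditionMessage(e)), call. = FALSE))
  nsmap <- xml2::xml_ns(doc)
  top <- xml2::xml_children(doc)

  classes <- character()
  edges_child <- character(); edges_parent <- character()
  ann <- list()
  ont_ann <- list()
  imports <- character()
  ontology_iri <- NULL; version_iri <- NULL
  ann_props <- character(); obj_props <- character()
  axioms <- list()

  add_ann <- function(subject, property, value, lang) {
    ann[[length(ann) + 1]] <<- list(subject = subject, property = property,
                                    value = value, lang = lang)
  }

  for (node in top) {
    ename <- expand_qname(xml2::xml_name(node, ns = nsmap), nsmap)
    about <- rdf_attr(node, nsmap, "about")
    if (!is.null(about)) check_absolute(about)

    if (identical(ename, IRI_OWL_ONTOLOGY)) {
      ontology_iri <- about
      for (ch in xml2::xml_children(node)) {
        pn <- expand_qname(xml2::xml_name(ch, ns = nsmap), nsmap)
        res <- rdf_attr(ch, nsmap, "resource")
        if (identical(pn, IRI_OWL_IMPORTS)) {
          imports <- c(imports, res)
        } else if (identical(pn, IRI_OWL_VERSION)) {
          version_iri <- res
        } else {
          val <- res %||% xml2::xml_text(ch)
          ont_ann[[length(ont_ann) + 1]] <-
            list(property = pn, value = val, lang = xml_lang(ch))
        }
      }
    } else if (identical(ename, IRI_OWL_ANNPROP)) {
      ann_props <- c(ann_props, about)
    } else if (identical(ename, IRI_OWL_OBJPROP)) {
      obj_props <- c(obj_props, about)
    } else if (identical(ename, IRI_OWL_CLASS) ||
               (identical(ename, paste0(NS$rdf, "Description")) && node_is_class(node, nsmap))) {
      if (is.null(about)) { # anonymous class: opaque
        axioms[[length(axioms) + 1]] <- capture_axiom(node, nsmap)
        next
      }
      classes <- c(classes, about)
      for (ch in xml2::xml_children(node)) {
        pn <- expand_qname(xml2::xml_name(ch, ns = nsmap), nsmap)
        res <- rdf_attr(ch, nsmap, "resource")
        has_children <- length(xml2::xml_children(ch)) > 0
        if (identical(pn, IRI_SUBCLASS_OF) && !is.null(res) && !has_children) {
          check_absolute(res)
          edges_child <- c(edges_child, about)
          edges_parent <- c(edges_parent, res)
        } else if (identical(pn, IRI_RDF_TYPE)) {
          next
        } else if (has_children ||
                   (is.null(res) && pn %in% c(IRI_SUBCLASS_OF,
                                              paste0(NS$owl, "equivalentClass"),
                                              paste0(NS$owl, "disjointWith")))) {
          axioms[[length(axioms) + 1]] <- capture_axiom(ch, nsmap, subject = about)
        } else if (!is.null(res)) {
          add_ann(about, pn, res, NA_character_)
        } else {
          add_ann(about, pn, xml2::xml_text(ch), xml_lang(ch))
        }
      }
    } else {
      # reified owl:Axiom blocks, datatype properties, individuals, ...
      axioms[[length(axioms) + 1]] <- capture_axiom(node, nsmap)
    }
  }

  ontology(
    ontology_iri = ontology_iri,
    version_iri = version_iri,
    imports = imports,
    classes = classes,
    edges = tibble::tibble(child = edges_child, parent = edges_parent),
    annotations = bind_records(ann),
    ontology_annotations = if (length(ont_ann) > 0) {
      tibble::tibble(property = vapply(ont_ann, `[[`, "", "property"),
                     value = vapply(ont_ann, `[[`, "", "value"),
                     lang = vapply(ont_ann, `[[`, "", "lang"))
    } else NULL,
    annotation_properties = ann_props,
    object_properties = obj_props,
    opaque_axioms = if (length(axioms) > 0) {
      tibble::tibble(payload = vapply(axioms, `[[`, "", "payload"),
                     entities = lapply(axioms, `[[`, "entities"))
    } else empty_axioms()
  )
}

bind_records <- function(recs) {
  if (length(recs) == 0) return(empty_annotations())
  tibble::tibble(
    subject = vapply(recs, `[[`, "", "subject"),
    property = vapply(recs, `[[`, "", "property"),
    value = vapply(recs, `[[`, "", "value"),
    lang = vapply(recs, `[[`, "", "lang")
  )
}

check_absolute <- function(iri) {
  if (!is_valid_iri(iri)) {
    stop(sprintf("relative or malformed IRI in document: '%s'", iri), call. = FALSE)
  }
  invisible(iri)
}

node_is_class <- function(node, nsmap) {
  for (ch in xml2::xml_children(node)) {
    pn <- expand_qname(xml2::xml_name(ch, ns = nsmap), nsmap)
    if (identical(pn, IRI_RDF_TYPE) &&
        identical(rdf_attr(ch, nsmap, "resource"), IRI_OWL_CLASS)) return(TRUE)
  }
  FALSE
}

# Expand "prefix:local" (prefixes as xml2 reports them for this document)
# to a full IRI. Names without a prefix have no namespace.
expand_qname <- function(qname, nsmap) {
  if (!grepl(":", qname, fixed = TRUE)) return(qname)
  parts <- strsplit(qname, ":", fixed = TRUE)[[1]]
  uri <- nsmap[[parts[[1]]]]
  if (is.null(uri) || is.na(uri)) return(qname)
  paste0(uri, paste(parts[-1], collapse = ":"))
}

# Fetch an attribute in the RDF namespace regardless of document prefix.
rdf_attr <- function(node, nsmap, local) {
  attrs <- xml2::xml_attrs(node, ns = nsmap)
  if (length(attrs) == 0) return(NULL)
  target <- paste0(NS$rdf, local)
  expanded <- vapply(names(attrs), expand_qname, character(1), nsmap = nsmap)
  hit <- which(expanded == target)
  if (length(hit) == 0) NULL else unname(attrs[[hit[[1]]]])
}

xml_lang <- function(node) {
  lang <- xml2::xml_attr(node, "xml:lang")
  if (is.na(lang)) NA_character_ else lang
}

# ---- opaque axiom capture ---------------------------------------------

# Canonical single-line serialization of an axiom-bearing XML node:
# fixed prefixes for the well-known namespaces, inline xmlns for others,
# attributes sorted by expanded name. Re-capturing a written payload
# reproduces it byte for byte.
capture_axiom <- function(node, nsmap, subject = NULL) {
  inner <- canon_xml(node, nsmap)
  payload <- if (is.null(subject)) {
    inner
  } else {
    sprintf("<owl:Class rdf:about=\"%s\">%s</owl:Class>", xml_escape_attr(subject), inner)
  }
  ents <- collect_entities(node, nsmap)
  if (!is.null(subject)) ents <- c(subject, ents)
  list(payload = payload, entities = sort(unique(ents)))
}

CANON_PREFIXES <- c(
  "http://www.w3.org/1999/02/22-rdf-syntax-ns#" = "rdf",
  "http://www.w3.org/2000/01/rdf-schema#" = "rdfs",
  "http://www.w3.org/2002/07/owl#" = "owl",
  "http://www.geneontology.org/formats/oboInOwl#" = "oboInOwl",
  "http://purl.org/dc/terms/" = "dcterms",
  "http://purl.obolibrary.org/obo/" = "obo"
)

canon_prefix <- function(ns) {
  if (!is.null(ns) && nzchar(ns) && ns %in% names(CANON_PREFIXES)) CANON_PREFIXES[[ns]] else NULL
}

split_expanded <- function(expanded) {
  m <- regexpr("[#/](?=[^#/]*$)", expanded, perl = TRUE)
  if (m == -1) return(list(ns = "", local = expanded))
  list(ns = substr(expanded, 1, m), local = substring(expanded, m + 1))
}

canon_xml <- function(node, nsmap) {
  ename <- expand_qname(xml2::xml_name(node, ns = nsmap), nsmap)
  sp <- split_expanded(ename)
  known <- canon_prefix(sp$ns)
  tag <- if (!is.null(known)) paste0(known, ":", sp$local) else sp$local
  xmlns <- if (is.null(known) && nzchar(sp$ns)) sprintf(" xmlns=\"%s\"", xml_escape_attr(sp$ns)) else ""

  attrs <- xml2::xml_attrs(node, ns = nsmap)
  attr_strs <- character()
  if (length(attrs) > 0) {
    expanded <- vapply(names(attrs), expand_qname, character(1), nsmap = nsmap)
    ord <- order(expanded)
    for (i in ord) {
      ae <- expanded[[i]]
      asp <- split_expanded(ae)
      aknown <- canon_prefix(asp$ns)
      aname <- if (!is.null(aknown)) {
        paste0(aknown, ":", asp$local)
      } else if (identical(asp$ns, "http://www.w3.org/XML/1998/namespace#") ||
                 grepl("^xml:", names(attrs)[[i]])) {
        paste0("xml:", asp$local)
      } else {
        asp$local
      }
      attr_strs <- c(attr_strs, sprintf(" %s=\"%s\"", aname, xml_escape_attr(attrs[[i]])))
    }
  }
  kids <- xml2::xml_contents(node)
  inner <- character()
  for (k in kids) {
    if (inherits(k, "xml_node") && xml2::xml_type(k) == "element") {
      inner <- c(inner, canon_xml(k, nsmap))
    } else {
      txt <- xml2::xml_text(k)
      if (nzchar(trimws(txt))) inner <- c(inner, xml_escape_text(txt))
    }
  }
  body <- paste(inner, collapse = "")
  if (nzchar(body)) {
    sprintf("<%s%s%s>%s</%s>", tag, xmlns, paste(attr_strs, collapse = ""), body, tag)
  } else {
    sprintf("<%s%s%s/>", tag, xmlns, paste(attr_strs, collapse = ""))
  }
}

collect_entities <- function(node, nsmap) {
  out <- character()
  walk <- function(n) {
    about <- rdf_attr(n, nsmap, "about")
    res <- rdf_attr(n, nsmap, "resource")
    if (!is.null(about) && is_valid_iri(about)) out <<- c(out, about)
    if (!is.null(res) && is_valid_iri(res)) out <<- c(out, res)
    for (k in xml2::xml_children(n)) walk(k)
  }
  walk(node)
  out
}

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  gsub("\"", "&quot;", xml_escape_text(x), fixed = TRUE)
}

# ---- RDF/XML writing ---------------------------------------------------

write_rdfxml <- function(ont) {
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"", NS$rdf, "\"",
           " xmlns:rdfs=\"", NS$rdfs, "\"",
           " xmlns:owl=\"", NS$owl, "\"",
           " xmlns:oboInOwl=\"", NS$oboInOwl, "\"",
           " xmlns:dcterms=\"", NS$dcterms, "\"",
           " xmlns:obo=\"", NS$obo, "\">")
  )
  # ontology header
  hdr_open <- if (is.null(ont$ontology_iri)) {
    "  <owl:Ontology>"
  } else {
    sprintf("  <owl:Ontology rdf:about=\"%s\">", xml_escape_attr(ont$ontology_iri))
  }
  hdr <- hdr_open
  if (!is.null(ont$version_iri)) {
    hdr <- c(hdr, sprintf("    <owl:versionIRI rdf:resource=\"%s\"/>",
                          xml_escape_attr(ont$version_iri)))
  }
  for (im in sort(ont$imports)) {
    hdr <- c(hdr, sprintf("    <owl:imports rdf:resource=\"%s\"/>", xml_escape_attr(im)))
  }
  oa <- dplyr::arrange(ont$ontology_annotations, .data$property, .data$value)
  if (nrow(oa) > 0) {
    for (i in seq_len(nrow(oa))) {
      hdr <- c(hdr, sprintf("    %s", property_element(oa$property[[i]], oa$value[[i]], oa$lang[[i]])))
    }
  }
  out <- c(out, hdr, "  </owl:Ontology>")

  for (p in sort(ont$annotation_properties)) {
    out <- c(out, sprintf("  <owl:AnnotationProperty rdf:about=\"%s\"/>", xml_escape_attr(p)))
  }
  for (p in sort(ont$object_properties)) {
    out <- c(out, sprintf("  <owl:ObjectProperty rdf:about=\"%s\"/>", xml_escape_attr(p)))
  }

  ann_by_subject <- split(seq_len(nrow(ont$annotations)), ont$annotations$subject)
  edges_by_child <- split(ont$edges$parent, ont$edges$child)
  for (cls in sort(ont$classes)) {
    out <- c(out, sprintf("  <owl:Class rdf:about=\"%s\">", xml_escape_attr(cls)))
    for (p in sort(edges_by_child[[cls]] %||% character())) {
      out <- c(out, sprintf("    <rdfs:subClassOf rdf:resource=\"%s\"/>", xml_escape_attr(p)))
    }
    idx <- ann_by_subject[[cls]] %||% integer()
    if (length(idx) > 0) {
      sub <- ont$annotations[idx, , drop = FALSE]
      sub <- dplyr::arrange(sub, .data$property, .data$value)
      for (i in seq_len(nrow(sub))) {
        out <- c(out, sprintf("    %s", property_element(sub$property[[i]], sub$value[[i]], sub$lang[[i]])))
      }
    }
    out <- c(out, "  </owl:Class>")
  }

  # annotations on undeclared subjects (e.g. kept properties)
  stray <- setdiff(unique(ont$annotations$subject), ont$classes)
  for (s in sort(stray)) {
    out <- c(out, sprintf("  <rdf:Description rdf:about=\"%s\">", xml_escape_attr(s)))
    sub <- ont$annotations[ont$annotations$subject == s, , drop = FALSE]
    sub <- dplyr::arrange(sub, .data$property, .data$value)
    for (i in seq_len(nrow(sub))) {
      out <- c(out, sprintf("    %s", property_element(sub$property[[i]], sub$value[[i]], sub$lang[[i]])))
    }
    out <- c(out, "  </rdf:Description>")
  }

  for (pl in sort(ont$opaque_axioms$payload)) {
    out <- c(out, paste0("  ", pl))
  }
  out <- c(out, "</rdf:RDF>", "")
  paste(out, collapse = "\n")
}

# Serialize one annotation as an RDF/XML property element with a
# deterministic prefix; IRI-shaped values become rdf:resource objects.
property_element <- function(property, value, lang) {
  sp <- split_expanded(property)
  pref <- canon_prefix(sp$ns)
  if (!is.null(pref)) {
    tag <- paste0(pref, ":", sp$local)
    xmlns <- ""
  } else {
    tag <- sp$local
    xmlns <- sprintf(" xmlns=\"%s\"", xml_escape_attr(sp$ns))
  }
  if (is_valid_iri(value)) {
    sprintf("<%s%s rdf:resource=\"%s\"/>", tag, xmlns, xml_escape_attr(value))
  } else {
    langattr <- if (!is.na(lang) && nzchar(lang)) sprintf(" xml:lang=\"%s\"", lang) else ""
    sprintf("<%s%s%s>%s</%s>", tag, xmlns, langattr, xml_escape_text(value), tag)
  }
}

# ---- Turtle ------------------------------------------------------------

write_turtle <- function(ont) {
  if (nrow(ont$opaque_axioms) > 0) {
    stop("turtle serialization covers the structural subset only; ",
         "this ontology carries opaque axioms - use rdfxml", call. = FALSE)
  }
  tl <- function(s, p, o_iri = NULL, o_lit = NULL, lang = NA_character_) {
    if (!is.null(o_iri)) {
      sprintf("<%s> <%s> <%s> .", s, p, o_iri)
    } else {
      lit <- gsub("\"", "\\\"", gsub("\\", "\\\\", o_lit, fixed = TRUE), fixed = TRUE)
      lit <- gsub("\n", "\\n", lit, fixed = TRUE)
      tag <- if (!is.na(lang) && nzchar(lang)) paste0("@", lang) else ""
      sprintf("<%s> <%s> \"%s\"%s .", s, p, lit, tag)
    }
  }
  lines <- character()
  subj <- ont$ontology_iri
  if (!is.null(subj)) {
    lines <- c(lines, tl(subj, IRI_RDF_TYPE, IRI_OWL_ONTOLOGY))
    if (!is.null(ont$version_iri)) lines <- c(lines, tl(subj, IRI_OWL_VERSION, ont$version_iri))
    for (im in sort(ont$imports)) lines <- c(lines, tl(subj, IRI_OWL_IMPORTS, im))
    oa <- ont$ontology_annotations
    for (i in seq_len(nrow(oa))) {
      lines <- c(lines, if (is_valid_iri(oa$value[[i]])) {
        tl(subj, oa$property[[i]], o_iri = oa$value[[i]])
      } else {
        tl(subj, oa$property[[i]], o_lit = oa$value[[i]], lang = oa$lang[[i]])
      })
    }
  }
  for (p in sort(ont$annotation_properties)) lines <- c(lines, tl(p, IRI_RDF_TYPE, IRI_OWL_ANNPROP))
  for (p in sort(ont$object_properties)) lines <- c(lines, tl(p, IRI_RDF_TYPE, IRI_OWL_OBJPROP))
  for (cls in sort(ont$classes)) lines <- c(lines, tl(cls, IRI_RDF_TYPE, IRI_OWL_CLASS))
  ed <- dplyr::arrange(ont$edges, .data$child, .data$parent)
  for (i in seq_len(nrow(ed))) lines <- c(lines, tl(ed$child[[i]], IRI_SUBCLASS_OF, ed$parent[[i]]))
  an <- dplyr::arrange(ont$annotations, .data$subject, .data$property, .data$value)
  for (i in seq_len(nrow(an))) {
    lines <- c(lines, if (is_valid_iri(an$value[[i]])) {
      tl(an$subject[[i]], an$property[[i]], o_iri = an$value[[i]])
    } else {
      tl(an$subject[[i]], an$property[[i]], o_lit = an$value[[i]], lang = an$lang[[i]])
    })
  }
  paste(c(sort(lines), ""), collapse = "\n")
}

TTL_TRIPLE_RE <- paste0(
  "^<([^>]+)>\\s+<([^>]+)>\\s+",
  "(?:<([^>]+)>|\"((?:[^\"\\\\]|\\\\.)*)\"(?:@([A-Za-z-]+))?)\\s*\\.\\s*$"
)

read_turtle <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  trips <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec(TTL_TRIPLE_RE, ln, perl = TRUE))[[1]]
    if (length(m) == 0) {
      stop(sprintf("turtle parse failure at line %d: %s", i, ln), call. = FALSE)
    }
    if (nzchar(m[[4]])) {
      trips[[length(trips) + 1]] <- list(s = m[[2]], p = m[[3]], o_iri = m[[4]],
                                         o_lit = NULL, lang = NA_character_)
    } else {
      v <- gsub("\\n", "\n", m[[5]], fixed = TRUE)
      v <- gsub("\\\"", "\"", v, fixed = TRUE)
      v <- gsub("\\\\", "\\", v, fixed = TRUE)
      trips[[length(trips) + 1]] <- list(
        s = m[[2]], p = m[[3]], o_iri = NULL, o_lit = v,
        lang = if (nzchar(m[[6]])) m[[6]] else NA_character_)
    }
  }
  triples_to_ontology(trips)
}

triples_to_ontology <- function(trips) {
  s <- vapply(trips, `[[`, "", "s")
  p <- vapply(trips, `[[`, "", "p")
  o_iri <- vapply(trips, function(t) t$o_iri %||% NA_character_, character(1))
  o_lit <- vapply(trips, function(t) t$o_lit %||% NA_character_, character(1))
  lang <- vapply(trips, function(t) t$lang %||% NA_character_, character(1))

  is_type <- p == IRI_RDF_TYPE
  ontology_iri <- s[is_type & o_iri %in% IRI_OWL_ONTOLOGY][1]
  if (is.na(ontology_iri)) ontology_iri <- NULL
  classes <- s[is_type & o_iri %in% IRI_OWL_CLASS]
  ann_props <- s[is_type & o_iri %in% IRI_OWL_ANNPROP]
  obj_props <- s[is_type & o_iri %in% IRI_OWL_OBJPROP]

  is_edge <- p == IRI_SUBCLASS_OF
  hdr <- !is.null(ontology_iri) & s %in% (ontology_iri %||% "")
  imports <- o_iri[p == IRI_OWL_IMPORTS & hdr]
  version_iri <- o_iri[p == IRI_OWL_VERSION & hdr][1]
  if (is.na(version_iri %||% NA)) version_iri <- NULL

  is_ont_ann <- hdr & !is_type & !is_edge & p != IRI_OWL_IMPORTS & p != IRI_OWL_VERSION
  is_ann <- !hdr & !is_type & !is_edge

  ontology(
    ontology_iri = ontology_iri,
    version_iri = version_iri,
    imports = imports[!is.na(imports)],
    classes = classes,
    edges = tibble::tibble(child = s[is_edge], parent = o_iri[is_edge]),
    annotations = tibble::tibble(
      subject = s[is_ann], property = p[is_ann],
      value = ifelse(is.na(o_iri[is_ann]), o_lit[is_ann], o_iri[is_ann]),
      lang = lang[is_ann]
    ),
    ontology_annotations = if (any(is_ont_ann)) tibble::tibble(
      property = p[is_ont_ann],
      value = ifelse(is.na(o_iri[is_ont_ann]), o_lit[is_ont_ann], o_iri[is_ont_ann]),
      lang = lang[is_ont_ann]
    ) else NULL,
    annotation_properties = ann_props,
    object_properties = obj_props
  )
}

#' Read a local import catalog
#'
#' Two-column tab-separated file mapping import IRIs to local paths
#' (`iri<TAB>path`). Lines starting with `#` and blank lines are skipped.
#'
#' @param path catalog file path.
#' @return named character vector (IRI -> path) usable as a
#'   [resolve_imports()] resolver.
#' @export
read_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop(sprintf("malformed catalog line (expected iri<TAB>path): %s", ln), call. = FALSE)
    }
    out[[parts[[1]]]] <- parts[[2]]
  }
  out
}
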