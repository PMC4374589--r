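# Shared RDF/OWL vocabulary: namespaces and well-known annotation
# property IRIs (OBO conventions), loaded before every other file.

# Well-known annotation property IRIs (OBO conventions).
NS <- list(
  rdf      = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs     = "http://www.w3.org/2000/01/rdf-schema#",
  owl      = "http://www.w3.org/2002/07/owl#",
  oboInOwl = "http://www.geneontology.org/formats/oboInOwl#",
  dcterms  = "http://purl.org/dc/terms/",
  obo      = "http://purl.obolibrary.org/obo/"
)

IRI_LABEL       <- paste0(NS$rdfs, "label")
IRI_COMMENT     <- paste0(NS$rdfs, "comment")
IRI_DEFINITION  <- paste0(NS$obo, "IAO_0000115")
IRI_EXACT_SYN   <- paste0(NS$oboInOwl, "hasExactSynonym")
IRI_RELATED_SYN <- paste0(NS$oboInOwl, "hasRelatedSynonym")
IRI_DBXREF      <- paste0(NS$oboInOwl, "hasDbXref")
IRI_DEPRECATED  <- paste0(NS$owl, "deprecated")
IRI_PUBLISHER   <- paste0(NS$dcterms, "publisher")
IRI_CREATED     <- paste0(NS$dcterms, "created")
IRI_SOURCE      <- paste0(NS$dcterms, "source")

SYNONYM_PROPERTIES <- c(IRI_EXACT_SYN, IRI_RELATED_SYN)

IRI_RDF_TYPE     <- paste0(NS$rdf, "type")
IRI_OWL_CLASS    <- paste0(NS$owl, "Class")
IRI_OWL_ONTOLOGY <- paste0(NS$owl, "Ontology")
IRI_OWL_IMPORTS  <- paste0(NS$owl, "imports")
IRI_OWL_VERSION  <- paste0(NS$owl, "versionIRI")
IRI_SUBCLASS_OF  <- paste0(NS$rdfs, "subClassOf")
IRI_OWL_ANNPROP  <- paste0(NS$owl, "AnnotationProperty")
IRI_OWL_OBJPROP  <- paste0(NS$owl, "ObjectProperty")

# Structural properties never stored as plain annotations.
STRUCTURAL_PROPS <- c(IRI_RDF_TYPE, IRI_SUBCLASS_OF, IRI_OWL_IMPORTS, IRI_OWL_VERSION)

`%||%` <- function(a, b) if (is.null(a)) b else a
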