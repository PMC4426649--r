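#' @rdname OntologyDAG-accessors
#' @export
setGeneric("goTerms", function(x, ...) standardGeneric("goTerms"))

#' @rdname OntologyDAG-accessors
#' @export
setGeneric("goRoots", function(x) standardGeneric("goRoots"))

#' @rdname OntologyDAG-accessors
#' @export
setGeneric("goParents", function(x, id) standardGeneric("goParents"))

#' @rdname OntologyDAG-accessors
#' @export
setGeneric("goNamespace", function(x, id) standardGeneric("goNamespace"))

#' @rdname OntologyDAG-accessors
#' @export
setGeneric("isObsolete", function(x, id) standardGeneric("isObsolete"))

#' @rdname goAncestors
#' @export
setGeneric("goAncestors", function(x, id) standardGeneric("goAncestors"))

#' @rdname goDepth
#' @export
setGeneric("goDepth", function(x, id) standardGeneric("goDepth"))

#' @rdname OrthologGraph-accessors
#' @export
setGeneric("orthoGenes", function(x) standardGeneric("orthoGenes"))

#' @rdname OrthologGraph-accessors
#' @export
setGeneric("orthoEdges", function(x) standardGeneric("orthoEdges"))

#' @rdname termSet
#' @export
setGeneric("termSet", function(x, species, gene) standardGeneric("termSet"))

#' @rdname AnnotationMap-accessors
#' @export
setGeneric("annSpecies", function(x) standardGeneric("annSpecies"))
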