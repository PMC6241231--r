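#' @rdname PharmNetwork-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname PharmNetwork-accessors
#' @export
setGeneric("nodeRoles", function(x) standardGeneric("nodeRoles"))

#' @rdname PharmNetwork-accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname PharmNetwork-accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname PharmNetwork-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname PharmNetwork-accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname PharmNetwork-accessors
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))

#' @rdname networkSummary
#' @export
setGeneric("networkSummary", function(x) standardGeneric("networkSummary"))

#' @rdname AnnotationSet-accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname AnnotationSet-accessors
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))

#' @rdname AnnotationSet-accessors
#' @export
setGeneric("termMembers", function(x) standardGeneric("termMembers"))

#' @rdname AnnotationSet-accessors
#' @export
setGeneric("backgroundSize", function(x) standardGeneric("backgroundSize"))

#' @rdname AnnotationSet-accessors
#' @export
setGeneric("backgroundSymbols", function(x) standardGeneric("backgroundSymbols"))
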