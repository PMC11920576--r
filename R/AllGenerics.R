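#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param object an object of the documented class.
#' @param ... passed to methods.
#' @return the slot value documented with each method.
#' @name secircuit-generics
NULL

#' @rdname secircuit-generics
#' @export
setGeneric("tfName", function(object, ...) standardGeneric("tfName"))

#' @rdname secircuit-generics
#' @export
setGeneric("motifMatrix", function(object, ...) standardGeneric("motifMatrix"))

#' @rdname secircuit-generics
#' @export
setGeneric("enhancerRegions",
           function(object, ...) standardGeneric("enhancerRegions"))

#' @rdname secircuit-generics
#' @export
setGeneric("constituents",
           function(object, ...) standardGeneric("constituents"))

#' @rdname secircuit-generics
#' @export
setGeneric("enhancerScores",
           function(object, ...) standardGeneric("enhancerScores"))

#' @rdname secircuit-generics
#' @export
setGeneric("superEnhancers",
           function(object, ...) standardGeneric("superEnhancers"))

#' @rdname secircuit-generics
#' @export
setGeneric("cutoffScore", function(object, ...) standardGeneric("cutoffScore"))

#' @rdname secircuit-generics
#' @export
setGeneric("nSuper", function(object, ...) standardGeneric("nSuper"))

#' @rdname secircuit-generics
#' @export
setGeneric("isDegenerate",
           function(object, ...) standardGeneric("isDegenerate"))

#' @rdname secircuit-generics
#' @export
setGeneric("graphNodes", function(object, ...) standardGeneric("graphNodes"))

#' @rdname secircuit-generics
#' @export
setGeneric("graphEdges", function(object, ...) standardGeneric("graphEdges"))

#' @rdname secircuit-generics
#' @export
setGeneric("inDegree", function(object, ...) standardGeneric("inDegree"))

#' @rdname secircuit-generics
#' @export
setGeneric("outDegree", function(object, ...) standardGeneric("outDegree"))
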