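#' @import methods
NULL

#' @rdname kgAccessors
#' @export
setGeneric("kgNodes", function(x) standardGeneric("kgNodes"))

#' @rdname kgAccessors
#' @export
setGeneric("kgTriples", function(x) standardGeneric("kgTriples"))

#' @rdname kgAccessors
#' @export
setGeneric("typeVocabulary", function(x) standardGeneric("typeVocabulary"))

#' @rdname kgAccessors
#' @export
setGeneric("relationVocabulary", function(x) standardGeneric("relationVocabulary"))

#' @rdname neighborhood
#' @export
setGeneric("neighborhood", function(x, cui, depth = 1L) standardGeneric("neighborhood"))

#' @rdname nodesOfType
#' @export
setGeneric("nodesOfType", function(x, nodeType) standardGeneric("nodesOfType"))

#' @rdname vennAccessors
#' @export
setGeneric("vennRegions", function(x) standardGeneric("vennRegions"))

#' @rdname vennAccessors
#' @export
setGeneric("vennTotals", function(x) standardGeneric("vennTotals"))

#' @rdname profileAccessors
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname profileAccessors
#' @export
setGeneric("profileNormalized", function(x) standardGeneric("profileNormalized"))

#' @rdname profileAccessors
#' @export
setGeneric("profileZscores", function(x) standardGeneric("profileZscores"))

#' @rdname profileAccessors
#' @export
setGeneric("profileOverall", function(x) standardGeneric("profileOverall"))
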