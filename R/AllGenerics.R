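#' @rdname SpliceArraySet-accessors
#' @export
setGeneric("expressionIndex", function(x) standardGeneric("expressionIndex"))

#' @rdname SpliceArraySet-accessors
#' @export
setGeneric("dabgMatrix", function(x) standardGeneric("dabgMatrix"))

#' @rdname SpliceArraySet-accessors
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname SpliceArraySet-accessors
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))

#' @rdname SpliceArraySet-accessors
#' @export
setGeneric("exonAnnotation", function(x) standardGeneric("exonAnnotation"))

#' @rdname SpliceArraySet-accessors
#' @export
setGeneric("junctionAnnotation", function(x) standardGeneric("junctionAnnotation"))

#' @rdname SplicingCalls-accessors
#' @export
setGeneric("callTable", function(x) standardGeneric("callTable"))

#' @rdname SplicingCalls-accessors
#' @export
setGeneric("junctionStats", function(x) standardGeneric("junctionStats"))

#' @rdname SplicingCalls-accessors
#' @export
setGeneric("geneSummary", function(x) standardGeneric("geneSummary"))

#' @rdname SplicingCalls-accessors
#' @export
setGeneric("geneIndex", function(x) standardGeneric("geneIndex"))

#' @rdname SplicingCalls-accessors
#' @export
setGeneric("callThresholds", function(x) standardGeneric("callThresholds"))
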