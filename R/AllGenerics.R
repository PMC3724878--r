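#' @rdname ThresholdNetwork-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname ThresholdNetwork-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname ThresholdNetwork-accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname ThresholdNetwork-accessors
#' @export
setGeneric("inputNodes", function(x) standardGeneric("inputNodes"))

#' @rdname ThresholdNetwork-accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname ThresholdNetwork-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname ThresholdNetwork-accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname Attractor-accessors
#' @export
setGeneric("attractorStates", function(x) standardGeneric("attractorStates"))

#' @rdname Attractor-accessors
#' @export
setGeneric("attractorKey", function(x) standardGeneric("attractorKey"))

#' @rdname Attractor-accessors
#' @export
setGeneric("attractorKind", function(x) standardGeneric("attractorKind"))

#' @rdname Attractor-accessors
#' @export
setGeneric("period", function(x) standardGeneric("period"))

#' @rdname PerturbedModel
#' @export
setGeneric("baseNetwork", function(x) standardGeneric("baseNetwork"))

#' @rdname PerturbedModel
#' @export
setGeneric("clamps", function(x) standardGeneric("clamps"))
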