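#' @rdname otuCounts
#' @export
setGeneric("otuCounts", function(x, ...) standardGeneric("otuCounts"))

#' @rdname relAbundance
#' @export
setGeneric("relAbundance", function(x, ...) standardGeneric("relAbundance"))

#' @rdname accessors
#' @export
setGeneric("replicateDesign",
           function(x, ...) standardGeneric("replicateDesign"))

#' @rdname accessors
#' @export
setGeneric("biomassCopies", function(x, ...) standardGeneric("biomassCopies"))

#' @rdname accessors
#' @export
setGeneric("taxonomyLabels", function(x, ...) standardGeneric("taxonomyLabels"))

#' @rdname distance-accessors
#' @export
setGeneric("intraDistances", function(x) standardGeneric("intraDistances"))

#' @rdname distance-accessors
#' @export
setGeneric("interDistances", function(x) standardGeneric("interDistances"))

#' @rdname distance-accessors
#' @export
setGeneric("distanceOverlap", function(x) standardGeneric("distanceOverlap"))

#' @rdname TransitionFit-accessors
#' @export
setGeneric("transitionMidpoint",
           function(x) standardGeneric("transitionMidpoint"))

#' @rdname TransitionFit-accessors
#' @export
setGeneric("transitionRange", function(x) standardGeneric("transitionRange"))
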