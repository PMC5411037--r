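#' @rdname accessors
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))
#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("popNames", function(x) standardGeneric("popNames"))
#' @rdname accessors
#' @export
setGeneric("nSeq", function(x) standardGeneric("nSeq"))
#' @rdname accessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))
#' @rdname accessors
#' @export
setGeneric("statMatrix", function(x) standardGeneric("statMatrix"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setGeneric("fixationIndices", function(x) standardGeneric("fixationIndices"))
#' @rdname accessors
#' @export
setGeneric("varianceComponents",
           function(x) standardGeneric("varianceComponents"))
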