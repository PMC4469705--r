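#' @rdname BarcodeSet-class
#' @param x,object an object.
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))

#' @rdname BarcodeSet-class
#' @export
setGeneric("codeMatrix", function(x) standardGeneric("codeMatrix"))

#' @rdname BarcodeSet-class
#' @export
setGeneric("barcodeLength", function(x) standardGeneric("barcodeLength"))

#' @rdname CbcMatrix-class
#' @export
setGeneric("cbcCounts", function(x) standardGeneric("cbcCounts"))

#' @rdname CbcMatrix-class
#' @export
setGeneric("hcbcCounts", function(x) standardGeneric("hcbcCounts"))

#' @rdname SpeciesPartition-class
#' @export
setGeneric("speciesBlocks", function(x) standardGeneric("speciesBlocks"))

#' @rdname SpeciesPartition-class
#' @export
setGeneric("conflictFlags", function(x) standardGeneric("conflictFlags"))

#' @rdname PairTable-class
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))
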