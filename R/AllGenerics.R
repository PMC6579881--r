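#' @rdname CytoEvents-class
#' @param object,x a package object
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname CytoEvents-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname CytoEvents-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname CytoEvents-class
#' @export
setGeneric("intensityScale", function(x) standardGeneric("intensityScale"))

#' @rdname CytoEvents-class
#' @export
setGeneric("acquisitionTime", function(x) standardGeneric("acquisitionTime"))

#' @rdname BarcodeScheme-class
#' @export
setGeneric("nCodes", function(x) standardGeneric("nCodes"))

#' @rdname BarcodeScheme-class
#' @export
setGeneric("codeChannels", function(x, codeId) standardGeneric("codeChannels"))

#' @rdname DebarcodeResult-class
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname DebarcodeResult-class
#' @export
setGeneric("perCodeCounts", function(x) standardGeneric("perCodeCounts"))

#' @rdname SubsetLabeling-class
#' @export
setGeneric("labels", function(object, ...) standardGeneric("labels"))

#' @rdname SubsetLabeling-class
#' @export
setGeneric("labelCounts", function(x) standardGeneric("labelCounts"))

#' @rdname AofReport-class
#' @export
setGeneric("aofMatrix", function(x) standardGeneric("aofMatrix"))

#' @rdname AofReport-class
#' @export
setGeneric("sampleQuality", function(x) standardGeneric("sampleQuality"))
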