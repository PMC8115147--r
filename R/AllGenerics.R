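#' @import methods
NULL

#' @rdname LarynxPhantom-class
#' @param object,x an object.
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))

#' @rdname LarynxPhantom-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname LarynxPhantom-class
#' @export
setGeneric("lesionLabel", function(x) standardGeneric("lesionLabel"))

#' @rdname FrameSequence-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameSequence-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("glottisMask", function(x) standardGeneric("glottisMask"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("cordMasks", function(x) standardGeneric("cordMasks"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("cordContours", function(x) standardGeneric("cordContours"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("cordIterations", function(x) standardGeneric("cordIterations"))

#' @rdname EntropyTrace-class
#' @export
setGeneric("entropyDifferences", function(x) standardGeneric("entropyDifferences"))

#' @rdname EntropyTrace-class
#' @export
setGeneric("optimalIteration", function(x) standardGeneric("optimalIteration"))
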