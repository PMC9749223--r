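#' @rdname FrameStack-class
#' @param object,x a `FrameStack`
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname FrameStack-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname FrameStack-class
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname FrameStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameStack-class
#' @export
setGeneric("fieldOfView", function(x) standardGeneric("fieldOfView"))

#' @rdname EigenwormBasis-class
#' @export
setGeneric("eigenworms", function(x) standardGeneric("eigenworms"))

#' @rdname EigenwormBasis-class
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname EigenwormBasis-class
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname PostureLibrary-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname PostureLibrary-class
#' @export
setGeneric("mirrorPairs", function(x) standardGeneric("mirrorPairs"))

#' @rdname PostureLibrary-class
#' @export
setGeneric("postureClasses", function(x) standardGeneric("postureClasses"))

#' @rdname PostureLibrary-class
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname PostureLibrary-class
#' @export
setGeneric("classRepresentatives", function(x) standardGeneric("classRepresentatives"))
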