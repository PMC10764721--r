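#' @rdname RGBImage-class
#' @param x an object.
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname IntensityMap-class
#' @param x an object.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname IntensityMap-class
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))

#' @rdname BinaryMask-class
#' @param x an object.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname IntensityHistogram-class
#' @param x an object.
#' @export
setGeneric("histBreaks", function(x) standardGeneric("histBreaks"))

#' @rdname IntensityHistogram-class
#' @export
setGeneric("histCounts", function(x) standardGeneric("histCounts"))

#' @rdname ThresholdResult-class
#' @param x an object.
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname ThresholdResult-class
#' @export
setGeneric("betweenClassVariance",
           function(x) standardGeneric("betweenClassVariance"))

#' @rdname ThresholdResult-class
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname TissueSegmentation-class
#' @param x an object.
#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))

#' @rdname TissueSegmentation-class
#' @export
setGeneric("tissueFraction", function(x) standardGeneric("tissueFraction"))

#' @rdname TissueSegmentation-class
#' @export
setGeneric("segMethod", function(x) standardGeneric("segMethod"))

#' @rdname TissueSegmentation-class
#' @export
setGeneric("reportList", function(x) standardGeneric("reportList"))

#' @rdname SyntheticSlide-class
#' @param x an object.
#' @export
setGeneric("slideImage", function(x) standardGeneric("slideImage"))

#' @rdname SyntheticSlide-class
#' @export
setGeneric("truthMasks", function(x) standardGeneric("truthMasks"))

#' @rdname SyntheticSlide-class
#' @export
setGeneric("slideSpec", function(x) standardGeneric("slideSpec"))

#' @rdname SyntheticSlide-class
#' @export
setGeneric("slideCategory", function(x) standardGeneric("slideCategory"))
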