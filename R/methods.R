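# Accessors, dim and show methods for the core classes.

#' @rdname RGBImage-class
#' @export
setMethod("pixelData", "RGBImage", function(x) x@data)

#' @rdname RGBImage-class
#' @export
setMethod("dim", "RGBImage", function(x) dim(x@data)[1:2])

#' @rdname IntensityMap-class
#' @export
setMethod("mapValues", "IntensityMap", function(x) x@values)

#' @rdname IntensityMap-class
#' @export
setMethod("mapKind", "IntensityMap", function(x) x@kind)

#' @rdname IntensityMap-class
#' @export
setMethod("dim", "IntensityMap", function(x) dim(x@values))

#' @rdname BinaryMask-class
#' @export
setMethod("maskMatrix", "BinaryMask", function(x) x@labels)

#' @rdname BinaryMask-class
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@labels))

#' @rdname IntensityHistogram-class
#' @export
setMethod("histBreaks", "IntensityHistogram", function(x) x@breaks)

#' @rdname IntensityHistogram-class
#' @export
setMethod("histCounts", "IntensityHistogram", function(x) x@counts)

#' @rdname ThresholdResult-class
#' @export
setMethod("thresholdValue", "ThresholdResult", function(x) x@threshold)

#' @rdname ThresholdResult-class
#' @export
setMethod("betweenClassVariance", "ThresholdResult",
          function(x) x@betweenClassVariance)

#' @rdname ThresholdResult-class
#' @export
setMethod("isDegenerate", "ThresholdResult", function(x) x@degenerate)

#' @rdname TissueSegmentation-class
#' @export
setMethod("tissueMask", "TissueSegmentation", function(x) x@mask)

#' @rdname TissueSegmentation-class
#' @export
setMethod("tissueFraction", "TissueSegmentation", function(x) x@tissueFraction)

#' @rdname TissueSegmentation-class
#' @export
setMethod("segMethod", "TissueSegmentation", function(x) x@method)

#' @rdname TissueSegmentation-class
#' @export
setMethod("isDegenerate", "TissueSegmentation",
          function(x) x@thresholdResult@degenerate)

#' Report of a segmentation as a plain list (JSON-ready)
#' @rdname TissueSegmentation-class
#' @export
setMethod("reportList", "TissueSegmentation", function(x) {
    list(schemaVersion = 1L,
         method = x@method,
         threshold = x@thresholdResult@threshold,
         betweenClassVariance = x@thresholdResult@betweenClassVariance,
         degenerate = x@thresholdResult@degenerate,
         tissueFraction = x@tissueFraction,
         nBins = x@nBins,
         histogramDomain = x@histRange,
         maskShape = as.integer(dim(x@mask)),
         sourcePath = x@sourcePath)
})

#' @rdname SyntheticSlide-class
#' @export
setMethod("slideImage", "SyntheticSlide", function(x) x@image)

#' @rdname SyntheticSlide-class
#' @export
setMethod("truthMasks", "SyntheticSlide", function(x) x@truth)

#' @rdname SyntheticSlide-class
#' @export
setMethod("slideSpec", "SyntheticSlide", function(x) x@spec)

#' Artefact category of a synthetic slide
#'
#' `"pen"` when the spec draws pen strokes, `"scanner"` when it draws scanner
#' blobs or a bounding box (and no pens), `"clean"` otherwise.
#' @rdname SyntheticSlide-class
#' @export
setMethod("slideCategory", "SyntheticSlide", function(x) {
    s <- x@spec
    if (length(s@penStrokes) > 0L) "pen"
    else if (s@scannerBlobs > 0L || s@boundingBox) "scanner"
    else "clean"
})

setMethod("show", "RGBImage", function(object) {
    d <- dim(object@data)
    cat(sprintf("RGBImage: %d x %d pixels, 3 channels in [0, 1]\n",
                d[1L], d[2L]))
    cat(sprintf("  channel means (R, G, B): %.3f, %.3f, %.3f\n",
                mean(object@data[, , 1L]), mean(object@data[, , 2L]),
                mean(object@data[, , 3L])))
})

setMethod("show", "IntensityMap", function(object) {
    cat(sprintf("IntensityMap (%s): %d x %d, range [%.4g, %.4g]\n",
                object@kind, nrow(object@values), ncol(object@values),
                min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
    cat(sprintf("BinaryMask: %d x %d, %.1f%% TRUE\n",
                nrow(object@labels), ncol(object@labels),
                100 * mean(object@labels)))
})

setMethod("show", "ThresholdResult", function(object) {
    cat(sprintf(
        "ThresholdResult: threshold = %.6g, sigma_b^2 = %.6g%s\n",
        object@threshold, object@betweenClassVariance,
        if (object@degenerate) " (degenerate)" else ""))
})

setMethod("show", "IntensityHistogram", function(object) {
    cat(sprintf("IntensityHistogram: %d bins over [%.4g, %.4g], %d pixels\n",
                length(object@counts), object@breaks[1L],
                object@breaks[length(object@breaks)],
                sum(object@counts)))
})

setMethod("show", "TissueSegmentation", function(object) {
    cat(sprintf("TissueSegmentation (%s)\n", object@method))
    cat(sprintf("  threshold: %.6g%s | tissue fraction: %.3f | bins: %d\n",
                object@thresholdResult@threshold,
                if (object@thresholdResult@degenerate) " (degenerate)" else "",
                object@tissueFraction, object@nBins))
})

setMethod("show", "SlideSpec", function(object) {
    pens <- if (length(object@penStrokes) == 0L) "none" else
        paste(vapply(object@penStrokes, function(s)
            sprintf("%s(%gpx)", s$colour, s$width), ""), collapse = ", ")
    cat(sprintf(
        "SlideSpec: %d x %d, %d tissue blob(s), pens: %s, box: %s, scanner blobs: %d, seed %d\n",
        object@height, object@width, object@tissueBlobs, pens,
        object@boundingBox, object@scannerBlobs, object@seed))
})

setMethod("show", "SyntheticSlide", function(object) {
    cat("SyntheticSlide\n  ")
    show(object@spec)
    fr <- vapply(object@truth, function(m) mean(m@labels), 0)
    cat("  class fractions:",
        paste(sprintf("%s %.3f", names(fr), fr), collapse = ", "), "\n")
})

setMethod("show", "EvaluationRecord", function(object) {
    cat(sprintf(
        "EvaluationRecord: dice %.3f, recall %.3f, incl (bg/pen/box/scan) %.3f/%.3f/%.3f/%.3f, verdict %s\n",
        object@dice, object@tissueRecall, object@backgroundInclusion,
        object@penInclusion, object@boxInclusion, object@scannerInclusion,
        object@verdict))
})

setMethod("show", "CubeMembership", function(object) {
    cat(sprintf(
        "CubeMembership: resolution %d, %d / %d points with T > 0 (%.4f)\n",
        object@resolution, object@memberCount, object@resolution^3,
        object@memberFraction))
})
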