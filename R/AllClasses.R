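#' @import methods
NULL

.HE_KINDS <- c("he_transform", "luminance")
.PEN_COLOURS <- c("blue", "green", "black", "red", "orange", "pink")
.TRUTH_CLASSES <- c("tissue", "background", "pen", "box", "scanner")

#' RGBImage: a normalized three-channel raster
#'
#' Holds a height x width x 3 array of red, green and blue planes with every
#' value a finite float in \[0, 1\]. This is the canonical in-memory form of a
#' slide overview; [normalizeImage()] produces it from integer rasters and
#' [readRGBImage()] / [extractOverview()] from files.
#'
#' @slot data numeric array of dimension height x width x 3, values in \[0,1\].
#' @export
setClass("RGBImage", representation(data = "array"))

setValidity("RGBImage", function(object) {
    d <- object@data
    if (length(dim(d)) != 3L || dim(d)[3L] != 3L)
        return("'data' must be a height x width x 3 array")
    if (any(!is.finite(d)))
        return("all channel values must be finite")
    if (min(d) < 0 || max(d) > 1)
        return("all channel values must lie in [0, 1]")
    TRUE
})

#' IntensityMap: a single-channel representation of an RGB overview
#'
#' Stores either the purple-pink transform T = ReLU(R-G) * ReLU(B-G)
#' (`kind = "he_transform"`) or Rec. 601 luminance (`kind = "luminance"`),
#' aligned pixel-for-pixel with its source [RGBImage-class].
#'
#' @slot values numeric matrix of non-negative intensities.
#' @slot kind either `"he_transform"` or `"luminance"`.
#' @export
setClass("IntensityMap",
    representation(values = "matrix", kind = "character"))

setValidity("IntensityMap", function(object) {
    if (length(object@kind) != 1L || !object@kind %in% .HE_KINDS)
        return(sprintf("'kind' must be one of: %s",
                       paste(.HE_KINDS, collapse = ", ")))
    v <- object@values
    if (any(!is.finite(v))) return("all values must be finite")
    if (min(v) < 0) return("all values must be non-negative")
    if (max(v) > 1) return("values must not exceed 1")
    TRUE
})

#' BinaryMask: per-pixel tissue labels
#'
#' A logical matrix aligned with an image; `TRUE` marks tissue. Coordinates
#' are row-major with the origin at the top-left, 0-based in files and 1-based
#' in R, as everywhere in this package.
#'
#' @slot labels logical matrix, `TRUE` = tissue (or, for ground-truth masks,
#'   membership of the mask's class).
#' @export
setClass("BinaryMask", representation(labels = "matrix"))

setValidity("BinaryMask", function(object) {
    if (!is.logical(object@labels)) return("'labels' must be logical")
    if (anyNA(object@labels)) return("'labels' must not contain NA")
    TRUE
})

#' IntensityHistogram: binned pixel intensities for the Otsu solver
#'
#' Equal-width bins spanning \[0, max\] of the data, with the right-most bin
#' closed. Built by [buildHistogram()].
#'
#' @slot breaks numeric vector of n+1 strictly increasing bin edges.
#' @slot counts integer vector of n non-negative per-bin counts.
#' @export
setClass("IntensityHistogram",
    representation(breaks = "numeric", counts = "integer"))

setValidity("IntensityHistogram", function(object) {
    if (length(object@breaks) != length(object@counts) + 1L)
        return("'breaks' must have length(counts) + 1 entries")
    if (any(diff(object@breaks) <= 0))
        return("'breaks' must be strictly increasing")
    if (any(object@counts < 0L)) return("'counts' must be non-negative")
    if (sum(as.numeric(object@counts)) <= 0) return("total count must be > 0")
    TRUE
})

#' ThresholdResult: the outcome of an Otsu threshold search
#'
#' @slot threshold numeric cut in data units; pixels are compared strictly
#'   against it.
#' @slot betweenClassVariance the maximized criterion w0*w1*(mu0-mu1)^2.
#' @slot degenerate `TRUE` when no bin boundary splits the data into two
#'   non-empty classes (e.g. a constant image); the threshold is then the
#'   lowest bin edge and downstream segmentation returns an empty mask.
#' @export
setClass("ThresholdResult",
    representation(threshold = "numeric",
                   betweenClassVariance = "numeric",
                   degenerate = "logical"))

setValidity("ThresholdResult", function(object) {
    if (length(object@threshold) != 1L || !is.finite(object@threshold))
        return("'threshold' must be a single finite number")
    if (object@betweenClassVariance < 0)
        return("'betweenClassVariance' must be >= 0")
    if (!object@degenerate && object@betweenClassVariance <= 0)
        return("non-degenerate results must have positive between-class variance")
    TRUE
})

#' TissueSegmentation: a mask plus its provenance report
#'
#' Returned by [segmentHE()] and [segmentLuminance()]. Bundles the binary
#' tissue mask with the threshold result, the tissue fraction, the histogram
#' settings actually used (bin count and domain) and the source path, so that
#' every mask is reproducible from its report.
#'
#' @slot mask a [BinaryMask-class].
#' @slot method `"he_otsu"` or `"luminance_otsu"`.
#' @slot thresholdResult a [ThresholdResult-class].
#' @slot tissueFraction fraction of pixels labelled tissue.
#' @slot nBins number of histogram bins used.
#' @slot histRange numeric(2), the histogram domain \[0, max\] used.
#' @slot sourcePath path of the source image ("" for in-memory input).
#' @export
setClass("TissueSegmentation",
    representation(mask = "BinaryMask",
                   method = "character",
                   thresholdResult = "ThresholdResult",
                   tissueFraction = "numeric",
                   nBins = "integer",
                   histRange = "numeric",
                   sourcePath = "character"))

setValidity("TissueSegmentation", function(object) {
    if (!object@method %in% c("he_otsu", "luminance_otsu"))
        return("'method' must be 'he_otsu' or 'luminance_otsu'")
    if (object@tissueFraction < 0 || object@tissueFraction > 1)
        return("'tissueFraction' must lie in [0, 1]")
    f <- mean(object@mask@labels)
    if (abs(f - object@tissueFraction) > 1e-9)
        return("'tissueFraction' does not match the mask")
    TRUE
})

#' SlideSpec: parameters of one synthetic slide
#'
#' Describes a synthetic H&E overview: raster size, number of tissue blobs,
#' pen strokes (colour class and stroke width in pixels), whether a scanner
#' bounding box is drawn, the number of dark scanner blobs, whether pens are
#' routed over the tissue, and the RNG seed that makes the slide fully
#' reproducible.
#'
#' @slot height,width raster size in pixels (each >= 32).
#' @slot tissueBlobs number of tissue blobs.
#' @slot penStrokes list of `list(colour =, width =)` entries; colour one of
#'   blue, green, black, red, orange, pink.
#' @slot boundingBox draw a thin dark rectangle near the border?
#' @slot scannerBlobs number of dark blob/text-like scanner artefacts.
#' @slot penOverTissue route pen strokes across the tissue (vs anywhere)?
#' @slot seed integer RNG seed.
#' @export
setClass("SlideSpec",
    representation(height = "integer", width = "integer",
                   tissueBlobs = "integer", penStrokes = "list",
                   boundingBox = "logical", scannerBlobs = "integer",
                   penOverTissue = "logical", seed = "integer"))

setValidity("SlideSpec", function(object) {
    if (object@height < 32L || object@width < 32L)
        return("slides must be at least 32 x 32 pixels")
    if (object@tissueBlobs < 0L) return("'tissueBlobs' must be >= 0")
    if (object@scannerBlobs < 0L) return("'scannerBlobs' must be >= 0")
    minDim <- min(object@height, object@width)
    for (s in object@penStrokes) {
        if (!is.list(s) || is.null(s$colour) || is.null(s$width))
            return("each pen stroke needs 'colour' and 'width'")
        if (!s$colour %in% .PEN_COLOURS)
            return(sprintf("unknown pen colour '%s'", s$colour))
        if (s$width < 1 || s$width > minDim / 4)
            return("pen stroke width must be in [1, min(height, width)/4]")
    }
    TRUE
})

#' SyntheticSlide: a generated overview with per-class ground truth
#'
#' The image plus five mutually exclusive, jointly exhaustive truth masks
#' (tissue, background, pen, box, scanner). Artefacts drawn over tissue claim
#' their pixels for the artefact class.
#'
#' @slot image an [RGBImage-class].
#' @slot truth named list of five [BinaryMask-class] objects.
#' @slot spec the [SlideSpec-class] the slide was generated from.
#' @export
setClass("SyntheticSlide",
    representation(image = "RGBImage", truth = "list", spec = "SlideSpec"))

setValidity("SyntheticSlide", function(object) {
    if (!identical(sort(names(object@truth)), sort(.TRUTH_CLASSES)))
        return(sprintf("'truth' must contain masks named: %s",
                       paste(.TRUTH_CLASSES, collapse = ", ")))
    d <- dim(object@image@data)[1:2]
    tot <- matrix(0L, d[1L], d[2L])
    for (m in object@truth) {
        if (!is(m, "BinaryMask")) return("'truth' entries must be BinaryMask")
        if (!identical(dim(m@labels), d))
            return("truth masks must match the image dimensions")
        tot <- tot + m@labels
    }
    if (any(tot != 1L))
        return("truth masks must partition the raster (disjoint and exhaustive)")
    TRUE
})

#' EvaluationRecord: quantitative scores of one segmentation
#'
#' Dice against the ground-truth tissue mask, tissue recall, the fraction of
#' each artefact/background class wrongly labelled tissue, and a boolean
#' success verdict (see [evaluateSlide()] for the verdict rule).
#'
#' @slot dice Sorensen-Dice coefficient vs truth tissue.
#' @slot tissueRecall fraction of truth-tissue pixels labelled tissue.
#' @slot backgroundInclusion,penInclusion,boxInclusion,scannerInclusion
#'   fraction of each truth class labelled tissue.
#' @slot verdict `TRUE` when the segmentation passes all four success rules.
#' @export
setClass("EvaluationRecord",
    representation(dice = "numeric", tissueRecall = "numeric",
                   backgroundInclusion = "numeric", penInclusion = "numeric",
                   boxInclusion = "numeric", scannerInclusion = "numeric",
                   verdict = "logical"))

setValidity("EvaluationRecord", function(object) {
    fr <- c(object@dice, object@tissueRecall, object@backgroundInclusion,
            object@penInclusion, object@boxInclusion, object@scannerInclusion)
    if (any(fr < 0) || any(fr > 1)) return("all fractions must lie in [0, 1]")
    TRUE
})

#' CubeMembership: the T > 0 region of the RGB colour cube
#'
#' Result of enumerating an RGB lattice and applying the purple-pink
#' transform at every point; members are exactly the points with R > G and
#' B > G. See [cubeMembership()].
#'
#' @slot resolution samples per channel.
#' @slot memberPoints numeric matrix (rows = member points, columns r, g, b);
#'   may have zero rows when point storage was disabled.
#' @slot memberCount number of lattice points with T > 0.
#' @slot memberFraction memberCount / resolution^3.
#' @export
setClass("CubeMembership",
    representation(resolution = "integer", memberPoints = "matrix",
                   memberCount = "numeric", memberFraction = "numeric"))
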