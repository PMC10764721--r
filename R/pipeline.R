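# End-to-end segmentation: overview image -> intensity map -> Otsu -> mask.
#
# Two pipelines share the same solver:
#   * segmentHE        — the purple-pink transform; tissue is *above* the
#                        threshold (the background mass sits exactly at 0).
#   * segmentLuminance — the conventional baseline; tissue is *below* the
#                        threshold (tissue is darker than the background).
# Both run with a single default (the bin count); no per-image tuning.

.makeSegmentation <- function(mask, method, th, hist, nBins, sourcePath) {
    new("TissueSegmentation",
        mask = new("BinaryMask", labels = mask),
        method = method,
        thresholdResult = th,
        tissueFraction = mean(mask),
        nBins = as.integer(nBins),
        histRange = range(hist@breaks),
        sourcePath = sourcePath)
}

.removeSmallObjects <- function(mask, minSize) {
    lab <- EBImage::bwlabel(mask)
    if (max(lab) == 0) return(mask)
    keep <- which(tabulate(lab[lab > 0]) >= minSize)
    array(lab %in% keep, dim = dim(mask))
}

#' Segment H&E tissue via the purple-pink transform and Otsu thresholding
#'
#' Computes `T = ReLU(R - G) * ReLU(B - G)`, builds a histogram over
#' `[0, max(T)]` and labels as tissue every pixel whose transform value is
#' strictly greater than the Otsu threshold. Because background, grey
#' artefacts and blue/green/black/red pen marks map to exactly zero, they can
#' never be labelled tissue. On a degenerate histogram (e.g. an overview with
#' no pinkish pixels at all) an all-`FALSE` mask is returned with a warning.
#'
#' @param image an [RGBImage-class].
#' @param nBins number of histogram bins (default 256).
#' @param sourcePath optional path recorded in the report.
#' @param minObjectSize if > 0, connected tissue components smaller than this
#'   many pixels are removed from the mask (off by default; the core method
#'   applies no morphological post-processing).
#' @return a [TissueSegmentation-class].
#' @examples
#' slide <- generateSlide(SlideSpec(seed = 7))
#' seg <- segmentHE(slideImage(slide))
#' tissueFraction(seg)
#' @export
segmentHE <- function(image, nBins = 256L, sourcePath = "",
                      minObjectSize = 0L) {
    stopifnot(is(image, "RGBImage"))
    tmap <- heTransform(image)
    hist <- buildHistogram(tmap, nBins)
    th <- otsuThreshold(hist)
    if (th@degenerate) {
        warning("degenerate threshold (no pinkish pixels); ",
                "returning an empty tissue mask")
        mask <- matrix(FALSE, nrow(tmap@values), ncol(tmap@values))
    } else {
        mask <- tmap@values > th@threshold
        if (minObjectSize > 0L) mask <- .removeSmallObjects(mask, minObjectSize)
    }
    .makeSegmentation(mask, "he_otsu", th, hist, nBins, sourcePath)
}

#' Baseline tissue segmentation: Otsu thresholding of the luminance
#'
#' The conventional approach: pixels darker than the Otsu threshold of the
#' Rec. 601 luminance are labelled tissue. Works on artefact-free slides but
#' cannot distinguish dark artefacts (pen marks, scanner blobs, bounding
#' boxes) from tissue; provided as the comparison baseline.
#'
#' @inheritParams segmentHE
#' @return a [TissueSegmentation-class].
#' @export
segmentLuminance <- function(image, nBins = 256L, sourcePath = "",
                             minObjectSize = 0L) {
    stopifnot(is(image, "RGBImage"))
    lmap <- luminance(image)
    hist <- buildHistogram(lmap, nBins)
    th <- otsuThreshold(hist)
    if (th@degenerate) {
        warning("degenerate threshold (constant luminance); ",
                "returning an empty tissue mask")
        mask <- matrix(FALSE, nrow(lmap@values), ncol(lmap@values))
    } else {
        mask <- lmap@values < th@threshold
        if (minObjectSize > 0L) mask <- .removeSmallObjects(mask, minObjectSize)
    }
    .makeSegmentation(mask, "luminance_otsu", th, hist, nBins, sourcePath)
}

#' Downscale an in-memory image so its longer side is at most maxDim
#'
#' Bilinear resampling; aspect ratio preserved; never upsamples.
#'
#' @param image an [RGBImage-class].
#' @param maxDim maximum length of the longer side, in pixels.
#' @return an [RGBImage-class].
#' @export
overviewFromImage <- function(image, maxDim = 2048L) {
    stopifnot(is(image, "RGBImage"))
    d <- dim(image)
    if (max(d) <= maxDim) return(image)
    sc <- maxDim / max(d)
    out <- EBImage::resize(image@data,
                           w = max(1L, round(d[1L] * sc)),
                           h = max(1L, round(d[2L] * sc)))
    RGBImage(pmin(pmax(out, 0), 1))
}

#' Extract a low-magnification overview from a raster or pyramidal slide file
#'
#' For a flat PNG/JPEG/TIFF the image is read and downscaled so that its
#' longer side is at most `maxDim` (never upsampled). For a multi-page
#' (pyramidal) TIFF the smallest level whose longer side is still at least
#' `maxDim` is chosen (falling back to the highest-resolution level if all
#' levels are smaller), then downscaled.
#'
#' @param slidePath path to a PNG/JPEG/TIFF file.
#' @param maxDim maximum length of the longer side of the overview, in
#'   pixels. The default 2048 preserves pen-stroke width at desk-scale cost.
#' @return an [RGBImage-class].
#' @export
extractOverview <- function(slidePath, maxDim = 2048L) {
    a <- .readRaster(slidePath, all = TRUE)
    if (is.list(a)) {
        sizes <- vapply(a, function(p) max(dim(p)[1:2]), 0)
        big <- which(sizes >= maxDim)
        pick <- if (length(big)) big[which.min(sizes[big])] else which.max(sizes)
        a <- a[[pick]]
    }
    overviewFromImage(.toRGBArray(a, slidePath), maxDim)
}

#' Upscale a mask to full resolution by nearest-neighbour replication
#'
#' Maps target pixel `(i, j)` to source pixel
#' `(ceiling(i * h / H), ceiling(j * w / W))`; for integer scale factors this
#' replicates each label into a block. No new label values can appear.
#'
#' @param mask a [BinaryMask-class].
#' @param targetHeight,targetWidth output size in pixels; each must be at
#'   least the mask's size.
#' @return a [BinaryMask-class] of the requested size.
#' @export
maskToFullResolution <- function(mask, targetHeight, targetWidth) {
    stopifnot(is(mask, "BinaryMask"))
    d <- dim(mask)
    if (targetHeight < d[1L] || targetWidth < d[2L])
        stop("invalid input: target dimensions must be >= mask dimensions")
    ri <- pmax(1L, ceiling(seq_len(targetHeight) * d[1L] / targetHeight))
    ci <- pmax(1L, ceiling(seq_len(targetWidth) * d[2L] / targetWidth))
    new("BinaryMask", labels = mask@labels[ri, ci, drop = FALSE])
}
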