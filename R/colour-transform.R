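# Channel normalization, the purple-pink transform and the luminance baseline.
#
# Tissue stained with haematoxylin and eosin appears purple-pink: both the red
# and the blue channel exceed the green channel. The transform
# T = ReLU(R - G) * ReLU(B - G) is therefore positive on tissue and exactly
# zero on every achromatic pixel (greys, white background, black artefacts)
# and on every green-dominant pixel (blue/green pens, for which one of the
# two factors is clipped to zero).

#' Construct an RGBImage from a normalized array
#'
#' @param data numeric array, height x width x 3, values in \[0, 1\].
#' @return an [RGBImage-class].
#' @export
RGBImage <- function(data) new("RGBImage", data = data)

#' Normalize an integer raster to an RGBImage
#'
#' Divides each colour plane by the sample type's maximum (255 for 8-bit,
#' 65535 for 16-bit). A fourth (alpha) plane, if present, is composited over a
#' white background and then dropped: slide scanners pad with white, so fully
#' transparent pixels become white.
#'
#' @param raw integer-valued array with 3 or 4 planes (height x width x 3|4).
#' @param bits bit depth of the samples: 8, 16 or `"auto"` (16 when any value
#'   exceeds 255).
#' @return an [RGBImage-class].
#' @examples
#' px <- array(c(51L, 102L, 204L), dim = c(1, 1, 3))
#' pixelData(normalizeImage(px))  # 0.2, 0.4, 0.8
#' @export
normalizeImage <- function(raw, bits = "auto") {
    if (length(dim(raw)) != 3L || !dim(raw)[3L] %in% c(3L, 4L))
        stop("invalid input: raster must have 3 or 4 planes, got ",
             if (length(dim(raw)) == 3L) dim(raw)[3L] else "a non-3D array")
    if (any(!is.finite(raw)))
        stop("invalid input: raster contains non-finite values")
    if (any(raw != round(raw)))
        stop("invalid input: raster samples must be integers ",
             "(8- or 16-bit); got non-integer values")
    if (any(raw < 0))
        stop("invalid input: raster samples must be non-negative")
    if (identical(bits, "auto")) bits <- if (max(raw) > 255) 16L else 8L
    bits <- as.integer(bits)
    if (!bits %in% c(8L, 16L))
        stop("invalid input: 'bits' must be 8, 16 or \"auto\"")
    maxv <- if (bits == 8L) 255 else 65535
    if (max(raw) > maxv)
        stop("invalid input: samples exceed the ", bits, "-bit maximum ", maxv)
    img <- raw / maxv
    if (dim(img)[3L] == 4L) {
        alpha <- img[, , 4L]
        rgb <- img[, , 1:3, drop = FALSE]
        for (k in 1:3) rgb[, , k] <- rgb[, , k] * alpha + (1 - alpha)
        img <- rgb
    }
    RGBImage(img)
}

#' Rectifier linear unit
#'
#' `max(x, 0)`, applied element-wise.
#'
#' @param x finite numeric vector, matrix or array.
#' @return object of the same shape with negative entries replaced by 0.
#' @export
relu <- function(x) {
    if (!is.numeric(x)) stop("invalid input: 'x' must be numeric")
    if (any(!is.finite(x))) stop("invalid input: 'x' must be finite")
    pmax(x, 0)
}

#' The purple-pink single-channel representation of an H&E overview
#'
#' Computes, per pixel, `T = max(R - G, 0) * max(B - G, 0)`. Tissue pixels
#' (more red than green and more blue than green) are positive; achromatic
#' pixels and pixels with a dominant green channel are exactly zero. The
#' resulting distribution is bimodal, with background, grey artefacts and
#' most pen colours sitting exactly at zero, which is what makes a subsequent
#' Otsu threshold robust to artefacts.
#'
#' @param image an [RGBImage-class].
#' @return an [IntensityMap-class] with `kind = "he_transform"`;
#'   values lie in \[0, 1\].
#' @examples
#' img <- RGBImage(array(c(0.90, 0.55, 0.71), dim = c(1, 1, 3)))
#' mapValues(heTransform(img))  # (0.90-0.55) * (0.71-0.55) = 0.056
#' @export
heTransform <- function(image) {
    stopifnot(is(image, "RGBImage"))
    d <- image@data
    v <- pmax(d[, , 1L] - d[, , 2L], 0) * pmax(d[, , 3L] - d[, , 2L], 0)
    if (!is.matrix(v)) v <- matrix(v, dim(d)[1L], dim(d)[2L])
    new("IntensityMap", values = v, kind = "he_transform")
}

#' Rec. 601 luminance of an RGB image
#'
#' The conventional greyscale representation `0.299 R + 0.587 G + 0.114 B`,
#' used here as the input to the baseline Otsu segmentation.
#'
#' @param image an [RGBImage-class].
#' @return an [IntensityMap-class] with `kind = "luminance"`.
#' @export
luminance <- function(image) {
    stopifnot(is(image, "RGBImage"))
    d <- image@data
    v <- 0.299 * d[, , 1L] + 0.587 * d[, , 2L] + 0.114 * d[, , 3L]
    if (!is.matrix(v)) v <- matrix(v, dim(d)[1L], dim(d)[2L])
    # weights sum to 1 but rounding can push a white pixel epsilon above it
    v <- pmin(pmax(v, 0), 1)
    new("IntensityMap", values = v, kind = "luminance")
}
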