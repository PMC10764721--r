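# Raster reading and mask/report writing.
#
# PNG and TIFF are read with the png and tiff packages; JPEG with the jpeg
# package when available. Masks are written as 8-bit single-channel PNGs
# (0 = non-tissue, 255 = tissue); reports as JSON with a schema version.

.toRGBArray <- function(a, path) {
    if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
    if (length(dim(a)) != 3L)
        stop("I/O error: '", path, "' is not a 2D raster")
    nc <- dim(a)[3L]
    if (nc == 2L) {                      # grey + alpha
        g <- a[, , 1L] * a[, , 2L] + (1 - a[, , 2L])
        a <- array(rep(g, 3L), dim = c(dim(g), 3L))
    } else if (nc == 4L) {               # RGBA: composite over white
        alpha <- a[, , 4L]
        rgb <- a[, , 1:3, drop = FALSE]
        for (k in 1:3) rgb[, , k] <- rgb[, , k] * alpha + (1 - alpha)
        a <- rgb
    } else if (nc != 3L) {
        stop("I/O error: '", path, "' has ", nc, " channels; expected 1-4")
    }
    RGBImage(pmin(pmax(a, 0), 1))
}

.readRaster <- function(path, all = FALSE) {
    if (!file.exists(path))
        stop("I/O error: file not found: '", path, "'")
    ext <- tolower(tools::file_ext(path))
    if (ext == "png") {
        png::readPNG(path)
    } else if (ext %in% c("tif", "tiff")) {
        tiff::readTIFF(path, all = all)
    } else if (ext %in% c("jpg", "jpeg")) {
        if (!requireNamespace("jpeg", quietly = TRUE))
            stop("I/O error: JPEG support requires the 'jpeg' package")
        jpeg::readJPEG(path)
    } else {
        stop("I/O error: unsupported format '", ext, "' for '", path, "'")
    }
}

#' Read a raster file as an RGBImage
#'
#' Reads a PNG, TIFF or JPEG file, composites any alpha channel over white,
#' replicates greyscale rasters to three channels and returns values in
#' \[0, 1\]. For a multi-page (pyramidal) TIFF the first page is returned;
#' see [extractOverview()] for level selection.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return an [RGBImage-class].
#' @export
readRGBImage <- function(path) {
    a <- .readRaster(path)
    if (is.list(a)) a <- a[[1L]]
    .toRGBArray(a, path)
}

#' Write a binary mask as an 8-bit single-channel PNG
#'
#' Tissue pixels are written as 255, non-tissue as 0.
#'
#' @param mask a [BinaryMask-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
    stopifnot(is(mask, "BinaryMask"))
    png::writePNG(mask@labels * 1.0, path)
    invisible(path)
}

#' Read a single-channel mask PNG written by [writeMaskPNG()]
#'
#' @param path path to the mask PNG.
#' @return a [BinaryMask-class]; pixels above half intensity are `TRUE`.
#' @export
readMaskPNG <- function(path) {
    a <- .readRaster(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    new("BinaryMask", labels = a > 0.5)
}

#' Write a segmentation report as JSON
#'
#' @param seg a [TissueSegmentation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSegmentationReport <- function(seg, path) {
    stopifnot(is(seg, "TissueSegmentation"))
    jsonlite::write_json(reportList(seg), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
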