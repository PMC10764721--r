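# In-code fixtures shared across test files.

# single-pixel RGBImage from a triple
px <- function(r, g, b) RGBImage(array(c(r, g, b), dim = c(1L, 1L, 3L)))

# RGBImage with n random pixels laid out as a 1 x n raster
randomImage <- function(n, seed = 1L) {
    set.seed(seed)
    RGBImage(array(runif(3L * n), dim = c(1L, n, 3L)))
}

# transform value of one pixel triple, straight from the definition
tOf <- function(r, g, b) max(r - g, 0) * max(b - g, 0)

# small pink-disc slide with an optional single pen stroke
discSlide <- function(penColour = NULL, seed = 7L, size = 128L, width = 4) {
    strokes <- if (is.null(penColour)) list() else
        list(list(colour = penColour, width = width))
    generateSlide(SlideSpec(height = size, width = size, tissueBlobs = 1L,
                            penStrokes = strokes, seed = seed))
}
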