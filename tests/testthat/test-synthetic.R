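test_that("tissue colour samples are always more red and blue than green", {
    set.seed(0)
    s <- sampleTissueColour(10000)
    expect_true(all(s[, "r"] > s[, "g"]))
    expect_true(all(s[, "b"] > s[, "g"]))
    tv <- pmax(s[, "r"] - s[, "g"], 0) * pmax(s[, "b"] - s[, "g"], 0)
    expect_true(all(tv > 0))
    # determinism
    set.seed(0); a <- sampleTissueColour(5)
    set.seed(0); b <- sampleTissueColour(5)
    expect_identical(a, b)
})

test_that("pen colour classes map to the intended transform values", {
    set.seed(1)
    for (colour in c("blue", "green", "black", "red", "orange")) {
        s <- samplePenColour(colour, 20000)
        tv <- pmax(s[, "r"] - s[, "g"], 0) * pmax(s[, "b"] - s[, "g"], 0)
        expect_true(all(tv == 0), label = paste(colour, "pen maps to T = 0"))
    }
    s <- samplePenColour("pink", 20000)
    tv <- pmax(s[, "r"] - s[, "g"], 0) * pmax(s[, "b"] - s[, "g"], 0)
    expect_true(all(tv > 0))
    expect_error(samplePenColour("violet", 1), "violet")
})

test_that("generateSlide is a pure function of its spec", {
    spec <- SlideSpec(height = 96, width = 96,
                      penStrokes = list(list(colour = "green", width = 3)),
                      boundingBox = TRUE, scannerBlobs = 1, seed = 7)
    a <- generateSlide(spec)
    b <- generateSlide(spec)
    expect_identical(pixelData(slideImage(a)), pixelData(slideImage(b)))
    for (cls in names(truthMasks(a)))
        expect_identical(maskMatrix(truthMasks(a)[[cls]]),
                         maskMatrix(truthMasks(b)[[cls]]))
})

test_that("truth masks partition the raster and empty classes stay empty", {
    slide <- generateSlide(SlideSpec(height = 80, width = 120, seed = 3))
    tm <- truthMasks(slide)
    expect_false(any(maskMatrix(tm$pen)))
    expect_false(any(maskMatrix(tm$box)))
    expect_false(any(maskMatrix(tm$scanner)))
    total <- Reduce(`+`, lapply(tm, maskMatrix))
    expect_true(all(total == 1))
    # fully loaded slide still partitions (checked by the class validity too)
    busy <- generateSlide(SlideSpec(height = 96, width = 96,
        penStrokes = list(list(colour = "blue", width = 4),
                          list(colour = "green", width = 3)),
        boundingBox = TRUE, scannerBlobs = 1, seed = 5))
    total <- Reduce(`+`, lapply(truthMasks(busy), maskMatrix))
    expect_true(all(total == 1))
})

test_that("slide invariants: background achromatic, tissue transform-positive", {
    slide <- generateSlide(SlideSpec(height = 96, width = 96, seed = 13))
    tv <- mapValues(heTransform(slideImage(slide)))
    tm <- truthMasks(slide)
    expect_true(all(tv[maskMatrix(tm$background)] == 0))
    expect_true(all(tv[maskMatrix(tm$tissue)] > 0))
})

test_that("SlideSpec validity rejects malformed specifications", {
    expect_error(SlideSpec(height = 8), "32")
    expect_error(SlideSpec(penStrokes = list(list(colour = "cyan", width = 3))),
                 "cyan")
    expect_error(SlideSpec(penStrokes = list(list(colour = "blue",
                                                  width = 200))), "width")
})

test_that("generateSuite produces the requested composition, reproducibly", {
    suite <- generateSuite(2, 2, 1, seed = 9, height = 64, width = 64)
    expect_length(suite, 5)
    cats <- vapply(suite, slideCategory, "")
    expect_identical(cats, c("clean", "clean", "pen", "pen", "scanner"))
    again <- generateSuite(2, 2, 1, seed = 9, height = 64, width = 64)
    expect_identical(pixelData(slideImage(suite[[3]])),
                     pixelData(slideImage(again[[3]])))
    expect_identical(generateSuite(0, 0, 0, seed = 1), list())
    # pen colours cycle through the requested classes
    pens <- vapply(suite[cats == "pen"], function(s)
        slideSpec(s)@penStrokes[[1]]$colour, "")
    expect_identical(pens, c("blue", "green"))
})

test_that("fixtures round-trip through PNG + JSON without losing truth", {
    d <- withr::local_tempdir()
    suite <- generateSuite(1, 1, 1, seed = 17, height = 64, width = 64)
    manifest <- writeSlideFixtures(suite, d)
    expect_true(file.exists(manifest))
    back <- readSlideFixtures(d)
    expect_length(back, 3)
    for (i in seq_along(suite)) {
        for (cls in names(truthMasks(suite[[i]])))
            expect_identical(
                maskMatrix(truthMasks(back[[i]])[[cls]]),
                maskMatrix(truthMasks(suite[[i]])[[cls]]))
        expect_identical(slideSpec(back[[i]])@seed, slideSpec(suite[[i]])@seed)
    }
    # 8-bit quantization must not move any pixel across the class boundary
    tv <- mapValues(heTransform(slideImage(back[[1]])))
    tm <- truthMasks(back[[1]])
    expect_true(all(tv[maskMatrix(tm$background)] == 0))
    expect_true(all(tv[maskMatrix(tm$tissue)] > 0))
})
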