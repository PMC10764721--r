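test_that("normalizeImage divides by the sample-type maximum", {
    img <- normalizeImage(array(c(255L, 255L, 255L), dim = c(1, 1, 3)))
    expect_equal(as.vector(pixelData(img)), c(1, 1, 1))
    img <- normalizeImage(array(0L, dim = c(1, 1, 3)))
    expect_equal(as.vector(pixelData(img)), c(0, 0, 0))
    img <- normalizeImage(array(c(51L, 102L, 204L), dim = c(1, 1, 3)))
    expect_equal(as.vector(pixelData(img)), c(0.2, 0.4, 0.8))
    img16 <- normalizeImage(array(c(65535L, 0L, 13107L), dim = c(1, 1, 3)),
                            bits = 16)
    expect_equal(as.vector(pixelData(img16)), c(1, 0, 13107 / 65535))
    # auto depth: any sample above 255 implies 16-bit
    auto <- normalizeImage(array(c(512L, 256L, 1024L), dim = c(1, 1, 3)))
    expect_equal(as.vector(pixelData(auto)), c(512, 256, 1024) / 65535)
})

test_that("normalizeImage composites alpha over white, then drops it", {
    # half-transparent pure red over white: 0.5*1 + 0.5 = 1 red, 0.5 g/b
    raw <- array(c(255L, 0L, 0L, 127L), dim = c(1, 1, 4))
    got <- as.vector(pixelData(normalizeImage(raw)))
    a <- 127 / 255
    expect_equal(got, c(a + (1 - a), 1 - a, 1 - a))
    # fully transparent pixel becomes white
    raw0 <- array(c(9L, 9L, 9L, 0L), dim = c(1, 1, 4))
    expect_equal(as.vector(pixelData(normalizeImage(raw0))), c(1, 1, 1))
})

test_that("normalizeImage rejects malformed rasters by name", {
    expect_error(normalizeImage(array(0L, dim = c(2, 2, 2))), "planes")
    expect_error(normalizeImage(array(0.5, dim = c(1, 1, 3))), "non-integer")
    expect_error(normalizeImage(array(-1L, dim = c(1, 1, 3))), "non-negative")
    expect_error(normalizeImage(array(300L, dim = c(1, 1, 3)), bits = 8),
                 "maximum")
})

test_that("relu is max(x, 0) element-wise and rejects non-finite input", {
    expect_identical(relu(0.3), 0.3)
    expect_identical(relu(-0.3), 0)
    expect_identical(relu(0), 0)
    expect_equal(relu(c(-1, 0.5, -0.2)), c(0, 0.5, 0))
    expect_error(relu(NaN), "finite")
    expect_error(relu(Inf), "finite")
})

test_that("heTransform matches its defining formula on canonical pixels", {
    for (v in c(0, 0.25, 0.5, 1))
        expect_identical(mapValues(heTransform(px(v, v, v)))[1], 0)
    expect_identical(mapValues(heTransform(px(1, 0, 1)))[1], 1)
    expect_equal(mapValues(heTransform(px(0.90, 0.55, 0.71)))[1],
                 0.35 * 0.16)  # eosin-like: 0.056
    expect_identical(mapValues(heTransform(px(0, 0, 1)))[1], 0)
    m <- heTransform(randomImage(10))
    expect_s4_class(m, "IntensityMap")
    expect_identical(mapKind(m), "he_transform")
})

test_that("heTransform zeroes every pixel with G >= R or G >= B", {
    # full 6-bit-per-channel cube, arranged as a 64 x 4096 raster
    v <- (0:63) / 63
    grid <- expand.grid(r = v, g = v, b = v)
    img <- RGBImage(array(c(grid$r, grid$g, grid$b), dim = c(64, 4096, 3)))
    tv <- as.vector(mapValues(heTransform(img)))
    zero <- grid$g >= grid$r | grid$g >= grid$b
    expect_true(all(tv[zero] == 0))
    expect_true(all(tv[!zero] > 0))
    # and on a random pixel sample
    set.seed(3)
    rnd <- randomImage(5000, seed = 3)
    d <- pixelData(rnd)
    tv <- as.vector(mapValues(heTransform(rnd)))
    zero <- d[, , 2] >= d[, , 1] | d[, , 2] >= d[, , 3]
    expect_true(all(tv[as.vector(zero)] == 0))
})

test_that("heTransform is within [0,1], homogeneous of degree 2 and monotone", {
    img <- randomImage(2000, seed = 11)
    tv <- mapValues(heTransform(img))
    expect_true(all(tv >= 0 & tv <= 1))
    for (c in c(0.25, 0.7)) {
        scaled <- RGBImage(pixelData(img) * c)
        expect_equal(mapValues(heTransform(scaled)), c^2 * tv,
                     tolerance = 1e-12)
    }
    # raising G never increases T; raising R or B never decreases it
    d <- pixelData(img)
    bumpG <- d; bumpG[, , 2] <- pmin(bumpG[, , 2] + 0.1, 1)
    expect_true(all(mapValues(heTransform(RGBImage(bumpG))) <= tv))
    bumpR <- d; bumpR[, , 1] <- pmin(bumpR[, , 1] + 0.1, 1)
    expect_true(all(mapValues(heTransform(RGBImage(bumpR))) >= tv))
    bumpB <- d; bumpB[, , 3] <- pmin(bumpB[, , 3] + 0.1, 1)
    expect_true(all(mapValues(heTransform(RGBImage(bumpB))) >= tv))
})

test_that("achromatic invariance: shifting R=B<=G pixels stays at zero", {
    set.seed(5)
    for (i in 1:50) {
        rb <- runif(1, 0, 0.6)
        g <- runif(1, rb, 1)
        shift <- runif(1, -rb, 1 - g)
        base <- mapValues(heTransform(px(rb, g, rb)))[1]
        shifted <- mapValues(heTransform(px(rb + shift, g + shift,
                                            rb + shift)))[1]
        expect_identical(base, 0)
        expect_identical(shifted, 0)
    }
})

test_that("luminance uses Rec. 601 weights", {
    expect_equal(mapValues(luminance(px(1, 1, 1)))[1], 1)
    expect_identical(mapValues(luminance(px(0, 0, 0)))[1], 0)
    expect_equal(mapValues(luminance(px(1, 0, 0)))[1], 0.299)
    expect_equal(mapValues(luminance(px(0, 1, 0)))[1], 0.587)
    expect_equal(mapValues(luminance(px(0, 0, 1)))[1], 0.114)
    expect_identical(mapKind(luminance(px(0.2, 0.4, 0.6))), "luminance")
})

test_that("RGBImage and IntensityMap validity catch broken objects", {
    expect_error(RGBImage(array(2, dim = c(1, 1, 3))), "0, 1")
    expect_error(RGBImage(array(0.5, dim = c(1, 1, 2))), "3 array")
    expect_error(new("IntensityMap", values = matrix(-1, 1, 1),
                     kind = "he_transform"), "non-negative")
    expect_error(new("IntensityMap", values = matrix(0, 1, 1),
                     kind = "other"), "kind")
})
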