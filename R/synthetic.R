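# Synthetic H&E slide overviews with per-class ground truth.
#
# The generator emulates the content of a scanned H&E overview at low
# magnification: pink/purple tissue blobs on a near-white background, pen
# strokes in the colours pathologists use (blue, green, black, red, orange,
# and the confusable pink), a thin dark bounding box near the border, and
# dark grey scanner blobs / text-like glyphs. Colour classes are constructed
# so that the purple-pink transform is provably zero on every achromatic or
# green-dominant artefact and provably positive on tissue and pink pen:
#   * tissue / pink pen: R > G and B > G by construction;
#   * blue pen: R <= G; green pen: R < G and B < G; black pen and all
#     scanner content: R = G = B; red and orange pens: B <= G.
# Per-pixel brightness jitter (sd 0.02) is added equally to all three
# channels, so these orderings survive jitter and [0, 1] clipping exactly.
#
# Stain hue is consistent within a slide: one base colour is drawn per slide
# and modulated by a smooth multiplicative brightness field (+-10%), the way
# staining intensity varies across a real section. Pixel-independent hues
# would spread the transform's tissue mode over more than an order of
# magnitude and destroy the bimodality the method relies on.

.jitterFill <- function(base, n, jitterSd = 0.02, scale = 1) {
    # shared-channel jitter: preserves channel order under clipping
    e <- stats::rnorm(n, 0, jitterSd)
    cbind(pmin(pmax(scale * base[1L] + e, 0), 1),
          pmin(pmax(scale * base[2L] + e, 0), 1),
          pmin(pmax(scale * base[3L] + e, 0), 1))
}

.tissueBase <- function(n) {
    r <- stats::runif(n, 0.75, 0.95)
    g <- stats::runif(n, 0.45, 0.65)
    b <- stats::runif(n, g + 0.05, 0.85)
    cbind(r, g, b, deparse.level = 0)
}

.penBase <- function(colour, n) {
    switch(colour,
        blue = {
            g <- stats::runif(n, 0.10, 0.30)
            cbind(stats::runif(n, 0.02, g), g, stats::runif(n, 0.70, 0.95))
        },
        green = {
            g <- stats::runif(n, 0.45, 0.75)
            cbind(stats::runif(n, 0.05, g - 0.10), g,
                  stats::runif(n, 0.05, g - 0.10))
        },
        black = {
            v <- stats::runif(n, 0.02, 0.15)
            cbind(v, v, v)
        },
        red = {
            g <- stats::runif(n, 0.10, 0.30)
            cbind(stats::runif(n, 0.70, 0.95), g, stats::runif(n, 0.02, g))
        },
        orange = {
            g <- stats::runif(n, 0.45, 0.65)
            cbind(stats::runif(n, 0.85, 0.98), g,
                  stats::runif(n, 0.05, g - 0.05))
        },
        pink = .tissueBase(n),
        stop("invalid input: unknown pen colour class '", colour, "'")
    )
}

#' Sample eosin/haematoxylin-like tissue colours
#'
#' Draws RGB triples from the tissue colour model
#' `R ~ U(0.75, 0.95)`, `G ~ U(0.45, 0.65)`, `B ~ U(G + 0.05, 0.85)`,
#' plus per-pixel brightness jitter (sd `jitterSd`, added equally to all
#' three channels and clipped to \[0, 1\]). Every sample satisfies `R > G`
#' and `B > G`, so its purple-pink transform value is strictly positive.
#' Uses the current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param n number of samples.
#' @param jitterSd standard deviation of the shared-channel jitter.
#' @return numeric matrix with `n` rows and columns r, g, b.
#' @export
sampleTissueColour <- function(n = 1L, jitterSd = 0.02) {
    base <- .tissueBase(n)
    e <- stats::rnorm(n, 0, jitterSd)
    out <- pmin(pmax(base + e, 0), 1)
    colnames(out) <- c("r", "g", "b")
    out
}

#' Sample pen-mark colours by colour class
#'
#' Blue, green and black pens are green-dominant or achromatic (transform
#' exactly 0); red and orange pens have `B <= G` (transform exactly 0); pink
#' pens are drawn from the tissue colour model and are therefore deliberately
#' confusable with tissue (transform > 0) — the documented failure mode.
#' Jitter as in [sampleTissueColour()].
#'
#' @param colour one of `"blue"`, `"green"`, `"black"`, `"red"`, `"orange"`,
#'   `"pink"`.
#' @param n number of samples.
#' @param jitterSd standard deviation of the shared-channel jitter.
#' @return numeric matrix with `n` rows and columns r, g, b.
#' @export
samplePenColour <- function(colour, n = 1L, jitterSd = 0.02) {
    base <- .penBase(colour, n)
    e <- stats::rnorm(n, 0, jitterSd)
    out <- pmin(pmax(base + e, 0), 1)
    colnames(out) <- c("r", "g", "b")
    out
}

#' Construct a SlideSpec
#'
#' @param height,width raster size in pixels.
#' @param tissueBlobs number of tissue blobs.
#' @param penStrokes list of `list(colour =, width =)` stroke descriptions.
#' @param boundingBox draw a thin dark rectangle near the border?
#' @param scannerBlobs number of dark scanner artefacts.
#' @param penOverTissue route pen strokes across the tissue?
#' @param seed integer RNG seed; the slide is a pure function of the spec.
#' @return a [SlideSpec-class].
#' @export
SlideSpec <- function(height = 256L, width = 256L, tissueBlobs = 2L,
                      penStrokes = list(), boundingBox = FALSE,
                      scannerBlobs = 0L, penOverTissue = TRUE, seed = 1L) {
    new("SlideSpec", height = as.integer(height), width = as.integer(width),
        tissueBlobs = as.integer(tissueBlobs), penStrokes = penStrokes,
        boundingBox = boundingBox, scannerBlobs = as.integer(scannerBlobs),
        penOverTissue = penOverTissue, seed = as.integer(seed))
}

# zero-mean, unit-sd Gaussian-smoothed noise field
.smoothField <- function(h, w, sigma) {
    f <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w),
                        sigma = max(sigma, 1))
    s <- stats::sd(f)
    if (s < 1e-12) matrix(0, h, w) else (f - mean(f)) / s
}

# irregular blob: radius modulated by a smooth field around a centre
.blobMask <- function(h, w, cy, cx, r, fieldSigma, wobble = 0.35) {
    f <- .smoothField(h, w, fieldSigma)
    mod <- pmax(1 + wobble * f, 0.2)
    dy <- matrix(seq_len(h) - cy, h, w)
    dx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
    sqrt(dy^2 + dx^2) < r * mod
}

# pixels within width/2 of a polyline (pts: matrix of y, x rows)
.strokeMask <- function(h, w, pts, width) {
    py <- matrix(seq_len(h), h, w)
    px <- matrix(rep(seq_len(w), each = h), h, w)
    m <- matrix(FALSE, h, w)
    for (k in seq_len(nrow(pts) - 1L)) {
        a <- pts[k, ]; b <- pts[k + 1L, ]
        vy <- b[1L] - a[1L]; vx <- b[2L] - a[2L]
        len2 <- vy^2 + vx^2
        t <- if (len2 < 1e-12) 0 else
            pmin(pmax(((py - a[1L]) * vy + (px - a[2L]) * vx) / len2, 0), 1)
        d2 <- (py - (a[1L] + t * vy))^2 + (px - (a[2L] + t * vx))^2
        m <- m | (d2 <= (width / 2)^2)
    }
    m
}

.fillPixels <- function(img, mask, colours) {
    idx <- which(mask)
    for (k in 1:3) {
        plane <- img[, , k]
        plane[idx] <- colours[, k]
        img[, , k] <- plane
    }
    img
}

#' Generate a synthetic H&E slide overview with ground truth
#'
#' Renders the slide described by `spec`: a near-white background (per-pixel
#' grey level `U(0.92, 0.99)`), irregular tissue blobs filled from a
#' per-slide tissue base colour modulated by a smooth brightness field, pen
#' strokes as random polylines, an optional 3-px dark bounding box near the
#' border and dark grey blob or text-like scanner artefacts. Drawing order is
#' tissue, pen, box, scanner; later layers claim their pixels in the truth
#' masks, which therefore partition the raster. Fully reproducible from
#' `spec@seed`.
#'
#' Pink pen strokes reuse the slide's own tissue base colour: on a real slide
#' the confusable pink pen is the same colour as the eosin staining.
#'
#' @param spec a [SlideSpec-class].
#' @return a [SyntheticSlide-class].
#' @examples
#' slide <- generateSlide(SlideSpec(penStrokes = list(
#'     list(colour = "blue", width = 4)), seed = 7))
#' slide
#' @export
generateSlide <- function(spec) {
    stopifnot(is(spec, "SlideSpec"))
    validObject(spec)
    withr::with_seed(spec@seed, .renderSlide(spec))
}

.renderSlide <- function(spec) {
    h <- spec@height; w <- spec@width
    minDim <- min(h, w)
    npix <- h * w

    bg <- stats::runif(npix, 0.92, 0.99)
    img <- array(rep(bg, 3L), dim = c(h, w, 3L))

    # --- tissue ---
    tisM <- matrix(FALSE, h, w)
    for (b in seq_len(spec@tissueBlobs)) {
        cy <- stats::runif(1, 0.25, 0.75) * h
        cx <- stats::runif(1, 0.25, 0.75) * w
        r <- stats::runif(1, 0.12, 0.20) * minDim
        tisM <- tisM | .blobMask(h, w, cy, cx, r, 0.05 * minDim)
    }
    tissueBase <- as.vector(.tissueBase(1L))
    if (any(tisM)) {
        bright <- pmin(pmax(1 + 0.10 * .smoothField(h, w, 0.08 * minDim),
                            0.85), 1.10)
        img <- .fillPixels(img, tisM,
                           .jitterFill(tissueBase, sum(tisM),
                                       scale = bright[tisM]))
    }

    # --- pen strokes ---
    penM <- matrix(FALSE, h, w)
    for (s in spec@penStrokes) {
        if (spec@penOverTissue && any(tisM)) {
            anchor <- which(tisM)[sample.int(sum(tisM), 1L)]
            ay <- ((anchor - 1L) %% h) + 1L
            ax <- ((anchor - 1L) %/% h) + 1L
            span <- 0.45 * minDim
            pts <- cbind(
                pmin(pmax(ay + stats::runif(3, -span, span), 2), h - 1),
                pmin(pmax(ax + stats::runif(3, -span, span), 2), w - 1))
        } else {
            pts <- cbind(stats::runif(3, 0.1, 0.9) * h,
                         stats::runif(3, 0.1, 0.9) * w)
        }
        sm <- .strokeMask(h, w, pts, s$width)
        if (s$colour == "pink") {
            cols <- .jitterFill(tissueBase, sum(sm))
        } else {
            cols <- .jitterFill(as.vector(.penBase(s$colour, 1L)), sum(sm))
        }
        img <- .fillPixels(img, sm, cols)
        penM <- penM | sm
    }

    # --- bounding box ---
    boxM <- matrix(FALSE, h, w)
    if (spec@boundingBox) {
        inset <- max(3L, round(0.03 * minDim))
        thick <- 3L
        rows <- (inset + 1L):(h - inset)
        cols <- (inset + 1L):(w - inset)
        boxM[c(utils::head(rows, thick), utils::tail(rows, thick)), cols] <- TRUE
        boxM[rows, c(utils::head(cols, thick), utils::tail(cols, thick))] <- TRUE
        v0 <- stats::runif(1, 0.10, 0.20)
        img <- .fillPixels(img, boxM, .jitterFill(rep(v0, 3L), sum(boxM)))
    }

    # --- scanner artefacts (dark grey blobs or text-like glyph rows) ---
    scanM <- matrix(FALSE, h, w)
    for (b in seq_len(spec@scannerBlobs)) {
        v0 <- stats::runif(1, 0.05, 0.25)
        if (stats::runif(1) < 0.5) {
            cy <- stats::runif(1, 0.15, 0.85) * h
            cx <- stats::runif(1, 0.15, 0.85) * w
            r <- stats::runif(1, 0.03, 0.07) * minDim
            m <- .blobMask(h, w, cy, cx, r, 0.05 * minDim, wobble = 0.4)
        } else {
            gh <- max(3L, round(0.03 * minDim))
            gw <- max(2L, round(0.02 * minDim))
            y0 <- round(stats::runif(1, 0.15, 0.80) * h)
            x0 <- round(stats::runif(1, 0.10, 0.60) * w)
            m <- matrix(FALSE, h, w)
            for (g in seq_len(sample.int(3L, 1L) + 1L)) {
                xs <- x0 + (g - 1L) * (gw + 2L)
                if (xs + gw > w || y0 + gh > h) break
                m[y0:(y0 + gh), xs:(xs + gw)] <- TRUE
            }
        }
        if (any(m)) img <- .fillPixels(img, m, .jitterFill(rep(v0, 3L), sum(m)))
        scanM <- scanM | m
    }

    truth <- list(
        scanner = scanM,
        box = boxM & !scanM,
        pen = penM & !boxM & !scanM,
        tissue = tisM & !penM & !boxM & !scanM)
    truth$background <- !(truth$tissue | truth$pen | truth$box | truth$scanner)
    truth <- lapply(truth[.TRUTH_CLASSES],
                    function(m) new("BinaryMask", labels = m))

    new("SyntheticSlide", image = RGBImage(img), truth = truth, spec = spec)
}

#' Generate a deterministic suite of synthetic slides
#'
#' Produces `nClean` artefact-free slides, `nPen` slides with pen strokes
#' (colours cycling through `penColours`) and `nScanner` slides with scanner
#' blobs plus a bounding box. Per-slide seeds are derived from the master
#' seed, so the suite is reproducible across sessions. The default suite
#' shape mirrors a curated clinical set: half clean, a quarter pen-marked, a
#' quarter with scanner artefacts.
#'
#' @param nClean,nPen,nScanner slide counts per category (each >= 0).
#' @param seed master seed.
#' @param height,width slide size in pixels.
#' @param penColours colour classes cycled over the pen slides; pink is
#'   excluded by default (it is the documented failure mode and is requested
#'   explicitly when wanted).
#' @param penOverTissue route pen strokes across the tissue?
#' @return list of [SyntheticSlide-class] objects (clean, then pen, then
#'   scanner).
#' @export
generateSuite <- function(nClean = 30L, nPen = 15L, nScanner = 15L, seed = 1L,
                          height = 256L, width = 256L,
                          penColours = c("blue", "green", "black", "red",
                                         "orange"),
                          penOverTissue = TRUE) {
    stopifnot(nClean >= 0L, nPen >= 0L, nScanner >= 0L)
    n <- nClean + nPen + nScanner
    if (n == 0L) return(list())
    draws <- withr::with_seed(seed, list(
        seeds = sample.int(.Machine$integer.max - 1L, n),
        widths = sample(3:6, max(n, 1L), replace = TRUE)))
    specs <- vector("list", n)
    for (i in seq_len(nClean))
        specs[[i]] <- SlideSpec(height, width, seed = draws$seeds[i])
    for (j in seq_len(nPen)) {
        i <- nClean + j
        colour <- penColours[(j - 1L) %% length(penColours) + 1L]
        specs[[i]] <- SlideSpec(height, width,
            penStrokes = list(list(colour = colour, width = draws$widths[i]),
                              list(colour = colour, width = draws$widths[i])),
            penOverTissue = penOverTissue, seed = draws$seeds[i])
    }
    for (j in seq_len(nScanner)) {
        i <- nClean + nPen + j
        specs[[i]] <- SlideSpec(height, width, boundingBox = TRUE,
                                scannerBlobs = 2L, seed = draws$seeds[i])
    }
    lapply(specs, generateSlide)
}

.specToList <- function(spec) {
    list(height = spec@height, width = spec@width,
         tissueBlobs = spec@tissueBlobs,
         penStrokes = lapply(spec@penStrokes, function(s)
             list(colour = s$colour, width = s$width)),
         boundingBox = spec@boundingBox, scannerBlobs = spec@scannerBlobs,
         penOverTissue = spec@penOverTissue, seed = spec@seed)
}

.specFromList <- function(x) {
    SlideSpec(height = x$height, width = x$width,
              tissueBlobs = x$tissueBlobs,
              penStrokes = lapply(x$penStrokes, function(s)
                  list(colour = s$colour, width = s$width)),
              boundingBox = isTRUE(x$boundingBox),
              scannerBlobs = x$scannerBlobs,
              penOverTissue = isTRUE(x$penOverTissue), seed = x$seed)
}

#' Write a suite of synthetic slides as plain-file fixtures
#'
#' Each slide is written as an 8-bit PNG plus one single-channel PNG per
#' truth class and a JSON sidecar holding its spec; a manifest JSON lists all
#' files with paths relative to `dir`, so reruns with the same suite produce
#' byte-identical manifests.
#'
#' @param suite list of [SyntheticSlide-class] objects.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeSlideFixtures <- function(suite, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("I/O error: cannot create directory '", dir, "'")
    entries <- vector("list", length(suite))
    for (i in seq_along(suite)) {
        slide <- suite[[i]]
        id <- sprintf("slide_%03d", i)
        imgFile <- paste0(id, ".png")
        png::writePNG(pixelData(slideImage(slide)), file.path(dir, imgFile))
        maskFiles <- list()
        for (cls in .TRUTH_CLASSES) {
            mf <- sprintf("%s_mask_%s.png", id, cls)
            writeMaskPNG(truthMasks(slide)[[cls]], file.path(dir, mf))
            maskFiles[[cls]] <- mf
        }
        sidecar <- paste0(id, ".json")
        jsonlite::write_json(
            list(schemaVersion = 1L, id = id, image = imgFile,
                 category = slideCategory(slide), masks = maskFiles,
                 spec = .specToList(slideSpec(slide))),
            file.path(dir, sidecar), auto_unbox = TRUE, digits = NA,
            pretty = TRUE)
        entries[[i]] <- list(id = id, image = imgFile, sidecar = sidecar,
                             category = slideCategory(slide))
    }
    manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(
        list(schemaVersion = 1L, nSlides = length(suite), slides = entries),
        manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

#' Read a fixture suite written by [writeSlideFixtures()]
#'
#' @param path the fixture directory or the manifest file itself.
#' @return list of [SyntheticSlide-class] objects.
#' @export
readSlideFixtures <- function(path) {
    manifest <- if (dir.exists(path)) file.path(path, "manifest.json") else path
    if (!file.exists(manifest))
        stop("invalid input: manifest not found at '", manifest, "'")
    dir <- dirname(manifest)
    man <- jsonlite::read_json(manifest)
    lapply(man$slides, function(entry) {
        side <- jsonlite::read_json(file.path(dir, entry$sidecar))
        img <- readRGBImage(file.path(dir, side$image))
        masks <- lapply(side$masks, function(mf) {
            p <- file.path(dir, mf)
            if (!file.exists(p))
                stop("invalid input: missing truth mask '", p, "'")
            readMaskPNG(p)
        })
        new("SyntheticSlide", image = img, truth = masks[.TRUTH_CLASSES],
            spec = .specFromList(side$spec))
    })
}
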