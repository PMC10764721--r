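# Quantitative evaluation: Dice overlap, per-class inclusion fractions, the
# four-rule success verdict, a two-arm method comparison, and enumeration of
# the transform-positive region of the RGB colour cube.
#
# The success rubric asks that (i) all tissue is segmented, (ii) all
# background is rejected, (iii) all bounding boxes are rejected and (iv) all
# other artefacts are rejected. On rasters those absolutes are operationalised
# as quantitative proxies: tissue recall >= 0.95 and each non-tissue class
# inclusion <= 0.01. The thresholds are reported alongside every verdict.

.asLabels <- function(x) {
    if (is(x, "TissueSegmentation")) x@mask@labels
    else if (is(x, "BinaryMask")) x@labels
    else if (is.logical(x) && is.matrix(x)) x
    else stop("invalid input: expected a BinaryMask, TissueSegmentation ",
              "or logical matrix")
}

#' Sorensen-Dice coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [BinaryMask-class] objects (or logical matrices) of equal shape.
#' @return a number in \[0, 1\].
#' @export
diceCoefficient <- function(a, b) {
    la <- .asLabels(a); lb <- .asLabels(b)
    if (!identical(dim(la), dim(lb)))
        stop("invalid input: mask shapes differ (",
             paste(dim(la), collapse = "x"), " vs ",
             paste(dim(lb), collapse = "x"), ")")
    denom <- sum(la) + sum(lb)
    if (denom == 0) return(1)
    2 * sum(la & lb) / denom
}

#' Score a segmentation against a synthetic slide's ground truth
#'
#' Computes the Dice coefficient against the truth tissue mask, tissue
#' recall, and the fraction of each non-tissue truth class (background, pen,
#' box, scanner) wrongly labelled tissue. The verdict is `TRUE` when
#' `tissueRecall >= recallMin` and every inclusion fraction is
#' `<= inclusionMax`. Empty truth classes score recall 1 / inclusion 0.
#'
#' @param mask a [BinaryMask-class], [TissueSegmentation-class] or logical
#'   matrix, shaped like the slide.
#' @param slide a [SyntheticSlide-class].
#' @param recallMin minimum tissue recall for success (default 0.95).
#' @param inclusionMax maximum per-class inclusion for success (default 0.01).
#' @return an [EvaluationRecord-class].
#' @export
evaluateSlide <- function(mask, slide, recallMin = 0.95, inclusionMax = 0.01) {
    stopifnot(is(slide, "SyntheticSlide"))
    m <- .asLabels(mask)
    truth <- truthMasks(slide)
    if (!identical(dim(m), dim(truth$tissue@labels)))
        stop("invalid input: mask shape does not match the slide")
    frac <- function(cls) {
        t <- truth[[cls]]@labels
        if (!any(t)) 0 else sum(m & t) / sum(t)
    }
    recall <- {
        t <- truth$tissue@labels
        if (!any(t)) 1 else sum(m & t) / sum(t)
    }
    incl <- vapply(c("background", "pen", "box", "scanner"), frac, 0)
    new("EvaluationRecord",
        dice = diceCoefficient(m, truth$tissue@labels),
        tissueRecall = recall,
        backgroundInclusion = incl[["background"]],
        penInclusion = incl[["pen"]],
        boxInclusion = incl[["box"]],
        scannerInclusion = incl[["scanner"]],
        verdict = recall >= recallMin && all(incl <= inclusionMax))
}

.recordRow <- function(rec) {
    data.frame(dice = rec@dice, tissueRecall = rec@tissueRecall,
               backgroundInclusion = rec@backgroundInclusion,
               penInclusion = rec@penInclusion,
               boxInclusion = rec@boxInclusion,
               scannerInclusion = rec@scannerInclusion,
               verdict = rec@verdict)
}

#' Compare the purple-pink method and the luminance baseline on a suite
#'
#' Segments every slide with each requested method, scores it against the
#' ground truth and aggregates success counts per artefact category.
#'
#' @param suite list of [SyntheticSlide-class] objects.
#' @param nBins histogram bins passed to the segmenters.
#' @param methods subset of `c("he", "luminance")`.
#' @param recallMin,inclusionMax verdict thresholds (see [evaluateSlide()]).
#' @return list with elements `perSlide` (one data.frame row per slide and
#'   method), `aggregate` (success counts per category and method) and
#'   `parameters` (the settings used).
#' @export
compareMethods <- function(suite, nBins = 256L,
                           methods = c("he", "luminance"),
                           recallMin = 0.95, inclusionMax = 0.01) {
    methods <- match.arg(methods, c("he", "luminance"), several.ok = TRUE)
    rows <- list()
    for (i in seq_along(suite)) {
        slide <- suite[[i]]
        for (m in methods) {
            seg <- if (m == "he") segmentHE(slideImage(slide), nBins)
                   else segmentLuminance(slideImage(slide), nBins)
            rec <- evaluateSlide(seg, slide, recallMin, inclusionMax)
            rows[[length(rows) + 1L]] <- cbind(
                data.frame(slide = i, category = slideCategory(slide),
                           method = segMethod(seg),
                           threshold = thresholdValue(seg@thresholdResult),
                           degenerate = isDegenerate(seg)),
                .recordRow(rec))
        }
    }
    perSlide <- if (length(rows)) do.call(rbind, rows) else
        data.frame(slide = integer(), category = character(),
                   method = character(), threshold = numeric(),
                   degenerate = logical(), dice = numeric(),
                   tissueRecall = numeric(), backgroundInclusion = numeric(),
                   penInclusion = numeric(), boxInclusion = numeric(),
                   scannerInclusion = numeric(), verdict = logical())
    aggregate <- if (nrow(perSlide)) {
        agg <- stats::aggregate(verdict ~ category + method, perSlide,
                                function(v) c(n = length(v), success = sum(v)))
        data.frame(category = agg$category, method = agg$method,
                   n = agg$verdict[, "n"], nSuccess = agg$verdict[, "success"])
    } else {
        data.frame(category = character(), method = character(),
                   n = integer(), nSuccess = integer())
    }
    list(perSlide = perSlide, aggregate = aggregate,
         parameters = list(nBins = as.integer(nBins),
                           recallMin = recallMin,
                           inclusionMax = inclusionMax))
}

#' Write a method comparison as CSV and JSON
#'
#' @param comparison result of [compareMethods()].
#' @param csvPath,jsonPath output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
writeComparison <- function(comparison, csvPath = NULL, jsonPath = NULL) {
    if (!is.null(csvPath))
        utils::write.csv(comparison$perSlide, csvPath, row.names = FALSE)
    if (!is.null(jsonPath))
        jsonlite::write_json(
            list(schemaVersion = 1L, parameters = comparison$parameters,
                 aggregate = comparison$aggregate,
                 perSlide = comparison$perSlide),
            jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE,
            dataframe = "rows")
    invisible(c(csvPath, jsonPath))
}

#' Enumerate the transform-positive region of the RGB colour cube
#'
#' Samples each channel at `resolution` equally spaced values in \[0, 1\],
#' applies the purple-pink transform at every lattice point and collects the
#' points with a strictly positive value. These are exactly the points with
#' `R > G` and `B > G`: at resolution `n` there are
#' `sum over g of (n - 1 - g)^2` of them out of `n^3`.
#'
#' @param resolution samples per channel (>= 2).
#' @param keepPoints store the member triples? Defaults to `TRUE` up to
#'   resolution 64 (beyond that only the count and fraction are kept).
#' @return a [CubeMembership-class].
#' @examples
#' cubeMembership(2)  # only the magenta corner (1, 0, 1) is a member
#' @export
cubeMembership <- function(resolution, keepPoints = resolution <= 64) {
    resolution <- as.integer(resolution)
    if (is.na(resolution) || resolution < 2L)
        stop("invalid input: 'resolution' must be an integer >= 2")
    v <- seq(0, 1, length.out = resolution)
    count <- 0
    pts <- if (keepPoints) vector("list", resolution) else NULL
    for (gi in seq_len(resolution)) {
        rv <- relu(v - v[gi])
        tSlice <- outer(rv, rv)           # T at (r, g = v[gi], b)
        hit <- tSlice > 0
        count <- count + sum(hit)
        if (keepPoints && any(hit)) {
            w <- which(hit, arr.ind = TRUE)
            pts[[gi]] <- cbind(r = v[w[, 1L]], g = v[gi], b = v[w[, 2L]])
        }
    }
    mp <- if (keepPoints) do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
          else matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("r", "g", "b")))
    if (is.null(mp)) mp <- matrix(numeric(0), 0L, 3L,
                                  dimnames = list(NULL, c("r", "g", "b")))
    new("CubeMembership", resolution = resolution, memberPoints = mp,
        memberCount = count, memberFraction = count / resolution^3)
}
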