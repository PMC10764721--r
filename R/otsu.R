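# Histogram-based Otsu threshold solver, written from first principles, plus
# a brute-force maximizer over raw values that serves as an independent test
# oracle.
#
# Binning convention: equal-width bins over [0, max(values, eps)] rather than
# a fixed [0, 1]. The purple-pink transform concentrates its mass near zero
# (a typical eosin pixel maps to ~0.05), so fixed unit-range bins would
# collapse all tissue into a handful of bins; binning to the observed maximum
# keeps the solver scale-free. The domain actually used is recorded in the
# segmentation report.

.histEps <- 1e-12

.binIndices <- function(v, nBins, hi) {
    # right-most bin closed; values == hi land in bin nBins
    pmin(floor(v / (hi / nBins)) + 1L, nBins)
}

#' Build an equal-width histogram of an intensity map
#'
#' Bins span `[0, max(values, eps)]` with the right-most bin closed, so every
#' pixel is counted exactly once.
#'
#' @param x an [IntensityMap-class] or a non-negative numeric vector.
#' @param nBins number of bins (>= 2); default 256, the classical grey-level
#'   resolution Otsu's criterion was formulated on.
#' @return an [IntensityHistogram-class].
#' @export
buildHistogram <- function(x, nBins = 256L) {
    v <- if (is(x, "IntensityMap")) as.vector(x@values) else as.vector(x)
    if (length(v) == 0L) stop("invalid input: empty intensity map")
    if (!is.numeric(v) || any(!is.finite(v)))
        stop("invalid input: values must be finite numerics")
    if (min(v) < 0) stop("invalid input: values must be non-negative")
    nBins <- as.integer(nBins)
    if (nBins < 2L) stop("invalid input: 'nBins' must be >= 2")
    hi <- max(v, .histEps)
    counts <- tabulate(.binIndices(v, nBins, hi), nBins)
    new("IntensityHistogram",
        breaks = seq(0, hi, length.out = nBins + 1L),
        counts = as.integer(counts))
}

# Shared tie handling: indices of boundaries within relative tolerance of the
# maximum criterion, reduced to the contiguous run containing the argmax.
.maximizingRun <- function(sigma, valid) {
    smax <- max(sigma[valid])
    tol <- max(abs(smax) * 1e-10, 1e-300)
    hit <- valid & (sigma >= smax - tol)
    k <- which.max(replace(sigma, !valid, -Inf))
    lo <- k; while (lo > 1L && hit[lo - 1L]) lo <- lo - 1L
    hi <- k; while (hi < length(hit) && hit[hi + 1L]) hi <- hi + 1L
    c(lo, hi)
}

#' Otsu threshold of a histogram
#'
#' Finds the bin boundary maximizing the between-class variance
#' `sigma_b^2 = w0 * w1 * (mu0 - mu1)^2` (class means from bin midpoints)
#' over all boundaries leaving both classes non-empty. When several
#' contiguous boundaries tie, the midpoint of the tying range is returned
#' (Otsu's averaging rule), which keeps the cut deterministic and symmetric.
#' If no boundary yields two non-empty classes the result is flagged
#' `degenerate` with the threshold at the lowest edge.
#'
#' @param hist an [IntensityHistogram-class].
#' @return a [ThresholdResult-class].
#' @export
otsuThreshold <- function(hist) {
    stopifnot(is(hist, "IntensityHistogram"))
    counts <- as.numeric(hist@counts)
    n <- length(counts)
    breaks <- hist@breaks
    mids <- (breaks[-1L] + breaks[-(n + 1L)]) / 2
    total <- sum(counts)
    cw <- cumsum(counts)
    cm <- cumsum(counts * mids)
    k <- seq_len(n - 1L)
    valid <- cw[k] > 0 & cw[k] < total
    if (!any(valid))
        return(new("ThresholdResult", threshold = breaks[1L],
                   betweenClassVariance = 0, degenerate = TRUE))
    w0 <- cw[k] / total
    w1 <- 1 - w0
    mu0 <- ifelse(cw[k] > 0, cm[k] / cw[k], 0)
    mu1 <- ifelse(cw[k] < total, (cm[n] - cm[k]) / (total - cw[k]), 0)
    sigma <- w0 * w1 * (mu0 - mu1)^2
    run <- .maximizingRun(sigma, valid)
    thr <- (breaks[run[1L] + 1L] + breaks[run[2L] + 1L]) / 2
    new("ThresholdResult", threshold = thr,
        betweenClassVariance = max(sigma[valid]), degenerate = FALSE)
}

#' Brute-force Otsu threshold over raw values (test oracle)
#'
#' Independent check of [otsuThreshold()]: bins the raw values exactly as
#' [buildHistogram()] does (each value represented at its bin midpoint, the
#' histogram's level set) and then evaluates the between-class variance at
#' every candidate boundary from scratch — explicit per-class means over the
#' values on each side, no cumulative-sum recurrence. By construction it
#' solves the same discrete optimization as the histogram solver, so the two
#' must agree exactly; it is used only in tests.
#'
#' @param values numeric vector with at least two distinct values.
#' @param nBins number of bins defining the candidate boundaries.
#' @return a [ThresholdResult-class].
#' @export
bruteForceThreshold <- function(values, nBins = 256L) {
    v <- as.vector(values)
    if (length(unique(v)) < 2L)
        stop("invalid input: need at least 2 distinct values")
    if (any(!is.finite(v)) || min(v) < 0)
        stop("invalid input: values must be finite and non-negative")
    nBins <- as.integer(nBins)
    hi <- max(v, .histEps)
    idx <- .binIndices(v, nBins, hi)
    breaks <- seq(0, hi, length.out = nBins + 1L)
    mids <- (breaks[-1L] + breaks[-(nBins + 1L)]) / 2
    vq <- mids[idx]                      # each value at its bin's level
    total <- length(v)
    sigma <- numeric(nBins - 1L)
    valid <- logical(nBins - 1L)
    for (k in seq_len(nBins - 1L)) {
        left <- idx <= k
        n0 <- sum(left)
        if (n0 == 0L || n0 == total) next
        valid[k] <- TRUE
        mu0 <- mean(vq[left])
        mu1 <- mean(vq[!left])
        w0 <- n0 / total
        sigma[k] <- w0 * (1 - w0) * (mu0 - mu1)^2
    }
    if (!any(valid))
        return(new("ThresholdResult", threshold = breaks[1L],
                   betweenClassVariance = 0, degenerate = TRUE))
    run <- .maximizingRun(sigma, valid)
    thr <- (breaks[run[1L] + 1L] + breaks[run[2L] + 1L]) / 2
    new("ThresholdResult", threshold = thr,
        betweenClassVariance = max(sigma[valid]), degenerate = FALSE)
}
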