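#' Monte Carlo sampling of the per-cell mutation burden
#'
#' Draws \code{nSamples} independent cells. For each cell the copy
#' number \eqn{Z} (via its log10 exponent \eqn{L} for a log10-uniform
#' distribution), the error rate \eqn{\mu} and the replication counts
#' \eqn{x_1, x_2, x_3} are drawn independently from their configured
#' distributions, and the burden is
#' \eqn{B = G \cdot Z \cdot (x_1 + x_2 + x_3) \cdot \mu / k}.
#' Copy number is redrawn per cell: the sample describes a heterogeneous
#' cell population, not repeated draws at one tissue-wide \eqn{Z}.
#'
#' Draws are taken in a fixed documented order (all \eqn{L}, then all
#' \eqn{\mu}, then \eqn{x_1}, \eqn{x_2}, \eqn{x_3}) from a single
#' generator seeded with \code{seed}, so identical \code{(model,
#' nSamples, seed)} give bit-identical samples.
#'
#' With \code{poisson = TRUE} each continuous expected burden is
#' replaced by an integer draw from Poisson(\eqn{B}), layering count
#' noise on top of parameter uncertainty; the default keeps \eqn{B}
#' continuous, which is what the tail tables act on.
#'
#' @param model a [BurdenModel-class].
#' @param nSamples number of cells to draw (>= 1), default 1e6.
#' @param seed integer RNG seed, recorded in the result.
#' @param poisson logical, add a Poisson count layer (default
#'   \code{FALSE}).
#' @return A [BurdenSample-class].
#' @examples
#' s <- sampleBurden(BurdenModel(), nSamples = 1e4, seed = 7)
#' mean(burdenValues(s) >= 500)
#' @export
setMethod("sampleBurden", "BurdenModel",
    function(model, nSamples = 1e6L, seed = 1L, poisson = FALSE) {
    validObject(model)
    n <- as.integer(nSamples)
    if (is.na(n) || n < 1L) stop("'nSamples' must be >= 1")
    seed <- as.integer(seed)
    set.seed(seed)
    z  <- drawParam(model@copyNumber, n)
    mu <- drawParam(model@errorRate, n)
    x1 <- drawParam(model@x1, n)
    x2 <- drawParam(model@x2, n)
    x3 <- drawParam(model@x3, n)
    # factor order mirrors expectedBurden() so degenerate configurations
    # reproduce the closed form to the last bit
    b <- model@genomeLength * z * (mu / model@halvingFactor) * (x1 + x2 + x3)
    if (poisson) b <- as.numeric(stats::rpois(n, b))
    new("BurdenSample", values = b, model = model, nSamples = n,
        seed = seed, poisson = isTRUE(poisson))
})

#' Access the raw burden draws
#'
#' @param sample a [BurdenSample-class].
#' @return Numeric vector of per-cell burdens.
#' @export
burdenValues <- function(sample) {
    stopifnot(is(sample, "BurdenSample"))
    sample@values
}

setMethod("show", "BurdenSample", function(object) {
    cat(sprintf(paste0("BurdenSample: %d cells (%s, age %g y), seed %d%s\n",
                       "  mean %.1f, median %.1f mutations/cell\n"),
        object@nSamples,
        if (object@model@proliferating) "proliferating" else "non-proliferating",
        object@model@ageYears, object@seed,
        if (object@poisson) ", Poisson counts" else "",
        mean(object@values), stats::median(object@values)))
})

#' Default tail-probability thresholds
#'
#' The ten standard rows used for burden tables: at most 10, 50, 100,
#' 200 mutations per cell, and at least 500, 1000, 1500, 2000, 3000,
#' 5000.
#'
#' @return A data.frame with columns \code{direction} ("le"/"ge") and
#'   \code{threshold}.
#' @export
defaultThresholds <- function() {
    data.frame(
        direction = rep(c("le", "ge"), c(4L, 6L)),
        threshold = c(10, 50, 100, 200, 500, 1000, 1500, 2000, 3000, 5000))
}

#' Empirical tail probabilities of the burden distribution
#'
#' For each requested row, the fraction of sampled cells with burden
#' \code{<=} (direction \code{"le"}) or \code{>=} (direction
#' \code{"ge"}) the threshold. A draw exactly at a threshold counts
#' toward both directions.
#'
#' @param sample a non-empty [BurdenSample-class].
#' @param thresholds a data.frame with columns \code{direction} and
#'   \code{threshold} (default [defaultThresholds()]).
#' @return A [TailTable-class].
#' @examples
#' s <- sampleBurden(BurdenModel(), nSamples = 1e4, seed = 7)
#' as.data.frame(tailProbabilities(s))
#' @export
setMethod("tailProbabilities", "BurdenSample",
    function(sample, thresholds = defaultThresholds()) {
    if (sample@nSamples < 1L) stop("empty sample")
    stopifnot(is.data.frame(thresholds),
              all(c("direction", "threshold") %in% names(thresholds)),
              all(thresholds$direction %in% c("le", "ge")))
    v <- sample@values
    p <- mapply(function(dir, thr)
        if (dir == "le") mean(v <= thr) else mean(v >= thr),
        thresholds$direction, thresholds$threshold)
    new("TailTable", direction = as.character(thresholds$direction),
        threshold = as.numeric(thresholds$threshold),
        probability = as.numeric(p),
        nSamples = sample@nSamples, seed = sample@seed)
})

#' Coerce a TailTable to a data.frame
#'
#' @param x a [TailTable-class].
#' @param row.names,optional,... standard coercion arguments, unused.
#' @return A data.frame with columns \code{direction}, \code{threshold},
#'   \code{probability}.
#' @export
setMethod("as.data.frame", "TailTable",
    function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(direction = x@direction, threshold = x@threshold,
               probability = x@probability)
})

setMethod("show", "TailTable", function(object) {
    cat(sprintf("TailTable (%d draws, seed %d):\n",
                object@nSamples, object@seed))
    df <- as.data.frame(object)
    df$row <- sprintf("%s%g", ifelse(df$direction == "le", "<=", ">="),
                      df$threshold)
    print(data.frame(mutations = df$row, probability = df$probability),
          row.names = FALSE)
})

#' Reversed cumulative distribution of the burden
#'
#' Returns \eqn{P(B \ge x)} on a user-supplied ascending grid — the
#' probability of at least \eqn{x} mutations per cell, the curve usually
#' plotted to compare proliferating and non-proliferating lineages.
#'
#' @param sample a non-empty [BurdenSample-class].
#' @param grid ascending numeric vector of burden values.
#' @return A data.frame with columns \code{x} and \code{probability};
#'   \code{probability} is non-increasing in \code{x}.
#' @export
setMethod("reversedCDF", "BurdenSample", function(sample, grid) {
    if (sample@nSamples < 1L) stop("empty sample")
    if (is.unsorted(grid)) stop("'grid' must be sorted ascending")
    # P(B >= x) = 1 - F(x-) ; ecdf gives F(x) = P(B <= x), so count >= x
    # directly via the sorted sample.
    sv <- sort(sample@values)
    nGE <- sample@nSamples - findInterval(grid, sv, left.open = TRUE)
    data.frame(x = as.numeric(grid),
               probability = nGE / sample@nSamples)
})

#' Summary statistics and histogram of a burden sample
#'
#' @param sample a non-empty [BurdenSample-class].
#' @param breaks histogram bin count or break vector (passed to
#'   [graphics::hist()] semantics via [base::cut()]-free binning with
#'   \code{hist(plot = FALSE)}).
#' @return A list with elements \code{mean}, \code{sd}, \code{quantiles}
#'   (1, 5, 25, 50, 75, 95, 99 percent), \code{histBreaks} and
#'   \code{histCounts} (counts summing to the sample size), plus
#'   \code{nSamples} and \code{seed}.
#' @export
setMethod("burdenSummary", "BurdenSample", function(sample, breaks = 50L) {
    if (sample@nSamples < 1L) stop("empty sample")
    v <- sample@values
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    list(mean = mean(v), sd = stats::sd(v),
         quantiles = stats::quantile(v, c(.01, .05, .25, .50, .75, .95, .99)),
         histBreaks = h$breaks, histCounts = h$counts,
         nSamples = sample@nSamples, seed = sample@seed)
})
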