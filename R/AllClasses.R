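#' @import methods
NULL

.DIST_KINDS <- c("fixed", "uniform", "log10_uniform")

#' ParamDistribution: a scalar model parameter with uncertainty
#'
#' Describes one scalar parameter of the burden model as either a fixed
#' value, a uniform distribution on an interval, or a log10-uniform
#' distribution (the base-10 logarithm of the quantity is uniform on
#' \code{[lower, upper]}, so \code{lower} and \code{upper} are exponents).
#'
#' @slot kind character, one of \code{"fixed"}, \code{"uniform"},
#'   \code{"log10_uniform"}.
#' @slot value numeric, the value for a fixed parameter (NA otherwise).
#' @slot lower,upper numeric interval bounds for the two interval kinds
#'   (exponents for \code{"log10_uniform"}; NA for \code{"fixed"}).
#'
#' @seealso [fixedParam()], [uniformParam()], [log10UniformParam()],
#'   [distMean()], [geometricMean()], [drawParam()]
#' @export
setClass("ParamDistribution",
    representation(kind = "character", value = "numeric",
                   lower = "numeric", upper = "numeric"),
    prototype(kind = "fixed", value = 0, lower = NA_real_, upper = NA_real_))

setValidity("ParamDistribution", function(object) {
    msg <- NULL
    if (length(object@kind) != 1L || !object@kind %in% .DIST_KINDS)
        msg <- c(msg, sprintf("'kind' must be one of: %s",
                              paste(.DIST_KINDS, collapse = ", ")))
    else if (object@kind == "fixed") {
        if (length(object@value) != 1L || !is.finite(object@value))
            msg <- c(msg, "'value' must be a single finite number for kind 'fixed'")
    } else {
        if (length(object@lower) != 1L || length(object@upper) != 1L ||
            !is.finite(object@lower) || !is.finite(object@upper))
            msg <- c(msg, "'lower' and 'upper' must be single finite numbers")
        else if (object@lower > object@upper)
            msg <- c(msg, "'lower' must not exceed 'upper'")
    }
    if (is.null(msg)) TRUE else msg
})

#' BurdenModel: full parameterization of the per-cell mutation burden
#'
#' Container for the somatic mtDNA mutation-burden model
#' \eqn{B = G \cdot Z \cdot (X_1 + X_2 + X_3) \cdot \mu / k}, where
#' \eqn{G} is the mtDNA genome length in bp, \eqn{Z} the per-cell mtDNA
#' copy number, \eqn{\mu} the POLG per-base per-replication error rate,
#' \eqn{X_1}–\eqn{X_3} the developmental, turnover and proliferation
#' replication-round counts, and \eqn{k} the halving factor converting
#' the raw polymerase error rate into an effective mutation rate
#' (each de novo mutation has an even chance of being lost at the next
#' segregation or turnover event, hence the default \eqn{k = 2}).
#'
#' @slot genomeLength single positive number, mtDNA length in bp.
#' @slot copyNumber,errorRate,x1,x2,x3 [ParamDistribution-class] objects
#'   for \eqn{Z}, \eqn{\mu}, \eqn{X_1}, \eqn{X_2}, \eqn{X_3}.
#' @slot proliferating logical; \code{FALSE} forces \code{x3} to the
#'   fixed distribution at 0.
#' @slot halvingFactor single positive number (default 2).
#' @slot ageYears single non-negative number, the age the replication
#'   counts refer to.
#'
#' @seealso [BurdenModel()], [expectedBurden()], [sampleBurden()]
#' @export
setClass("BurdenModel",
    representation(genomeLength = "numeric",
                   copyNumber = "ParamDistribution",
                   errorRate = "ParamDistribution",
                   x1 = "ParamDistribution",
                   x2 = "ParamDistribution",
                   x3 = "ParamDistribution",
                   proliferating = "logical",
                   halvingFactor = "numeric",
                   ageYears = "numeric"))

.distSupportMin <- function(d) if (d@kind == "fixed") d@value else
    if (d@kind == "log10_uniform") 10^d@lower else d@lower

setValidity("BurdenModel", function(object) {
    msg <- NULL
    if (length(object@genomeLength) != 1L || !is.finite(object@genomeLength) ||
        object@genomeLength <= 0)
        msg <- c(msg, "'genomeLength' must be a single positive number")
    if (length(object@halvingFactor) != 1L || !is.finite(object@halvingFactor) ||
        object@halvingFactor <= 0)
        msg <- c(msg, "'halvingFactor' must be a single positive number")
    if (length(object@proliferating) != 1L || is.na(object@proliferating))
        msg <- c(msg, "'proliferating' must be TRUE or FALSE")
    if (length(object@ageYears) != 1L || !is.finite(object@ageYears) ||
        object@ageYears < 0)
        msg <- c(msg, "'ageYears' must be a single non-negative number")
    for (nm in c("copyNumber", "errorRate", "x1", "x2", "x3")) {
        d <- slot(object, nm)
        if (.distSupportMin(d) < 0)
            msg <- c(msg, sprintf("support of '%s' must be non-negative", nm))
    }
    if (isFALSE(object@proliferating) &&
        !(object@x3@kind == "fixed" && object@x3@value == 0))
        msg <- c(msg, "a non-proliferating model must have 'x3' fixed at 0")
    if (is.null(msg)) TRUE else msg
})

#' TurnoverParams: calendar constants for replication-round accounting
#'
#' @slot halfLifeDays mtDNA half-life in days (default 91.3125, i.e.
#'   3 months of 365.25/4 days).
#' @slot hscCycleWeeks stem-cell self-renewal interval in weeks
#'   (default 40).
#' @slot daysPerYear,weeksPerYear calendar conventions (365.25, 52.18).
#'
#' @seealso [TurnoverParams()], [turnoverRounds()], [hscExtraRounds()]
#' @export
setClass("TurnoverParams",
    representation(halfLifeDays = "numeric", hscCycleWeeks = "numeric",
                   daysPerYear = "numeric", weeksPerYear = "numeric"),
    prototype(halfLifeDays = 91.3125, hscCycleWeeks = 40,
              daysPerYear = 365.25, weeksPerYear = 52.18))

setValidity("TurnoverParams", function(object) {
    msg <- NULL
    for (nm in c("halfLifeDays", "hscCycleWeeks", "daysPerYear", "weeksPerYear")) {
        v <- slot(object, nm)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("'%s' must be a single positive number", nm))
    }
    if (is.null(msg)) TRUE else msg
})

#' BurdenSample: Monte Carlo draws of the per-cell mutation burden
#'
#' Holds the simulated per-cell burdens together with the model, sample
#' size and seed that produced them, so that every downstream table or
#' export can be reproduced exactly.
#'
#' @slot values numeric vector of non-negative per-cell burden draws.
#' @slot model the [BurdenModel-class] the draws came from.
#' @slot nSamples integer, number of draws.
#' @slot seed integer seed used for the draws.
#' @slot poisson logical; if \code{TRUE} the values were rounded to
#'   integer counts through a Poisson layer.
#'
#' @seealso [sampleBurden()], [tailProbabilities()], [reversedCDF()],
#'   [burdenSummary()]
#' @export
setClass("BurdenSample",
    representation(values = "numeric", model = "BurdenModel",
                   nSamples = "integer", seed = "integer",
                   poisson = "logical"))

setValidity("BurdenSample", function(object) {
    msg <- NULL
    if (length(object@values) != object@nSamples)
        msg <- c(msg, "length(values) must equal nSamples")
    if (object@nSamples < 1L)
        msg <- c(msg, "'nSamples' must be >= 1")
    if (any(object@values < 0))
        msg <- c(msg, "burden values must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' TailTable: tail probabilities of the burden distribution
#'
#' One row per threshold, each carrying a direction (\code{"le"} for
#' \eqn{P(B \le x)}, \code{"ge"} for \eqn{P(B \ge x)}) and the estimated
#' probability. Ties (a draw exactly at the threshold) count toward both
#' directions.
#'
#' @slot direction character vector of \code{"le"}/\code{"ge"}.
#' @slot threshold numeric thresholds.
#' @slot probability numeric probabilities in \code{[0, 1]}.
#' @slot nSamples,seed provenance of the estimates.
#'
#' @seealso [tailProbabilities()], [defaultThresholds()]
#' @export
setClass("TailTable",
    representation(direction = "character", threshold = "numeric",
                   probability = "numeric", nSamples = "integer",
                   seed = "integer"))

setValidity("TailTable", function(object) {
    msg <- NULL
    n <- length(object@direction)
    if (length(object@threshold) != n || length(object@probability) != n)
        msg <- c(msg, "'direction', 'threshold' and 'probability' must have equal length")
    if (!all(object@direction %in% c("le", "ge")))
        msg <- c(msg, "'direction' entries must be 'le' or 'ge'")
    if (any(object@probability < 0 | object@probability > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' DriftParams: deterministic heteroplasmy projection parameters
#'
#' @slot h0 starting heteroplasmy fraction in \code{[0, 1]}.
#' @slot advantage stated per-round proliferative advantage \eqn{s}
#'   (a fraction, e.g. 0.02 for a 2\% advantage), \eqn{s \ge 0}.
#' @slot nRounds non-negative integer count of replication rounds.
#' @slot convention \code{"halved"} (effective advantage \eqn{a = s/2},
#'   the default) or \code{"full"} (\eqn{a = s}).
#'
#' @seealso [DriftParams()], [projectHeteroplasmy()], [roundsToThreshold()]
#' @export
setClass("DriftParams",
    representation(h0 = "numeric", advantage = "numeric",
                   nRounds = "integer", convention = "character"),
    prototype(h0 = 0.01, advantage = 0.02, nRounds = 280L,
              convention = "halved"))

setValidity("DriftParams", function(object) {
    msg <- NULL
    if (length(object@h0) != 1L || !is.finite(object@h0) ||
        object@h0 < 0 || object@h0 > 1)
        msg <- c(msg, "'h0' must be a single number in [0, 1]")
    if (length(object@advantage) != 1L || !is.finite(object@advantage) ||
        object@advantage < 0)
        msg <- c(msg, "'advantage' must be a single non-negative number")
    if (length(object@nRounds) != 1L || is.na(object@nRounds) ||
        object@nRounds < 0L)
        msg <- c(msg, "'nRounds' must be a single non-negative integer")
    if (length(object@convention) != 1L ||
        !object@convention %in% c("halved", "full"))
        msg <- c(msg, "'convention' must be 'halved' or 'full'")
    if (is.null(msg)) TRUE else msg
})
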