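#' Construct a per-cell mutation-burden model
#'
#' Builds a [BurdenModel-class] with literature defaults: genome length
#' 16,569 bp; copy number \eqn{Z} log10-uniform with exponents on
#' \code{[2, 4]} (geometric mean 1000); POLG error rate \eqn{\mu}
#' uniform on \code{[2.8e-8, 5.6e-7]} per base per replication;
#' developmental replications \eqn{X_1 \sim} Unif(10, 80); turnover
#' replications \eqn{X_2 \sim} Unif(180, 380) at age 70; extra
#' proliferation replications \eqn{X_3 \sim} Unif(81, 101) at age 70 for
#' a proliferating (stem-cell-like) lineage, or fixed at 0 otherwise.
#'
#' For ages other than 70 the \eqn{X_2} and \eqn{X_3} default intervals
#' scale linearly with age (both bounds multiplied by \code{ageYears/70},
#' keeping the coefficient of variation constant); \eqn{X_1} is
#' developmental and age-independent. Explicitly supplied distributions
#' are never rescaled.
#'
#' @param genomeLength mtDNA length in bp.
#' @param copyNumber,errorRate,x1,x2,x3 [ParamDistribution-class]
#'   objects (or \code{NULL} to use the age-appropriate default).
#' @param proliferating logical; \code{FALSE} fixes \code{x3} at 0.
#' @param halvingFactor divisor converting the raw polymerase error rate
#'   into the effective mutation rate (default 2: a new mutation has an
#'   even chance of being lost to segregation or turnover).
#' @param ageYears age in years (default 70).
#' @return A validated [BurdenModel-class] object.
#' @examples
#' m <- BurdenModel()
#' expectedBurden(m)                        # about 1013 mutations/cell
#' expectedBurden(BurdenModel(proliferating = FALSE))
#' @export
BurdenModel <- function(genomeLength = 16569,
                        copyNumber = log10UniformParam(2, 4),
                        errorRate = uniformParam(2.8e-8, 5.6e-7),
                        x1 = uniformParam(10, 80),
                        x2 = NULL, x3 = NULL,
                        proliferating = TRUE,
                        halvingFactor = 2,
                        ageYears = 70) {
    f <- ageYears / 70
    if (is.null(x2)) x2 <- uniformParam(180 * f, 380 * f)
    if (is.null(x3)) x3 <- uniformParam(81 * f, 101 * f)
    if (!proliferating) x3 <- fixedParam(0)
    new("BurdenModel", genomeLength = as.numeric(genomeLength),
        copyNumber = copyNumber, errorRate = errorRate,
        x1 = x1, x2 = x2, x3 = x3,
        proliferating = as.logical(proliferating),
        halvingFactor = as.numeric(halvingFactor),
        ageYears = as.numeric(ageYears))
}

#' Closed-form expected mutation burden per cell
#'
#' Evaluates \eqn{E(B) = G \cdot \tilde{Z} \cdot E(\mu)/k \cdot
#' (E(X_1) + E(X_2) + E(X_3))}, where \eqn{\tilde{Z}} is the geometric
#' mean of the copy-number distribution (its fixed value if fixed). The
#' geometric-mean convention keeps the headline expectation at the
#' representative copy number of 1000 rather than the arithmetic mean of
#' the heavily right-skewed log10-uniform distribution (about 2149); the
#' Monte Carlo sample mean from [sampleBurden()] tracks the arithmetic
#' mean instead and is therefore roughly twice as large.
#'
#' @param model a [BurdenModel-class]; its copy number must be fixed or
#'   log10-uniform (a plain uniform copy number has no geometric-mean
#'   convention in the closed form and raises an error).
#' @return Expected mutations per cell (a single number, not rounded).
#' @examples
#' round(expectedBurden(BurdenModel()))                              # 1013
#' round(expectedBurden(BurdenModel(errorRate = fixedParam(5.6e-7)))) # 1930
#' @export
setMethod("expectedBurden", "BurdenModel", function(model) {
    validObject(model)
    if (!model@copyNumber@kind %in% c("fixed", "log10_uniform"))
        stop("unsupported configuration: the closed form requires a 'fixed' ",
             "or 'log10_uniform' copy-number distribution")
    zTilde <- geometricMean(model@copyNumber)
    ey <- arithMean(model@x1) + arithMean(model@x2) + arithMean(model@x3)
    model@genomeLength * zTilde *
        (arithMean(model@errorRate) / model@halvingFactor) * ey
})

setMethod("show", "BurdenModel", function(object) {
    fmt <- function(d) switch(d@kind,
        fixed = sprintf("fixed %g", d@value),
        uniform = sprintf("Unif(%g, %g)", d@lower, d@upper),
        log10_uniform = sprintf("log10-Unif(%g, %g)", d@lower, d@upper))
    cat("BurdenModel (", if (object@proliferating) "proliferating"
        else "non-proliferating", ", age ", object@ageYears, " y)\n",
        "  genome length: ", object@genomeLength, " bp",
        " | halving factor: ", object@halvingFactor, "\n",
        "  Z  (copy number): ", fmt(object@copyNumber), "\n",
        "  mu (error rate):  ", fmt(object@errorRate), "\n",
        "  X1 (development): ", fmt(object@x1), "\n",
        "  X2 (turnover):    ", fmt(object@x2), "\n",
        "  X3 (proliferation): ", fmt(object@x3), "\n",
        "  E(B) = ", round(expectedBurden(object), 1), " mutations/cell\n",
        sep = "")
})

#' Calendar and turnover constants
#'
#' @param halfLifeDays mtDNA half-life in days; the default 91.3125 is
#'   3 months at 365.25 days/year.
#' @param hscCycleWeeks stem-cell self-renewal interval in weeks.
#' @param daysPerYear,weeksPerYear calendar conventions.
#' @return A validated [TurnoverParams-class] object.
#' @export
TurnoverParams <- function(halfLifeDays = 91.3125, hscCycleWeeks = 40,
                           daysPerYear = 365.25, weeksPerYear = 52.18) {
    new("TurnoverParams", halfLifeDays = as.numeric(halfLifeDays),
        hscCycleWeeks = as.numeric(hscCycleWeeks),
        daysPerYear = as.numeric(daysPerYear),
        weeksPerYear = as.numeric(weeksPerYear))
}

setMethod("show", "TurnoverParams", function(object) {
    cat(sprintf(paste0("TurnoverParams: half-life %g d, HSC cycle %g wk ",
                       "(%g d/y, %g wk/y)\n"),
        object@halfLifeDays, object@hscCycleWeeks,
        object@daysPerYear, object@weeksPerYear))
})
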