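#' Construct parameter distributions
#'
#' Convenience constructors for [ParamDistribution-class] objects. A
#' fixed parameter is a point mass; a uniform parameter is uniform on
#' \code{[lower, upper]}; a log10-uniform parameter has its base-10
#' logarithm uniform on \code{[lower, upper]} (the bounds are exponents,
#' so \code{log10UniformParam(2, 4)} spans 100 to 10,000).
#'
#' @param value the fixed value.
#' @param lower,upper interval bounds (exponents for the log10 kind).
#' @return A [ParamDistribution-class] object.
#' @examples
#' distMean(uniformParam(2.8e-8, 5.6e-7))   # POLG error-rate midpoint
#' geometricMean(log10UniformParam(2, 4))   # copy-number geometric mean 1000
#' @export
fixedParam <- function(value)
    new("ParamDistribution", kind = "fixed", value = as.numeric(value),
        lower = NA_real_, upper = NA_real_)

#' @rdname fixedParam
#' @export
uniformParam <- function(lower, upper)
    new("ParamDistribution", kind = "uniform", value = NA_real_,
        lower = as.numeric(lower), upper = as.numeric(upper))

#' @rdname fixedParam
#' @export
log10UniformParam <- function(lower, upper)
    new("ParamDistribution", kind = "log10_uniform", value = NA_real_,
        lower = as.numeric(lower), upper = as.numeric(upper))

#' Mean of a parameter distribution
#'
#' For a fixed parameter the value itself; for a uniform parameter the
#' interval midpoint; for a log10-uniform parameter the mean of the
#' exponent, i.e. \code{(lower + upper) / 2} on the log10 scale. Use
#' [geometricMean()] to map a log10-uniform mean back to the natural
#' scale, or [arithMean()] for the arithmetic mean of the quantity.
#'
#' @param x a [ParamDistribution-class] object.
#' @return A single number.
#' @export
setMethod("distMean", "ParamDistribution", function(x) {
    switch(x@kind,
        fixed = x@value,
        uniform = (x@lower + x@upper) / 2,
        log10_uniform = (x@lower + x@upper) / 2)
})

#' Geometric mean of a parameter distribution
#'
#' Defined for log10-uniform parameters as \code{10^((lower+upper)/2)}
#' and for fixed parameters as the value; undefined (error) for plain
#' uniform parameters.
#'
#' @param x a [ParamDistribution-class] object.
#' @return A single number.
#' @export
setMethod("geometricMean", "ParamDistribution", function(x) {
    switch(x@kind,
        fixed = x@value,
        log10_uniform = 10^((x@lower + x@upper) / 2),
        stop("geometricMean() is defined for 'fixed' and 'log10_uniform' ",
             "parameters only"))
})

#' Arithmetic mean of the quantity itself
#'
#' Unlike [distMean()], which for a log10-uniform parameter returns the
#' mean exponent, this returns \eqn{E[10^L] = (10^u - 10^l) /
#' ((u - l)\ln 10)} — the arithmetic mean of the natural-scale quantity.
#' For the default copy-number distribution (exponents on \code{[2, 4]})
#' this is about 2149, far above the geometric mean of 1000; the
#' closed-form expected burden deliberately uses the geometric mean.
#'
#' @param x a [ParamDistribution-class] object.
#' @return A single number.
#' @export
arithMean <- function(x) {
    stopifnot(is(x, "ParamDistribution"))
    switch(x@kind,
        fixed = x@value,
        uniform = (x@lower + x@upper) / 2,
        log10_uniform = if (x@lower == x@upper) 10^x@lower else
            (10^x@upper - 10^x@lower) / ((x@upper - x@lower) * log(10)))
}

#' Draw random values from a parameter distribution
#'
#' @param x a [ParamDistribution-class] object.
#' @param n number of draws.
#' @return Numeric vector of length \code{n}; draws use the current RNG
#'   state (seed management belongs to the caller).
#' @export
setMethod("drawParam", "ParamDistribution", function(x, n) {
    n <- as.integer(n)
    switch(x@kind,
        fixed = rep.int(x@value, n),
        uniform = stats::runif(n, x@lower, x@upper),
        log10_uniform = 10^stats::runif(n, x@lower, x@upper))
})

setMethod("show", "ParamDistribution", function(object) {
    cat(switch(object@kind,
        fixed = sprintf("ParamDistribution: fixed at %g", object@value),
        uniform = sprintf("ParamDistribution: Unif(%g, %g)",
                          object@lower, object@upper),
        log10_uniform = sprintf(
            "ParamDistribution: log10-Unif(%g, %g) [%g .. %g]",
            object@lower, object@upper, 10^object@lower, 10^object@upper)),
        "\n")
})
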