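#' @rdname distMean
#' @export
setGeneric("distMean", function(x) standardGeneric("distMean"))

#' @rdname geometricMean
#' @export
setGeneric("geometricMean", function(x) standardGeneric("geometricMean"))

#' @rdname drawParam
#' @export
setGeneric("drawParam", function(x, n) standardGeneric("drawParam"))

#' @rdname expectedBurden
#' @export
setGeneric("expectedBurden", function(model) standardGeneric("expectedBurden"))

#' @rdname sampleBurden
#' @export
setGeneric("sampleBurden",
    function(model, nSamples = 1e6L, seed = 1L, poisson = FALSE)
        standardGeneric("sampleBurden"))

#' @rdname tailProbabilities
#' @export
setGeneric("tailProbabilities",
    function(sample, thresholds = defaultThresholds())
        standardGeneric("tailProbabilities"))

#' @rdname reversedCDF
#' @export
setGeneric("reversedCDF", function(sample, grid) standardGeneric("reversedCDF"))

#' @rdname burdenSummary
#' @export
setGeneric("burdenSummary",
    function(sample, breaks = 50L) standardGeneric("burdenSummary"))

#' @rdname projectHeteroplasmy
#' @export
setGeneric("projectHeteroplasmy",
    function(params, ...) standardGeneric("projectHeteroplasmy"))
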