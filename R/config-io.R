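## JSON configuration round-trip. The on-disk schema mirrors the model
## field names: a "model" block (genome_length_bp, copy_number,
## polg_error_rate, x1, x2, x3, proliferating, halving_factor,
## age_years), a "turnover" block (half_life_days, hsc_cycle_weeks,
## days_per_year, weeks_per_year), a "simulation" block (n_samples,
## seed) and an optional "drift" array of projection scenarios
## (h0, advantage, n_rounds, convention). Every distribution is written
## as {kind, value | lower, upper}.

.distToList <- function(d) {
    if (d@kind == "fixed") list(kind = "fixed", value = d@value)
    else list(kind = d@kind, lower = d@lower, upper = d@upper)
}

.listToDist <- function(x, field) {
    if (is.null(x$kind))
        stop(sprintf("distribution '%s' is missing its 'kind'", field))
    switch(x$kind,
        fixed = {
            if (is.null(x$value))
                stop(sprintf("fixed distribution '%s' needs 'value'", field))
            fixedParam(x$value)
        },
        uniform = ,
        log10_uniform = {
            if (is.null(x$lower) || is.null(x$upper))
                stop(sprintf("interval distribution '%s' needs 'lower' and 'upper'",
                             field))
            if (x$kind == "uniform") uniformParam(x$lower, x$upper)
            else log10UniformParam(x$lower, x$upper)
        },
        stop(sprintf("unknown distribution kind '%s' for '%s'", x$kind, field)))
}

.modelToList <- function(m) list(
    genome_length_bp = m@genomeLength,
    copy_number = .distToList(m@copyNumber),
    polg_error_rate = .distToList(m@errorRate),
    x1 = .distToList(m@x1), x2 = .distToList(m@x2), x3 = .distToList(m@x3),
    proliferating = m@proliferating,
    halving_factor = m@halvingFactor,
    age_years = m@ageYears)

.listToModel <- function(x) {
    pick <- function(nm, default) if (is.null(x[[nm]])) default else x[[nm]]
    prolif <- isTRUE(pick("proliferating", TRUE))
    age <- pick("age_years", 70)
    dist <- function(nm, default)
        if (is.null(x[[nm]])) default else .listToDist(x[[nm]], nm)
    BurdenModel(
        genomeLength = pick("genome_length_bp", 16569),
        copyNumber = dist("copy_number", log10UniformParam(2, 4)),
        errorRate = dist("polg_error_rate", uniformParam(2.8e-8, 5.6e-7)),
        x1 = dist("x1", uniformParam(10, 80)),
        x2 = if (is.null(x$x2)) NULL else .listToDist(x$x2, "x2"),
        x3 = if (is.null(x$x3) || !prolif) NULL else .listToDist(x$x3, "x3"),
        proliferating = prolif,
        halvingFactor = pick("halving_factor", 2),
        ageYears = age)
}

.turnoverToList <- function(tp) list(
    half_life_days = tp@halfLifeDays, hsc_cycle_weeks = tp@hscCycleWeeks,
    days_per_year = tp@daysPerYear, weeks_per_year = tp@weeksPerYear)

.listToTurnover <- function(x) {
    pick <- function(nm, default) if (is.null(x[[nm]])) default else x[[nm]]
    TurnoverParams(halfLifeDays = pick("half_life_days", 91.3125),
                   hscCycleWeeks = pick("hsc_cycle_weeks", 40),
                   daysPerYear = pick("days_per_year", 365.25),
                   weeksPerYear = pick("weeks_per_year", 52.18))
}

.driftToList <- function(d) list(h0 = d@h0, advantage = d@advantage,
                                 n_rounds = d@nRounds,
                                 convention = d@convention)

.listToDrift <- function(x) {
    for (nm in c("h0", "advantage", "n_rounds"))
        if (is.null(x[[nm]]))
            stop(sprintf("drift scenario is missing '%s'", nm))
    DriftParams(x$h0, x$advantage, x$n_rounds,
                if (is.null(x$convention)) "halved" else x$convention)
}

#' Read a burden-model configuration from JSON
#'
#' Parses and validates a configuration file; any structural or domain
#' problem raises an error naming the offending field, and nothing is
#' partially constructed. Missing blocks fall back to the package
#' defaults, so \code{{}} is a valid configuration describing the
#' default age-70 proliferating model.
#'
#' @param path path to a JSON configuration file, or \code{NULL} for
#'   the bundled default (\code{system.file("extdata",
#'   "default-config.json", package = "mitoburden")}).
#' @return A named list with components \code{model} (a
#'   [BurdenModel-class]), \code{turnover} (a [TurnoverParams-class]),
#'   \code{simulation} (list with \code{nSamples} and \code{seed}) and
#'   \code{drift} (list of [DriftParams-class] scenarios, possibly
#'   empty).
#' @seealso [writeBurdenConfig()], [runBurdenReport()]
#' @export
readBurdenConfig <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "default-config.json",
                            package = "mitoburden")
    if (!file.exists(path)) stop("configuration file not found: ", path)
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    sim <- raw$simulation
    pickN <- function(nm, default)
        if (is.null(sim[[nm]])) default else as.integer(sim[[nm]])
    nSamples <- pickN("n_samples", 1000000L)
    if (is.na(nSamples) || nSamples < 1L)
        stop("'simulation$n_samples' must be a positive integer")
    config <- list(
        model = .listToModel(raw$model),
        turnover = .listToTurnover(raw$turnover),
        simulation = list(nSamples = nSamples, seed = pickN("seed", 1L)),
        drift = lapply(raw$drift, .listToDrift))
    validObject(config$model)
    validObject(config$turnover)
    config
}

#' Write a burden-model configuration to JSON
#'
#' Serializes a configuration list (as returned by [readBurdenConfig()])
#' so that reading it back reproduces the same resolved configuration —
#' parse, serialize, parse is the identity.
#'
#' @param config a configuration list with components \code{model},
#'   \code{turnover}, \code{simulation}, \code{drift}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBurdenConfig <- function(config, path) {
    stopifnot(is(config$model, "BurdenModel"),
              is(config$turnover, "TurnoverParams"))
    out <- list(
        model = .modelToList(config$model),
        turnover = .turnoverToList(config$turnover),
        simulation = list(n_samples = config$simulation$nSamples,
                          seed = config$simulation$seed),
        drift = lapply(config$drift, .driftToList))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
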