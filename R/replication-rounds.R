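#' Replication rounds imposed by mtDNA turnover
#'
#' Even in post-mitotic cells, mtDNA is continually degraded and
#' resynthesized (relaxed replication). Each elapsed half-life removes
#' half the population, which must be replaced by one
#' population-doubling-equivalent of replication, so the number of
#' turnover rounds by a given age is \code{ageYears * daysPerYear /
#' halfLifeDays}.
#'
#' @param ageYears age in years (>= 0).
#' @param halfLifeDays mtDNA half-life in days (> 0).
#' @param daysPerYear calendar convention, default 365.25.
#' @return Replication rounds (real; round to taste). A 3-month
#'   half-life gives ~280 rounds by age 70; a 12-day half-life ~2131; a
#'   12-month half-life 70.
#' @examples
#' round(turnoverRounds(70, 91.3125))  # 280
#' round(turnoverRounds(70, 12))       # 2131
#' @export
turnoverRounds <- function(ageYears, halfLifeDays, daysPerYear = 365.25) {
    stopifnot(is.numeric(ageYears), all(ageYears >= 0))
    if (!is.numeric(halfLifeDays) || any(halfLifeDays <= 0))
        stop("'halfLifeDays' must be positive")
    ageYears * daysPerYear / halfLifeDays
}

#' Extra replication rounds from stem-cell self-renewal
#'
#' A proliferating lineage such as hematopoietic stem cells adds one
#' full mtDNA doubling per self-renewal cycle on top of turnover:
#' \code{ageYears * weeksPerYear / cycleWeeks}.
#'
#' @param ageYears age in years (>= 0).
#' @param cycleWeeks self-renewal interval in weeks (> 0), default 40.
#' @param weeksPerYear calendar convention, default 52.18.
#' @return Additional replication rounds; ~91 by age 70 at a 40-week
#'   cycle.
#' @examples
#' round(hscExtraRounds(70, 40))  # 91
#' @export
hscExtraRounds <- function(ageYears, cycleWeeks = 40, weeksPerYear = 52.18) {
    stopifnot(is.numeric(ageYears), all(ageYears >= 0))
    if (!is.numeric(cycleWeeks) || any(cycleWeeks <= 0))
        stop("'cycleWeeks' must be positive")
    ageYears * weeksPerYear / cycleWeeks
}

#' Complete population doublings needed to reach a cell count
#'
#' \code{floor(log2(nCells))}: the number of complete doublings achieved
#' starting from a single cell — the conservative ("at least") reading
#' of developmental division counts. The adult human estimate of
#' 3.72e13 cells gives 45 doublings (2^45 is about 3.52e13, one short of
#' the target, so 45 understates the true division count by at most
#' one round).
#'
#' @param nCells cell count (>= 1).
#' @return Integer doublings.
#' @examples
#' divisionsToCellCount(3.72e13)  # 45
#' @export
divisionsToCellCount <- function(nCells) {
    if (!is.numeric(nCells) || any(nCells < 1))
        stop("'nCells' must be >= 1")
    as.integer(floor(log2(nCells)))
}

#' Expected de novo mtDNA mutations per cell division
#'
#' Doubling a population of \code{copyNumber} genomes of
#' \code{genomeLength} bases synthesizes \code{copyNumber *
#' genomeLength} bases, so a per-base error rate \code{errorRate} yields
#' \code{copyNumber * genomeLength * errorRate} expected new mutations.
#' This is the pre-segregation count of mutations created — no halving
#' factor — matching the headline "0.5 to 9.2 new mutations per
#' division" arithmetic.
#'
#' @param copyNumber mtDNA copies per cell (> 0).
#' @param genomeLength genome length in bp (> 0), default 16,569.
#' @param errorRate per-base per-replication error rate (>= 0).
#' @return Expected new mutations per division.
#' @examples
#' perDivisionMutationCount(1000, 16569, 5.6e-7)  # ~9.28
#' perDivisionMutationCount(1000, 16569, 2.8e-8)  # ~0.46
#' @export
perDivisionMutationCount <- function(copyNumber, genomeLength = 16569,
                                     errorRate) {
    stopifnot(all(copyNumber > 0), all(genomeLength > 0), all(errorRate >= 0))
    copyNumber * genomeLength * errorRate
}

#' De novo mutation burden present at birth
#'
#' Multiplies the per-division mutation count by the number of
#' developmental divisions, for a low and a high error-rate bound. The
#' default bounds are the raw POLG fidelity estimates of one error per
#' 3.6e7 and per 1.8e6 bases synthesized (i.e. 1/3.6e7 and 1/1.8e6 per
#' base), which put the per-division rate at 0.46–9.21 and the birth
#' burden near 21–414.
#'
#' \code{mode = "display"} reproduces the headline integers 22 and 414 by
#' following the display arithmetic of the source estimates: the
#' per-division rate is first rounded to one decimal (0.5 and 9.2),
#' multiplied by the division count, and the product truncated to an
#' integer (0.5 x 45 = 22.5 -> 22; 9.2 x 45 = 414). \code{mode = "raw"}
#' (the default) keeps full precision throughout.
#'
#' @param copyNumber mtDNA copies per cell, default 1000.
#' @param genomeLength genome length in bp, default 16,569.
#' @param errorRateLow,errorRateHigh per-base error-rate bounds
#'   (low <= high).
#' @param divisions developmental division count (>= 0), default 45.
#' @param mode \code{"raw"} or \code{"display"}.
#' @return Named numeric vector \code{c(low = , high = )}.
#' @examples
#' birthBurdenRange(mode = "display")  # c(low = 22, high = 414)
#' birthBurdenRange()                # c(low = 20.7, high = 414.2) approx.
#' @export
birthBurdenRange <- function(copyNumber = 1000, genomeLength = 16569,
                             errorRateLow = 1 / 3.6e7,
                             errorRateHigh = 1 / 1.8e6,
                             divisions = 45,
                             mode = c("raw", "display")) {
    mode <- match.arg(mode)
    stopifnot(errorRateLow <= errorRateHigh, divisions >= 0)
    perDiv <- perDivisionMutationCount(copyNumber, genomeLength,
                                       c(errorRateLow, errorRateHigh))
    # epsilon guard: 9.2 * 45 is 413.999... in binary floating point
    out <- if (mode == "display") floor(round(perDiv, 1) * divisions + 1e-9)
           else perDiv * divisions
    names(out) <- c("low", "high")
    out
}

#' Total mtDNA copies carried by an individual
#'
#' The product of the body cell count and the per-cell copy-number
#' range. With ~3.72e13 cells and 100–10,000 copies per cell the total
#' spans ~3.7e15 to ~3.7e17 molecules; as an order-of-magnitude
#' statement this is the familiar 10^16–10^17 copies per adult.
#'
#' @param nCells body cell count (>= 0).
#' @param copiesPerCellLow,copiesPerCellHigh per-cell copy-number bounds.
#' @return Named numeric vector \code{c(low = , high = )}.
#' @export
bodyCopyEstimate <- function(nCells = 3.72e13, copiesPerCellLow = 100,
                             copiesPerCellHigh = 1e4) {
    stopifnot(nCells >= 0, copiesPerCellLow > 0, copiesPerCellHigh > 0,
              copiesPerCellLow <= copiesPerCellHigh)
    c(low = nCells * copiesPerCellLow, high = nCells * copiesPerCellHigh)
}
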