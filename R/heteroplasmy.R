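#' Heteroplasmy projection parameters
#'
#' @param h0 starting heteroplasmy fraction in \code{[0, 1]}.
#' @param advantage stated per-round proliferative advantage \eqn{s}
#'   (fraction, e.g. 0.02), \eqn{s \ge 0}.
#' @param nRounds number of mtDNA replication rounds (>= 0).
#' @param convention \code{"halved"} (effective advantage
#'   \eqn{a = s/2}; the default) or \code{"full"} (\eqn{a = s}). Under
#'   the halved convention only half of each round's replicative edge is
#'   realized as a frequency gain, the other half being dissipated by
#'   random loss at segregation/turnover — this is the convention that
#'   reproduces the published projection scenarios.
#' @return A validated [DriftParams-class].
#' @examples
#' projectHeteroplasmy(DriftParams(0.01, 0.02, 280))  # ~0.14
#' @export
DriftParams <- function(h0, advantage, nRounds,
                        convention = c("halved", "full")) {
    convention <- match.arg(convention)
    new("DriftParams", h0 = as.numeric(h0), advantage = as.numeric(advantage),
        nRounds = as.integer(nRounds), convention = convention)
}

.effectiveAdvantage <- function(advantage, convention)
    if (convention == "halved") advantage / 2 else advantage

#' Deterministic heteroplasmy projection under a proliferative advantage
#'
#' A variant with a per-round effective replicative advantage \eqn{a}
#' multiplies its odds by \eqn{(1 + a)} each round, so after \eqn{n}
#' rounds
#' \deqn{h_n = \frac{o_n}{1 + o_n}, \quad
#'       o_n = \frac{h_0}{1 - h_0}(1 + a)^n,}
#' the discrete logistic growth of an allele under constant selection.
#' The fixation states \eqn{h_0 = 0} and \eqn{h_0 = 1} are absorbing and
#' returned unchanged.
#'
#' @param params a [DriftParams-class], or a numeric \code{h0} with
#'   \code{advantage}, \code{nRounds}, \code{convention} supplied.
#' @param ... passed to the numeric method.
#' @param advantage,nRounds,convention see [DriftParams()];
#'   \code{nRounds} may be a vector to trace a trajectory.
#' @return Heteroplasmy fraction(s) after \code{nRounds} rounds.
#' @examples
#' projectHeteroplasmy(0.05, 0.20, 45)          # ~0.79 (>70%)
#' projectHeteroplasmy(0.01, 0.02, 371)         # ~0.29 in an HSC lineage
#' projectHeteroplasmy(0.01, 0.05, 280)         # ~0.91 (>90%)
#' @export
setMethod("projectHeteroplasmy", "DriftParams", function(params, ...) {
    validObject(params)
    projectHeteroplasmy(params@h0, advantage = params@advantage,
                        nRounds = params@nRounds,
                        convention = params@convention)
})

#' @rdname projectHeteroplasmy-DriftParams-method
#' @export
setMethod("projectHeteroplasmy", "numeric",
    function(params, advantage, nRounds,
             convention = c("halved", "full"), ...) {
    h0 <- params
    convention <- match.arg(convention)
    if (any(!is.finite(h0)) || any(h0 < 0) || any(h0 > 1))
        stop("'h0' must lie in [0, 1]")
    stopifnot(advantage >= 0, all(nRounds >= 0))
    a <- .effectiveAdvantage(advantage, convention)
    # log-odds scale for numerical range; 0 and 1 are absorbing
    len <- max(length(h0), length(nRounds))
    h0 <- rep_len(h0, len)
    nRounds <- rep_len(nRounds, len)
    out <- h0
    interior <- h0 > 0 & h0 < 1
    out[interior] <- stats::plogis(
        log(h0[interior] / (1 - h0[interior])) +
        nRounds[interior] * log1p(a))
    out
})

#' Rounds needed to reach a target heteroplasmy
#'
#' Inverts the projection: the smallest non-negative integer \eqn{n}
#' with \eqn{h_n \ge} \code{target}. Solved in closed form on the
#' log-odds scale, then adjusted by an integer check of the neighbouring
#' round counts to absorb floating-point edge effects.
#'
#' @param h0 starting fraction, strictly inside \code{(0, 1)}.
#' @param advantage stated per-round advantage \eqn{s > 0} (\code{s = 0}
#'   with an unreached target is an error).
#' @param target target fraction, \code{target < 1}.
#' @param convention \code{"halved"} or \code{"full"}.
#' @return Smallest integer round count reaching the target (0 if
#'   already reached).
#' @examples
#' roundsToThreshold(0.01, 0.02, 0.14)  # ~280 rounds
#' @export
roundsToThreshold <- function(h0, advantage, target,
                              convention = c("halved", "full")) {
    convention <- match.arg(convention)
    stopifnot(h0 > 0, h0 < 1, target < 1)
    if (target <= h0) return(0L)
    if (advantage <= 0)
        stop("target is unreachable with a non-positive advantage")
    a <- .effectiveAdvantage(advantage, convention)
    n <- ceiling((log(target / (1 - target)) - log(h0 / (1 - h0))) / log1p(a))
    n <- max(0, n)
    while (n > 0 &&
           projectHeteroplasmy(h0, advantage, n - 1, convention) >= target)
        n <- n - 1
    while (projectHeteroplasmy(h0, advantage, n, convention) < target)
        n <- n + 1
    as.integer(n)
}

#' Neutral stochastic segregation of heteroplasmy
#'
#' Simulates random mitotic segregation with no selection: at each of
#' \code{nDivisions} divisions a daughter's mutant count is drawn as
#' Binomial(\code{copyNumber}, current heteroplasmy) — a
#' constant-copy-number resampling model of vegetative segregation.
#' Heteroplasmy drifts as a martingale (its mean is conserved) while its
#' variance grows, and the fixation states 0 and 1 are absorbing, so
#' lineages progressively sort toward homoplasmy.
#'
#' This simulator is a qualitative extension for exploring random
#' heteroplasmy shifts; it is deliberately minimal (no selection, no
#' copy-number fluctuation, no germline bottleneck).
#'
#' @param h0 starting heteroplasmy fraction in \code{[0, 1]}.
#' @param copyNumber mtDNA copies per cell (>= 1).
#' @param nDivisions number of divisions to simulate (>= 0).
#' @param nLineages number of independent lineages.
#' @param seed integer RNG seed.
#' @return Numeric matrix of heteroplasmy fractions with
#'   \code{nLineages} rows and \code{nDivisions + 1} columns (column 1
#'   is the starting state); dimnames give division indices.
#' @examples
#' traj <- segregateStochastic(0.3, 200, 20, 100, seed = 1)
#' mean(traj[, 21])  # ~0.3: the mean is conserved
#' @export
segregateStochastic <- function(h0, copyNumber, nDivisions, nLineages,
                                seed = 1L) {
    stopifnot(h0 >= 0, h0 <= 1, copyNumber >= 1, nDivisions >= 0,
              nLineages >= 1)
    copyNumber <- as.integer(copyNumber)
    nDivisions <- as.integer(nDivisions)
    nLineages <- as.integer(nLineages)
    set.seed(as.integer(seed))
    traj <- matrix(NA_real_, nrow = nLineages, ncol = nDivisions + 1L,
                   dimnames = list(NULL, paste0("div", 0:nDivisions)))
    h <- rep(h0, nLineages)
    traj[, 1L] <- h
    for (d in seq_len(nDivisions)) {
        h <- stats::rbinom(nLineages, copyNumber, h) / copyNumber
        traj[, d + 1L] <- h
    }
    traj
}
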