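# Independent oracles used by the property and acceptance tests. These
# deliberately avoid the package's own sampling path.

# Discretized probability mass of a Unif(lo, hi) on an equal-step grid
# (bin midpoints), for numeric convolution.
uniformMass <- function(lo, hi, step) {
    mids <- seq(lo + step / 2, hi - step / 2, by = step)
    list(offset = mids[1], step = step, mass = rep(1 / length(mids),
                                                   length(mids)))
}

convolveMass <- function(a, b) {
    stopifnot(isTRUE(all.equal(a$step, b$step)))
    m <- stats::convolve(a$mass, rev(b$mass), type = "open")
    m[m < 0] <- 0  # FFT round-off
    list(offset = a$offset + b$offset, step = a$step, mass = m / sum(m))
}

# Semi-analytic P(B >= threshold): mu is integrated in closed form
# conditional on (L, Y) (a clamped linear CDF), L by a fine midpoint
# rule on [2, 4], and the density of Y = X1 + X2 (+ X3) by numeric
# convolution of the uniform components.
tailProbOracleGE <- function(threshold, proliferating = TRUE,
                             G = 16569, halving = 2,
                             muLo = 2.8e-8, muHi = 5.6e-7,
                             yStep = 0.5, nL = 2000L) {
    comps <- list(c(10, 80), c(180, 380))
    if (proliferating) comps <- c(comps, list(c(81, 101)))
    ym <- Reduce(convolveMass,
                 lapply(comps, function(g) uniformMass(g[1], g[2], yStep)))
    y <- ym$offset + (seq_along(ym$mass) - 1) * ym$step
    Lmid <- seq(2 + 1 / nL, 4 - 1 / nL, length.out = nL)
    scale <- (G / halving) * 10^Lmid                  # per L value
    muCut <- threshold / outer(scale, y)              # nL x nY
    p <- pmin(pmax((muHi - muCut) / (muHi - muLo), 0), 1)
    as.numeric(colMeans(p) %*% ym$mass)
}

# Brute-force per-division mutation count: Z * G Bernoulli(mu) trials
# summarized as a binomial draw per replicate.
perDivisionBruteForce <- function(copyNumber, genomeLength, errorRate,
                                  nRep = 1e4L, seed = 1L) {
    set.seed(seed)
    draws <- stats::rbinom(nRep, copyNumber * genomeLength, errorRate)
    list(mean = mean(draws), se = stats::sd(draws) / sqrt(nRep))
}

# Round-by-round iteration of the odds projection, the slow oracle for
# the closed-form heteroplasmy projection and its inverse.
projectIteratively <- function(h0, advantage, nRounds,
                               convention = "halved") {
    a <- if (convention == "halved") advantage / 2 else advantage
    h <- h0
    for (i in seq_len(nRounds)) {
        o <- h / (1 - h) * (1 + a)
        h <- o / (1 + o)
    }
    h
}

defaultModel <- function(proliferating = TRUE)
    BurdenModel(proliferating = proliferating)

# Table of published tail probabilities at age 70 (the acceptance
# reference); the <=10 proliferating row is the bound "<0.001".
publishedTailTable <- function() {
    data.frame(
        direction = rep(c("le", "ge"), c(4L, 6L)),
        threshold = c(10, 50, 100, 200, 500, 1000, 1500, 2000, 3000, 5000),
        proliferating = c(0.001, 0.031, 0.084, 0.195,
                          0.606, 0.455, 0.370, 0.311, 0.231, 0.137),
        nonProliferating = c(0.001, 0.050, 0.118, 0.250,
                             0.550, 0.402, 0.318, 0.261, 0.183, 0.097))
}
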