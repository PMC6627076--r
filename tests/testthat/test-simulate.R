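test_that("degenerate distributions reproduce the closed form exactly", {
    m <- BurdenModel(copyNumber = fixedParam(1000),
                     errorRate = fixedParam(2.94e-7),
                     x1 = fixedParam(45), x2 = fixedParam(280),
                     x3 = fixedParam(91))
    s <- sampleBurden(m, nSamples = 100, seed = 1)
    expect_equal(unique(burdenValues(s)), expectedBurden(m))
    # reversed CDF is a unit step at the closed-form value
    b <- expectedBurden(m)
    rc <- reversedCDF(s, c(0, b - 1, b, b + 1))
    expect_equal(rc$probability, c(1, 1, 1, 0))
    sm <- burdenSummary(s)
    expect_equal(sm$mean, b)
    expect_equal(sm$sd, 0)
    expect_equal(unname(sm$quantiles["50%"]), b)
})

test_that("sampling is reproducible and seed-sensitive", {
    m <- BurdenModel()
    s1 <- sampleBurden(m, nSamples = 5000, seed = 99)
    s2 <- sampleBurden(m, nSamples = 5000, seed = 99)
    s3 <- sampleBurden(m, nSamples = 5000, seed = 100)
    expect_identical(burdenValues(s1), burdenValues(s2))
    expect_false(identical(burdenValues(s1), burdenValues(s3)))
    expect_true(all(burdenValues(s1) >= 0))
})

test_that("sample moments match the analytic arithmetic-mean expectation", {
    # E(B) under sampling uses the arithmetic mean of Z = 10^L,
    # (10^4 - 10^2) / (2 ln 10) ~ 2150, not the geometric mean 1000
    n <- 2e5
    s <- sampleBurden(BurdenModel(), nSamples = n, seed = 12)
    v <- burdenValues(s)
    analytic <- 16569 * (1e4 - 1e2) / (2 * log(10)) * (2.94e-7 / 2) * 416
    expect_equal(mean(v), analytic, tolerance = 3 * sd(v) / sqrt(n) / analytic)
})

test_that("tail probabilities count ties in both directions", {
    m <- BurdenModel(copyNumber = fixedParam(1000),
                     errorRate = fixedParam(2.94e-7),
                     x1 = fixedParam(45), x2 = fixedParam(280),
                     x3 = fixedParam(91))
    s <- sampleBurden(m, nSamples = 10, seed = 1)
    b <- expectedBurden(m)
    tt <- tailProbabilities(s, data.frame(direction = c("le", "ge"),
                                          threshold = c(b, b)))
    expect_equal(tt@probability, c(1, 1))
    # and P(B >= 0) is always 1
    s2 <- sampleBurden(BurdenModel(), nSamples = 1000, seed = 2)
    tt2 <- tailProbabilities(s2, data.frame(direction = "ge", threshold = 0))
    expect_equal(tt2@probability, 1)
})

test_that("le and ge probabilities are complementary for continuous draws", {
    s <- sampleBurden(BurdenModel(), nSamples = 5e4, seed = 3)
    thr <- data.frame(direction = rep(c("le", "ge"), 3),
                      threshold = rep(c(200, 500, 1000), each = 2))
    tt <- as.data.frame(tailProbabilities(s, thr))
    pLe <- tt$probability[tt$direction == "le"]
    pGe <- tt$probability[tt$direction == "ge"]
    expect_equal(pLe + pGe, rep(1, 3))  # ties have probability ~0
})

test_that("tail-table direction monotonicity holds", {
    s <- sampleBurden(BurdenModel(), nSamples = 5e4, seed = 4)
    tt <- as.data.frame(tailProbabilities(s))
    expect_true(all(diff(tt$probability[tt$direction == "le"]) >= 0))
    expect_true(all(diff(tt$probability[tt$direction == "ge"]) <= 0))
})

test_that("reversed CDF is a non-increasing curve starting at 1 for grid = 0", {
    s <- sampleBurden(BurdenModel(), nSamples = 2e4, seed = 5)
    grid <- seq(0, 8000, by = 250)
    rc <- reversedCDF(s, grid)
    expect_equal(rc$probability[1], 1)
    expect_true(all(diff(rc$probability) <= 0))
    expect_error(reversedCDF(s, c(10, 5)), "sorted")
    # agrees with direct counting
    expect_equal(rc$probability[grid == 500],
                 mean(burdenValues(s) >= 500))
})

test_that("histogram counts conserve the sample size and quantiles are monotone", {
    s <- sampleBurden(BurdenModel(), nSamples = 3e4, seed = 6)
    sm <- burdenSummary(s, breaks = 40)
    expect_identical(sum(sm$histCounts), 30000L)
    expect_true(all(diff(sm$quantiles) >= 0))
})

test_that("the Poisson layer yields integer counts with the right mean", {
    m <- BurdenModel(copyNumber = fixedParam(1000),
                     errorRate = fixedParam(2.94e-7),
                     x1 = fixedParam(45), x2 = fixedParam(280),
                     x3 = fixedParam(91))
    n <- 2e4
    s <- sampleBurden(m, nSamples = n, seed = 7, poisson = TRUE)
    v <- burdenValues(s)
    expect_true(all(v == round(v)))
    b <- expectedBurden(m)
    expect_equal(mean(v), b, tolerance = 3 * sqrt(b / n) / b)
})

test_that("Monte Carlo error shrinks as one over root n", {
    # replicate tail estimates at n and 4n: the spread should halve
    est <- function(n, seeds) vapply(seeds, function(sd)
        mean(burdenValues(sampleBurden(BurdenModel(), n, seed = sd)) >= 500),
        0)
    e1 <- est(1e4, 1:40)
    e2 <- est(4e4, 41:80)
    ratio <- sd(e1) / sd(e2)
    expect_gt(ratio, 1.3)   # consistent with the theoretical factor 2
    expect_lt(ratio, 3.1)
    # and both agree with the analytic binomial standard error
    p <- mean(e1)
    expect_equal(sd(e1), sqrt(p * (1 - p) / 1e4), tolerance = 0.35)
})

test_that("proliferating cells stochastically dominate non-proliferating ones", {
    n <- 1e5
    sp <- sampleBurden(BurdenModel(), nSamples = n, seed = 21)
    sn <- sampleBurden(BurdenModel(proliferating = FALSE), nSamples = n,
                       seed = 21)  # shared seed pairs the draws
    grid <- c(50, 100, 200, 500, 1000, 2000, 5000)
    pP <- reversedCDF(sp, grid)$probability
    pN <- reversedCDF(sn, grid)$probability
    se <- sqrt(pP * (1 - pP) / n) + sqrt(pN * (1 - pN) / n)
    expect_true(all(pP >= pN - 2 * se))
})

test_that("empirical tails agree with the semi-analytic oracle", {
    n <- 1e5
    for (prolif in c(TRUE, FALSE)) {
        s <- sampleBurden(BurdenModel(proliferating = prolif),
                          nSamples = n, seed = 31)
        for (thr in c(100, 500, 1500, 3000)) {
            pHat <- mean(burdenValues(s) >= thr)
            pOracle <- tailProbOracleGE(thr, proliferating = prolif)
            se <- sqrt(pOracle * (1 - pOracle) / n)
            expect_lt(abs(pHat - pOracle), 3 * se)
        }
    }
})
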