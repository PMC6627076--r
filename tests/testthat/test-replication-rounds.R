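test_that("turnover rounds match the half-life arithmetic", {
    expect_equal(round(turnoverRounds(70, 91.3125)), 280)
    expect_equal(round(turnoverRounds(70, 12)), 2131)
    expect_equal(turnoverRounds(70, 365.25), 70)
    expect_equal(turnoverRounds(0, 12), 0)
    expect_error(turnoverRounds(70, 0), "positive")
    expect_error(turnoverRounds(-1, 91), "ageYears")
})

test_that("stem-cell extra rounds match the cycle arithmetic", {
    expect_equal(round(hscExtraRounds(70, 40)), 91)
    expect_equal(hscExtraRounds(0, 40), 0)
    expect_equal(round(hscExtraRounds(40, 40)), 52)  # 40 * 52.18 / 40
    expect_error(hscExtraRounds(70, -1), "positive")
})

test_that("round counts are monotone in age and half-life", {
    ages <- seq(0, 90, by = 5)
    tr <- turnoverRounds(ages, 91.3125)
    hr <- hscExtraRounds(ages, 40)
    expect_true(all(diff(tr) > 0))
    expect_true(all(diff(hr) > 0))
    # linear in age
    expect_equal(turnoverRounds(35, 91.3125), tr[which(ages == 70)] / 2)
    # strictly decreasing in half-life
    hl <- c(12, 30, 91.3125, 182, 365.25)
    expect_true(all(diff(turnoverRounds(70, hl)) < 0))
})

test_that("doubling count is the floor of log2 and monotone", {
    expect_identical(divisionsToCellCount(3.72e13), 45L)
    expect_identical(divisionsToCellCount(1), 0L)
    ks <- 0:50
    expect_identical(divisionsToCellCount(2^ks), as.integer(ks))
    set.seed(8)
    n <- sort(10^runif(200, 0, 15))
    expect_true(all(diff(divisionsToCellCount(n)) >= 0L))
    expect_error(divisionsToCellCount(0.5), ">= 1")
})

test_that("per-division mutation counts match direct and brute-force arithmetic", {
    expect_equal(perDivisionMutationCount(1000, 16569, 5.6e-7),
                 9.27864, tolerance = 1e-6)
    expect_equal(perDivisionMutationCount(1000, 16569, 2.8e-8),
                 0.463932, tolerance = 1e-6)
    expect_equal(perDivisionMutationCount(1000, 16569, 0), 0)
    # Z * G Bernoulli trials, summarized as a binomial draw
    bf <- perDivisionBruteForce(1000, 16569, 5.6e-7, nRep = 1e4, seed = 2)
    expect_lt(abs(bf$mean - perDivisionMutationCount(1000, 16569, 5.6e-7)),
              3 * bf$se)
})

test_that("birth burden reproduces both display and raw arithmetic", {
    expect_equal(birthBurdenRange(mode = "display"),
                 c(low = 22, high = 414))
    # raw mode with the rounded error-rate interval bounds
    raw <- birthBurdenRange(errorRateLow = 2.8e-8, errorRateHigh = 5.6e-7)
    expect_equal(unname(raw), c(20.87694, 417.5388), tolerance = 1e-6)
    expect_equal(birthBurdenRange(divisions = 0),
                 c(low = 0, high = 0))
    expect_error(birthBurdenRange(errorRateLow = 1e-6, errorRateHigh = 1e-8))
})

test_that("total-body copy estimate spans the order-of-magnitude range", {
    est <- bodyCopyEstimate(3.72e13, 100, 1e4)
    expect_equal(unname(est), c(3.72e15, 3.72e17))
    expect_equal(unname(bodyCopyEstimate(0, 100, 1e4)), c(0, 0))
})
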