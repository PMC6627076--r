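test_that("projection reproduces the published advantage scenarios", {
    # 1% variant, 2% stated advantage: ~14% after 280 rounds (neurons),
    # ~28% after 371 rounds (HSC lineage)
    expect_equal(projectHeteroplasmy(0.01, 0.02, 280), 0.14, tolerance = 0.01)
    expect_equal(projectHeteroplasmy(0.01, 0.02, 371), 0.29, tolerance = 0.01)
    # published lower bounds
    expect_gt(projectHeteroplasmy(0.10, 0.02, 280), 0.60)
    expect_gt(projectHeteroplasmy(0.05, 0.20, 45), 0.70)
    expect_gt(projectHeteroplasmy(0.01, 0.05, 280), 0.90)
})

test_that("neutral variants and fixation states are invariant", {
    expect_equal(projectHeteroplasmy(0.37, 0, 500), 0.37)
    expect_equal(projectHeteroplasmy(0, 0.2, 100), 0)
    expect_equal(projectHeteroplasmy(1, 0.2, 100), 1)
    expect_error(projectHeteroplasmy(1.2, 0.1, 10), "\\[0, 1\\]")
})

test_that("projection is monotone, bounded and composable", {
    h <- projectHeteroplasmy(0.01, 0.02, 0:400)
    expect_true(all(diff(h) > 0))
    expect_true(all(h > 0 & h < 1))
    expect_equal(h[1], 0.01)
    # strictly increasing in the advantage
    s <- seq(0, 0.3, by = 0.005)
    expect_true(all(diff(vapply(s, function(a)
        projectHeteroplasmy(0.01, a, 100), 0)) > 0))
    h0s <- seq(0.01, 0.99, by = 0.01)
    expect_true(all(diff(projectHeteroplasmy(h0s, 0.02, 50)) > 0))
    # composition: n1 rounds then n2 from the intermediate state
    h1 <- projectHeteroplasmy(0.03, 0.04, 120)
    expect_equal(projectHeteroplasmy(h1, 0.04, 80),
                 projectHeteroplasmy(0.03, 0.04, 200))
})

test_that("halved convention equals full convention at half the advantage", {
    for (s in c(0.02, 0.1, 0.4)) {
        expect_identical(
            projectHeteroplasmy(0.05, s, 60, convention = "halved"),
            projectHeteroplasmy(0.05, s / 2, 60, convention = "full"))
    }
    # the full convention is strictly more aggressive
    expect_gt(projectHeteroplasmy(0.01, 0.02, 280, convention = "full"),
              projectHeteroplasmy(0.01, 0.02, 280, convention = "halved"))
})

test_that("DriftParams dispatch agrees with the scalar interface", {
    d <- DriftParams(0.05, 0.20, 45)
    expect_equal(projectHeteroplasmy(d),
                 projectHeteroplasmy(0.05, 0.20, 45))
    expect_error(DriftParams(-0.1, 0.2, 10), "h0")
    expect_error(DriftParams(0.1, -0.2, 10), "advantage")
})

test_that("closed-form round inversion matches the iterative oracle", {
    expect_identical(roundsToThreshold(0.5, 0.1, 0.4), 0L)
    n <- roundsToThreshold(0.01, 0.02, 0.14)
    expect_true(abs(n - 280L) <= 1L)
    set.seed(17)
    for (i in 1:100) {
        h0 <- runif(1, 0.001, 0.5)
        s <- runif(1, 0.005, 0.3)
        target <- runif(1, h0 + 0.01, 0.99)
        conv <- sample(c("halved", "full"), 1)
        n <- roundsToThreshold(h0, s, target, conv)
        # smallest integer reaching the target, checked by iteration
        expect_gte(projectIteratively(h0, s, n, conv), target - 1e-12)
        if (n > 0)
            expect_lt(projectIteratively(h0, s, n - 1, conv), target)
    }
    expect_error(roundsToThreshold(0.01, 0, 0.5), "unreachable")
})

test_that("stochastic segregation is a bounded martingale with absorbing ends", {
    expect_true(all(segregateStochastic(0, 500, 20, 50, seed = 1) == 0))
    expect_true(all(segregateStochastic(1, 500, 20, 50, seed = 1) == 1))
    nL <- 10000L
    traj <- segregateStochastic(0.3, 1000, 50, nL, seed = 3)
    expect_identical(dim(traj), c(nL, 51L))
    expect_true(all(traj >= 0 & traj <= 1))
    # mean conserved within 3 binomial-bound standard errors
    se <- sqrt(0.3 * 0.7 / nL)
    expect_lt(abs(mean(traj[, 51]) - 0.3), 3 * se)
    # variance across lineages grows with divisions
    v <- apply(traj[, c(2, 11, 26, 51)], 2, var)
    expect_true(all(diff(v) > 0))
    # once fixed, always fixed
    fixedAt <- which(traj[, 26] %in% c(0, 1))
    expect_true(all(traj[fixedAt, 26] == traj[fixedAt, 51]))
    # absorption fraction increases with divisions
    expect_gte(mean(traj[, 51] %in% c(0, 1)), mean(traj[, 11] %in% c(0, 1)))
})
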