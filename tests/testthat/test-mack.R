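test_that("MacK score is exact on forced fixtures", {
    ## strictly increasing gene with positive velocity scores 1
    fx <- makeMonotoneFixture()
    expect_equal(unname(mackScores(
        mackScore(fx$states, fx$vel, fx$time, fx$graph))), 1)
    ## negated velocity scores 0
    neg <- VelocityField(-velocityValues(fx$vel), "genes")
    expect_equal(unname(mackScores(
        mackScore(fx$states, neg, fx$time, fx$graph))), 0)
    ## 3-of-5 agreement fixture scores exactly 0.6
    f35 <- makeThreeOfFiveFixture()
    expect_equal(unname(mackScores(
        mackScore(f35$states, f35$vel, f35$time, f35$graph))), 0.6)
    ## and its negation scores exactly 0.4 (no abstentions)
    neg35 <- VelocityField(-velocityValues(f35$vel), "genes")
    expect_equal(unname(mackScores(
        mackScore(f35$states, neg35, f35$time, f35$graph))), 0.4)
})

test_that("MacK score is invariant to monotone time transforms and
           satisfies the negation bound", {
    set.seed(30)
    dat <- makeRandomData(40, 5, seed = 30)
    g <- buildKnnGraph(dat$states, k = 5)
    t <- runif(40)
    s1 <- mackScores(mackScore(dat$states, dat$vel, t, g))
    for (f in list(function(x) 10 * x - 3, exp, function(x) x^3)) {
        s2 <- mackScores(mackScore(dat$states, dat$vel, f(t), g))
        expect_equal(s1, s2)
    }
    neg <- VelocityField(-velocityValues(dat$vel), "genes")
    sNeg <- mackScores(mackScore(dat$states, neg, t, g))
    ## continuous data: no zero signs, so the scores are complementary
    expect_true(all(s1 + sNeg <= 1 + 1e-12))
    expect_equal(unname(s1 + sNeg), rep(1, 5))
})

test_that("one-sided zeros abstain by default and penalize in strict mode", {
    ## flat gene with nonzero velocity: every pair has slope sign 0 vs
    ## velocity sign 1 -> all pairs abstain -> score NaN under "abstain",
    ## 0 under "strict"
    fx <- makeMonotoneFixture()
    flat <- CellStateSet(matrix(1, 30, 1,
                                dimnames = list(cellIds(fx$states), "g")))
    res <- mackScore(flat, fx$vel, fx$time, fx$graph)
    expect_true(is.nan(mackScores(res)[["g"]]))
    resStrict <- mackScore(flat, fx$vel, fx$time, fx$graph,
                           zeroHandling = "strict")
    expect_equal(unname(mackScores(resStrict)), 0)
    ## flat gene with zero velocity: both signs 0 count as matches
    zeroVel <- VelocityField(matrix(0, 30, 1), "genes")
    resZero <- mackScore(flat, zeroVel, fx$time, fx$graph)
    expect_equal(unname(mackScores(resZero)), 1)
})

test_that("a constant time vector is rejected and tied-time cells are
           excluded, not scored", {
    fx <- makeMonotoneFixture()
    expect_error(mackScore(fx$states, fx$vel, rep(1, 30), fx$graph),
                 "constant")
    ## two time blocks: cells deep inside a block see only zero time
    ## differences and are excluded; boundary cells still carry the score
    t2 <- c(rep(1, 15), rep(2, 15))
    res <- mackScore(fx$states, fx$vel, t2, fx$graph)
    expect_equal(unname(mackScores(res)), 1)   # increasing gene, v > 0
    expect_true(anyNA(res@perCell))            # excluded cells are NA
})

test_that("gene selection ranks by score with deterministic ties", {
    scores <- c(b = 0.5, a = 0.5, c = 0.9, d = 0.1)
    res <- new("MacKResult", scores = scores,
               perCell = matrix(numeric(0), 0, 0), nEvaluated = integer(4))
    expect_equal(selectMackGenes(res, topN = 4), c("c", "a", "b", "d"))
    expect_equal(selectMackGenes(res, topN = 2), c("c", "a"))
    expect_equal(selectMackGenes(res, threshold = 0.5), c("c", "a", "b"))
    expect_warning(out <- selectMackGenes(res, topN = 10), "exceeds")
    expect_equal(out, c("c", "a", "b", "d"))
})

test_that("sign-flipped genes separate to the bottom of the MacK ranking", {
    tr <- simulateGRN("linear", nCells = 300, nGenes = 40, seed = 1)
    g <- buildKnnGraph(trajStates(tr), k = 15)
    set.seed(31)
    flip <- sample(featureIds(trajStates(tr)), 8)
    V <- velocityValues(trajVelocity(tr))
    V[, flip] <- -V[, flip]
    mk <- mackScore(trajStates(tr), VelocityField(V, "genes"),
                    trajTimes(tr), g)
    expect_lt(mean(mackScores(mk)[flip]),
              mean(mackScores(mk)[setdiff(names(mackScores(mk)), flip)]))
})

test_that("cell-specific rates invert the splicing kinetics", {
    ## steady state: alpha = u, gamma = u/s at beta = 1
    kr <- cellSpecificRates(u = c(2, 4), s = c(1, 8), du = c(0, 0),
                            ds = c(0, 0), beta = 1)
    expect_equal(kr@alpha, c(2, 4))
    expect_equal(kr@gamma, c(2, 0.5))
    ## u = 2, du = 1, beta = 1 -> alpha = 3
    kr2 <- cellSpecificRates(2, 1, 1, 0, beta = 1)
    expect_equal(kr2@alpha, 3)
    ## gamma undefined below the mature-abundance floor, flagged not thrown
    kr3 <- cellSpecificRates(u = c(1, 1), s = c(1, 1e-9), du = c(0, 0),
                             ds = c(0, 0))
    expect_false(is.na(kr3@gamma[1]))
    expect_true(is.na(kr3@gamma[2]))
})

test_that("modality fractions are exact count ratios", {
    X <- rbind(c(2, 3, 5), c(0, 0, 0), c(1, 0, 1))
    dimnames(X) <- list(paste0("c", 1:3), c("viral1", "viral2", "host"))
    s <- CellStateSet(X)
    expect_equal(unname(modalityFraction(s, c("viral1", "viral2", "host"))),
                 c(1, 0, 1))
    expect_equal(unname(modalityFraction(s, c("viral1", "viral2"))),
                 c(0.5, 0, 0.5))
    expect_equal(unname(modalityFraction(s, "viral2"))[3], 0)
    expect_error(modalityFraction(s, character()), "parameter error")
    ## random fixture matches the brute-force ratio
    set.seed(32)
    M <- matrix(rpois(60, 4), 10, 6,
                dimnames = list(paste0("c", 1:10), paste0("g", 1:6)))
    sub <- c("g2", "g5")
    got <- modalityFraction(CellStateSet(M), sub)
    expect_equal(unname(got), unname(rowSums(M[, sub]) / rowSums(M)))
})
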