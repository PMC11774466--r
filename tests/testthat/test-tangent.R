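test_that("cosine-kernel coefficients are exact cosines", {
    basis <- rbind(c(1, 1), c(0, 1))
    expect_equal(cosineKernelCoefficients(c(1, 0), basis),
                 c(sqrt(2) / 2, 0))
    ## zero velocity -> all-zero coefficients by convention
    expect_equal(cosineKernelCoefficients(c(0, 0), basis), c(0, 0))
    ## zero-norm displacement entries get coefficient 0
    basis2 <- rbind(c(1, 0), c(0, 0))
    expect_equal(cosineKernelCoefficients(c(1, 0), basis2), c(1, 0))
    ## all-zero basis is degenerate
    expect_error(cosineKernelCoefficients(c(1, 0), matrix(0, 3, 2)),
                 "degenerate")
    ## random fixture matches elementwise brute force
    set.seed(9)
    v <- rnorm(4); B <- matrix(rnorm(20), 5, 4)
    ref <- apply(B, 1, function(d)
        sum(v * d) / (sqrt(sum(v^2)) * sqrt(sum(d^2))))
    expect_equal(cosineKernelCoefficients(v, B), ref)
})

test_that("the TSP loss evaluates its three terms exactly", {
    set.seed(10)
    B <- matrix(rnorm(12), 4, 3)
    v <- rnorm(3)
    ## phi = 0, b = 0: loss is ||v||^2
    expect_equal(tspLoss(numeric(4), v, B, numeric(4),
                         tspConfig(b = 0, lam = 0)), sum(v^2))
    ## perfect fit with aligned direction and lam = 0: loss = -b
    pc <- cosineKernelCoefficients(rnorm(3), B)
    vExact <- as.vector(crossprod(B, pc))
    expect_equal(tspLoss(pc, vExact, B, pc, tspConfig(b = 2.5, lam = 0)),
                 -2.5)
    ## arbitrary fixture matches an independent re-evaluation of the formula
    phi <- rnorm(4); pc2 <- rnorm(4)
    cfg <- tspConfig(b = 0.7, lam = 0.3)
    resid <- v - colSums(phi * B)
    cosTerm <- sum(phi * pc2) / (sqrt(sum(phi^2)) * sqrt(sum(pc2^2)))
    expect_equal(tspLoss(phi, v, B, pc2, cfg),
                 sum(resid^2) - 0.7 * cosTerm + 0.3 * sum(phi^2))
    ## zero-norm arguments make the cosine term 0
    expect_equal(tspLoss(numeric(4), v, B, pc2, tspConfig(b = 5, lam = 0)),
                 sum(v^2))
})

test_that("projection reproduces representable velocities and kills
           orthogonal ones", {
    ## 4 cells on a plane embedded in 3D; velocities within the plane are
    ## exactly representable, velocities along the normal are annihilated
    X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
    dimnames(X) <- list(paste0("c", 1:4), c("x", "y", "z"))
    s <- CellStateSet(X)
    g <- buildKnnGraph(s, k = 3)
    inPlane <- matrix(rep(c(0.3, -0.2, 0), each = 4), 4, 3,
                      dimnames = dimnames(X))
    fit <- tspProject(s, VelocityField(inPlane, "genes"), g,
                      tspConfig(b = 0, lam = 0))
    expect_equal(velocityValues(fit$velocity), inPlane, tolerance = 1e-10)
    normal <- matrix(rep(c(0, 0, 1), each = 4), 4, 3,
                     dimnames = dimnames(X))
    fit2 <- tspProject(s, VelocityField(normal, "genes"), g,
                       tspConfig(b = 0, lam = 0))
    expect_lt(max(abs(velocityValues(fit2$velocity))), 1e-10)
})

test_that("b = 0 coefficients match the minimum-norm least-squares oracle", {
    set.seed(12)
    ## one random 3D cell with 4 neighbors: rank-deficient normal equations,
    ## minimum-norm solution via the pseudoinverse oracle
    X <- matrix(rnorm(15), 5, 3,
                dimnames = list(paste0("c", 1:5), c("x", "y", "z")))
    s <- CellStateSet(X)
    g <- buildKnnGraph(s, k = 4)
    V <- matrix(rnorm(15), 5, 3, dimnames = dimnames(X))
    fit <- tspProject(s, VelocityField(V, "genes"), g,
                      tspConfig(b = 0, lam = 0))
    d <- displacements(s, g)
    for (i in 1:5) {
        B <- matrix(d[i, , ], nrow = 4)
        phiRef <- as.vector(MASS::ginv(t(B)) %*% V[i, ])
        expect_equal(unname(coefValues(fit$phi)[i, ]), phiRef,
                     tolerance = 1e-6)
    }
})

test_that("ridge-regularized fits match the normal-equations oracle on a
           50-cell fixture", {
    dat <- makeRandomData(50, 3, seed = 13)
    g <- buildKnnGraph(dat$states, k = 4)
    lam <- 1e-8
    fit <- tspProject(dat$states, dat$vel, g, tspConfig(b = 0, lam = lam))
    d <- displacements(dat$states, g)
    V <- velocityValues(dat$vel)
    for (i in seq_len(50)) {
        B <- matrix(d[i, , ], nrow = 4)
        ref <- ridgeOracle(B, V[i, ], lam)
        expect_equal(unname(coefValues(fit$phi)[i, ]), ref,
                     tolerance = 1e-5)
    }
})

test_that("returned loss never exceeds the initialization loss", {
    dat <- makeRandomData(40, 3, seed = 14)
    g <- buildKnnGraph(dat$states, k = 5)
    fit <- tspProject(dat$states, dat$vel, g, tspConfig(b = 1.5, lam = 0.01))
    expect_true(all(fit$phi@loss <= fit$phi@initLoss + 1e-12))
})

test_that("zero-velocity cells are skipped with phi = 0", {
    dat <- makeRandomData(20, 3, seed = 15)
    V <- velocityValues(dat$vel)
    V[4, ] <- 0
    g <- buildKnnGraph(dat$states, k = 4)
    fit <- tspProject(dat$states, VelocityField(V, "genes"), g)
    expect_equal(unname(coefValues(fit$phi)[4, ]), numeric(4))
    expect_equal(unname(velocityValues(fit$velocity)[4, ]), numeric(3))
})

test_that("non-finite velocities raise an input error", {
    dat <- makeRandomData(10, 2)
    g <- buildKnnGraph(dat$states, k = 3)
    V <- velocityValues(dat$vel)
    expect_error(
        tspProject(dat$states,
                   new("VelocityField",
                       values = {V[1, 1] <- 1; V},
                       representation = "genes"), g),
        NA)
    Vbad <- V; Vbad[2, 2] <- NaN
    bad <- new("VelocityField", values = matrix(0, 10, 2),
               representation = "genes")
    bad@values <- Vbad  # bypass constructor validity to hit the solver check
    expect_error(tspProject(dat$states, bad, g), "input error")
})

test_that("the direction term pulls solutions toward the cosine kernel", {
    ## with a huge b and tiny residual weight the fitted phi direction must
    ## align with phi_corr far better than the pure least-squares fit
    dat <- makeRandomData(25, 3, seed = 16)
    g <- buildKnnGraph(dat$states, k = 5)
    d <- displacements(dat$states, g)
    V <- velocityValues(dat$vel)
    fit0 <- tspProject(dat$states, dat$vel, g, tspConfig(b = 0, lam = 1e-4))
    fitB <- suppressWarnings(
        tspProject(dat$states, dat$vel, g, tspConfig(b = 50, lam = 1e-4)))
    cosTo <- function(fit) sapply(seq_len(25), function(i) {
        B <- matrix(d[i, , ], nrow = 5)
        pc <- cosineKernelCoefficients(V[i, ], B)
        sum(coefValues(fit$phi)[i, ] * pc) /
            (sqrt(sum(coefValues(fit$phi)[i, ]^2)) * sqrt(sum(pc^2)))
    })
    expect_gt(median(cosTo(fitB)), median(cosTo(fit0)))
})
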