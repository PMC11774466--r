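makeLinearField <- function(n = 100, seed = 70) {
    set.seed(seed)
    A <- matrix(c(-1, 0.5, 0.3, 0.2, -0.8, 0.1, 0, 0.4, -1.2), 3, 3,
                byrow = TRUE)
    X <- matrix(rnorm(3 * n), n, 3,
                dimnames = list(sprintf("c%03d", 1:n), c("x", "y", "z")))
    V <- X %*% t(A); dimnames(V) <- dimnames(X)
    list(A = A, states = CellStateSet(X, representation = "x"),
         vel = VelocityField(V, "x"))
}

test_that("the closed-form coefficients satisfy the stationarity condition
           of the regularized loss", {
    fx <- makeLinearField(60)
    fld <- fitRKHSField(fx$states, fx$vel, nCenters = 40, lambda = 0.1,
                        seed = 1)
    K <- graphvelo:::.rkhsKernel(stateValues(fx$states), fld@centers, fld@w)
    Kt <- graphvelo:::.rkhsKernel(fld@centers, fld@centers, fld@w)
    C <- fld@coefficients
    grad <- 2 * crossprod(K, K %*% C - velocityValues(fx$vel)) +
            fld@lambda * Kt %*% C
    expect_lt(max(abs(grad)), 1e-8)
})

test_that("the field interpolates with all centers and vanishes under
           heavy regularization", {
    fx <- makeLinearField(50)
    fld <- fitRKHSField(fx$states, fx$vel, nCenters = 50, lambda = 1e-12,
                        seed = 1)
    resid <- suppressWarnings(
        evaluateField(fld, stateValues(fx$states))) -
        velocityValues(fx$vel)
    expect_lt(max(abs(resid)), 1e-6)
    heavy <- fitRKHSField(fx$states, fx$vel, nCenters = 50, lambda = 1e9,
                          seed = 1)
    expect_lt(max(abs(heavy@coefficients)), 1e-6)
    expect_lt(max(abs(evaluateField(heavy, stateValues(fx$states)))), 1e-4)
})

test_that("field evaluation is linear in the coefficients", {
    fx <- makeLinearField(40)
    fld <- fitRKHSField(fx$states, fx$vel, nCenters = 30, lambda = 1e-4,
                        seed = 2)
    dbl <- fld
    dbl@coefficients <- 2 * fld@coefficients
    X <- stateValues(fx$states)
    expect_equal(evaluateField(dbl, X), 2 * evaluateField(fld, X))
})

test_that("the analytic Jacobian matches finite differences and the
           generating matrix of a linear field", {
    fx <- makeLinearField(200)
    fld <- suppressWarnings(
        fitRKHSField(fx$states, fx$vel, nCenters = 200, lambda = 1e-10,
                     seed = 3))
    ## zero-coefficient field has a zero Jacobian
    z <- fld; z@coefficients <- 0 * fld@coefficients
    expect_equal(unname(fieldJacobian(z, c(0, 0, 0))), matrix(0, 3, 3))
    ## finite-difference oracle at random points
    set.seed(71)
    for (r in 1:3) {
        x0 <- rnorm(3, 0, 0.5)
        J <- fieldJacobian(fld, x0)
        eps <- 1e-5
        Jfd <- vapply(1:3, function(j) {
            e <- numeric(3); e[j] <- eps
            (evaluateField(fld, x0 + e) - evaluateField(fld, x0 - e)) /
                (2 * eps)
        }, numeric(3))
        expect_equal(unname(J), unname(Jfd), tolerance = 1e-5)
    }
    ## averaged over data points the Jacobian recovers A within 5%
    pts <- stateValues(fx$states)[sample(200, 25), ]
    Jbar <- Reduce(`+`, lapply(seq_len(25), function(i)
        fieldJacobian(fld, pts[i, ]))) / 25
    expect_lt(max(abs(Jbar - fx$A)) / max(abs(fx$A)), 0.05)
    ## acceleration is J v
    x0 <- c(0.2, -0.1, 0.3)
    expect_equal(fieldAcceleration(fld, x0),
                 as.vector(fieldJacobian(fld, x0) %*%
                           t(evaluateField(fld, x0))))
})

test_that("the field fit tracks the toggle-switch drift", {
    tr <- simulateToggleSwitch(nCells = 400, seed = 4)
    ## Gillespie states include near-duplicates, so the center kernel is
    ## near-singular at tiny lambda; the documented jitter fallback applies
    fld <- suppressWarnings(
        fitRKHSField(trajStates(tr), trajVelocity(tr), nCenters = 200,
                     lambda = 1e-6, seed = 5))
    pred <- evaluateField(fld, stateValues(trajStates(tr)))
    ev <- evaluateVelocity(pred, velocityValues(trajVelocity(tr)))
    expect_gte(ev$medianCosine, 0.99)
})

test_that("dose-response curves integrate Jacobian elements correctly", {
    fx <- makeLinearField(150)
    fld <- suppressWarnings(
        fitRKHSField(fx$states, fx$vel, nCenters = 150, lambda = 1e-8,
                     seed = 6))
    ## constant Jacobian element A[2,1]: the curve is a straight line of
    ## slope A[2,1] through the origin
    dr <- doseResponse(fld, "x", "y", fx$states)
    expect_equal(length(dr$grid), 100)
    expect_equal(dr$response[1], 0)
    fitLine <- lm(dr$response ~ dr$grid)
    expect_equal(unname(coef(fitLine)[2]), fx$A[2, 1], tolerance = 0.05)
    expect_lt(max(abs(dr$response - dr$grid * fx$A[2, 1])), 0.05)
    ## a zero element gives a flat curve at 0: build a field with the
    ## y-output coefficients zeroed
    z <- fld; z@coefficients[, 2] <- 0
    drZ <- doseResponse(z, "x", "y", fx$states)
    expect_equal(drZ$response, rep(0, 100))
    ## monotone nonnegative element -> nondecreasing curve
    expect_true(all(diff(dr$response) *
                    sign(fx$A[2, 1]) >= -1e-12))
    ## matches a direct trapezoid oracle on the per-bin means
    me <- dr$meanElement
    ref <- c(0, cumsum(diff(dr$grid) * (me[-1] + me[-100]) / 2))
    expect_equal(dr$response, ref)
    ## constant regulator is degenerate
    Xc <- stateValues(fx$states); Xc[, 1] <- 1
    expect_error(doseResponse(fld, "x", "y", CellStateSet(Xc)),
                 "degenerate")
})
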