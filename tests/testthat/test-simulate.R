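test_that("recorded velocities equal the model drift at the recorded
           states", {
    tr <- simulateToggleSwitch(nCells = 200, seed = 3)
    S <- stateValues(trajStates(tr))
    expect_identical(velocityValues(trajVelocity(tr)),
                     toggleSwitchDrift(S[, 1], S[, 2], tr@params[1:12]))
    grn <- simulateGRN("linear", nCells = 100, nGenes = 10, seed = 4)
    U <- trajLayer(grn, "u"); Sm <- stateValues(trajStates(grn))
    p <- grn@params
    drift <- p$beta * U - Sm * rep(p$gamma, each = 100)
    expect_equal(unname(velocityValues(trajVelocity(grn))), unname(drift))
})

test_that("simulators are seed-deterministic", {
    a <- simulateToggleSwitch(nCells = 150, seed = 7)
    b <- simulateToggleSwitch(nCells = 150, seed = 7)
    expect_identical(stateValues(trajStates(a)), stateValues(trajStates(b)))
    expect_identical(trajTimes(a), trajTimes(b))
    c1 <- simulateGRN("cyclic", nCells = 80, nGenes = 12, seed = 9)
    c2 <- simulateGRN("cyclic", nCells = 80, nGenes = 12, seed = 9)
    expect_identical(stateValues(trajStates(c1)), stateValues(trajStates(c2)))
    d1 <- simulateToggleSwitch(nCells = 150, seed = 8)
    expect_false(identical(stateValues(trajStates(a)),
                           stateValues(trajStates(d1))))
})

test_that("with no production the toggle switch decays to the origin", {
    p <- toggleSwitchParams(a1 = 0, a2 = 0, b1 = 0, b2 = 0)
    expect_equal(unname(toggleSwitchDrift(2, 3, p)[1, ]), c(-2, -3))
    tr <- simulateToggleSwitch(p, nCells = 100, seed = 1, engine = "ode",
                               tMax = 20)
    late <- trajTimes(tr) > 15
    expect_lt(max(abs(stateValues(trajStates(tr))[late, ])), 1e-3)
})

test_that("late toggle-switch states concentrate near the stable fixed
           points of the drift", {
    p <- toggleSwitchParams()
    ## independent fixed-point oracle: root finding on the drift restricted
    ## to the committed regime (one gene high, the other low)
    drift1 <- function(x, y) toggleSwitchDrift(x, y, p)[1, 1]
    drift2 <- function(x, y) toggleSwitchDrift(x, y, p)[1, 2]
    xHi <- uniroot(function(x) drift1(x, 0.05), c(0.8, 2))$root
    yLo <- uniroot(function(y) drift2(xHi, y), c(1e-6, 0.4))$root
    tr <- simulateToggleSwitch(p, nCells = 1000, seed = 2)
    S <- stateValues(trajStates(tr))
    late <- S[trajTimes(tr) > 9, ]
    ## distance of each late cell to its nearest (symmetric) fixed point
    d <- pmin(sqrt((late[, 1] - xHi)^2 + (late[, 2] - yLo)^2),
              sqrt((late[, 1] - yLo)^2 + (late[, 2] - xHi)^2))
    expect_lt(median(d), 0.25)
})

test_that("the sphere lift clamps, scales and differentiates correctly", {
    X <- rbind(c(0, 0), c(10, 10), c(30, 40))
    dimnames(X) <- list(paste0("c", 1:3), c("x", "y"))
    V <- matrix(c(1, -1, 0.5, 0.2, 1, 1), 3, 2, dimnames = dimnames(X))
    tr <- new("SimulationTrajectory",
              states = CellStateSet(X), velocity = VelocityField(V, "genes"),
              times = 1:3, labels = character(), layers = list(),
              params = list())
    up <- liftToSphere(tr, r = 70, dt = 1)
    S3 <- stateValues(trajStates(up))
    expect_equal(unname(S3[1, 3]), 70)                    # origin -> pole
    expect_equal(unname(S3[3, 3]), sqrt(70^2 - 30^2 - 40^2))
    ## outside the disk the height clamps to zero
    X2 <- rbind(c(69, 69), c(1, 1))
    dimnames(X2) <- list(c("a", "b"), c("x", "y"))
    tr2 <- new("SimulationTrajectory", states = CellStateSet(X2),
               velocity = VelocityField(matrix(0.1, 2, 2), "genes"),
               times = 1:2, labels = character(), layers = list(),
               params = list())
    expect_equal(unname(stateValues(trajStates(liftToSphere(tr2)))[1, 3]), 0)
    ## as dt -> 0 the finite-difference z-velocity approaches the analytic
    ## tangent derivative -(x xdot + y ydot)/z
    up4 <- liftToSphere(tr, r = 70, dt = 1e-4)
    V3 <- velocityValues(trajVelocity(up4))
    zAn <- -(X[, 1] * V[, 1] + X[, 2] * V[, 2]) / S3[, 3]
    expect_equal(unname(V3[2, 3]), unname(zAn[2]), tolerance = 1e-3)
    expect_equal(unname(V3[3, 3]), unname(zAn[3]), tolerance = 1e-3)
})

test_that("burst kinetics start at zero, approach the pre-burst steady
           state, then rise above the steady-state line", {
    p <- splicingSimParams()
    tr <- simulateBurst(p)
    V <- velocityValues(trajVelocity(tr))
    S <- stateValues(trajStates(tr))
    t <- trajTimes(tr)
    ## at t = 0: du/dt = alpha, ds/dt = 0
    expect_equal(unname(V[1, ]), c(p$alpha0, 0))
    ## just before the burst the state is near (alpha/beta, alpha/gamma)
    pre <- max(which(t < p$burstTime))
    expect_equal(unname(S[pre, ]),
                 c(p$alpha0 / p$beta, p$alpha0 / p$gamma0), tolerance = 0.05)
    ## after the burst: phase point above u = (gamma/beta) s with du/dt > 0
    post <- t > p$burstTime + 0.2 & t < p$burstTime + 2
    expect_true(all(S[post, "u"] > (p$gamma0 / p$beta) * S[post, "s"]))
    expect_true(all(V[post, "u"] > 0))
})

test_that("microRNA-driven degradation reproduces the closed-form microRNA
           curve and the negative-velocity sign trap", {
    p <- splicingSimParams(tMax = 15)
    tr <- simulateMirnaDegradation(p)
    t <- trajTimes(tr)
    m <- trajLayer(tr, "m")[, 1]
    expect_equal(m, (p$alphaM / p$gammaM) * (1 - exp(-p$gammaM * t)),
                 tolerance = 1e-6, ignore_attr = TRUE)
    V <- velocityValues(trajVelocity(tr))
    S <- stateValues(trajStates(tr))
    ## steady-state start: du/dt = ds/dt = 0 at t = 0
    expect_equal(unname(V[1, ]), c(0, 0), tolerance = 1e-10)
    ## mid-trajectory: ds/dt < 0 while still above the naive steady-state
    ## line u = (gamma0/beta) s
    mid <- t > 0.5 & t < 6
    expect_true(all(V[mid, "s"] < 0))
    expect_true(all(S[mid, "u"] > (p$gamma0 / p$beta) * S[mid, "s"]))
    ## the programmed degradation rate is recoverable exactly
    kr <- cellSpecificRates(S[, "u"], S[, "s"], V[, "u"], V[, "s"],
                            beta = p$beta)
    expect_equal(kr@gamma, tr@params$gammaTrue, tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("GRN topologies produce their defining geometry", {
    ## linear: activation onsets follow the cascade order
    lin <- simulateGRN("linear", nCells = 400, nGenes = 40, noiseSd = 0,
                       seed = 5)
    S <- stateValues(trajStates(lin))
    onset <- apply(S, 2, function(x)
        trajTimes(lin)[min(which(x > 0.5 * max(x)))])
    byModule <- tapply(onset, lin@params$geneModule, mean)
    expect_true(all(diff(byModule) > 0))
    ## cyclic: winding number >= 1 around the centroid in the first two PCs
    cyc <- simulateGRN("cyclic", nCells = 400, nGenes = 40, seed = 5)
    pc <- prcomp(stateValues(trajStates(cyc)), rank. = 2)$x
    cen <- colMeans(pc)
    ang <- atan2(pc[, 2] - cen[2], pc[, 1] - cen[1])[order(trajTimes(cyc))]
    dw <- diff(ang)
    dw <- ifelse(dw > pi, dw - 2 * pi, ifelse(dw < -pi, dw + 2 * pi, dw))
    expect_gte(abs(sum(dw)) / (2 * pi), 1)
    ## bifurcating: terminal states form two clean k-means clusters
    bif <- simulateGRN("bifurcating", nCells = 400, nGenes = 40, seed = 5)
    late <- trajTimes(bif) > 0.7 * max(trajTimes(bif))
    X <- stateValues(trajStates(bif))[late, ]
    km <- kmeans(X, 2, nstart = 5)
    D <- as.matrix(dist(X))
    sil <- vapply(seq_len(nrow(X)), function(i) {
        own <- km$cluster[i]
        a <- mean(D[i, km$cluster == own & seq_len(nrow(X)) != i])
        b <- min(vapply(setdiff(unique(km$cluster), own),
                        function(cc) mean(D[i, km$cluster == cc]),
                        numeric(1)))
        (b - a) / max(a, b)
    }, numeric(1))
    expect_gt(mean(sil), 0.5)
    expect_error(simulateGRN("star"), "arg")
})

test_that("noise injection honors its contracts", {
    dat <- makeRandomData(2000, 8, seed = 40)
    ## level 0 returns the input object unchanged
    expect_identical(addNoise(dat$vel, "gaussian", level = 0), dat$vel)
    ## normal-component noise is parallel to the supplied normals
    sph <- liftToSphere(simulateToggleSwitch(nCells = 100, seed = 1))
    nrm <- sphereNormals(trajStates(sph))
    noisy <- addNoise(trajVelocity(sph), "normal_component", level = 1,
                      seed = 2, normals = nrm)
    diff <- velocityValues(noisy) - velocityValues(trajVelocity(sph))
    cosines <- abs(rowSums(diff * nrm)) / sqrt(rowSums(diff^2))
    expect_equal(unname(cosines), rep(1, 100), tolerance = 1e-9)
    expect_error(addNoise(dat$vel, "normal_component", level = 1),
                 "normals")
    ## gaussian noise sd matches level * per-feature sd within 5%
    noisyG <- addNoise(dat$vel, "gaussian", level = 1, seed = 3)
    added <- velocityValues(noisyG) - velocityValues(dat$vel)
    ratio <- apply(added, 2, sd) / apply(velocityValues(dat$vel), 2, sd)
    expect_true(all(abs(ratio - 1) < 0.05))
})
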