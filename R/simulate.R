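# Ground-truth synthetic data: stochastic toggle-switch bifurcation lifted to
# a sphere, splicing-kinetics ODEs with transcription bursts and
# microRNA-driven degradation, a small gene-regulatory-network trajectory
# simulator, and noise injectors. Every simulator records the exact model
# drift at each sampled state as the ground-truth velocity.

#' Toggle-switch parameters
#'
#' Mutual-inhibition / self-activation two-gene circuit with Hill kinetics:
#' `dx/dt = a1 x^n/(S1^n + x^n) + b1 K1^n/(K1^n + y^n) - g1 x` and
#' symmetrically for y, divided by the timescale `tau`.
#'
#' @param a1,a2 self-activation strengths.
#' @param b1,b2 cross-inhibition (basal, repressed by the other gene)
#'   strengths.
#' @param S1,S2,K1,K2 Hill half-saturation constants.
#' @param n Hill exponent (>= 1).
#' @param gamma1,gamma2 first-order decay rates.
#' @param tau overall timescale.
#' @return named list of parameters.
#' @export
toggleSwitchParams <- function(a1 = 1, a2 = 1, b1 = 0.5, b2 = 0.5,
                               S1 = 0.5, S2 = 0.5, K1 = 0.5, K2 = 0.5,
                               n = 4, gamma1 = 1, gamma2 = 1, tau = 1) {
    p <- list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, S1 = S1, S2 = S2,
              K1 = K1, K2 = K2, n = n, gamma1 = gamma1, gamma2 = gamma2,
              tau = tau)
    if (any(c(a1, a2, b1, b2) < 0))
        stop("parameter error: production strengths must be nonnegative")
    if (any(c(S1, S2, K1, K2, gamma1, gamma2, tau) <= 0))
        stop("parameter error: half-saturations, decay rates and tau must be ",
             "positive")
    if (n < 1) stop("parameter error: Hill exponent n must be >= 1")
    p
}

#' Deterministic toggle-switch drift
#'
#' @param x,y concentrations of the two genes (vectors of equal length).
#' @param params a [toggleSwitchParams()] list.
#' @return two-column matrix of (dx/dt, dy/dt).
#' @export
toggleSwitchDrift <- function(x, y, params = toggleSwitchParams()) {
    p <- params
    dx <- p$a1 * x^p$n / (p$S1^p$n + x^p$n) +
          p$b1 * p$K1^p$n / (p$K1^p$n + y^p$n) - p$gamma1 * x
    dy <- p$a2 * y^p$n / (p$S2^p$n + y^p$n) +
          p$b2 * p$K2^p$n / (p$K2^p$n + x^p$n) - p$gamma2 * y
    cbind(x = dx, y = dy) / p$tau
}

## one Gillespie realization; counts scaled by volume omega, states recorded
## (as concentrations) at the requested times
.gillespieToggle <- function(params, omega, sampleTimes, tMax) {
    p <- params
    nx <- 0L; ny <- 0L; t <- 0
    out <- matrix(0, length(sampleTimes), 2)
    nextSample <- 1L
    nS <- length(sampleTimes)
    while (nextSample <= nS) {
        x <- nx / omega; y <- ny / omega
        a <- c(omega * (p$a1 * x^p$n / (p$S1^p$n + x^p$n) +
                        p$b1 * p$K1^p$n / (p$K1^p$n + y^p$n)) / p$tau,
               p$gamma1 * nx / p$tau,
               omega * (p$a2 * y^p$n / (p$S2^p$n + y^p$n) +
                        p$b2 * p$K2^p$n / (p$K2^p$n + x^p$n)) / p$tau,
               p$gamma2 * ny / p$tau)
        A <- sum(a)
        tNext <- if (A > 0) t + rexp(1L, A) else Inf
        while (nextSample <= nS && sampleTimes[nextSample] < tNext) {
            out[nextSample, ] <- c(nx, ny) / omega
            nextSample <- nextSample + 1L
        }
        if (tNext > tMax) break
        t <- tNext
        r <- runif(1L) * A
        if (r < a[1L]) nx <- nx + 1L
        else if (r < a[1L] + a[2L]) nx <- nx - 1L
        else if (r < a[1L] + a[2L] + a[3L]) ny <- ny + 1L
        else ny <- ny - 1L
    }
    out
}

#' Simulate a toggle-switch bifurcation
#'
#' Samples cell states along stochastic (Gillespie with molecule-count
#' scaling `omega`) or deterministic trajectories of the two-gene
#' toggle-switch circuit, starting near the origin so trajectories rise
#' through the unstable symmetric state and commit to one of the two stable
#' attractors. The recorded ground-truth velocity is the deterministic drift
#' evaluated at each sampled state.
#'
#' @param params a [toggleSwitchParams()] list.
#' @param nCells number of sampled cell states (default 2000).
#' @param seed RNG seed.
#' @param engine `"gillespie"` (default) or `"ode"`.
#' @param omega molecule-count volume scaling for the Gillespie engine.
#' @param tMax trajectory length in model time units.
#' @param nTraj number of independent trajectories to pool.
#' @return a [SimulationTrajectory-class] with 2-feature states (x, y).
#' @export
simulateToggleSwitch <- function(params = toggleSwitchParams(), nCells = 2000L,
                                 seed = 0L, engine = c("gillespie", "ode"),
                                 omega = 100, tMax = 12,
                                 nTraj = max(2L, ceiling(nCells / 50))) {
    engine <- match.arg(engine)
    if (nCells < 2L) stop("parameter error: nCells must be >= 2")
    set.seed(seed)
    perTraj <- ceiling(nCells / nTraj)
    states <- NULL; times <- NULL
    for (tr in seq_len(nTraj)) {
        st <- sort(runif(perTraj, 0, tMax))
        if (engine == "gillespie") {
            S <- .gillespieToggle(params, omega, st, tMax)
        } else {
            x0 <- runif(2L, 0, 0.05)
            sol <- deSolve::ode(
                y = c(x = x0[1L], y = x0[2L]),
                times = c(0, st),
                func = function(t, s, p)
                    list(as.vector(toggleSwitchDrift(s[1L], s[2L], p))),
                parms = params)
            S <- unname(sol[-1L, c("x", "y"), drop = FALSE])
        }
        states <- rbind(states, S)
        times <- c(times, st)
    }
    keep <- seq_len(nCells)
    states <- states[keep, , drop = FALSE]
    times <- times[keep]
    colnames(states) <- c("x", "y")
    rownames(states) <- sprintf("cell_%04d", seq_len(nCells))
    drift <- toggleSwitchDrift(states[, 1L], states[, 2L], params)
    dimnames(drift) <- dimnames(states)
    new("SimulationTrajectory",
        states = CellStateSet(states, representation = "genes"),
        velocity = VelocityField(drift, "genes"),
        times = times, labels = character(),
        layers = list(),
        params = c(params, list(engine = engine, omega = omega, seed = seed)))
}

#' Lift a planar trajectory onto a sphere
#'
#' Maps 2D states (x, y) onto the upper cap of a sphere of radius `r` via
#' `z = sqrt(max(r^2 - x^2 - y^2, 0))` and produces correctly scaled 3D
#' velocities by finite-step propagation:
#' `zdot = (z(x + xdot*dt, y + ydot*dt) - z(x, y)) / dt`. Cells outside the
#' disk get `z = 0` with `zdot` from the same formula. The lifted surface is
#' a curved 2D manifold with an analytic unit normal (x, y, z)/r, making it
#' the reference benchmark for tangent projection.
#'
#' @param traj a 2D [SimulationTrajectory-class] (e.g. from
#'   [simulateToggleSwitch()]).
#' @param r sphere radius (default 70).
#' @param dt propagation step for the z-velocity (default 1).
#' @return a 3D [SimulationTrajectory-class] with representation "sphere".
#' @export
liftToSphere <- function(traj, r = 70, dt = 1) {
    stopifnot(is(traj, "SimulationTrajectory"), r > 0, dt > 0)
    S <- traj@states@values
    V <- traj@velocity@values
    if (ncol(S) != 2L) stop("liftToSphere expects 2D states")
    zOf <- function(x, y) sqrt(pmax(r^2 - x^2 - y^2, 0))
    z <- zOf(S[, 1L], S[, 2L])
    zdot <- (zOf(S[, 1L] + V[, 1L] * dt, S[, 2L] + V[, 2L] * dt) - z) / dt
    S3 <- cbind(S, z = z)
    V3 <- cbind(V, z = zdot)
    colnames(S3) <- colnames(V3) <- c("x", "y", "z")
    rownames(V3) <- rownames(S3)
    new("SimulationTrajectory",
        states = CellStateSet(S3, representation = "sphere"),
        velocity = VelocityField(V3, "sphere"),
        times = traj@times, labels = traj@labels, layers = traj@layers,
        params = c(traj@params, list(r = r, liftDt = dt)))
}

#' Analytic unit surface normals of the sphere lift
#'
#' @param states a [CellStateSet-class] of 3D sphere-lifted coordinates.
#' @param r sphere radius.
#' @return cells x 3 matrix of unit normals (x, y, z)/r.
#' @export
sphereNormals <- function(states, r = 70) {
    N <- states@values / r
    N / pmax(sqrt(rowSums(N^2)), .Machine$double.eps)
}

#' Splicing-kinetics simulation parameters
#'
#' Shared parameter block for the transcription-burst and the
#' microRNA-driven rapid-degradation simulations of the two-stage splicing
#' model `du/dt = alpha - beta u`, `ds/dt = beta u - gamma s`.
#'
#' @param alpha0 baseline transcription rate.
#' @param beta splicing rate.
#' @param gamma0 baseline degradation rate.
#' @param kAlpha,kGamma coupling strengths of the microRNA signal to
#'   transcription (inhibiting) and degradation (promoting).
#' @param alphaM,gammaM microRNA production and decay rates.
#' @param burstFactor fold change of alpha at the burst (default 3).
#' @param burstTime time of the transcription burst.
#' @param tMax simulated time span.
#' @param nSteps number of output time points.
#' @param seed RNG seed (the ODEs are deterministic; kept for interface
#'   uniformity).
#' @param alphaForm `"mirna"` (default; transcription inhibited by the
#'   microRNA level m) or `"time"` (inhibited linearly in time).
#' @return named list of parameters.
#' @export
splicingSimParams <- function(alpha0 = 2, beta = 1, gamma0 = 0.5,
                              kAlpha = 0.1, kGamma = 0.5, alphaM = 1,
                              gammaM = 0.5, burstFactor = 3, burstTime = 10,
                              tMax = 25, nSteps = 500L, seed = 0L,
                              alphaForm = c("mirna", "time")) {
    alphaForm <- match.arg(alphaForm)
    p <- list(alpha0 = alpha0, beta = beta, gamma0 = gamma0,
              kAlpha = kAlpha, kGamma = kGamma, alphaM = alphaM,
              gammaM = gammaM, burstFactor = burstFactor,
              burstTime = burstTime, tMax = tMax, nSteps = as.integer(nSteps),
              seed = seed, alphaForm = alphaForm)
    if (any(unlist(p[1:7]) <= 0)) stop("parameter error: rates must be positive")
    if (burstFactor <= 0) stop("parameter error: burstFactor must be > 0")
    p
}

.splicingTraj <- function(u, s, du, ds, t, layers = list(), params) {
    X <- cbind(u = u, s = s)
    V <- cbind(u = du, s = ds)
    rownames(X) <- rownames(V) <- sprintf("t_%04d", seq_along(t))
    new("SimulationTrajectory",
        states = CellStateSet(X, representation = "splicing"),
        velocity = VelocityField(V, "splicing"),
        times = t, labels = character(), layers = layers, params = params)
}

#' Simulate a transcription burst on the phase portrait
#'
#' Two-stage splicing kinetics from `u(0) = s(0) = 0` with constant rates,
#' except that at `burstTime` the transcription rate jumps to
#' `burstFactor * alpha0`. After the burst the (s, u) phase point rises above
#' the pre-burst steady-state line `u = (gamma/beta) s` while `du/dt > 0` —
#' the geometry that misleads constant-rate velocity estimators.
#'
#' @param params a [splicingSimParams()] list.
#' @return a [SimulationTrajectory-class] over features (u, s) whose velocity
#'   layer holds the exact piecewise drift.
#' @export
simulateBurst <- function(params = splicingSimParams()) {
    p <- params
    alphaAt <- function(t) ifelse(t >= p$burstTime, p$burstFactor * p$alpha0,
                                  p$alpha0)
    rhs <- function(t, y, parms) {
        a <- alphaAt(t)
        list(c(a - p$beta * y[1L], p$beta * y[1L] - p$gamma0 * y[2L]))
    }
    t1 <- seq(0, p$burstTime, length.out = ceiling(p$nSteps * p$burstTime / p$tMax))
    t2 <- seq(p$burstTime, p$tMax, length.out = p$nSteps - length(t1) + 1L)
    s1 <- deSolve::ode(c(u = 0, s = 0), t1, rhs, NULL)
    s2 <- deSolve::ode(s1[nrow(s1), c("u", "s")], t2, rhs, NULL)
    sol <- rbind(s1, s2[-1L, ])
    t <- sol[, "time"]; u <- sol[, "u"]; s <- sol[, "s"]
    du <- alphaAt(t) - p$beta * u
    ds <- p$beta * u - p$gamma0 * s
    .splicingTraj(u, s, du, ds, t, params = p)
}

#' Simulate microRNA-driven rapid degradation
#'
#' A minimal circuit in which an external signal both inhibits transcription
#' and produces a microRNA that linearly increases the mRNA degradation rate:
#' `dm/dt = alphaM - gammaM m`, `du/dt = alpha0 - kAlpha m - beta u`,
#' `ds/dt = beta u - (gamma0 + kGamma m) s`, started at the unperturbed
#' steady state `u = alpha0/beta`, `s = alpha0/gamma0`, `m = 0`. As m rises,
#' `ds/dt` turns negative while the phase point still sits above the naive
#' steady-state line — the sign trap for constant-rate estimators. The
#' programmed degradation rate `gamma0 + kGamma m(t)` is echoed in
#' `params$gammaTrue`.
#'
#' @param params a [splicingSimParams()] list; `alphaForm = "time"` switches
#'   the transcription inhibition from m-coupled to linear-in-time.
#' @return a [SimulationTrajectory-class] over features (u, s) with the
#'   microRNA level in layer `"m"`.
#' @export
simulateMirnaDegradation <- function(params = splicingSimParams(tMax = 15)) {
    p <- params
    rhs <- function(t, y, parms) {
        m <- y[1L]; u <- y[2L]; s <- y[3L]
        a <- if (p$alphaForm == "mirna") p$alpha0 - p$kAlpha * m
             else p$alpha0 - p$kAlpha * t
        list(c(p$alphaM - p$gammaM * m,
               a - p$beta * u,
               p$beta * u - (p$gamma0 + p$kGamma * m) * s))
    }
    t <- seq(0, p$tMax, length.out = p$nSteps)
    y0 <- c(m = 0, u = p$alpha0 / p$beta, s = p$alpha0 / p$gamma0)
    sol <- deSolve::ode(y0, t, rhs, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-10)
    m <- sol[, "m"]; u <- sol[, "u"]; s <- sol[, "s"]
    alphaT <- if (p$alphaForm == "mirna") p$alpha0 - p$kAlpha * m
              else p$alpha0 - p$kAlpha * t
    gammaT <- p$gamma0 + p$kGamma * m
    du <- alphaT - p$beta * u
    ds <- p$beta * u - gammaT * s
    mLayer <- matrix(m, ncol = 1L, dimnames = list(NULL, "m"))
    .splicingTraj(u, s, du, ds, t, layers = list(m = mLayer),
                  params = c(p, list(gammaTrue = gammaT, alphaTrue = alphaT)))
}

## Hill activation / repression used by the GRN module cascade
.hillAct <- function(a, K = 0.5, h = 4) a^h / (K^h + a^h)
.hillRep <- function(a, K = 0.5, h = 4) K^h / (K^h + a^h)

## module-activity right-hand side for each topology
.grnModuleRHS <- function(topology, nModules) {
    switch(topology,
        linear = function(t, a, parms) {
            d <- numeric(nModules)
            d[1L] <- 1 - a[1L]
            for (m in 2:nModules) d[m] <- .hillAct(a[m - 1L]) - a[m]
            list(d)
        },
        cyclic = function(t, a, parms) {
            prev <- c(nModules, seq_len(nModules - 1L))
            list(.hillRep(a[prev]) - a)
        },
        bifurcating = function(t, a, parms) {
            ## a = (root, A1, A2, B1, B2); A1 and B1 mutually repress
            d <- numeric(5L)
            d[1L] <- 1 - a[1L]
            d[2L] <- 2 * .hillAct(a[1L]) * .hillRep(a[4L]) - a[2L]
            d[4L] <- 2 * .hillAct(a[1L]) * .hillRep(a[2L]) - a[4L]
            d[3L] <- .hillAct(a[2L]) - a[3L]
            d[5L] <- .hillAct(a[4L]) - a[5L]
            list(d)
        },
        stop("invalid topology tag: ", topology))
}

#' Simulate a small gene-regulatory-network trajectory
#'
#' A cascade-of-Hill-modules model: a small set of module activities evolves
#' by ODEs wired to the requested topology (sequential activation for
#' `"linear"`, an odd repressive ring producing a limit cycle for
#' `"cyclic"`, mutual repression downstream of a common root for
#' `"bifurcating"`), and every gene follows two-stage splicing kinetics
#' driven by its module: `du_g/dt = c_g a_m(g) - beta u_g`,
#' `ds_g/dt = beta u_g - gamma_g s_g`. Cells are states sampled along the
#' trajectory at random times; optional Gaussian measurement noise is added
#' to u and s, and the recorded ground-truth velocity is the exact mature
#' drift `beta u - gamma s` re-evaluated at the recorded (noisy) state.
#'
#' @param topology `"linear"`, `"cyclic"`, or `"bifurcating"`.
#' @param nCells number of sampled cells (default 1000).
#' @param nGenes number of genes (default 100, >= 4).
#' @param noiseSd measurement noise as a fraction of each feature's standard
#'   deviation (default 0.05).
#' @param seed RNG seed.
#' @param nModules number of regulatory modules (fixed at 5 for
#'   `"bifurcating"`).
#' @return a [SimulationTrajectory-class]; states are mature abundances,
#'   layer `"u"` holds nascent abundances, `params$geneModule` maps genes to
#'   modules and `params$gamma`/`params$scale` echo the per-gene rates.
#' @export
simulateGRN <- function(topology = c("linear", "cyclic", "bifurcating"),
                        nCells = 1000L, nGenes = 100L, noiseSd = 0.05,
                        seed = 0L, nModules = 5L) {
    topology <- match.arg(topology)
    if (nGenes < 4L) stop("parameter error: nGenes must be >= 4")
    if (topology == "bifurcating") nModules <- 5L
    set.seed(seed)
    beta <- 1
    geneModule <- rep(seq_len(nModules), length.out = nGenes)
    geneModule <- sort(geneModule)
    scale <- exp(runif(nGenes, log(0.5), log(2)))
    gamma <- runif(nGenes, 0.5, 1.5)
    moduleRHS <- .grnModuleRHS(topology, nModules)
    tWindow <- switch(topology, linear = c(0, 12), cyclic = c(12, 60),
                      bifurcating = c(0, 12))
    rhs <- function(t, y, parms) {
        a <- y[seq_len(nModules)]
        u <- y[nModules + seq_len(nGenes)]
        s <- y[nModules + nGenes + seq_len(nGenes)]
        da <- moduleRHS(t, a, parms)[[1L]]
        du <- scale * a[geneModule] - beta * u
        ds <- beta * u - gamma * s
        list(c(da, du, ds))
    }
    solveBranch <- function(a0, cellTimes) {
        y0 <- c(a0, numeric(2L * nGenes))
        times <- sort(unique(c(0, cellTimes)))
        sol <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                            rtol = 1e-8, atol = 1e-8)
        sol[match(cellTimes, sol[, 1L]), -1L, drop = FALSE]
    }
    if (topology == "bifurcating") {
        nA <- ceiling(nCells / 2); nB <- nCells - nA
        tA <- sort(runif(nA, tWindow[1L], tWindow[2L]))
        tB <- sort(runif(nB, tWindow[1L], tWindow[2L]))
        a0A <- c(0, 0.05, 0, 0, 0); a0B <- c(0, 0, 0, 0.05, 0)
        Y <- rbind(solveBranch(a0A, tA), solveBranch(a0B, tB))
        times <- c(tA, tB)
        branch <- rep(c("A", "B"), c(nA, nB))
        labels <- ifelse(times < 0.3 * tWindow[2L], "progenitor",
                         paste0("branch", branch))
    } else {
        times <- sort(runif(nCells, tWindow[1L], tWindow[2L]))
        a0 <- if (topology == "cyclic")
                  0.5 + 0.4 * sin(2 * pi * seq_len(nModules) / nModules)
              else numeric(nModules)
        Y <- solveBranch(a0, times)
        labels <- character()
    }
    U <- Y[, nModules + seq_len(nGenes), drop = FALSE]
    S <- Y[, nModules + nGenes + seq_len(nGenes), drop = FALSE]
    if (noiseSd > 0) {
        U <- U + matrix(rnorm(length(U)), nrow(U)) *
             rep(noiseSd * pmax(apply(U, 2L, sd), 1e-12), each = nrow(U))
        S <- S + matrix(rnorm(length(S)), nrow(S)) *
             rep(noiseSd * pmax(apply(S, 2L, sd), 1e-12), each = nrow(S))
        U[U < 0] <- 0; S[S < 0] <- 0
    }
    geneIds <- sprintf("gene_%03d", seq_len(nGenes))
    cellIds <- sprintf("cell_%04d", seq_len(nrow(S)))
    dimnames(S) <- dimnames(U) <- list(cellIds, geneIds)
    V <- beta * U - S * rep(gamma, each = nrow(S))
    dimnames(V) <- dimnames(S)
    new("SimulationTrajectory",
        states = CellStateSet(S, representation = "genes"),
        velocity = VelocityField(V, "genes"),
        times = times, labels = labels,
        layers = list(u = U),
        params = list(topology = topology, nModules = nModules,
                      geneModule = setNames(geneModule, geneIds),
                      scale = setNames(scale, geneIds),
                      gamma = setNames(gamma, geneIds), beta = beta,
                      noiseSd = noiseSd, seed = seed))
}

#' Corrupt a velocity field with noise
#'
#' Two noise models used in benchmarking: `"gaussian"` adds i.i.d. noise per
#' entry with standard deviation `level` times the per-feature velocity
#' standard deviation; `"normal_component"` adds noise only along supplied
#' unit surface normals, with per-cell amplitude drawn from
#' `N(0, (level * mean speed)^2)` — corrupting exactly the direction a
#' tangent projection should remove.
#'
#' @param vel a [VelocityField-class].
#' @param mode `"gaussian"` or `"normal_component"`.
#' @param level noise level; 0 returns the input unchanged.
#' @param seed RNG seed.
#' @param normals cells x d matrix of unit normals (required for
#'   `"normal_component"`).
#' @return a [VelocityField-class].
#' @export
addNoise <- function(vel, mode = c("gaussian", "normal_component"),
                     level = 1, seed = 0L, normals = NULL) {
    mode <- match.arg(mode)
    if (level == 0) return(vel)
    V <- vel@values
    set.seed(seed)
    if (mode == "gaussian") {
        sds <- apply(V, 2L, sd)
        noise <- matrix(rnorm(length(V)), nrow(V)) *
                 rep(level * sds, each = nrow(V))
        out <- V + noise
    } else {
        if (is.null(normals))
            stop("normal_component mode requires surface normals")
        if (!all(dim(normals) == dim(V)))
            stop("alignment error: normals shape must match velocity")
        amp <- level * mean(sqrt(rowSums(V^2)))
        out <- V + normals * rnorm(nrow(V), 0, amp)
    }
    VelocityField(out, vel@representation)
}
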