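# Tangent-space projection: cosine-kernel coefficients, the TSP loss, and the
# per-cell solver yielding tangent coefficients phi and projected velocity.
#
# For cell i with velocity v_i and neighbor displacements delta_ij, the
# projected velocity is v||_i = sum_j phi_ij delta_ij, with phi_i minimizing
#
#   ||v_i - sum_j phi_ij delta_ij||^2 - b * cos(phi_i, phi_i^corr)
#     + lam * ||phi_i||^2 .
#
# The first term learns correctly scaled magnitudes, the second retains the
# direction information carried by the cosine-kernel weights phi^corr (which
# asymptotically point the right way but discard magnitude), and the third
# bounds the coefficients.

## cosine of two vectors; 0 when either has zero norm (documented convention)
.safeCos <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
}

#' Cosine-kernel coefficients for one cell
#'
#' The heuristic weights used throughout velocity analyses to project vectors
#' onto graphs and embeddings: the coefficient for neighbor j is the cosine
#' similarity between the cell's velocity and the displacement to neighbor j.
#' The weights carry reliable direction information but no magnitude. Raw
#' (signed, unnormalized) cosines are returned; only their direction as a
#' vector over neighbors enters the projection loss, so monotone rescalings
#' are irrelevant.
#'
#' @param v velocity vector of the cell.
#' @param basis k x d matrix whose rows are the displacements delta_ij.
#' @return length-k numeric vector of cosines; entries are 0 for zero-norm
#'   displacements or a zero velocity.
#' @export
cosineKernelCoefficients <- function(v, basis) {
    basis <- as.matrix(basis)
    norms <- sqrt(rowSums(basis^2))
    if (all(norms == 0))
        stop("degenerate basis: all displacement vectors have zero norm")
    .cosineCoefs(v, basis, norms)
}

## internal, no degenerate-basis error (duplicate cells are tolerated here)
.cosineCoefs <- function(v, basis, norms = sqrt(rowSums(basis^2))) {
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(numeric(nrow(basis)))
    phi <- as.vector(basis %*% v) / (nv * pmax(norms, .Machine$double.xmin))
    phi[norms == 0] <- 0
    phi
}

#' Tangent-space-projection loss for one cell
#'
#' Evaluates `||v - t(basis) %*% phi||^2 - b * cos(phi, phiCorr) +
#' lam * ||phi||^2`. The cosine term is defined as 0 when either argument has
#' zero norm.
#'
#' @param phi length-k coefficient vector.
#' @param v velocity vector (length d).
#' @param basis k x d matrix of displacements.
#' @param phiCorr length-k cosine-kernel coefficient vector.
#' @param cfg a [TSPConfig-class].
#' @param ... ignored (allows precomputed solver quantities to pass through).
#' @return scalar loss value.
#' @export
tspLoss <- function(phi, v, basis, phiCorr, cfg = tspConfig(), ...) {
    r <- v - as.vector(crossprod(basis, phi))
    sum(r^2) - cfg@b * .safeCos(phi, phiCorr) + cfg@lam * sum(phi^2)
}

## analytic gradient of the per-cell loss
.tspGrad <- function(phi, v, basis, phiCorr, b, lam, BBt, Bv, ...) {
    g <- 2 * (as.vector(BBt %*% phi) - Bv) + 2 * lam * phi
    if (b != 0) {
        np <- sqrt(sum(phi^2)); nc <- sqrt(sum(phiCorr^2))
        if (np > 1e-300 && nc > 0) {
            g <- g - b * (phiCorr / (np * nc) -
                          sum(phi * phiCorr) * phi / (np^3 * nc))
        }
    }
    g
}

## ridge / minimum-norm least-squares initialization.
## basis: k x d (rows delta); returns phi minimizing ||v - t(basis) phi||^2
## + lam ||phi||^2 (min-norm solution via the pseudoinverse when lam == 0).
.ridgeSolve <- function(basis, v, lam) {
    k <- nrow(basis)
    if (lam > 0) {
        A <- tcrossprod(basis) + diag(lam, k)
        return(as.vector(solve(A, basis %*% v)))
    }
    sv <- svd(basis)                      # basis = U D V'
    dpos <- sv$d > max(dim(basis)) * .Machine$double.eps * max(sv$d, 0)
    dinv <- ifelse(dpos, 1 / sv$d, 0)
    as.vector(sv$u %*% (dinv * as.vector(crossprod(sv$v, v))))
}

#' Project velocities onto the manifold tangent space
#'
#' Minimizes the TSP loss independently for every cell (quasi-Newton with
#' analytic gradients, initialized at the ridge least-squares solution) and
#' returns both the fitted coefficients and the projected velocity field
#' `v||_i = sum_j phi_ij delta_ij`. Zero-velocity cells are skipped and get
#' `phi = 0`, `v|| = 0`. The returned loss never exceeds the loss at the
#' initialization point (the initializer is kept when the line search cannot
#' improve on it).
#'
#' @param states a [CellStateSet-class]; its representation defines the
#'   displacement basis.
#' @param vel a [VelocityField-class] aligned with `states`.
#' @param graph a [NeighborGraph-class] over the same cells.
#' @param cfg a [TSPConfig-class]; see [tspConfig()] for the defaults.
#' @return list with elements `phi` (a [TangentCoefficients-class]) and
#'   `velocity` (the projected [VelocityField-class]).
#' @examples
#' traj <- simulateToggleSwitch(nCells = 100, seed = 1)
#' g <- buildKnnGraph(trajStates(traj), k = 10)
#' fit <- tspProject(trajStates(traj), trajVelocity(traj), g)
#' fit$phi
#' @export
tspProject <- function(states, vel, graph, cfg = tspConfig()) {
    stopifnot(is(states, "CellStateSet"), is(vel, "VelocityField"),
              is(graph, "NeighborGraph"))
    validObject(cfg)
    .checkCells(states, graph, "states and graph")
    V <- vel@values
    if (!all(dim(V) == dim(states@values)))
        stop("alignment error: velocity shape does not match states")
    if (any(!is.finite(V)))
        stop("input error: velocity contains non-finite entries")
    delta <- displacements(states, graph)
    n <- nrow(V); k <- graph@k
    phi <- matrix(0, n, k)
    conv <- rep(TRUE, n)
    lossFinal <- numeric(n)
    lossInit <- numeric(n)
    b <- cfg@b; lam <- cfg@lam
    for (i in seq_len(n)) {
        v <- V[i, ]
        if (all(v == 0)) next
        B <- matrix(delta[i, , ], nrow = k)       # k x d
        norms <- sqrt(rowSums(B^2))
        if (all(norms == 0)) next                 # duplicate-collapsed cell
        pc <- .cosineCoefs(v, B, norms)
        p0 <- .ridgeSolve(B, v, lam)
        BBt <- tcrossprod(B)
        Bv <- as.vector(B %*% v)
        f0 <- tspLoss(p0, v, B, pc, cfg)
        lossInit[i] <- f0
        if (b == 0) {                             # quadratic: init is optimal
            phi[i, ] <- p0
            lossFinal[i] <- f0
        } else {
            fit <- tryCatch(
                optim(p0, fn = tspLoss, gr = .tspGrad,
                      v = v, basis = B, phiCorr = pc, cfg = cfg,
                      b = b, lam = lam, BBt = BBt, Bv = Bv,
                      method = "BFGS",
                      control = list(maxit = cfg@maxIter, reltol = cfg@tol)),
                error = function(e) NULL)
            if (is.null(fit) || fit$value > f0) { # keep the initializer
                phi[i, ] <- p0
                lossFinal[i] <- f0
                conv[i] <- !is.null(fit)
            } else {
                phi[i, ] <- fit$par
                lossFinal[i] <- fit$value
                conv[i] <- fit$convergence == 0L
            }
        }
    }
    ## reconstruct v|| through the same accumulation used by
    ## transformVelocity, so transforming to the source representation is
    ## bit-identical
    vpar <- .phiTimesDelta(phi, delta, dimnames(V))
    if (any(!conv))
        warning(sum(!conv), " cells did not reach the gradient tolerance; ",
                "best iterate returned (flagged in the converged slot)")
    tc <- new("TangentCoefficients", phi = phi, k = as.integer(k),
              representation = states@representation,
              cellIds = rownames(states@values),
              converged = conv, loss = lossFinal, initLoss = lossInit)
    list(phi = tc, velocity = VelocityField(vpar, states@representation))
}

#' Cosine-kernel baseline projection
#'
#' The heuristic the TSP loss is benchmarked against: each cell's velocity is
#' replaced by the cosine-weighted sum of neighbor displacements. With
#' `normalize = TRUE` (default) the result is scaled to unit norm per cell —
#' the direction-only behavior of transition-kernel projections, which
#' discards all magnitude information.
#'
#' @param states a [CellStateSet-class].
#' @param vel a [VelocityField-class].
#' @param graph a [NeighborGraph-class].
#' @param normalize scale each projected vector to unit norm.
#' @return a [VelocityField-class].
#' @export
cosineKernelProject <- function(states, vel, graph, normalize = TRUE) {
    .checkCells(states, graph, "states and graph")
    delta <- displacements(states, graph)
    V <- vel@values
    n <- nrow(V); k <- graph@k
    out <- matrix(0, n, ncol(V), dimnames = dimnames(V))
    for (i in seq_len(n)) {
        B <- matrix(delta[i, , ], nrow = k)
        pc <- .cosineCoefs(V[i, ], B)
        out[i, ] <- as.vector(crossprod(B, pc))
        if (normalize) {
            nrm <- sqrt(sum(out[i, ]^2))
            if (nrm > 0) out[i, ] <- out[i, ] / nrm
        }
    }
    VelocityField(out, states@representation)
}
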