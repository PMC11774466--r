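# Continuous vector-field learning: ridge-regularized expansion in Gaussian
# bases (RKHS), with analytic Jacobians, acceleration, and dose-response
# integration over Jacobian elements.
#
# v(x) = sum_a Gamma(x, center_a) c_a,  Gamma(x, c) = exp(-w ||x - c||^2 / 2).
# The coefficients minimize
#   Phi(C) = sum_i ||v_i - K_i. C||^2 + (lambda/2) tr(C' Ktilde C),
# solved in closed form by (K'K + (lambda/2) Ktilde) C = K'V.

## kernel matrix between rows of X and rows of centers
.rkhsKernel <- function(X, centers, w) {
    d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * tcrossprod(X, centers)
    d2[d2 < 0] <- 0
    exp(-w * d2 / 2)
}

#' Fit a continuous vector field in a Gaussian RKHS
#'
#' Learns a smooth velocity function from `(state, velocity)` pairs as a
#' linear combination of Gaussian basis functions centered at reference
#' points chosen by uniform random subsampling (all cells when `nCenters`
#' reaches the cell count). The coefficients solve the regularized normal
#' equations in closed form. The default bandwidth follows the median
#' heuristic `w = 1 / median(pairwise distance)^2`.
#'
#' @param states a [CellStateSet-class].
#' @param vel the matching [VelocityField-class].
#' @param nCenters number of basis centers (default: min(500, cells)).
#' @param w kernel bandwidth; NULL picks the median heuristic.
#' @param lambda Tikhonov regularization weight (default 1e-5).
#' @param seed RNG seed for center subsampling.
#' @return an [RKHSField-class].
#' @export
fitRKHSField <- function(states, vel, nCenters = NULL, w = NULL,
                         lambda = 1e-5, seed = 0L) {
    X <- states@values; V <- vel@values
    if (!all(dim(V) == dim(X)))
        stop("alignment error: velocity shape does not match states")
    n <- nrow(X)
    if (is.null(nCenters)) nCenters <- min(500L, n)
    if (nCenters > n) nCenters <- n
    set.seed(seed)
    centers <- if (nCenters >= n) X else
        X[sort(sample.int(n, nCenters)), , drop = FALSE]
    if (is.null(w)) {
        sub <- X[sample.int(n, min(n, 300L)), , drop = FALSE]
        pd <- dist(sub)
        mz <- median(pd[pd > 0])
        w <- 1 / mz^2
    }
    K <- .rkhsKernel(X, centers, w)
    Kt <- .rkhsKernel(centers, centers, w)
    if (nCenters >= n) {
        ## centers == data: the stationarity condition K(2KC - 2V + lam C)=0
        ## reduces to (K + lam/2 I) C = V, much better conditioned than the
        ## squared normal equations
        A <- K + diag(lambda / 2, n)
        C <- tryCatch(solve(A, V), error = function(e) {
            warning("singular RKHS system; applying jitter ridge 1e-10")
            solve(A + diag(1e-10, n), V)
        })
    } else {
        A <- crossprod(K) + (lambda / 2) * Kt
        C <- tryCatch(solve(A, crossprod(K, V)), error = function(e) {
            warning("singular RKHS system; applying jitter ridge 1e-10")
            solve(A + diag(1e-10, nrow(A)), crossprod(K, V))
        })
    }
    rownames(C) <- NULL
    new("RKHSField", centers = unname(centers), coefficients = as.matrix(C),
        w = w, lambda = lambda,
        featureIds = colnames(X) %||% paste0("f", seq_len(ncol(X))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an RKHS vector field
#'
#' @param field an [RKHSField-class].
#' @param X matrix of points (rows) or a single point vector.
#' @return matrix of field values, one row per point.
#' @export
evaluateField <- function(field, X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    K <- .rkhsKernel(as.matrix(X), field@centers, field@w)
    out <- K %*% field@coefficients
    colnames(out) <- field@featureIds
    out
}

#' Analytic Jacobian of an RKHS field at a point
#'
#' The gradient of the Gaussian-basis expansion:
#' `J(x) = -w * sum_a Gamma_a(x) c_a (x - center_a)'`, an
#' output-by-input matrix whose element (e, r) is the sensitivity of the
#' effector-e velocity to the regulator-r level — the substrate of gene
#' regulatory inference on the fitted field.
#'
#' @param field an [RKHSField-class].
#' @param x a single point (numeric vector).
#' @return d_out x d_in Jacobian matrix.
#' @export
fieldJacobian <- function(field, x) {
    x <- as.numeric(x)
    diffs <- sweep(field@centers, 2L, x, "-")        # m x d (center - x)
    g <- exp(-field@w * rowSums(diffs^2) / 2)        # Gamma_a(x)
    ## J = -w sum_a g_a c_a (x - center_a)' = w * t(C) %*% (g * diffs)
    J <- field@w * crossprod(field@coefficients, g * diffs)
    dimnames(J) <- list(field@featureIds, field@featureIds)
    J
}

#' Acceleration of an RKHS field at a point
#'
#' The time derivative of the velocity along the flow,
#' `a(x) = J(x) v(x)`.
#'
#' @param field an [RKHSField-class].
#' @param x a single point.
#' @return numeric acceleration vector.
#' @export
fieldAcceleration <- function(field, x) {
    as.vector(fieldJacobian(field, x) %*% t(evaluateField(field, x)))
}

#' Effective dose-response curve from Jacobian elements
#'
#' Integrates the Jacobian element d(effector velocity)/d(regulator) over the
#' regulator axis: cells are binned by min-max-normalized regulator level on
#' a 100-point grid, the mean Jacobian element per bin is computed (empty
#' bins filled by linear interpolation), and the cumulative trapezoidal
#' integral — anchored at 0 at the lowest bin — is returned. For a constant
#' element c the curve is a straight line of slope c; saturating regulation
#' produces a saturating curve.
#'
#' @param field an [RKHSField-class] fitted in the representation containing
#'   both features.
#' @param regulator,effector feature ids (or indices) in the field.
#' @param states the [CellStateSet-class] used for the fit (supplies the
#'   evaluation points and regulator levels).
#' @param nGrid grid resolution (default 100).
#' @return list with `grid` (normalized regulator levels), `response`
#'   (integrated curve), `meanElement` (per-bin mean Jacobian element).
#' @export
doseResponse <- function(field, regulator, effector, states, nGrid = 100L) {
    X <- states@values
    rIdx <- if (is.character(regulator)) match(regulator, field@featureIds)
            else as.integer(regulator)
    eIdx <- if (is.character(effector)) match(effector, field@featureIds)
            else as.integer(effector)
    if (is.na(rIdx) || is.na(eIdx))
        stop("unknown regulator/effector feature")
    lev <- X[, rIdx]
    if (diff(range(lev)) == 0)
        stop("degenerate input: regulator expression is constant")
    norm <- .minmax(lev)
    elem <- vapply(seq_len(nrow(X)),
                   function(i) fieldJacobian(field, X[i, ])[eIdx, rIdx],
                   numeric(1L))
    grid <- seq(0, 1, length.out = nGrid)
    bin <- pmin(pmax(round(norm * (nGrid - 1L)) + 1L, 1L), nGrid)
    meanElem <- vapply(seq_len(nGrid), function(bn) {
        v <- elem[bin == bn]
        if (length(v)) mean(v) else NA_real_
    }, numeric(1L))
    if (anyNA(meanElem)) {
        filled <- which(!is.na(meanElem))
        meanElem <- approx(grid[filled], meanElem[filled], xout = grid,
                           rule = 2L)$y
    }
    h <- diff(grid)
    resp <- c(0, cumsum(h * (meanElem[-1L] + meanElem[-nGrid]) / 2))
    list(grid = grid, response = resp, meanElement = meanElem)
}
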