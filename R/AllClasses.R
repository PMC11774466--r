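#' @import methods
#' @importFrom stats median sd cor quantile rnorm runif setNames approx prcomp
#'   kmeans dist optim rexp
#' @importFrom utils read.csv write.csv read.delim head tail
NULL

#' Cell-state matrix for one representation
#'
#' A cells-by-features matrix of real values (expression, chromatin
#' accessibility, or embedding coordinates) together with cell and feature
#' identifiers and a tag naming the representation the values live in
#' (e.g. `"genes"`, `"pca"`, `"atac"`, `"joint"`).
#'
#' @slot values numeric matrix, cells in rows, features in columns, with
#'   complete dimnames.
#' @slot representation single string tagging the representation.
#' @export
setClass("CellStateSet",
    representation(values = "matrix", representation = "character"))

setValidity("CellStateSet", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "values must carry cell (row) and feature (column) names")
    if (anyNA(v) || any(!is.finite(v)))
        msg <- c(msg, "values contain missing or non-finite entries")
    if (length(object@representation) != 1L)
        msg <- c(msg, "representation must be a single tag")
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate cell ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate feature ids")
    if (length(msg)) msg else TRUE
})

#' Velocity matrix paired with a CellStateSet
#'
#' Time derivatives of the paired state matrix, aligned cell-for-cell and
#' feature-for-feature; same units per unit time as the states.
#'
#' @slot values numeric matrix, cells in rows, features in columns.
#' @slot representation tag of the paired representation.
#' @export
setClass("VelocityField",
    representation(values = "matrix", representation = "character"))

setValidity("VelocityField", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
    if (anyNA(v) || any(!is.finite(v)))
        msg <- c(msg, "velocity contains missing or non-finite entries")
    if (length(object@representation) != 1L)
        msg <- c(msg, "representation must be a single tag")
    if (length(msg)) msg else TRUE
})

#' k-nearest-neighbor graph over cells
#'
#' Per-cell neighbor indices and distances defining the discrete manifold.
#' Self-neighbors are excluded and per-cell distances are sorted ascending.
#'
#' @slot k number of neighbors per cell.
#' @slot indices integer matrix (cells x k) of neighbor cell positions.
#' @slot distances numeric matrix (cells x k), nonnegative, row-sorted.
#' @slot metric distance metric tag.
#' @slot builtOn representation tag the graph was built on.
#' @slot cellIds cell identifiers, in matrix row order.
#' @export
setClass("NeighborGraph",
    representation(k = "integer", indices = "matrix", distances = "matrix",
        metric = "character", builtOn = "character", cellIds = "character"))

setValidity("NeighborGraph", function(object) {
    msg <- character()
    n <- length(object@cellIds)
    idx <- object@indices
    d <- object@distances
    if (!all(dim(idx) == c(n, object@k)) || !all(dim(d) == c(n, object@k)))
        msg <- c(msg, "indices/distances must be cells x k")
    else {
        if (any(idx < 1L) || any(idx > n)) msg <- c(msg, "neighbor index out of range")
        if (any(idx == seq_len(n))) msg <- c(msg, "a cell is its own neighbor")
        if (any(d < 0)) msg <- c(msg, "negative distances")
        if (object@k > 1L && any(d[, -1L, drop = FALSE] <
                d[, -object@k, drop = FALSE] - 1e-12))
            msg <- c(msg, "distances not sorted ascending per cell")
    }
    if (length(msg)) msg else TRUE
})

#' Per-cell tangent-space coefficients over graph neighbors
#'
#' The transferable object of the method: for each cell a length-k vector of
#' coefficients over the displacements to its neighbors, such that the
#' tangent-projected velocity is the coefficient-weighted sum of
#' displacements. Because the same cells exist in every representation, the
#' coefficients move velocities between representations.
#'
#' @slot phi numeric matrix (cells x k) of coefficients.
#' @slot k neighbors per cell (matches the fitting graph).
#' @slot representation representation the fit was performed in.
#' @slot cellIds cell identifiers.
#' @slot converged logical per cell; FALSE marks solver non-convergence.
#' @slot loss final per-cell loss values.
#' @slot initLoss per-cell loss at the initialization point.
#' @export
setClass("TangentCoefficients",
    representation(phi = "matrix", k = "integer", representation = "character",
        cellIds = "character", converged = "logical", loss = "numeric",
        initLoss = "numeric"))

setValidity("TangentCoefficients", function(object) {
    msg <- character()
    if (ncol(object@phi) != object@k) msg <- c(msg, "phi must have k columns")
    if (nrow(object@phi) != length(object@cellIds))
        msg <- c(msg, "phi rows must match cellIds")
    if (any(!is.finite(object@phi))) msg <- c(msg, "non-finite coefficients")
    if (length(msg)) msg else TRUE
})

#' Configuration of the tangent-space-projection solver
#'
#' @slot b nonnegative direction-retention weight on the cosine term.
#' @slot lam nonnegative L2 regularization weight.
#' @slot solver solver tag ("bfgs").
#' @slot maxIter iteration cap per cell.
#' @slot tol gradient tolerance.
#' @slot init initialization tag ("ridge").
#' @export
setClass("TSPConfig",
    representation(b = "numeric", lam = "numeric", solver = "character",
        maxIter = "integer", tol = "numeric", init = "character"))

setValidity("TSPConfig", function(object) {
    msg <- character()
    if (object@b < 0) msg <- c(msg, "b must be >= 0")
    if (object@lam < 0) msg <- c(msg, "lam must be >= 0")
    if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
    if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Manifold-consistency (MacK) scores
#'
#' @slot scores per-gene score in `[0, 1]`, named by gene.
#' @slot perCell optional cells x genes matrix of per-cell agreement
#'   fractions (NA where a cell abstained on all pairs).
#' @slot nEvaluated number of neighbor pairs evaluated per gene.
#' @export
setClass("MacKResult",
    representation(scores = "numeric", perCell = "matrix",
        nEvaluated = "integer"))

setValidity("MacKResult", function(object) {
    s <- object@scores
    if (any(s < -1e-12 | s > 1 + 1e-12, na.rm = TRUE))
        "scores must lie in [0, 1]" else TRUE
})

#' Ground-truth synthetic trajectory
#'
#' States, exact model-drift velocities, sample times, optional branch/phase
#' labels, auxiliary layers (e.g. nascent counts), and an echo of the
#' generating parameters.
#'
#' @slot states a [CellStateSet-class].
#' @slot velocity the exact drift at each sampled state, as a
#'   [VelocityField-class].
#' @slot times per-cell sample time.
#' @slot labels per-cell branch/phase tag (may be empty).
#' @slot layers named list of auxiliary cells x features matrices.
#' @slot params generating parameters.
#' @export
setClass("SimulationTrajectory",
    representation(states = "CellStateSet", velocity = "VelocityField",
        times = "numeric", labels = "character", layers = "list",
        params = "list"))

setValidity("SimulationTrajectory", function(object) {
    msg <- character()
    n <- nrow(object@states@values)
    if (!all(dim(object@velocity@values) == dim(object@states@values)))
        msg <- c(msg, "velocity shape must match states")
    if (length(object@times) != n) msg <- c(msg, "times must match cell count")
    if (length(object@labels) && length(object@labels) != n)
        msg <- c(msg, "labels must be empty or match cell count")
    if (length(msg)) msg else TRUE
})

#' Continuous vector field in a Gaussian RKHS expansion
#'
#' v(x) = sum_a Gamma(x, center_a) coef_a with Gaussian bases
#' Gamma(x, c) = exp(-w ||x - c||^2 / 2).
#'
#' @slot centers matrix (m x d) of basis centers.
#' @slot coefficients matrix (m x d) of coefficient vectors.
#' @slot w positive kernel bandwidth parameter.
#' @slot lambda ridge weight used in the fit.
#' @slot featureIds feature names of the fitted representation.
#' @export
setClass("RKHSField",
    representation(centers = "matrix", coefficients = "matrix", w = "numeric",
        lambda = "numeric", featureIds = "character"))

setValidity("RKHSField", function(object) {
    msg <- character()
    if (nrow(object@centers) != nrow(object@coefficients))
        msg <- c(msg, "one coefficient vector per center required")
    if (object@w <= 0) msg <- c(msg, "w must be > 0")
    if (length(msg)) msg else TRUE
})

#' Smoothed per-gene velocity trend on a fixed grid
#'
#' @slot grid strictly increasing axis values (default length 100) spanning
#'   the observed axis range.
#' @slot fitted predicted trend values on the grid.
#' @slot gene gene identifier.
#' @slot axisTag name of the ordering axis.
#' @export
setClass("VelocityTrend",
    representation(grid = "numeric", fitted = "numeric", gene = "character",
        axisTag = "character"))

setValidity("VelocityTrend", function(object) {
    msg <- character()
    if (length(object@grid) != length(object@fitted))
        msg <- c(msg, "grid and fitted must have equal length")
    if (length(object@grid) > 1L && any(diff(object@grid) <= 0))
        msg <- c(msg, "grid must be strictly increasing")
    if (length(msg)) msg else TRUE
})
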