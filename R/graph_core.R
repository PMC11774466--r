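# Neighbor-graph construction, displacement bases, and neighborhood smoothing.

## internal: check that two containers describe the same cells
.checkCells <- function(a, b, what = "inputs") {
    na <- if (is(a, "NeighborGraph")) length(a@cellIds) else nrow(a@values)
    nb <- if (is(b, "NeighborGraph")) length(b@cellIds) else nrow(b@values)
    if (na != nb)
        stop("alignment error: ", what, " describe different numbers of cells (",
             na, " vs ", nb, ")")
    invisible(TRUE)
}

## internal: pairwise Euclidean distances between rows of X and rows of Y
.euclidean <- function(X, Y) {
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
    d2[d2 < 0] <- 0
    sqrt(d2)
}

#' Build a k-nearest-neighbor graph over cells
#'
#' Exact brute-force kNN on the supplied representation. The graph defines the
#' discrete approximation of the cell-state manifold: the displacements to a
#' cell's neighbors span its local tangent space. Ties in distance are broken
#' by ascending cell index for reproducibility; a cell is never its own
#' neighbor.
#'
#' @param states a [CellStateSet-class]; distances are computed on its values
#'   (typically a PCA/LSI embedding or the gene space).
#' @param k number of neighbors, `2 <= k < nCells`. The default 30 matches the
#'   usual choice for single-modality single-cell graphs.
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @return a [NeighborGraph-class] with exactly `k` neighbors per cell.
#' @examples
#' s <- CellStateSet(matrix(rnorm(40), 20, 2), representation = "pca")
#' g <- buildKnnGraph(s, k = 5)
#' graphK(g)
#' @export
buildKnnGraph <- function(states, k = 30L, metric = "euclidean") {
    stopifnot(is(states, "CellStateSet"))
    metric <- match.arg(metric, "euclidean")
    X <- states@values
    n <- nrow(X)
    k <- as.integer(k)
    if (k < 1L || k >= n)
        stop("parameter error: k must satisfy 1 <= k < number of cells (",
             n, "), got ", k)
    idx <- matrix(0L, n, k)
    dst <- matrix(0, n, k)
    block <- max(1L, floor(2e6 / n))
    for (start in seq(1L, n, by = block)) {
        rows <- start:min(start + block - 1L, n)
        D <- .euclidean(X[rows, , drop = FALSE], X)
        for (ii in seq_along(rows)) {
            i <- rows[ii]
            d <- D[ii, ]
            d[i] <- Inf                       # exclude self
            o <- order(d)[seq_len(k)]         # stable: ties -> lower index
            idx[i, ] <- o
            dst[i, ] <- d[o]
        }
    }
    NeighborGraph(idx, dst, cellIds = rownames(X), metric = metric,
                  builtOn = states@representation)
}

#' Displacement vectors to graph neighbors
#'
#' For every cell i and neighbor j, the displacement
#' `delta_ij = x_j - x_i` computed in the representation of `states` (which
#' may differ from the representation the graph was built on). These
#' displacements form a complete, possibly redundant basis of the local
#' tangent space.
#'
#' @param states a [CellStateSet-class] supplying the coordinates.
#' @param graph a [NeighborGraph-class] over the same cells.
#' @return numeric array with dimensions (cells, k, features).
#' @export
displacements <- function(states, graph) {
    stopifnot(is(states, "CellStateSet"), is(graph, "NeighborGraph"))
    .checkCells(states, graph, "states and graph")
    X <- states@values
    n <- nrow(X); k <- graph@k; d <- ncol(X)
    idx <- graph@indices
    ## X[idx, ] stacks neighbor coordinates for (cell, neighbor) pairs
    delta <- array(X[as.vector(idx), , drop = FALSE] -
                   X[rep(seq_len(n), times = k), , drop = FALSE],
                   dim = c(n, k, d))
    dimnames(delta) <- list(rownames(X), NULL, colnames(X))
    delta
}

## shared reconstruction path: v_i = sum_j phi_ij delta_ij, accumulated
## neighbor-by-neighbor so projection, transformation and extension are
## bit-identical on identical coordinates
.phiTimesDelta <- function(phi, delta, dimNames) {
    n <- dim(delta)[1L]; k <- dim(delta)[2L]; d <- dim(delta)[3L]
    out <- matrix(0, n, d, dimnames = dimNames)
    for (j in seq_len(k))
        out <- out + phi[, j] * matrix(delta[, j, ], nrow = n)
    out
}

#' Neighborhood-average smoothing of a velocity field
#'
#' Replaces each cell's velocity with the mean over its graph neighborhood,
#' the numerical analogue of ensemble-averaging stochastic velocities over
#' nearby states. The mean is self-inclusive: cell i contributes its own
#' vector alongside its k neighbors.
#'
#' @param vel a [VelocityField-class].
#' @param graph a [NeighborGraph-class] over the same cells.
#' @return a smoothed [VelocityField-class].
#' @export
smoothVelocity <- function(vel, graph) {
    stopifnot(is(vel, "VelocityField"), is(graph, "NeighborGraph"))
    .checkCells(vel, graph, "velocity and graph")
    V <- vel@values
    n <- nrow(V); k <- graph@k
    out <- V
    idx <- graph@indices
    for (j in seq_len(k)) out <- out + V[idx[, j], , drop = FALSE]
    VelocityField(out / (k + 1), vel@representation)
}
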