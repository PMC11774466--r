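# Smooth per-gene velocity trends along an ordering axis, cluster the
# trends, and quantify cross-modality decoupling with dynamic time warping.

#' Fit a smooth velocity trend along an axis
#'
#' Models a gene's per-cell velocity as `v = b0 + f(t)` with f a penalized
#' B-spline smooth (basis dimension 10, smoothing parameter by generalized
#' cross-validation) and evaluates the fit on `nGrid` equally spaced points
#' spanning the observed axis range. The smoothed trend is the time series
#' used by trend clustering and decoupling analysis.
#'
#' @param axis per-cell ordering values (pseudotime, viral fraction, ...).
#' @param v per-cell velocity values of one gene.
#' @param nGrid number of grid points (default 100).
#' @param gene gene id stored in the result.
#' @param axisTag name of the axis stored in the result.
#' @param basisDim B-spline basis dimension (default 10).
#' @return a [VelocityTrend-class].
#' @export
fitVelocityTrend <- function(axis, v, nGrid = 100L, gene = "gene",
                             axisTag = "t", basisDim = 10L) {
    if (length(axis) != length(v))
        stop("alignment error: axis and velocity lengths differ")
    if (length(v) < 20L) stop("need at least 20 cells to fit a trend")
    if (any(!is.finite(axis))) stop("axis contains non-finite values")
    if (diff(range(axis)) == 0) stop("degenerate axis: all values equal")
    grid <- seq(min(axis), max(axis), length.out = nGrid)
    if (sd(v) == 0) {                      # intercept-only limit
        return(new("VelocityTrend", grid = grid,
                   fitted = rep(v[1L], nGrid), gene = gene, axisTag = axisTag))
    }
    df <- data.frame(t = axis, y = v)
    fit <- mgcv::gam(y ~ s(t, bs = "ps", k = basisDim), data = df,
                     method = "GCV.Cp")
    pred <- as.vector(mgcv::predict.gam(fit, newdata = data.frame(t = grid)))
    new("VelocityTrend", grid = grid, fitted = pred, gene = gene,
        axisTag = axisTag)
}

#' Fit trends for all columns of a velocity matrix
#'
#' @param axis per-cell ordering values.
#' @param vel a [VelocityField-class] or cells x genes matrix.
#' @param nGrid,axisTag,basisDim see [fitVelocityTrend()].
#' @return named list of [VelocityTrend-class] objects, one per gene.
#' @export
fitVelocityTrends <- function(axis, vel, nGrid = 100L, axisTag = "t",
                              basisDim = 10L) {
    V <- if (is(vel, "VelocityField")) vel@values else as.matrix(vel)
    genes <- colnames(V)
    if (is.null(genes)) genes <- paste0("gene_", seq_len(ncol(V)))
    out <- lapply(seq_len(ncol(V)), function(g)
        fitVelocityTrend(axis, V[, g], nGrid = nGrid, gene = genes[g],
                         axisTag = axisTag, basisDim = basisDim))
    names(out) <- genes
    out
}

## stack a list of VelocityTrend into a genes x grid matrix
.trendMatrix <- function(trends) {
    stopifnot(length(trends) >= 1L)
    L <- lengths(lapply(trends, trendValues))
    if (length(unique(L)) != 1L)
        stop("alignment error: trends evaluated on grids of different length")
    M <- do.call(rbind, lapply(trends, trendValues))
    rownames(M) <- vapply(trends, function(tr) tr@gene, character(1L))
    M
}

#' Cluster smoothed velocity trends
#'
#' Builds a kNN graph (Euclidean distance between fitted grid vectors) over
#' genes and partitions it with the Leiden algorithm (modularity objective)
#' at the given resolution, then summarizes each cluster by its pointwise
#' mean and standard deviation on the grid. Defaults (k = 15, resolution
#' 0.3) are deliberately coarse to avoid over-clustering trends.
#'
#' @param trends list of [VelocityTrend-class] objects on a common grid.
#' @param k neighbors for the gene-gene kNN graph.
#' @param resolution Leiden resolution parameter.
#' @param seed RNG seed (Leiden refinement is stochastic).
#' @return list with `labels` (named integer cluster per gene), `means` and
#'   `sds` (cluster x grid matrices), `grid`.
#' @export
clusterTrends <- function(trends, k = 15L, resolution = 0.3, seed = 0L) {
    M <- .trendMatrix(trends)
    nGenes <- nrow(M)
    if (nGenes < k + 1L)
        stop("parameter error: need at least k + 1 = ", k + 1L,
             " genes, got ", nGenes)
    D <- .euclidean(M, M)
    edges <- NULL
    for (i in seq_len(nGenes)) {
        d <- D[i, ]; d[i] <- Inf
        nb <- order(d)[seq_len(k)]
        edges <- rbind(edges, cbind(i, nb))
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5L)
    labels <- setNames(igraph::membership(cl), rownames(M))
    grid <- trendGrid(trends[[1L]])
    uq <- sort(unique(labels))
    means <- t(vapply(uq, function(cc)
        colMeans(M[labels == cc, , drop = FALSE]), numeric(ncol(M))))
    sds <- t(vapply(uq, function(cc)
        apply(M[labels == cc, , drop = FALSE], 2L, sd), numeric(ncol(M))))
    rownames(means) <- rownames(sds) <- paste0("cluster_", uq)
    list(labels = labels, means = means, sds = sds, grid = grid)
}

#' Dynamic-time-warping distance between two series
#'
#' Classic unconstrained symmetric DTW recursion with squared pointwise
#' costs; the returned distance is the square root of the accumulated cost
#' along the optimal alignment path (zero iff the series are identical).
#'
#' @param a,b numeric vectors.
#' @return nonnegative scalar distance.
#' @export
dtwDistance <- function(a, b) {
    n <- length(a); m <- length(b)
    prev <- c(0, rep(Inf, m))
    for (i in seq_len(n)) {
        cur <- rep(Inf, m + 1L)
        cost <- (a[i] - b)^2
        for (j in seq_len(m)) {
            cur[j + 1L] <- cost[j] + min(prev[j], prev[j + 1L], cur[j])
        }
        prev <- cur
    }
    sqrt(prev[m + 1L])
}

## min-max normalization to [0, 1]; constant series map to all zeros
.minmax <- function(x) {
    r <- range(x)
    if (r[2L] - r[1L] == 0) return(rep(0, length(x)))
    (x - r[1L]) / (r[2L] - r[1L])
}

#' Elbow of a ranked curve
#'
#' Index of the point with maximum perpendicular distance to the chord
#' joining the first and last points of the sorted curve — the standard
#' knee heuristic.
#'
#' @param y numeric vector, sorted (ascending or descending).
#' @return integer index of the elbow.
#' @export
findElbow <- function(y) {
    n <- length(y)
    if (n < 3L) return(n)
    x <- seq_len(n)
    chord <- c(n - 1, y[n] - y[1L])
    chord <- chord / sqrt(sum(chord^2))
    dx <- x - 1; dy <- y - y[1L]
    perp <- abs(dx * chord[2L] - dy * chord[1L])
    which.max(perp)
}

#' Decoupling analysis of paired trends via dynamic time warping
#'
#' For each gene, min-max normalizes the two modality trends (e.g. RNA
#' velocity vs chromatin velocity) to `[0, 1]`, computes the DTW distance,
#' ranks genes by distance ascending, finds the elbow of the ranked curve,
#' and flags genes beyond the elbow as decoupled — loci whose transcription
#' and chromatin dynamics follow different temporal programs.
#'
#' @param trendsA,trendsB named lists of [VelocityTrend-class] objects over
#'   the same genes on grids of equal length.
#' @return list with `distance` (named, per gene), `ranked` (gene ids,
#'   ascending distance), `elbow` (index into `ranked`), `decoupled`
#'   (gene ids past the elbow).
#' @export
dtwDecoupling <- function(trendsA, trendsB) {
    MA <- .trendMatrix(trendsA)
    MB <- .trendMatrix(trendsB)
    if (!identical(sort(rownames(MA)), sort(rownames(MB))))
        stop("alignment error: trend lists cover different gene sets")
    MB <- MB[rownames(MA), , drop = FALSE]
    if (ncol(MA) != ncol(MB))
        stop("alignment error: grids differ in length")
    d <- vapply(seq_len(nrow(MA)), function(g)
        dtwDistance(.minmax(MA[g, ]), .minmax(MB[g, ])), numeric(1L))
    names(d) <- rownames(MA)
    ord <- order(d, names(d))
    ranked <- names(d)[ord]
    elbow <- findElbow(d[ord])
    list(distance = d, ranked = ranked, elbow = elbow,
         decoupled = if (elbow < length(ranked))
             ranked[(elbow + 1L):length(ranked)] else character())
}
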