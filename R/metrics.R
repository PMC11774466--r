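# Evaluation metrics for velocity fields: direction (cosine), magnitude
# (RMSE), sign (accuracy), per-cell speed, and cross-boundary correctness.

#' Compare an estimated velocity field against ground truth
#'
#' Computes three complementary metrics: per-cell cosine similarity of the
#' full vectors (direction), root-mean-square error over all matrix entries
#' (magnitude; a per-cell norm RMSE is also reported), and entrywise sign
#' accuracy (exact zeros match only zeros; an optional deadband treats small
#' magnitudes as zero). Cells where either vector has zero norm are excluded
#' from the cosine summary, with the count reported.
#'
#' @param est,true aligned [VelocityField-class] objects (or numeric
#'   matrices).
#' @param deadband entries with `|v| < deadband` are treated as zeros for the
#'   sign accuracy (default 0).
#' @return list with `cosine` (per cell), `medianCosine`, `meanCosine`,
#'   `rmse`, `perCellNormRmse`, `accuracy`, `nZeroNormExcluded`.
#' @export
evaluateVelocity <- function(est, true, deadband = 0) {
    E <- if (is(est, "VelocityField")) est@values else as.matrix(est)
    Tr <- if (is(true, "VelocityField")) true@values else as.matrix(true)
    if (!all(dim(E) == dim(Tr)))
        stop("alignment error: estimated and true velocities differ in shape")
    ne <- sqrt(rowSums(E^2)); nt <- sqrt(rowSums(Tr^2))
    ok <- ne > 0 & nt > 0
    cosine <- rep(NA_real_, nrow(E))
    cosine[ok] <- rowSums(E[ok, , drop = FALSE] * Tr[ok, , drop = FALSE]) /
                  (ne[ok] * nt[ok])
    se <- if (deadband > 0) ifelse(abs(E) < deadband, 0, sign(E)) else sign(E)
    st <- if (deadband > 0) ifelse(abs(Tr) < deadband, 0, sign(Tr)) else sign(Tr)
    list(cosine = cosine,
         medianCosine = median(cosine, na.rm = TRUE),
         meanCosine = mean(cosine, na.rm = TRUE),
         rmse = sqrt(mean((E - Tr)^2)),
         perCellNormRmse = sqrt(mean((ne - nt)^2)),
         accuracy = mean(se == st),
         nZeroNormExcluded = sum(!ok))
}

#' Per-cell speed
#'
#' L2 norm of the velocity vector per cell, optionally restricted to a
#' feature subset (e.g. viral transcripts only, to read infection speed).
#'
#' @param vel a [VelocityField-class].
#' @param features optional character vector of feature ids.
#' @return numeric vector of nonnegative speeds.
#' @export
cellSpeed <- function(vel, features = NULL) {
    V <- vel@values
    if (!is.null(features)) {
        if (length(features) == 0L)
            stop("parameter error: empty feature subset")
        missing <- setdiff(features, colnames(V))
        if (length(missing))
            stop("unknown features: ", paste(head(missing, 5), collapse = ", "))
        V <- V[, features, drop = FALSE]
    }
    sqrt(rowSums(V^2))
}

#' Cross-boundary correctness (CBC) score
#'
#' Quantifies whether cells of a source cluster, following their current
#' velocities, move toward an annotated target cluster: for every
#' source-cluster cell with at least one graph neighbor in the target
#' cluster, the mean cosine between the cell's velocity and the
#' displacements to those target-cluster neighbors. Scores lie in `[-1, 1]`;
#' negating the velocities negates the score cell by cell.
#'
#' @param states a [CellStateSet-class] (coordinates for the displacements).
#' @param vel the matching [VelocityField-class].
#' @param graph a [NeighborGraph-class].
#' @param labels per-cell cluster labels covering all cells.
#' @param pair length-2 character vector `(source, target)`.
#' @return list with `perCell` (named scores of the boundary cells) and
#'   `mean`; both empty/NaN with a warning when no boundary cells exist.
#' @export
cbcScore <- function(states, vel, graph, labels, pair) {
    .checkCells(states, graph, "states and graph")
    n <- nrow(states@values)
    if (length(labels) != n)
        stop("alignment error: labels must cover all cells")
    if (length(pair) != 2L) stop("pair must be (source, target)")
    if (!all(pair %in% labels))
        stop("pair labels not present in the annotation: ",
             paste(setdiff(pair, labels), collapse = ", "))
    idx <- neighborIndices(graph)
    X <- states@values; V <- vel@values
    src <- which(labels == pair[1L])
    scores <- numeric(0)
    for (i in src) {
        js <- idx[i, ][labels[idx[i, ]] == pair[2L]]
        if (!length(js)) next
        d <- X[js, , drop = FALSE] -
             matrix(X[i, ], length(js), ncol(X), byrow = TRUE)
        cs <- vapply(seq_len(nrow(d)),
                     function(r) .safeCos(V[i, ], d[r, ]), numeric(1L))
        scores <- c(scores, setNames(mean(cs), rownames(X)[i]))
    }
    if (!length(scores)) {
        warning("no boundary cells between '", pair[1L], "' and '", pair[2L],
                "'")
        return(list(perCell = scores, mean = NaN))
    }
    list(perCell = scores, mean = mean(scores))
}
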