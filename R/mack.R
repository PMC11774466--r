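# Manifold-consistency (MacK) scoring, gene selection, kinetic rates, and
# modality fractions.
#
# A gene's velocity is manifold-consistent when its sign agrees with the sign
# of the expression change per unit time toward each neighbor on the state
# manifold: score_g = mean over cells of the fraction of neighbor pairs with
# sgn(dx_ij^g / dt_ij) == sgn(v_i^g). Genes whose splicing-based velocity has
# the wrong sign (transcription bursts, regulated degradation) score low.

#' Per-cell transcription and degradation rates
#'
#' @slot alpha per-cell transcription rate.
#' @slot gamma per-cell degradation rate; NA where the mature abundance is
#'   below the stability floor.
#' @slot beta splicing rate constant.
#' @export
setClass("KineticRates",
    representation(alpha = "numeric", gamma = "numeric", beta = "numeric"))

setMethod("show", "KineticRates", function(object) {
    cat("KineticRates:", length(object@alpha), "cells, beta =", object@beta,
        ",", sum(is.na(object@gamma)), "gamma entries undefined\n")
})

## validate a per-cell time/pseudotime vector
.checkTime <- function(time, n) {
    if (length(time) != n)
        stop("alignment error: time vector length ", length(time),
             " does not match ", n, " cells")
    if (any(!is.finite(time))) stop("time vector contains non-finite entries")
    if (length(unique(time)) == 1L) stop("time vector is constant")
    invisible(TRUE)
}

#' Manifold-consistency (MacK) score per gene
#'
#' For every cell and graph neighbor with a nonzero time difference, compares
#' the sign of the finite-difference expression slope along the manifold with
#' the sign of the cell's velocity for that gene. Pairs where both signs are
#' zero count as matches; with the default `zeroHandling = "abstain"`, pairs
#' where exactly one sign is zero are excluded rather than penalized (flat
#' genes are not punished). Per-cell fractions are averaged (unweighted) over
#' cells into the per-gene score. Only signs of the time differences enter,
#' so the score is invariant to strictly increasing transforms of the time
#' vector.
#'
#' @param states a [CellStateSet-class] with the genes to score.
#' @param vel the matching [VelocityField-class].
#' @param time per-cell ordering values (pseudotime, latent time, lineage
#'   time, or a proxy such as viral fraction).
#' @param graph a [NeighborGraph-class] built on the state manifold (not on
#'   time).
#' @param zeroHandling `"abstain"` (default) or `"strict"` (one-sided zeros
#'   count as mismatches).
#' @return a [MacKResult-class].
#' @export
mackScore <- function(states, vel, time, graph,
                      zeroHandling = c("abstain", "strict")) {
    zeroHandling <- match.arg(zeroHandling)
    .checkCells(states, graph, "states and graph")
    X <- states@values; V <- vel@values
    if (!all(dim(V) == dim(X)))
        stop("alignment error: velocity shape does not match states")
    n <- nrow(X); G <- ncol(X)
    .checkTime(time, n)
    idx <- neighborIndices(graph)
    perCell <- matrix(NA_real_, n, G, dimnames = dimnames(X))
    nEval <- integer(G)
    anyCell <- FALSE
    for (i in seq_len(n)) {
        js <- idx[i, ]
        dtij <- time[js] - time[i]
        keep <- dtij != 0
        if (!any(keep)) next                   # cell excluded: no time signal
        anyCell <- TRUE
        dx <- X[js[keep], , drop = FALSE] -
              matrix(X[i, ], sum(keep), G, byrow = TRUE)
        slopeSign <- sign(dx) * sign(dtij[keep])          # pairs x genes
        vSign <- matrix(sign(V[i, ]), sum(keep), G, byrow = TRUE)
        match <- slopeSign == vSign
        if (zeroHandling == "abstain") {
            valid <- !(xor(slopeSign == 0, vSign == 0))   # drop one-sided 0s
        } else {
            valid <- matrix(TRUE, sum(keep), G)
        }
        nv <- colSums(valid)
        frac <- ifelse(nv > 0, colSums(match & valid) / nv, NA_real_)
        perCell[i, ] <- frac
        nEval <- nEval + nv
    }
    if (!anyCell)
        stop("degenerate input: every cell has zero time difference to all ",
             "of its neighbors")
    scores <- colMeans(perCell, na.rm = TRUE)
    names(scores) <- colnames(X)
    new("MacKResult", scores = scores, perCell = perCell,
        nEvaluated = as.integer(nEval))
}

#' Select manifold-consistent genes
#'
#' Sorts genes by MacK score descending (ties broken by gene id) and returns
#' the top `topN`, or all genes at or above `threshold`.
#'
#' @param result a [MacKResult-class].
#' @param topN number of genes to keep.
#' @param threshold minimum score to keep (used when `topN` is NULL).
#' @return character vector of gene ids, best first.
#' @export
selectMackGenes <- function(result, topN = NULL, threshold = NULL) {
    stopifnot(is(result, "MacKResult"))
    s <- result@scores
    ord <- order(-s, names(s))
    ranked <- names(s)[ord]
    if (!is.null(topN)) {
        if (topN > length(ranked)) {
            warning("topN = ", topN, " exceeds the ", length(ranked),
                    " scored genes; returning all")
            topN <- length(ranked)
        }
        return(ranked[seq_len(topN)])
    }
    if (is.null(threshold)) stop("provide topN or threshold")
    ranked[s[ord] >= threshold]
}

#' Cell-specific transcription and degradation rates
#'
#' Inverts the standard splicing kinetics per cell: with nascent abundance u,
#' mature abundance s and their velocities, `alpha_i = du_i + beta * u_i` and
#' `gamma_i = (beta * u_i - ds_i) / s_i`. Under constant-rate kinetics these
#' are constants; trends in `gamma_i` along a trajectory expose regulated
#' (e.g. microRNA-driven) degradation. `gamma` is set to NA (flagged, not
#' thrown) where `s` falls below `1e-6 * max(s)` for division stability.
#'
#' @param u,s nonnegative nascent and mature abundances (per cell).
#' @param du,ds their time derivatives.
#' @param beta splicing rate constant (default 1; the kinetics equations
#'   carry it with unit value).
#' @return a [KineticRates-class].
#' @export
cellSpecificRates <- function(u, s, du, ds, beta = 1) {
    stopifnot(length(u) == length(s), length(du) == length(u),
              length(ds) == length(u))
    if (any(u < 0) || any(s < 0)) stop("u and s must be nonnegative")
    if (any(!is.finite(du)) || any(!is.finite(ds)))
        stop("velocities must be finite")
    alpha <- du + beta * u
    floor <- 1e-6 * max(s)
    gamma <- ifelse(s > floor, (beta * u - ds) / s, NA_real_)
    new("KineticRates", alpha = alpha, gamma = gamma, beta = beta)
}

#' Per-cell fraction of signal attributable to a feature set
#'
#' Sum of counts over `featureSet` divided by the total per cell — e.g. the
#' percentage of viral transcripts in each cell, a monotone proxy of
#' infection progression. Cells with zero total get 0.
#'
#' @param states a [CellStateSet-class] of nonnegative counts.
#' @param featureSet character vector of feature ids (nonempty).
#' @return numeric vector in `[0, 1]` per cell.
#' @export
modalityFraction <- function(states, featureSet) {
    if (length(featureSet) == 0L)
        stop("parameter error: featureSet must be nonempty")
    X <- states@values
    if (any(X < 0)) stop("counts must be nonnegative")
    missing <- setdiff(featureSet, colnames(X))
    if (length(missing))
        stop("unknown features: ", paste(head(missing, 5), collapse = ", "))
    tot <- rowSums(X)
    sub <- rowSums(X[, featureSet, drop = FALSE])
    ifelse(tot > 0, sub / tot, 0)
}
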