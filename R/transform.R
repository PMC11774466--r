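# Moving velocities between representations with fitted tangent coefficients.
#
# A locally linear map connects the same neighborhood patch in two
# representations, so the coefficients phi fitted in one space transfer:
# v||(y_i) = sum_j phi_ij (y_j - y_i). This carries velocities to embeddings,
# to other modalities, and from a trusted gene subset to the whole feature
# space.

#' Transform a velocity field into another representation
#'
#' Applies the fitted coefficients to displacements computed in the target
#' representation: `v'(y_i) = sum_j phi_ij (y_j - y_i)`. With
#' `target = source` this reproduces the projected velocity exactly; the
#' operation is linear, so any affine map of the target coordinates maps the
#' output accordingly (translations drop out through the displacements).
#'
#' @param phi a [TangentCoefficients-class] fitted on a graph over the same
#'   cells.
#' @param target a [CellStateSet-class] giving the target coordinates of the
#'   same cells, in the same order.
#' @param graph the [NeighborGraph-class] the coefficients were fitted with.
#' @return a [VelocityField-class] in the target representation.
#' @export
transformVelocity <- function(phi, target, graph) {
    stopifnot(is(phi, "TangentCoefficients"), is(target, "CellStateSet"),
              is(graph, "NeighborGraph"))
    .checkCells(target, graph, "target and graph")
    if (nrow(phi@phi) != nrow(target@values))
        stop("alignment error: coefficient rows do not match target cells")
    if (phi@k != graph@k)
        stop("alignment error: coefficients were fitted with k = ", phi@k,
             " but the graph has k = ", graph@k)
    delta <- displacements(target, graph)
    out <- .phiTimesDelta(phi@phi, delta, dimnames(target@values))
    VelocityField(out, target@representation)
}

#' Per-cell adaptive extrapolation step size
#'
#' A velocity-scaled step that keeps the one-step extrapolation
#' `x_i + v_i * dt_i` inside the sampled manifold: the mean distance to the
#' cell's neighbors divided by the cell's speed. Cells with zero speed get
#' the population median step (their extrapolation does not move anyway).
#'
#' @param states a [CellStateSet-class].
#' @param vel a [VelocityField-class] aligned with `states`.
#' @param graph a [NeighborGraph-class].
#' @return numeric vector of positive per-cell step sizes.
#' @export
adaptiveDt <- function(states, vel, graph) {
    .checkCells(states, graph, "states and graph")
    if (!all(dim(vel@values) == dim(states@values)))
        stop("alignment error: velocity shape does not match states")
    speed <- sqrt(rowSums(vel@values^2))
    if (all(speed == 0))
        stop("degenerate input: every cell has zero velocity")
    meanDist <- rowMeans(neighborDistances(graph))
    dt <- ifelse(speed > 0, meanDist / speed, NA_real_)
    dt[is.na(dt)] <- median(dt, na.rm = TRUE)
    dt
}

#' Denoise velocities by extrapolation into principal-component space
#'
#' Extrapolates each cell by its adaptive step, maps current and extrapolated
#' states through the PC loading matrix, and differences them back:
#' `v_PCA = ((x + v dt) Q - x Q) / dt`. For a linear loading matrix this
#' equals `v Q` exactly; the two-step route is kept so nonlinear post-maps
#' (centering, log transforms) can be composed into the projection.
#'
#' @param states a [CellStateSet-class] in the space `Q` was estimated on.
#' @param vel a [VelocityField-class] aligned with `states`.
#' @param Q features x PCs loading matrix; a warning is issued if its columns
#'   are not orthonormal.
#' @param graph a [NeighborGraph-class] (supplies the adaptive step sizes).
#' @param dt optional per-cell step sizes overriding [adaptiveDt()].
#' @return a [VelocityField-class] in PC space.
#' @export
denoiseInPCA <- function(states, vel, Q, graph, dt = NULL) {
    Q <- as.matrix(Q)
    if (nrow(Q) != ncol(states@values))
        stop("alignment error: Q must have one row per feature")
    orth <- crossprod(Q)
    if (max(abs(orth - diag(ncol(Q)))) > 1e-6)
        warning("Q columns are not orthonormal; projected velocities remain ",
                "the linear image v %*% Q but are not an isometry")
    if (is.null(dt)) dt <- adaptiveDt(states, vel, graph)
    if (any(dt <= 0)) stop("degenerate step sizes: dt must be positive")
    X <- states@values
    Xf <- X + vel@values * dt
    out <- ((Xf %*% Q) - (X %*% Q)) / dt
    rownames(out) <- rownames(X)
    colnames(out) <- colnames(Q)
    VelocityField(out, "pca")
}

#' Extend velocities from a fitted subspace to any feature set
#'
#' The whole-genome / cross-modality inference step: coefficients fitted on a
#' trusted representation (e.g. manifold-consistent genes, PCA, or the RNA
#' modality of a multiome) are applied to displacements of arbitrary features
#' measured on the same cells — all genes, viral transcripts, or chromatin
#' accessibility. A smooth one-to-one correspondence between the manifold in
#' the fitted subspace and in the full space (guaranteed for a well-chosen
#' subset by the Whitney embedding theorem) is the modeling assumption.
#'
#' @param phi a [TangentCoefficients-class].
#' @param fullStates a [CellStateSet-class] holding the features to extend to.
#' @param graph the fitting [NeighborGraph-class].
#' @return a [VelocityField-class] over the features of `fullStates`.
#' @export
extendToFeatures <- function(phi, fullStates, graph) {
    transformVelocity(phi, fullStates, graph)
}
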