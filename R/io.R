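# File I/O. Three container formats, all plain text and lossless:
#   "csv"      one cells x features table (header = feature ids, first
#              column = cell ids); a sibling *_velocity.csv holds velocities.
#   "mtx"      a directory with matrix.mtx + features.tsv + cells.tsv
#              sidecars (velocity.mtx optional); features-x-cells
#              orientation is auto-detected from the sidecar lengths.
#   "h5ad-dir" a directory mirroring the AnnData schema as text: X.csv,
#              layers/<name>.csv (spliced/unspliced/velocity...),
#              obsm/<key>.csv (X_pca, X_umap...), obsp/distances.mtx for the
#              neighbor graph, uns.json for tags.
# Numeric values are written with 17 significant digits so write -> read
# round-trips bitwise.

.fmt17 <- function(x) sprintf("%.17g", x)

.writeMatrixCSV <- function(M, file) {
    if (is.null(colnames(M))) colnames(M) <- paste0("V", seq_len(ncol(M)))
    if (is.null(rownames(M))) rownames(M) <- paste0("row_", seq_len(nrow(M)))
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste(c("", colnames(M)), collapse = ","), con)
    body <- apply(M, 1L, function(r) paste(.fmt17(r), collapse = ","))
    writeLines(paste(rownames(M), body, sep = ","), con)
}

.readMatrixCSV <- function(file) {
    df <- read.csv(file, row.names = 1L, check.names = FALSE)
    as.matrix(df)
}

.writeMTX <- function(M, file) {
    sp <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                                  "generalMatrix"), "TsparseMatrix")
    con <- file(file, "w")
    on.exit(close(con))
    writeLines("%%MatrixMarket matrix coordinate real general", con)
    writeLines(paste(nrow(M), ncol(M), length(sp@x)), con)
    if (length(sp@x))
        writeLines(paste(sp@i + 1L, sp@j + 1L, .fmt17(sp@x)), con)
}

.readMTX <- function(file) as.matrix(Matrix::readMM(file))

#' Write a dataset container
#'
#' @param states a [CellStateSet-class].
#' @param path output file (csv) or directory (mtx, h5ad-dir).
#' @param format `"csv"`, `"mtx"`, or `"h5ad-dir"`.
#' @param velocity optional [VelocityField-class].
#' @param graph optional [NeighborGraph-class] (h5ad-dir only).
#' @param layers named list of extra cells x features matrices (h5ad-dir).
#' @param obsm named list of per-cell embedding matrices (h5ad-dir).
#' @return `path`, invisibly.
#' @export
writeDataset <- function(states, path, format = c("h5ad-dir", "mtx", "csv"),
                         velocity = NULL, graph = NULL, layers = list(),
                         obsm = list()) {
    format <- match.arg(format)
    X <- states@values
    if (format == "csv") {
        .writeMatrixCSV(X, path)
        if (!is.null(velocity)) {
            V <- velocity@values
            dimnames(V) <- dimnames(X)
            .writeMatrixCSV(V, sub("(\\.csv)?$", "_velocity.csv", path,
                                   perl = TRUE))
        }
        return(invisible(path))
    }
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    if (format == "mtx") {
        .writeMTX(X, file.path(path, "matrix.mtx"))
        writeLines(colnames(X), file.path(path, "features.tsv"))
        writeLines(rownames(X), file.path(path, "cells.tsv"))
        if (!is.null(velocity))
            .writeMTX(velocity@values, file.path(path, "velocity.mtx"))
        return(invisible(path))
    }
    ## h5ad-dir
    .writeMatrixCSV(X, file.path(path, "X.csv"))
    uns <- list(representation = states@representation)
    if (!is.null(velocity)) {
        V <- velocity@values
        dimnames(V) <- dimnames(X)
        layers <- c(layers, list(velocity = V))
        uns$velocity_representation <- velocity@representation
    }
    if (length(layers)) {
        dir.create(file.path(path, "layers"), showWarnings = FALSE)
        for (nm in names(layers)) {
            L <- as.matrix(layers[[nm]])
            if (is.null(rownames(L)) && nrow(L) == nrow(X))
                rownames(L) <- rownames(X)
            if (is.null(colnames(L)))
                colnames(L) <- if (ncol(L) == ncol(X)) colnames(X) else
                    paste0(nm, "_", seq_len(ncol(L)))
            .writeMatrixCSV(L, file.path(path, "layers",
                                         paste0(nm, ".csv")))
        }
    }
    if (length(obsm)) {
        dir.create(file.path(path, "obsm"), showWarnings = FALSE)
        for (nm in names(obsm)) {
            E <- as.matrix(obsm[[nm]])
            rownames(E) <- rownames(X)
            if (is.null(colnames(E)))
                colnames(E) <- paste0(nm, "_", seq_len(ncol(E)))
            .writeMatrixCSV(E, file.path(path, "obsm", paste0(nm, ".csv")))
        }
    }
    if (!is.null(graph)) {
        dir.create(file.path(path, "obsp"), showWarnings = FALSE)
        n <- nCells(graph)
        idx <- neighborIndices(graph); dst <- neighborDistances(graph)
        ## obsp-style sparse distance matrix for interoperability; the dense
        ## neighbor tables below are the lossless source on read (a sparse
        ## entry cannot represent a true zero distance)
        sp <- Matrix::sparseMatrix(
            i = rep(seq_len(n), times = graphK(graph)),
            j = as.vector(idx),
            x = as.vector(dst), dims = c(n, n))
        .writeMTX(as.matrix(sp), file.path(path, "obsp", "distances.mtx"))
        .writeMatrixCSV(matrix(as.numeric(idx), n,
                               dimnames = list(rownames(X), NULL)),
                        file.path(path, "obsp", "neighbor_indices.csv"))
        .writeMatrixCSV(matrix(as.numeric(dst), n,
                               dimnames = list(rownames(X), NULL)),
                        file.path(path, "obsp", "neighbor_distances.csv"))
        uns$graph <- list(k = graphK(graph), metric = graph@metric,
                          built_on = graph@builtOn)
    }
    jsonlite::write_json(uns, file.path(path, "uns.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

.namedKeyError <- function(key, available, where) {
    stop("key '", key, "' not found in ", where, "; available: ",
         if (length(available)) paste(available, collapse = ", ") else "none")
}

#' Read a dataset container
#'
#' Inverse of [writeDataset()]; the round trip preserves values bitwise and
#' names exactly. For `"h5ad-dir"`, `layer` selects a layer as the state
#' matrix (default: the main X), and the velocity layer is looked up under
#' `velocityKey` (first match wins). Missing keys raise an error listing the
#' available keys.
#'
#' @param path file (csv) or directory (mtx, h5ad-dir).
#' @param format `"csv"`, `"mtx"`, or `"h5ad-dir"`.
#' @param layer optional layer name to use as states (h5ad-dir).
#' @param velocityKey candidate velocity layer names.
#' @param obsmKey optional embedding key to attach (h5ad-dir).
#' @return list with `states`, `velocity` (or NULL), `graph` (or NULL), and
#'   for h5ad-dir also `layers` (named list) and `obsm`.
#' @export
readDataset <- function(path, format = c("h5ad-dir", "mtx", "csv"),
                        layer = NULL,
                        velocityKey = c("velocity_S", "velocity"),
                        obsmKey = NULL) {
    format <- match.arg(format)
    if (format == "csv") {
        X <- .readMatrixCSV(path)
        vfile <- sub("(\\.csv)?$", "_velocity.csv", path, perl = TRUE)
        vel <- if (file.exists(vfile))
            VelocityField(.readMatrixCSV(vfile), "genes") else NULL
        return(list(states = CellStateSet(X, representation = "genes"),
                    velocity = vel, graph = NULL))
    }
    if (format == "mtx") {
        M <- .readMTX(file.path(path, "matrix.mtx"))
        feats <- readLines(file.path(path, "features.tsv"))
        cells <- readLines(file.path(path, "cells.tsv"))
        if (nrow(M) == length(feats) && ncol(M) == length(cells) &&
            length(feats) != length(cells))
            M <- t(M)                       # features x cells orientation
        if (nrow(M) != length(cells) || ncol(M) != length(feats))
            stop("alignment error: matrix dims do not match sidecars")
        dimnames(M) <- list(cells, feats)
        vfile <- file.path(path, "velocity.mtx")
        vel <- NULL
        if (file.exists(vfile)) {
            V <- .readMTX(vfile)
            if (nrow(V) == length(feats) && ncol(V) == length(cells) &&
                length(feats) != length(cells)) V <- t(V)
            dimnames(V) <- dimnames(M)
            vel <- VelocityField(V, "genes")
        }
        return(list(states = CellStateSet(M, representation = "genes"),
                    velocity = vel, graph = NULL))
    }
    ## h5ad-dir
    uns <- if (file.exists(file.path(path, "uns.json")))
        jsonlite::read_json(file.path(path, "uns.json"),
                            simplifyVector = TRUE) else list()
    layerDir <- file.path(path, "layers")
    layerNames <- if (dir.exists(layerDir))
        sub("\\.csv$", "", list.files(layerDir, pattern = "\\.csv$"))
        else character()
    layers <- lapply(layerNames, function(nm)
        .readMatrixCSV(file.path(layerDir, paste0(nm, ".csv"))))
    names(layers) <- layerNames
    rep <- uns$representation %||% "genes"
    if (!is.null(layer)) {
        if (!layer %in% layerNames) .namedKeyError(layer, layerNames, "layers")
        X <- layers[[layer]]
    } else {
        X <- .readMatrixCSV(file.path(path, "X.csv"))
    }
    velName <- intersect(velocityKey, layerNames)
    vel <- if (length(velName))
        VelocityField(layers[[velName[1L]]],
                      uns$velocity_representation %||% rep) else NULL
    obsmDir <- file.path(path, "obsm")
    obsmNames <- if (dir.exists(obsmDir))
        sub("\\.csv$", "", list.files(obsmDir, pattern = "\\.csv$"))
        else character()
    obsm <- lapply(obsmNames, function(nm)
        .readMatrixCSV(file.path(obsmDir, paste0(nm, ".csv"))))
    names(obsm) <- obsmNames
    if (!is.null(obsmKey) && !obsmKey %in% obsmNames)
        .namedKeyError(obsmKey, obsmNames, "obsm")
    graph <- NULL
    gi <- file.path(path, "obsp", "neighbor_indices.csv")
    if (file.exists(gi) && !is.null(uns$graph)) {
        idx <- .readMatrixCSV(gi)
        dst <- .readMatrixCSV(file.path(path, "obsp",
                                        "neighbor_distances.csv"))
        graph <- NeighborGraph(idx, dst, cellIds = rownames(X),
                               metric = uns$graph$metric %||% "euclidean",
                               builtOn = uns$graph$built_on %||% rep)
    }
    list(states = CellStateSet(X, representation = rep), velocity = vel,
         graph = graph, layers = layers, obsm = obsm)
}
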