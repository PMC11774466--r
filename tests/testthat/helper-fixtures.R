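# Shared fixtures and independent oracles, all built in code.

## small random dataset with states + velocities
makeRandomData <- function(nCells = 50, nFeatures = 3, seed = 1,
                           representation = "genes") {
    set.seed(seed)
    X <- matrix(rnorm(nCells * nFeatures), nCells, nFeatures,
                dimnames = list(sprintf("c%03d", seq_len(nCells)),
                                sprintf("f%02d", seq_len(nFeatures))))
    V <- matrix(rnorm(nCells * nFeatures), nCells, nFeatures,
                dimnames = dimnames(X))
    list(states = CellStateSet(X, representation = representation),
         vel = VelocityField(V, representation))
}

## brute-force kNN oracle: full all-pairs distance sort, ties by index
bruteKnn <- function(X, k) {
    n <- nrow(X)
    idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
    for (i in seq_len(n)) {
        d <- sqrt(colSums((t(X) - X[i, ])^2))
        d[i] <- Inf
        o <- order(d)[seq_len(k)]
        idx[i, ] <- o; dst[i, ] <- d[o]
    }
    list(indices = idx, distances = dst)
}

## independently coded ridge least-squares oracle for one cell:
## phi minimizing ||v - t(B) phi||^2 + lam ||phi||^2 via normal equations
ridgeOracle <- function(B, v, lam) {
    k <- nrow(B)
    solve(B %*% t(B) + diag(lam, k), B %*% v)[, 1L]
}

## MacK fixture in which every cell agrees with exactly 3 of its 5 neighbor
## comparisons: 6 cells, complete graph (k = 5), t = 1..6, expression
## x = (3,2,1,6,5,4) (each element participates in exactly 2 of the 15
## order inversions), velocity +1 everywhere.
makeThreeOfFiveFixture <- function() {
    x <- c(3, 2, 1, 6, 5, 4)
    states <- CellStateSet(matrix(x, ncol = 1,
                                  dimnames = list(paste0("c", 1:6), "g")),
                           representation = "genes")
    vel <- VelocityField(matrix(1, 6, 1, dimnames = dimnames(states@values)),
                         "genes")
    graph <- buildKnnGraph(states, k = 5)
    ## independent count of agreeing pairs per cell
    agree <- sapply(1:6, function(i) {
        js <- setdiff(1:6, i)
        sum(sign(x[js] - x[i]) * sign(js - i) == 1)
    })
    stopifnot(all(agree == 3))
    list(states = states, vel = vel, graph = graph, time = 1:6)
}

## strictly monotone gene fixture: expression increases with time,
## velocity positive; graph over a 1D manifold
makeMonotoneFixture <- function(n = 30) {
    t <- seq_len(n)
    X <- matrix(t + 0.1 * sin(t), ncol = 1,
                dimnames = list(sprintf("c%02d", t), "g"))
    states <- CellStateSet(X, representation = "genes")
    vel <- VelocityField(matrix(1, n, 1, dimnames = dimnames(X)), "genes")
    graph <- buildKnnGraph(states, k = 4)
    list(states = states, vel = vel, graph = graph, time = as.numeric(t))
}

## brute-force DTW oracle: recursive enumeration over all monotone
## alignment paths (tiny series only)
dtwOracle <- function(a, b) {
    rec <- function(i, j) {
        cost <- (a[i] - b[j])^2
        if (i == 1 && j == 1) return(cost)
        prev <- Inf
        if (i > 1) prev <- min(prev, rec(i - 1, j))
        if (j > 1) prev <- min(prev, rec(i, j - 1))
        if (i > 1 && j > 1) prev <- min(prev, rec(i - 1, j - 1))
        cost + prev
    }
    sqrt(rec(length(a), length(b)))
}

## planted two-family trend fixture (accelerating vs decelerating)
makeTrendFamilies <- function(nPerFamily = 30, nCells = 300, seed = 3) {
    set.seed(seed)
    t <- sort(runif(nCells, 0, 1))
    acc <- lapply(seq_len(nPerFamily), function(i) {
        a <- runif(1, 0.8, 1.2)
        fitVelocityTrend(t, a * t^2 + rnorm(nCells, 0, 0.05),
                         gene = sprintf("acc%02d", i))
    })
    dec <- lapply(seq_len(nPerFamily), function(i) {
        a <- runif(1, 0.8, 1.2)
        fitVelocityTrend(t, a * (1 - (1 - t)^2) + rnorm(nCells, 0, 0.05),
                         gene = sprintf("dec%02d", i))
    })
    trends <- c(acc, dec)
    names(trends) <- vapply(trends, function(x) x@gene, character(1))
    list(trends = trends, truth = rep(1:2, each = nPerFamily))
}

## paired multiome trend fixture: first nDecoupled genes have decaying RNA
## velocity trends while chromatin stays open (slight continued opening);
## the rest share one shape across modalities up to scale
makeMultiomeTrends <- function(nGenes = 100, nDecoupled = 20, nCells = 400,
                               seed = 4) {
    set.seed(seed)
    t <- sort(runif(nCells, 0, 1))
    rna <- list(); chrom <- list()
    for (i in seq_len(nGenes)) {
        gn <- sprintf("g%03d", i)
        if (i <= nDecoupled) {
            rna[[gn]] <- fitVelocityTrend(t, exp(-3 * t) +
                                          rnorm(nCells, 0, 0.03), gene = gn)
            chrom[[gn]] <- fitVelocityTrend(t, 1 + 0.2 * t +
                                            rnorm(nCells, 0, 0.03), gene = gn)
        } else {
            sh <- runif(1, 0.5, 2)
            f <- sin(pi * t + runif(1, 0, 1))
            rna[[gn]] <- fitVelocityTrend(t, sh * f + rnorm(nCells, 0, 0.03),
                                          gene = gn)
            chrom[[gn]] <- fitVelocityTrend(t, 3 * sh * f +
                                            rnorm(nCells, 0, 0.03), gene = gn)
        }
    }
    list(rna = rna, chrom = chrom,
         planted = sprintf("g%03d", seq_len(nDecoupled)))
}
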