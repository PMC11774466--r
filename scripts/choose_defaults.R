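#!/usr/bin/env Rscript
# Coarse-grid chooser for the tangent-projection defaults (b, lam), run on
# the shipped sphere benchmark. Selection rule: fix b at the smallest value
# within 0.01 median-cosine of the best under isotropic (gaussian) noise,
# where the direction term earns its keep; then pick the largest lam whose
# speed-RMSE ratio under normal-component noise stays within 0.1 of the grid
# minimum (strongest regularization with no visible magnitude cost).
# Usage: Rscript scripts/choose_defaults.R [--seed 0]
suppressPackageStartupMessages(library(graphvelo))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 0L

traj <- liftToSphere(simulateToggleSwitch(nCells = 2000, seed = seed))
st <- trajStates(traj); vt <- trajVelocity(traj)
nrm <- sphereNormals(st)
g <- buildKnnGraph(st, k = 30)
Vt <- velocityValues(vt); spT <- sqrt(rowSums(Vt^2))

run <- function(noisy, b, lam) {
    fit <- suppressWarnings(tspProject(st, noisy, g, tspConfig(b = b, lam = lam)))
    Vp <- velocityValues(fit$velocity)
    c(medcos = evaluateVelocity(fit$velocity, vt)$medianCosine,
      ratio = sqrt(mean((sqrt(rowSums(Vp^2)) - spT)^2)) / mean(spT))
}

bGrid <- c(0, 0.1, 0.5, 1, 2)
lamGrid <- c(1e-4, 1e-3, 1e-2)

gauss <- addNoise(vt, "gaussian", level = 1, seed = seed + 1L)
cosByB <- sapply(bGrid, function(b) run(gauss, b, 1e-3)["medcos"])
cat("gaussian-noise median cosine by b:\n")
print(setNames(round(cosByB, 4), bGrid))
bStar <- bGrid[min(which(cosByB >= max(cosByB) - 0.01))]

normal <- addNoise(vt, "normal_component", level = 1, seed = seed + 1L,
                   normals = nrm)
ratByLam <- sapply(lamGrid, function(l) run(normal, bStar, l)["ratio"])
cat("normal-noise speed-RMSE ratio by lam (b =", bStar, "):\n")
print(setNames(round(ratByLam, 4), lamGrid))
lamStar <- max(lamGrid[ratByLam <= min(ratByLam) + 0.1])

cat(sprintf("chosen defaults: b = %g, lam = %g\n", bStar, lamStar))
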