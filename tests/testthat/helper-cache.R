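# cache for simulation runs shared between test files (computed once per
# test_dir invocation)
.tgCache <- new.env(parent = emptyenv())

cachedRun <- function(name, expr) {
    if (!exists(name, envir = .tgCache)) {
        assign(name, force(expr), envir = .tgCache)
    }
    get(name, envir = .tgCache)
}

# reduced-scale leopard run with growth: spots organize for 10000 iterations,
# then the surface grows to 2.5x; used by engine, render and spectrum tests
leopardRunSmall <- function() cachedRun("leopardSmall", {
    cfg <- presetConfig("leopard", gridDim = c(96L, 96L), maxSurface = 2.5,
                        seed = 11L, snapshotEvery = 500L, dilution = FALSE)
    runSimulation(cfg)
})

# no-growth control at the same parameters
leopardNoGrowth <- function(seed = 11L, iters = 20000L,
                            gridDim = c(96L, 96L), d0 = 1) {
    cachedRun(sprintf("noGrowth_%d_%d_%d_%g", seed, iters, gridDim[1], d0), {
        cfg <- presetConfig("leopard", gridDim = gridDim, totalIters = iters,
                            maxSurface = 1, seed = seed,
                            snapshotEvery = 2500L)
        cfg@growth@g <- 0
        cfg@reaction@d0 <- d0
        runSimulation(cfg)
    })
}

# dominant off-DC spectral radius of the binarized pattern: rises when
# interleaving shortens the wavelength on the fixed grid
peakRadius <- function(a) {
    bin <- binarizeImage(a, mean(range(a)))
    m <- dftMagnitude(bin)@magnitude
    ctr <- floor(dim(m) / 2) + 1L
    m[ctr[1], ctr[2]] <- 0
    ri <- row(m) - ctr[1]; ci <- col(m) - ctr[2]
    rad <- sqrt(ri^2 + ci^2)
    w <- which(m == max(m), arr.ind = TRUE)[1, ]
    rad[w[1], w[2]]
}

# reduced-scale pomacanthus run: middle stripe organizes into parallel
# stripes, growth to 2.5x, long relaxation so interleaving completes
pomacanthusRunSmall <- function() cachedRun("pomacanthusSmall", {
    cfg <- presetConfig("pomacanthus", gridDim = c(96L, 96L),
                        maxSurface = 2.5, seed = 21L, snapshotEvery = 2500L)
    cfg@growth@tStart <- 8000L
    cfg@totalIters <- as.integer(8000 + ceiling(log(2.5) / log1p(1e-4)) + 20000)
    runSimulation(cfg)
})

# brute-force 8-connected flood-fill component count (independent oracle for
# motif counting on binary images)
floodFillCount <- function(bin) {
    nr <- nrow(bin); nc <- ncol(bin)
    lab <- matrix(0L, nr, nc); cur <- 0L
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (bin[i, j] == 1 && lab[i, j] == 0L) {
            cur <- cur + 1L
            stack <- list(c(i, j)); lab[i, j] <- cur
            while (length(stack)) {
                p <- stack[[length(stack)]]
                stack[[length(stack)]] <- NULL
                for (di in -1:1) for (dj in -1:1) {
                    ii <- p[1] + di; jj <- p[2] + dj
                    if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                        bin[ii, jj] == 1 && lab[ii, jj] == 0L) {
                        lab[ii, jj] <- cur
                        stack[[length(stack) + 1L]] <- c(ii, jj)
                    }
                }
            }
        }
    }
    cur
}

# brute-force nine-point Laplacian with modular wrap (independent oracle)
laplacianOracle <- function(x) {
    nr <- nrow(x); nc <- ncol(x)
    w <- matrix(c(1, 4, 1, 4, -20, 4, 1, 4, 1), 3, 3) / 6
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        acc <- 0
        for (di in -1:1) for (dj in -1:1) {
            ii <- ((i - 1 + di) %% nr) + 1
            jj <- ((j - 1 + dj) %% nc) + 1
            acc <- acc + w[di + 2, dj + 2] * x[ii, jj]
        }
        out[i, j] <- acc
    }
    out
}
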