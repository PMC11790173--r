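# Reduced-scale qualitative signatures of the five scenario presets.  The
# published figures are qualitative, so these assert motif counts and simple
# shape statistics, never pixel identity.

test_that("leopard scenario: spots subdivide into rosette clusters under growth", {
    h <- leopardRunSmall()
    tStart <- h@config@growth@tStart
    nPre <- countHistoryMotifs(h, iteration = tStart)
    nFinal <- countHistoryMotifs(h)
    expect_gte(nPre, 3)                      # a proper spot pattern formed
    expect_gt(nFinal, nPre)                  # motifs multiplied after growth
    # counts increase through the growth phase (sampled at quarters)
    gEnd <- h@growthEndIter
    mid <- countHistoryMotifs(h, iteration = tStart + (gEnd - tStart) %/% 2)
    expect_gte(mid, nPre)
    expect_gte(nFinal, mid)
})

test_that("no-growth control: surface stays 1 and counts are stationary", {
    h <- leopardNoGrowth()
    expect_true(all(h@surface == 1))
    expect_true(is.na(h@growthEndIter))
    k <- length(h)
    late <- unique(vapply(seq(ceiling(0.8 * k), k, by = 1), function(i)
        countHistoryMotifs(h, i), 0L))
    expect_length(late, 1L)                  # constant over the last 20%
})

test_that("pomacanthus scenario: new stripes interleave between old ones", {
    h <- pomacanthusRunSmall()
    tStart <- h@config@growth@tStart
    # interleaving shortens the on-grid wavelength: the dominant spectral
    # radius rises by about sqrt(2.5), and sub-motifs multiply
    rPre <- peakRadius(aField(h, iteration = tStart))
    rFin <- peakRadius(aField(h))
    expect_gte(rPre, 2)                      # a periodic stripe pattern formed
    expect_gte(rFin / rPre, 1.3)
    expect_gt(countHistoryMotifs(h),
              countHistoryMotifs(h, iteration = tStart))
})

test_that("emu scenario: the memory render shows intermediate bands", {
    h <- cachedRun("emuSmall", {
        cfg <- presetConfig("emu", gridDim = c(96L, 96L), maxSurface = 2.5,
                            seed = 31L, snapshotEvery = 1000L)
        cfg@growth@tStart <- 8000L
        cfg@totalIters <- as.integer(8000 + ceiling(log(2.5) / log1p(1e-4)) + 12000)
        runSimulation(cfg)
    })
    mem <- renderMemory(h, patternPalette("emu"), from = "growth")[, , 1]
    expect_gt(mean(mem > 0.15 & mem < 0.85), 0.05)  # intermediate bands
    expect_gt(mean(mem >= 0.85), 0.02)              # light-throughout stripes
    expect_lte(min(mem), 0.35)   # pixels dark through most of the window
                                 # (interleaving keeps relocating the dark
                                 # phase, so strictly-always-dark is rare)
})

test_that("ictidomys scenario: stripes break into aligned dots", {
    h <- cachedRun("ictidomysSmall", {
        cfg <- presetConfig("ictidomys", gridDim = c(96L, 96L),
                            maxSurface = 2.5, seed = 41L,
                            snapshotEvery = 2500L)
        cfg@initNoise <- 0.2                 # a noisy system helps break stripes
        cfg@totalIters <- as.integer(1000 + ceiling(log(2.5) / log1p(0.01 * 0.002)) + 10000)
        runSimulation(cfg)
    })
    nPre <- countHistoryMotifs(h, iteration = 1000)
    nFin <- countHistoryMotifs(h)
    expect_gt(nFin, nPre + 3)                # stripes fragmented into dots
    # dots are compact: median foreground component no wider than ~2x tall
    a <- aField(h)
    bin <- binarizeImage(-a, -mean(range(a)))  # dark (low-a) motifs
    if (requireNamespace("EBImage", quietly = TRUE)) {
        lab <- EBImage::bwlabel(bin)
        feats <- EBImage::computeFeatures.shape(lab)
        expect_gte(nrow(feats), nFin * 0.5)
    }
})

test_that("tetraodon scenario: motif count rises as mazes nest", {
    h <- cachedRun("tetraodonSmall", {
        cfg <- presetConfig("tetraodon", gridDim = c(96L, 96L),
                            maxSurface = 2.5, seed = 51L,
                            snapshotEvery = 2500L)
        runSimulation(cfg)
    })
    nPre <- countHistoryMotifs(h, iteration = h@config@growth@tStart)
    nFin <- countHistoryMotifs(h)
    expect_gte(nPre, 3)
    expect_gt(nFin, nPre)
})

test_that("spectral band inclusion: the mid-growth stage combines early and late", {
    h <- leopardRunSmall()
    tStart <- h@config@growth@tStart
    gEnd <- h@growthEndIter
    bandsOf <- function(iter) {
        a <- aField(h, iteration = iter)
        bin <- binarizeImage(a, mean(range(a)))
        sp <- postprocessSpectrum(dftMagnitude(bin), log = TRUE,
                                  normalizeBy = "own_max",
                                  thresholdFraction = 1 / 20)
        radialBandSet(sp, nBands = 8)$bands
    }
    early <- bandsOf(tStart)
    mid <- bandsOf(tStart + (gEnd - tStart) %/% 2)
    late <- bandsOf(h@config@totalIters)
    target <- union(early, late)
    # intermediate covers the union up to one-band tolerance
    expect_lte(length(setdiff(target, mid)), 1)
})

test_that("simulated spot spectra are roughly circular (no preferred axis)", {
    # compare raw spectra: a pure square wave is degenerate under the
    # log-floor convention (its single harmonic IS the smallest positive
    # magnitude), so the angular-variance comparison uses the raw tables
    h <- leopardNoGrowth()
    a <- aField(h)
    bin <- binarizeImage(a, mean(range(a)))
    sp <- dftMagnitude(bin)
    stripes <- matrix(rep(c(0, 0, 1, 1), length.out = 96 * 96), 96, 96)
    spStripes <- dftMagnitude(stripes)
    expect_lt(radialSymmetryScore(sp, 8), radialSymmetryScore(spStripes, 8))
    # and the degenerate case is reported as NA, not a number
    dc <- dftMagnitude(matrix(1, 32, 32))
    expect_true(is.na(radialSymmetryScore(dc, 8)))
})
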