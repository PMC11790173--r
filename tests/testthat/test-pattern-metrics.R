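test_that("binarization is a strict threshold with provenance", {
    img <- matrix(c(3.9, 4.1, 4.0, 4.2), 2, 2)
    bin <- binarizeImage(img, 4.0)
    expect_equal(as.vector(bin), c(0, 1, 0, 1))
    expect_equal(attr(bin, "threshold"), 4.0)
    expect_equal(binarizeImage(matrix(0, 4, 4), 0.5),
                 matrix(0, 4, 4), ignore_attr = TRUE)
})

test_that("motif counting: blanks, blobs, merges and binary components", {
    expect_equal(countMotifs(matrix(0, 32, 32)), 0L)
    expect_equal(countMotifs(matrix(5, 10, 10)), 0L)   # flat non-zero

    fx <- generateBlobImage(7, c(256, 256), 30, seed = 3)
    expect_equal(countMotifs(fx$image), 7L)

    # two blobs close enough that the saddle sits above peak - tolerance:
    # they merge into a single motif
    ri <- row(matrix(0, 64, 64)); ci <- col(matrix(0, 64, 64))
    blob <- function(y, x, s = 6) exp(-((ri - y)^2 + (ci - x)^2) / (2 * s^2))
    img <- blob(32, 28) + blob(32, 36)
    expect_equal(countMotifs(img, noiseTolerance = 0.3 * diff(range(img))), 1L)
    # well-separated at the same tolerance: two motifs
    img2 <- blob(16, 16) + blob(48, 48)
    expect_equal(countMotifs(img2, noiseTolerance = 0.3 * diff(range(img2))), 2L)
})

test_that("on binary images the count equals 8-connected components (oracle)", {
    set.seed(101)
    for (k in 1:6) {
        bin <- matrix(as.numeric(runif(64 * 64) < 0.25), 64, 64)
        expect_equal(countMotifs(bin, noiseTolerance = 0.5),
                     floodFillCount(bin), info = paste("replicate", k))
    }
    # sparse foreground too (well-separated blobs)
    bin <- matrix(as.numeric(runif(64 * 64) < 0.03), 64, 64)
    expect_equal(countMotifs(bin, noiseTolerance = 0.5), floodFillCount(bin))
})

test_that("periodic connectivity joins motifs across the wrap", {
    img <- matrix(0, 32, 32)
    img[1:2, 15:17] <- 1; img[31:32, 15:17] <- 1   # one blob split by the seam
    expect_equal(countMotifs(img, 0.5), 2L)
    expect_equal(countMotifs(img, 0.5, periodic = TRUE), 1L)
})

test_that("DFT magnitude spectrum: DC centering, symmetry, Parseval, cosine", {
    # constant image: only the DC bin is nonzero
    sp <- dftMagnitude(matrix(2, 32, 32))
    m <- sp@magnitude
    ctr <- dcIndex(sp)
    expect_equal(m[ctr[1], ctr[2]], 2 * 32 * 32)
    expect_equal(sum(m) - m[ctr[1], ctr[2]], 0)

    # vertical cosine stripes of period 50 px on a 500-wide image: off-DC
    # magnitude concentrated at horizontal frequency index +/-10
    n <- 500L
    img <- matrix(rep(cos(2 * pi * (0:(n - 1)) / 50), each = 100), 100, n,
                  byrow = FALSE)
    sp <- dftMagnitude(img)
    m <- sp@magnitude; ctr <- dcIndex(sp)
    m[ctr[1], ctr[2]] <- 0
    peaks <- which(m > 0.5 * max(m), arr.ind = TRUE)
    expect_setequal(peaks[, "col"] - ctr[2], c(-10L, 10L))
    expect_true(all(peaks[, "row"] == ctr[1]))

    # real input: point symmetry about the centre, and Parseval
    set.seed(9)
    img <- matrix(runif(48 * 36), 48, 36)
    sp <- dftMagnitude(img)
    m <- sp@magnitude
    flipped <- m[c(1, nrow(m):2), c(1, ncol(m):2)]  # reflection about DC
    expect_equal(m, flipped, tolerance = 1e-9)
    expect_equal(sum(m^2), length(img) * sum(img^2), tolerance = 1e-8)
    expect_true(all(m >= 0))
})

test_that("spectrum post-processing: log, normalization and threshold rules", {
    set.seed(3)
    img <- matrix(runif(64 * 64) < 0.3, 64, 64) + 0
    sp <- dftMagnitude(img)

    norm <- postprocessSpectrum(sp, log = TRUE, normalizeBy = "own_max")
    expect_equal(max(norm@magnitude), 1)
    expect_identical(norm@state, "normalized")

    thr <- postprocessSpectrum(sp, log = TRUE, normalizeBy = "own_max",
                               thresholdFraction = 1 / 20)
    mm <- thr@magnitude
    expect_true(all(mm[mm > 0] >= max(mm) / 20))
    expect_true(all(mm[mm < max(mm) / 20] == 0))

    # series normalization: all spectra divided by the single largest value
    imgs <- lapply(1:3, function(k) {
        set.seed(k); matrix(runif(32 * 32) < 0.3, 32, 32) + 0
    })
    sps <- lapply(imgs, dftMagnitude)
    smax <- seriesMaximum(sps, log = TRUE)
    post <- lapply(sps, postprocessSpectrum, log = TRUE,
                   normalizeBy = "series_max", seriesMax = smax)
    expect_equal(max(vapply(post, function(p) max(p@magnitude), 0)), 1)
    expect_true(all(vapply(post, function(p) max(p@magnitude), 0) <= 1))

    expect_error(postprocessSpectrum(sp, thresholdFraction = 2), "thresholdFraction")
})

test_that("radial band sets capture multi-periodicity as set inclusion", {
    # DC-only spectrum: empty band set, richness 0
    sp <- dftMagnitude(matrix(1, 64, 64))
    thr <- postprocessSpectrum(sp, log = FALSE, normalizeBy = "own_max",
                               thresholdFraction = 1 / 20)
    bs <- radialBandSet(thr, nBands = 8)
    expect_identical(bs$bands, integer(0))
    expect_equal(bs$richness, 0)
    expect_error(radialBandSet(thr, nBands = 1), "nBands")

    # two superimposed periodicities occupy (at least) the union of the bands
    # each occupies alone
    n <- 128L
    grid <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
    coarse <- matrix(cos(2 * pi * grid$j / 32), n, n)
    fine <- matrix(cos(2 * pi * grid$i / 8), n, n)
    bands <- function(img) {
        sp <- postprocessSpectrum(dftMagnitude(img), log = FALSE,
                                  normalizeBy = "own_max",
                                  thresholdFraction = 1 / 20)
        radialBandSet(sp, nBands = 10)$bands
    }
    both <- bands(coarse + fine)
    expect_true(all(bands(coarse) %in% both))
    expect_true(all(bands(fine) %in% both))
    expect_gt(length(both), length(bands(coarse)))
})
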