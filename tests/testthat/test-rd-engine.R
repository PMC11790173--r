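test_that("nine-point Laplacian matches the stencil and wraps periodically", {
    # constant field: Laplacian vanishes
    expect_equal(laplacian9(matrix(4, 5, 7)), matrix(0, 5, 7))

    # single impulse of 6 at an interior cell: -20 at the cell, 4 at the
    # orthogonal neighbours, 1 at the diagonals (weights /6 times value 6)
    x <- matrix(0, 7, 7); x[4, 4] <- 6
    L <- laplacian9(x)
    expect_equal(L[4, 4], -20)
    expect_equal(L[3, 4], 4); expect_equal(L[5, 4], 4)
    expect_equal(L[4, 3], 4); expect_equal(L[4, 5], 4)
    expect_equal(L[3, 3], 1); expect_equal(L[5, 5], 1)
    expect_equal(sum(abs(L)), 20 + 4 * 4 + 4 * 1)

    # impulse at the corner: neighbours appear at wrapped positions
    x <- matrix(0, 6, 6); x[1, 1] <- 6
    expect_equal(laplacian9(x), laplacianOracle(x))
    L <- laplacian9(x)
    expect_equal(L[6, 1], 4)   # wrapped up
    expect_equal(L[1, 6], 4)   # wrapped left
    expect_equal(L[6, 6], 1)   # wrapped diagonal

    # general agreement with the brute-force modular oracle
    set.seed(42)
    y <- matrix(rnorm(15 * 11), 15, 11)
    expect_equal(laplacian9(y), laplacianOracle(y), tolerance = 1e-12)

    expect_error(laplacian9(matrix(0, 2, 5)), "3x3")
})

test_that("stencil conserves mass: grid sum of the Laplacian is zero", {
    set.seed(7)
    for (k in 1:5) {
        x <- matrix(runif(64 * 48, 0, 10), 64, 48)
        expect_lt(abs(sum(laplacian9(x))), 1e-8)
    }
})

test_that("reaction step: homogeneous (4,4) is a fixed point and clamps bind", {
    p <- new("ReactionParams")
    a <- matrix(4, 8, 8); b <- matrix(4, 8, 8)
    st <- reactionStep(a, b, p, gNow = 0)
    expect_identical(st$a, a)   # 16 - ab = 0 exactly
    expect_identical(st$b, b)   # ab - b - 12 = 0 exactly
    expect_identical(st$d, p@d0)

    # growing uniform state: direct arithmetic of the printed update
    st <- reactionStep(a, b, p, gNow = 0.05)
    f <- 1 + 0.05 * 0.002
    expect_equal(st$a, matrix(4 / f + (16 - 16 / f^2) * 0.002, 8, 8))
    expect_equal(st$b, matrix(4 / f + (16 / f^2 - 4 / f - 12) * 0.002, 8, 8))
    expect_equal(st$d, p@d0 / f)           # default d = 1/S coupling
    st2 <- reactionStep(a, b, p, gNow = 0.05, dGrowthExponent = 2)
    expect_equal(st2$d, p@d0 / f^2)        # steeper optional reading

    # clamp: a raw update above maxA comes out exactly 4.4
    a2 <- matrix(4.4, 8, 8); b2 <- matrix(3.5, 8, 8)
    st <- reactionStep(a2, b2, p)          # 16 - 15.4 > 0 pushes a further up
    expect_true(all(st$a == 4.4))
    expect_error(reactionStep(a, b[1:4, ], p), "shape")
})

test_that("initial conditions are seeded, shaped and typed as documented", {
    ic1 <- makeInitialCondition("random_noise", c(64, 64), seed = 1)
    ic2 <- makeInitialCondition("random_noise", c(64, 64), seed = 1)
    expect_identical(ic1, ic2)                       # bit-identical
    expect_false(identical(
        ic1, makeInitialCondition("random_noise", c(64, 64), seed = 2)))
    expect_true(all(abs(ic1$a - 4) <= 0.5) && all(abs(ic1$b - 4) <= 0.5))

    # middle stripe: elevated cells form one contiguous band containing the
    # central column
    ic <- makeInitialCondition("middle_stripe", c(64, 64), seed = 1, noise = 0)
    hot <- which(apply(ic$a > 4.2, 2, any))
    expect_true(32L %in% hot || 33L %in% hot)
    expect_true(all(diff(hot) == 1L))                # contiguous
    expect_equal(countMotifs(ic$a, 0.1), 1L)

    # periodic stripes: circular autocorrelation along the cross-stripe axis
    # peaks at lag 64/5 ~ 13
    ic <- makeInitialCondition("periodic_stripes", c(64, 64), seed = 1,
                               noise = 0, stripes = 5)
    prof <- colMeans(ic$a) - mean(ic$a)
    ac <- sapply(1:32, function(l) sum(prof * prof[((seq_along(prof) - 1 + l)
                                                    %% 64) + 1]))
    expect_true((which.max(ac[3:32]) + 2L) %in% 12:14)

    expect_error(makeInitialCondition("weird", c(64, 64)), "arg")
})

test_that("simulation is deterministic and respects the clamp invariants", {
    cfg <- presetConfig("leopard", gridDim = c(48, 48), totalIters = 3000L,
                        maxSurface = 1, seed = 5, snapshotEvery = 500L)
    h1 <- runSimulation(cfg)
    h2 <- runSimulation(cfg)
    expect_identical(h1@aFields, h2@aFields)         # bit-identical histories
    expect_identical(h1@bFields, h2@bFields)
    for (i in seq_along(h1@iterations)) {
        a <- aField(h1, i); b <- bField(h1, i)
        expect_true(all(is.finite(a)) && all(is.finite(b)))
        expect_gte(min(a), 0);   expect_lte(max(a), 4.4)
        expect_gte(min(b), 3.5); expect_lte(max(b), 100)
    }
})

test_that("homogeneous start with no noise stays exactly stationary", {
    cfg <- presetConfig("leopard", gridDim = c(16, 16), totalIters = 500L,
                        maxSurface = 1, seed = 1)
    cfg@growth@g <- 0
    cfg@initNoise <- 0
    h <- runSimulation(cfg)
    expect_identical(aField(h), matrix(4, 16, 16))   # stepper injects no noise
    expect_identical(bField(h), matrix(4, 16, 16))
})

test_that("named presets carry the published parameter table", {
    tab <- list(
        leopard     = c(s = 6, r = 30, g = 0.05, tStart = 10000),
        emu         = c(s = 10, r = 6, g = 0.05, tStart = 10000),
        pomacanthus = c(s = 10, r = 6, g = 0.05, tStart = 20000),
        ictidomys   = c(s = 6, r = 30, g = 0.01, tStart = 1000),
        tetraodon   = c(s = 10, r = 8, g = 0.075, tStart = 10000))
    inits <- c(leopard = "random_noise", emu = "middle_stripe",
               pomacanthus = "middle_stripe", ictidomys = "periodic_stripes",
               tetraodon = "random_noise")
    for (nm in names(tab)) {
        cfg <- presetConfig(nm)
        expect_equal(cfg@reaction@s, tab[[nm]]["s"], ignore_attr = TRUE)
        expect_equal(cfg@reaction@r, tab[[nm]]["r"], ignore_attr = TRUE)
        expect_equal(cfg@growth@g, tab[[nm]]["g"], ignore_attr = TRUE)
        expect_equal(cfg@growth@tStart, as.integer(tab[[nm]]["tStart"]),
                     ignore_attr = TRUE)
        expect_equal(cfg@reaction@dt, 0.002)
        expect_identical(cfg@init, inits[[nm]])
    }
})

test_that("surface bookkeeping: growth is exponential, then stops", {
    cfg <- presetConfig("leopard", gridDim = c(32, 32), seed = 2,
                        maxSurface = 1.05, snapshotEvery = 250L,
                        totalIters = 14000L)
    h <- runSimulation(cfg)
    s <- h@surface; it <- h@iterations
    expect_true(all(diff(s) >= 0))                       # non-decreasing
    expect_true(all(s[it <= 10000] == 1))                # flat before tStart
    expect_equal(h@finalSurface, 1.05, tolerance = 1e-3) # stops at max
    expect_true(all(s[it > h@growthEndIter] == h@finalSurface))
    # growth end timing: n steps with (1+g dt)^n = maxSurface
    expect_equal(h@growthEndIter - 10000,
                 ceiling(log(1.05) / log1p(0.05 * 0.002)), tolerance = 1)
    # effective diffusion tracks 1/S under the default coupling
    expect_equal(h@d, 1 / s, tolerance = 1e-9)
})
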