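test_that("rosette correction applies +15% with a +/-5 point band", {
    rc <- applyRosetteCorrection(100, TRUE)
    expect_equal(rc$corrected, 115)
    expect_equal(rc$lower, 110)
    expect_equal(rc$upper, 120)

    expect_equal(applyRosetteCorrection(100, FALSE)$corrected, 100)

    rc <- applyRosetteCorrection(40, TRUE)
    expect_equal(rc$corrected, 46)       # kept real-valued, happens integral
    expect_equal(rc$lower, 44)
    expect_equal(rc$upper, 48)

    expect_error(applyRosetteCorrection(0, TRUE), ">= 1")
})

test_that("formation relative size is the corrected count ratio", {
    counts <- data.frame(id = c("head", "trunk"), count = c(10, 30))
    expect_equal(formationRelativeSize(counts, "trunk"), 3)
    counts <- data.frame(id = c("head", "neck"), count = c(12, 12))
    expect_equal(formationRelativeSize(counts, "neck"), 1)

    # composition with the rosette correction: 23*1.15/10
    counts <- data.frame(id = c("head", "tail"), count = c(10, 23),
                         rosettes = c(FALSE, TRUE))
    expect_equal(formationRelativeSize(counts, "tail"), 2.645)

    expect_error(formationRelativeSize(counts, "tail", reference = "nope"),
                 "reference")
})

test_that("timing estimation inverts a linear relative trajectory", {
    # rel(stage) = 0.2 + 0.08 stage; formation ratio 0.6 inverts to stage 5
    stages <- 1:10
    traj <- rbind(
        data.frame(id = "head", stage = stages, length = 10),
        data.frame(id = "d1", stage = stages, length = 10 * (0.2 + 0.08 * stages)),
        data.frame(id = "d2", stage = stages, length = 10 * (0.1 + 0.05 * stages)))
    counts <- data.frame(id = c("head", "d1", "d2"), count = c(10, 6, 6))
    # d1 ratio 0.6 -> stage 5; d2 ratio 0.6 -> (0.6-0.1)/0.05 = 10
    est <- estimateTiming(traj, counts)
    pd <- est@perDistance
    expect_equal(pd$stage[pd$id == "d1"], 5)
    expect_equal(pd$stage[pd$id == "d2"], 10)
    expect_false(any(pd$extrapolated))

    # ratio equal to the last-stage relative size: estimated stage is the
    # observation stage and wavelength = adult length / count
    counts2 <- data.frame(id = c("head", "d1", "d2"), count = c(10, 10, 6))
    est2 <- estimateTiming(traj, counts2)
    pd2 <- est2@perDistance
    expect_equal(pd2$stage[pd2$id == "d1"], 10)
    expect_equal(pd2$wavelength[pd2$id == "d1"], 10 * (0.2 + 0.8) / 10)

    # a ratio outside the observed range is flagged, not clipped
    counts3 <- data.frame(id = c("head", "d1", "d2"), count = c(10, 20, 6))
    est3 <- estimateTiming(traj, counts3)
    expect_true(est3@perDistance$extrapolated[est3@perDistance$id == "d1"])
})

test_that("parameter recovery on noiseless synthetic fixtures is exact", {
    fx <- generateTrajectories(nDistances = 6, stages = 1:10,
                               formationStage = 5, wavelength = 2, seed = 4)
    est <- estimateTiming(fx$trajectories, fx$counts)
    expect_equal(est@consensusStage, 5, tolerance = 1e-6)
    expect_equal(unname(est@stageIQR), 0, tolerance = 1e-6)
    expect_equal(est@consensusWavelength, 2, tolerance = 0.02)  # < 1%
    expect_lt(max(abs(est@perDistance$wavelength - 2)) / 2, 0.01)
})

test_that("timing is scale-invariant; wavelength scales with the unit", {
    fx <- generateTrajectories(nDistances = 4, stages = 1:8,
                               formationStage = 3, wavelength = 1.5, seed = 8)
    est1 <- estimateTiming(fx$trajectories, fx$counts)
    scaled <- fx$trajectories
    scaled$length <- scaled$length * 7.3
    est2 <- estimateTiming(scaled, fx$counts)
    expect_equal(est2@perDistance$stage, est1@perDistance$stage)
    expect_equal(est2@consensusWavelength, 7.3 * est1@consensusWavelength)
})

test_that("under 5% count noise the median stage error stays within 1 stage", {
    errs <- vapply(1:100, function(k) {
        fx <- generateTrajectories(nDistances = 6, stages = 1:10,
                                   formationStage = 5, wavelength = 2,
                                   countNoise = 0.05, seed = 1000 + k)
        est <- estimateTiming(fx$trajectories, fx$counts)
        abs(est@consensusStage - 5)
    }, numeric(1))
    expect_lte(median(errs), 1)
})

test_that("through-origin proportionality fit and its residuals", {
    fit <- expectedMotifCount(c(1, 2), c(50, 100))
    expect_equal(fit$slope, 50)
    expect_equal(fit$predict(4), 200)
    expect_equal(fit$residuals, c(0, 0))

    fit <- expectedMotifCount(c(1, 2, 4), c(50, 98, 205))
    expect_equal(fit$slope, sum(c(1, 2, 4) * c(50, 98, 205)) / sum(c(1, 4, 16)))
    expect_true(all(abs(fit$residuals) < 0.05))

    expect_error(expectedMotifCount(c(2, 2), c(50, 52)), "two or more")
})
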