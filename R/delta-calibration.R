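#' Count motifs in a simulation snapshot
#'
#' Applies the persistence counter (\code{\link{countMotifs}}) to a recorded
#' field with the package's conventions for simulator output: periodic
#' connectivity (the domain is a torus) and a noise tolerance expressed as a
#' fraction of the field's value range.  Motifs are counted on the b-field
#' by default: its peaks are sharply localized at motif centres (the a-field
#' saturates near its clamps), so nascent sub-motifs are resolved earlier
#' and the count is stable against the tolerance choice.
#'
#' @param history a \linkS4class{SimulationHistory}.
#' @param which snapshot index (default last).
#' @param iteration alternatively, pick the snapshot nearest this iteration.
#' @param field "b" (maxima, default) or "a" (minima: activator valleys
#'   coincide with motif centres at equilibrium).
#' @param tolerance prominence threshold as a fraction of the field range,
#'   default 0.05.
#' @return integer motif count.
#' @export
countHistoryMotifs <- function(history, which = length(history),
                               iteration = NULL, field = c("b", "a"),
                               tolerance = 0.05) {
    field <- match.arg(field)
    x <- if (field == "b") bField(history, which, iteration)
         else aField(history, which, iteration)
    countMotifs(x, tolerance * diff(range(x)), periodic = TRUE,
                invert = (field == "a"))
}

#' Motif-count delta calibration under growth
#'
#' Quantifies the counting deficit that growth imposes on a Turing pattern.
#' For every combination of growth rate and final surface multiple, the
#' simulator is run (spot-forming parameters, growth starting after the
#' pattern has organized, no dilution -- growth acts through the diffusion
#' scale) to the end of growth and on to equilibrium.  The observed motif
#' count is compared with the proportional expectation \eqn{c S}, where the
#' slope \eqn{c} is fitted through the origin on no-growth runs at matched
#' effective sizes (diffusion multiplier fixed at \eqn{1/S}):
#' \deqn{\delta(t) = 100 (c S(t) - N_{obs}(t)) / (c S(t)).}
#' \eqn{\delta} is reported at the end of growth and at final equilibrium,
#' averaged over replicate seeds.  Scenarios whose motif count did not
#' increase during growth are flagged \code{growthPatterns = FALSE} (the
#' system had no time to produce growth patterns) and excluded from the
#' recommended counting correction, which is the mean final delta across the
#' remaining scenarios.
#'
#' @param rates numeric vector of growth rates, default the published grid
#'   c(0.01, 0.02, 0.05, 0.1, 0.2).
#' @param maxSizes numeric vector of final surface multiples, default
#'   c(2.5, 4, 5.4) (= 1/0.4, 1/0.25, 1/0.185).
#' @param reps replicate seeds per scenario, >= 1 (default 3).
#' @param seed master seed; all child seeds derive from it.
#' @param gridDim grid shape, default 128x128.
#' @param s,r reaction parameters, default the spot-forming (leopard) set
#'   s = 6, r = 30.
#' @param tStart growth start iteration, default 10000.
#' @param relaxIters iterations run after growth ends, default 15000.
#' @param baselineIters iteration budget of the no-growth fit runs.
#' @param baselineSizes effective sizes of the no-growth runs; defaults to
#'   size 1 plus \code{maxSizes}.
#' @param tolerance motif-count tolerance (fraction of field range).
#' @param verbose print per-run progress.
#' @return a \linkS4class{DeltaReport}.
#' @export
deltaCalibration <- function(rates = c(0.01, 0.02, 0.05, 0.1, 0.2),
                             maxSizes = c(2.5, 4, 5.4),
                             reps = 3L, seed = 1L,
                             gridDim = c(128L, 128L),
                             s = 6, r = 30, tStart = 10000L,
                             relaxIters = 15000L,
                             baselineIters = 30000L,
                             baselineSizes = NULL,
                             tolerance = 0.05,
                             verbose = FALSE) {
    if (reps < 1L) stop("'reps' must be >= 1")
    if (is.null(baselineSizes)) baselineSizes <- unique(c(1, maxSizes))
    if (length(baselineSizes) < 2L) stop("need >= 2 baseline sizes")
    dt <- 0.002
    childSeeds <- withr::with_seed(as.integer(seed),
        sample.int(.Machine$integer.max %/% 2L,
                   reps * (length(baselineSizes) + length(rates) * length(maxSizes))))
    si <- 0L
    nextSeed <- function() { si <<- si + 1L; childSeeds[si] }

    mkcfg <- function(sd, total, maxSurface, g, d0) {
        cfg <- new("SimulationConfig",
                   reaction = new("ReactionParams", s = s, r = r, d0 = d0),
                   growth = new("GrowthSchedule", g = g,
                                tStart = as.integer(tStart),
                                maxSurface = maxSurface),
                   gridDim = as.integer(gridDim), init = "random_noise",
                   totalIters = as.integer(total),
                   snapshotEvery = as.integer(max(2500L, total)),
                   seed = as.integer(sd), dilution = FALSE)
        cfg
    }

    baseline <- do.call(rbind, lapply(baselineSizes, function(S) {
        do.call(rbind, lapply(seq_len(reps), function(k) {
            cfg <- mkcfg(nextSeed(), baselineIters, 1, 0, 1 / S)
            h <- runSimulation(cfg)
            n <- countHistoryMotifs(h, tolerance = tolerance)
            if (verbose) message(sprintf("baseline S=%.3g rep %d: N=%d", S, k, n))
            data.frame(size = S, rep = k, count = n)
        }))
    }))
    fit <- expectedMotifCount(baseline$size, baseline$count)
    cc <- fit$slope

    runs <- do.call(rbind, lapply(maxSizes, function(S) {
        do.call(rbind, lapply(rates, function(g) {
            gsteps <- as.integer(ceiling(log(S) / log1p(g * dt)))
            total <- tStart + gsteps + relaxIters
            do.call(rbind, lapply(seq_len(reps), function(k) {
                cfg <- mkcfg(nextSeed(), total, S, g, 1)
                h <- runSimulation(cfg,
                                   snapshotAt = c(tStart, tStart + gsteps))
                iEnd <- which.min(abs(snapshotIterations(h) - h@growthEndIter))
                nPre <- countHistoryMotifs(h, iteration = tStart,
                                           tolerance = tolerance)
                nEnd <- countHistoryMotifs(h, iEnd, tolerance = tolerance)
                nFin <- countHistoryMotifs(h, tolerance = tolerance)
                expd <- cc * S
                if (verbose)
                    message(sprintf("g=%.3g S=%.3g rep %d: %d -> %d -> %d (exp %.1f)",
                                    g, S, k, nPre, nEnd, nFin, expd))
                data.frame(g = g, maxSize = S, rep = k,
                           nPre = nPre, nEnd = nEnd, nFinal = nFin,
                           expected = expd,
                           deltaEnd = 100 * (expd - nEnd) / expd,
                           deltaFinal = 100 * (expd - nFin) / expd,
                           growthPatterns = nEnd > nPre)
            }))
        }))
    }))

    scen <- do.call(rbind, lapply(split(runs, list(runs$g, runs$maxSize),
                                        drop = TRUE), function(d) {
        data.frame(g = d$g[1], maxSize = d$maxSize[1],
                   deltaEnd = mean(d$deltaEnd),
                   deltaFinal = mean(d$deltaFinal),
                   growthPatterns = all(d$growthPatterns))
    }))
    scen <- scen[order(scen$maxSize, scen$g), ]
    rownames(scen) <- NULL
    ok <- scen$growthPatterns
    corr <- if (any(ok)) mean(scen$deltaFinal[ok]) else NA_real_
    spread <- if (any(ok)) range(scen$deltaFinal[ok]) else c(NA_real_, NA_real_)

    new("DeltaReport", runs = runs, scenarios = scen, baseline = baseline,
        slope = cc, correction = corr, correctionSpread = spread)
}

setMethod("show", "DeltaReport", function(object) {
    cat(sprintf("DeltaReport: %d scenarios x %d seeds, slope c = %.3g motifs/size\n",
                nrow(object@scenarios), max(object@runs$rep), object@slope))
    cat(sprintf("  recommended correction: +%.1f%% (final deltas %.1f..%.1f%%)\n",
                object@correction, object@correctionSpread[1],
                object@correctionSpread[2]))
    print(object@scenarios, digits = 3)
})
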