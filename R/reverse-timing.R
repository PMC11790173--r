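#' Rosette correction of a motif count
#'
#' Under growth the equilibrium motif count falls short of the count expected
#' from strict proportionality to tissue size by roughly 15\% (see
#' \code{\link{deltaCalibration}}).  When rosettes (re-divided motifs) are
#' present, the raw count is therefore corrected by +15\% with a +/-5
#' percentage-point uncertainty band.  Corrected counts are kept as reals;
#' round only for reporting.
#'
#' @param count numeric motif count(s), >= 1.
#' @param rosettesPresent logical; if FALSE the count is returned unchanged
#'   (band collapses onto the count).
#' @param correction central correction, default 0.15.
#' @param halfBand half-width of the band, default 0.05.
#' @return data.frame with columns \code{corrected}, \code{lower},
#'   \code{upper}.
#' @examples
#' applyRosetteCorrection(100, TRUE)   # 115 [110, 120]
#' @export
applyRosetteCorrection <- function(count, rosettesPresent,
                                   correction = 0.15, halfBand = 0.05) {
    if (any(count < 1)) stop("counts must be >= 1")
    f <- ifelse(rosettesPresent, 1 + correction, 1)
    lo <- ifelse(rosettesPresent, 1 + correction - halfBand, 1)
    hi <- ifelse(rosettesPresent, 1 + correction + halfBand, 1)
    data.frame(corrected = count * f, lower = count * lo, upper = count * hi)
}

#' Relative tissue size at pattern formation
#'
#' At the time the pattern formed, motifs were equally spaced with a common
#' wavelength everywhere on the tissue, so the ratio of (corrected) motif
#' counts along two distances equals the ratio of their lengths at that time.
#' This returns \code{correctedCount(distance) / correctedCount(reference)}
#' -- the relative size the distance must have had, to be matched against
#' its measured relative-size trajectory.
#'
#' @param counts data.frame with columns \code{id}, \code{count} and
#'   optionally \code{rosettes} (logical); counts >= 1.
#' @param distanceId which distance.
#' @param reference id of the reference distance (default "head").
#' @return numeric(1) formation ratio.
#' @export
formationRelativeSize <- function(counts, distanceId, reference = "head") {
    cc <- .correctedCounts(counts)
    if (!reference %in% cc$id) stop("reference distance '", reference,
                                    "' missing from counts")
    if (!distanceId %in% cc$id) stop("distance '", distanceId, "' missing")
    cc$corrected[cc$id == distanceId] / cc$corrected[cc$id == reference]
}

.correctedCounts <- function(counts) {
    if (!all(c("id", "count") %in% names(counts)))
        stop("counts need columns 'id' and 'count'")
    if (any(counts$count < 1)) stop("motif counts must be >= 1")
    ros <- if ("rosettes" %in% names(counts)) counts$rosettes else
        rep(FALSE, nrow(counts))
    data.frame(id = counts$id,
               corrected = applyRosetteCorrection(counts$count, ros)$corrected)
}

# invert a piecewise-linear trajectory rel(stage): earliest stage (possibly
# fractional) where rel equals the target; if the target is outside the
# observed range, the nearest endpoint is returned with extrapolated = TRUE
.invertTrajectory <- function(stage, rel, target) {
    n <- length(stage)
    if (target >= min(rel) && target <= max(rel)) {
        for (i in seq_len(n - 1L)) {
            lo <- min(rel[i], rel[i + 1]); hi <- max(rel[i], rel[i + 1])
            if (target >= lo && target <= hi) {
                if (rel[i + 1] == rel[i])
                    return(list(stage = stage[i], extrapolated = FALSE))
                t <- (target - rel[i]) / (rel[i + 1] - rel[i])
                return(list(stage = stage[i] + t * (stage[i + 1] - stage[i]),
                            extrapolated = FALSE))
            }
        }
    }
    best <- which.min(abs(rel - target))
    list(stage = stage[best], extrapolated = TRUE)
}

.interpAt <- function(stage, value, at) {
    stats::approx(stage, value, xout = at, rule = 2)$y
}

#' Estimate pattern-formation timing and wavelength (reverse method)
#'
#' For each measured body distance, finds the developmental stage at which
#' its relative size (relative to the reference distance, conventionally the
#' head) equals the formation ratio implied by the motif counts
#' (\code{\link{formationRelativeSize}}), interpolating linearly between
#' stages.  If the per-distance estimates converge to a common stage, that
#' stage is the end of pattern production; the wavelength then follows as
#' the absolute distance length at the estimated stage divided by the
#' corrected motif count.  Ratios outside the observed trajectory range are
#' flagged as extrapolated, not silently clipped.
#'
#' @param trajectories data.frame with columns \code{id}, \code{stage},
#'   \code{length} (absolute units), covering the reference and all counted
#'   distances over at least two stages.
#' @param counts data.frame with columns \code{id}, \code{count}, optional
#'   \code{rosettes}.
#' @param reference reference distance id, default "head".
#' @return a \linkS4class{TimingEstimate}.
#' @export
estimateTiming <- function(trajectories, counts, reference = "head") {
    for (nm in c("id", "stage", "length"))
        if (!nm %in% names(trajectories))
            stop("trajectories need column '", nm, "'")
    cc <- .correctedCounts(counts)
    if (!reference %in% cc$id) stop("reference count missing")
    ids <- setdiff(cc$id, reference)
    if (length(ids) < 2L) stop("need at least two non-reference distances")
    ref <- trajectories[trajectories$id == reference, ]
    if (nrow(ref) < 2L) stop("reference trajectory needs >= 2 stages")
    ref <- ref[order(ref$stage), ]
    refCount <- cc$corrected[cc$id == reference]

    rows <- lapply(ids, function(id) {
        tr <- trajectories[trajectories$id == id, ]
        if (nrow(tr) < 2L) stop("trajectory for '", id, "' needs >= 2 stages")
        tr <- tr[order(tr$stage), ]
        stages <- intersect(tr$stage, ref$stage)
        if (length(stages) < 2L)
            stop("trajectories for '", id, "' and the reference share < 2 stages")
        rel <- tr$length[match(stages, tr$stage)] /
            ref$length[match(stages, ref$stage)]
        ratio <- cc$corrected[cc$id == id] / refCount
        inv <- .invertTrajectory(stages, rel, ratio)
        len <- .interpAt(tr$stage, tr$length, inv$stage)
        data.frame(id = id, formationRatio = ratio,
                   stage = inv$stage, extrapolated = inv$extrapolated,
                   lengthAtStage = len,
                   correctedCount = cc$corrected[cc$id == id],
                   wavelength = len / cc$corrected[cc$id == id])
    })
    per <- do.call(rbind, rows)
    new("TimingEstimate",
        perDistance = per,
        consensusStage = stats::median(per$stage),
        stageIQR = unname(diff(stats::quantile(per$stage, c(0.25, 0.75)))),
        consensusWavelength = stats::median(per$wavelength),
        reference = reference)
}

setMethod("show", "TimingEstimate", function(object) {
    cat(sprintf("TimingEstimate over %d distances (reference '%s')\n",
                nrow(object@perDistance), object@reference))
    cat(sprintf("  consensus stage %.3g (IQR %.3g), wavelength %.4g\n",
                object@consensusStage, object@stageIQR,
                object@consensusWavelength))
    if (any(object@perDistance$extrapolated))
        cat("  note: ", sum(object@perDistance$extrapolated),
            "distance(s) extrapolated beyond the observed trajectory\n")
})

#' Through-origin proportionality fit of motif counts versus tissue size
#'
#' For a fixed parameter set and no growth, the equilibrium motif count is
#' proportional to tissue size.  Fits \code{N(S) = c S} by least squares
#' through the origin and reports the relative residuals.
#'
#' @param sizes numeric vector of tissue sizes (surface multiples).
#' @param counts numeric vector of equilibrium motif counts.
#' @return list with \code{slope}, \code{predict} (a function of S),
#'   \code{residuals} (relative, per point).
#' @examples
#' fit <- expectedMotifCount(c(1, 2), c(50, 100))
#' fit$slope           # 50
#' fit$predict(4)      # 200
#' @export
expectedMotifCount <- function(sizes, counts) {
    if (length(sizes) != length(counts)) stop("length mismatch")
    if (length(unique(sizes)) < 2L)
        stop("need counts at two or more distinct sizes")
    cc <- sum(sizes * counts) / sum(sizes^2)
    list(slope = cc,
         predict = function(S) cc * S,
         residuals = (counts - cc * sizes) / (cc * sizes))
}
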