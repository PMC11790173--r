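#' Seeded Gaussian-blob test image
#'
#' Generates \code{n} Gaussian blobs at rejection-sampled positions with a
#' minimum pairwise (toroidal-free, plain Euclidean) separation, on a zero
#' background.  The ground-truth centres are returned with the image, so
#' detector tests can assert exact counts.  Regenerating with the same
#' arguments is bit-identical.
#'
#' @param n number of blobs (0 gives a blank image).
#' @param gridDim integer(2) image shape.
#' @param minSeparation minimum centre-to-centre distance in pixels.
#' @param seed RNG seed.
#' @param sigma blob standard deviation in pixels.
#' @param amplitude peak height (all blobs equal by default; a vector
#'   recycles over blobs).
#' @param maxTries rejection-sampling budget before giving up.
#' @return list with \code{image} (numeric matrix) and \code{centers}
#'   (n x 2 matrix of row/column positions).
#' @examples
#' fx <- generateBlobImage(7, c(256, 256), 30, seed = 3)
#' countMotifs(fx$image)  # 7
#' @export
generateBlobImage <- function(n, gridDim = c(256L, 256L), minSeparation = 30,
                              seed = 1L, sigma = 5, amplitude = 1,
                              maxTries = 2000L) {
    gridDim <- as.integer(gridDim)
    img <- matrix(0, gridDim[1], gridDim[2])
    if (n == 0L)
        return(list(image = img, centers = matrix(numeric(0), 0, 2)))
    margin <- 3 * sigma
    if (gridDim[1] - 2 * margin < 1 || gridDim[2] - 2 * margin < 1)
        stop("blobs do not fit: grid too small for sigma")
    amplitude <- rep_len(amplitude, n)
    withr::with_seed(as.integer(seed), {
        centers <- matrix(NA_real_, n, 2)
        placed <- 0L
        tries <- 0L
        while (placed < n) {
            if ((tries <- tries + 1L) > maxTries)
                stop("could not place ", n, " blobs at separation ",
                     minSeparation, " after ", maxTries, " tries")
            cand <- c(stats::runif(1, margin, gridDim[1] - margin),
                      stats::runif(1, margin, gridDim[2] - margin))
            if (placed > 0L) {
                d <- sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                                   matrix(cand, placed, 2, byrow = TRUE))^2))
                if (any(d < minSeparation)) next
            }
            placed <- placed + 1L
            centers[placed, ] <- cand
        }
        ri <- row(img); ci <- col(img)
        for (k in seq_len(n)) {
            d2 <- (ri - centers[k, 1])^2 + (ci - centers[k, 2])^2
            img <- img + amplitude[k] * exp(-d2 / (2 * sigma^2))
        }
        list(image = img, centers = centers)
    })
}

#' Synthetic growth trajectories with a known formation stage
#'
#' Builds per-distance absolute-length trajectories and the matching motif
#' counts for parameter-recovery tests of \code{\link{estimateTiming}}.  At
#' the formation stage every distance's length is an exact integer multiple
#' of the wavelength, so the noiseless counts invert exactly: the estimator
#' must recover \code{formationStage} and \code{wavelength} to within
#' interpolation error.  Distances grow exponentially at per-distance rates
#' faster than the reference ("head"), giving monotone increasing relative
#' sizes.
#'
#' @param nDistances number of non-reference distances, >= 2.
#' @param stages integer vector of stage indices (>= 2 stages).
#' @param formationStage stage at which the pattern formed (must lie within
#'   \code{stages}).
#' @param wavelength pattern wavelength at formation, in length units.
#' @param countNoise multiplicative noise s.d. applied to the counts
#'   (0 = noiseless).
#' @param seed RNG seed.
#' @param refCount motif count along the reference distance.
#' @return list with \code{trajectories} (data.frame id/stage/length),
#'   \code{counts} (data.frame id/count/rosettes) and the true parameters.
#' @export
generateTrajectories <- function(nDistances = 5L, stages = 1:10,
                                 formationStage = 5, wavelength = 2,
                                 countNoise = 0, seed = 1L,
                                 refCount = 10L) {
    if (nDistances < 2L) stop("need >= 2 distances")
    if (formationStage < min(stages) || formationStage > max(stages))
        stop("'formationStage' must lie within 'stages'")
    withr::with_seed(as.integer(seed), {
        refLen0 <- refCount * wavelength
        refRate <- 0.03
        ids <- paste0("d", seq_len(nDistances))
        trueCounts <- refCount + seq_len(nDistances) * 4L
        rates <- refRate + 0.05 + 0.04 * stats::runif(nDistances)
        traj <- do.call(rbind, c(
            list(data.frame(id = "head", stage = stages,
                            length = refLen0 * exp(refRate * (stages - formationStage)))),
            lapply(seq_len(nDistances), function(k) {
                lenForm <- trueCounts[k] * wavelength
                data.frame(id = ids[k], stage = stages,
                           length = lenForm * exp(rates[k] * (stages - formationStage)))
            })))
        counts <- data.frame(id = c("head", ids),
                             count = c(refCount, trueCounts),
                             rosettes = FALSE)
        if (countNoise > 0)
            counts$count <- pmax(1, counts$count *
                                 (1 + stats::rnorm(nrow(counts), 0, countNoise)))
        if (wavelength > min(counts$count * wavelength))
            stop("wavelength exceeds the shortest formation-stage length")
        list(trajectories = traj, counts = counts,
             formationStage = formationStage, wavelength = wavelength)
    })
}

#' Synthetic landmark segment table
#'
#' Random segments on an image frame with growth factors drawn uniformly in
#' a range, for growth-map tests; the layout mimics a landmark panel spread
#' over a body outline.
#'
#' @param nSegments number of segments, default 22.
#' @param gridDim image shape the segments live on.
#' @param factorRange range of growth factors (uniform draw).
#' @param seed RNG seed.
#' @return data.frame with id, x1, y1, x2, y2, length_stage_a,
#'   length_stage_b and factor columns.
#' @export
generateSegmentTable <- function(nSegments = 22L, gridDim = c(200L, 200L),
                                 factorRange = c(1, 4), seed = 1L) {
    withr::with_seed(as.integer(seed), {
        x1 <- stats::runif(nSegments, 5, gridDim[2] - 5)
        y1 <- stats::runif(nSegments, 5, gridDim[1] - 5)
        ang <- stats::runif(nSegments, 0, 2 * pi)
        len <- stats::runif(nSegments, 10, 40)
        x2 <- pmin(gridDim[2] - 1, pmax(2, x1 + len * cos(ang)))
        y2 <- pmin(gridDim[1] - 1, pmax(2, y1 + len * sin(ang)))
        f <- stats::runif(nSegments, factorRange[1], factorRange[2])
        la <- stats::runif(nSegments, 20, 60)
        data.frame(id = paste0("seg", seq_len(nSegments)),
                   x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                   length_stage_a = la, length_stage_b = la * f,
                   factor = f)
    })
}

#' Synthetic survey record set
#'
#' Generates a record table with prescribed numbers of positive, maybe and
#' negative labels, for tally and annotation tests.
#'
#' @param nY,nM,nNq,nN counts of pgtcp labels Y, M, N?, N.
#' @param rank taxonomic rank string stored on every record.
#' @param seed RNG seed (shuffles record order).
#' @return data.frame of records.
#' @export
generateRecordSet <- function(nY = 5L, nM = 3L, nNq = 2L, nN = 10L,
                              rank = "order", seed = 1L) {
    n <- nY + nM + nNq + nN
    labels <- rep(c("Y", "M", "N?", "N"), c(nY, nM, nNq, nN))
    withr::with_seed(as.integer(seed), {
        labels <- sample(labels)
        data.frame(taxon = paste0("taxon_", seq_len(n)), rank = rank,
                   classic_label = sample(c("Y", "N"), n, replace = TRUE),
                   pgtcp_label = labels,
                   categories = ifelse(labels == "Y", "rosettes", ""),
                   motif_count_at_least_3 = labels == "Y",
                   based_on_preexisting_periodicity = FALSE,
                   stringsAsFactors = FALSE)
    })
}
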