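#' Binarize a greyscale image
#'
#' Produces a pure black-and-white {0,1} image: pixel = 1 iff its value
#' strictly exceeds the threshold.  The default threshold is the homogeneous
#' activator fixed point (4), appropriate for raw a-field snapshots; images
#' already scaled to [0,1] should pass e.g. \code{threshold = 0.5}.
#'
#' @param image numeric matrix.
#' @param threshold numeric(1).
#' @return numeric {0,1} matrix with attribute \code{"threshold"} recording
#'   the value used.
#' @export
binarizeImage <- function(image, threshold = 4) {
    if (!is.matrix(image) || !is.numeric(image))
        stop("'image' must be a numeric matrix")
    out <- (image > threshold) + 0
    attr(out, "threshold") <- threshold
    out
}

#' Count pattern motifs (Find-maxima analogue)
#'
#' Counts distinct motifs as local maxima whose prominence strictly exceeds
#' \code{noiseTolerance}; maxima connected at a level within the tolerance of
#' each other merge into a single motif.  This is the persistence-based
#' equivalent of the Fiji "Find maxima" detector.  On a binary {0,1} image
#' the count reduces exactly to the number of 8-connected foreground
#' components.  Deterministic.
#'
#' @param image numeric matrix (greyscale or binary).
#' @param noiseTolerance prominence threshold in the units of the image;
#'   default 10\% of the image value range.
#' @param periodic treat the image as periodic in both axes (appropriate for
#'   simulator snapshots, where motifs may straddle the wrap); default FALSE.
#' @param invert count minima instead of maxima (motifs darker than the
#'   background).
#' @return integer motif count (0 for an empty or flat image).
#' @examples
#' img <- matrix(0, 32, 32); img[8, 8] <- 1; img[24, 24] <- 1
#' countMotifs(img)  # 2
#' @export
countMotifs <- function(image, noiseTolerance = NULL, periodic = FALSE,
                        invert = FALSE) {
    if (!is.matrix(image) || !is.numeric(image))
        stop("'image' must be a numeric matrix")
    if (length(image) == 0L) return(0L)
    rng <- range(image)
    if (is.null(noiseTolerance)) noiseTolerance <- 0.1 * diff(rng)
    if (diff(rng) == 0) return(0L)
    if (invert) image <- rng[2] + rng[1] - image
    .count_motifs_cpp(image, noiseTolerance, periodic)
}

#' Centered 2D DFT magnitude spectrum
#'
#' Computes the two-dimensional discrete Fourier transform of the image and
#' returns the magnitude (modulus) of each frequency bin, with the (0,0)
#' frequency -- the image mean -- moved to the centre of the table.  The
#' output has the same shape as the input; distance from the centre is
#' frequency (short wavelengths far from the centre).
#'
#' @param image numeric matrix (typically a binarized pattern).
#' @return a \linkS4class{Spectrum} in state "raw".
#' @export
dftMagnitude <- function(image) {
    if (!is.matrix(image) || !is.numeric(image))
        stop("'image' must be a numeric matrix")
    mag <- Mod(stats::fft(image))
    new("Spectrum", magnitude = .fftshift2(mag), state = "raw")
}

# move the DC bin of an FFT table to position (floor(n/2)+1, floor(m/2)+1)
.fftshift2 <- function(x) {
    nr <- nrow(x); nc <- ncol(x)
    x[c(seq(floor(nr / 2) + 1L, nr), seq_len(floor(nr / 2))),
      c(seq(floor(nc / 2) + 1L, nc), seq_len(floor(nc / 2))), drop = FALSE]
}

#' Index of the DC (zero-frequency) bin of a centered spectrum
#' @param spec a \linkS4class{Spectrum}.
#' @return integer(2) row/column index.
#' @export
dcIndex <- function(spec) {
    d <- dim(spec@magnitude)
    floor(d / 2) + 1L
}

#' Post-process a magnitude spectrum
#'
#' Applies, in order: a log10 transform of the magnitudes (zero bins are
#' mapped to the smallest positive magnitude present before taking the log,
#' so they stay the minimum of the table); division by a maximum -- either
#' the spectrum's own or a supplied series maximum, so that several spectra
#' can share one normalization; and a threshold zeroing every bin below
#' \code{thresholdFraction} times the maximum (the published pipeline uses
#' 1/20 or 1/100).
#'
#' @param spec a \linkS4class{Spectrum} in state "raw" or "log10".
#' @param log apply log10 first.
#' @param normalizeBy "own_max", "series_max" or "none".
#' @param seriesMax the shared maximum when \code{normalizeBy =
#'   "series_max"} (see \code{\link{seriesMaximum}}).
#' @param thresholdFraction fraction in (0,1), or NA for no threshold.
#' @return a \linkS4class{Spectrum} in the resulting state.
#' @export
postprocessSpectrum <- function(spec, log = TRUE,
                                normalizeBy = c("own_max", "series_max", "none"),
                                seriesMax = NULL,
                                thresholdFraction = NA_real_) {
    stopifnot(is(spec, "Spectrum"))
    normalizeBy <- match.arg(normalizeBy)
    if (!is.na(thresholdFraction) &&
        (thresholdFraction <= 0 || thresholdFraction >= 1))
        stop("'thresholdFraction' must be in (0,1) or NA")
    m <- spec@magnitude
    state <- spec@state
    if (state %in% c("normalized", "thresholded"))
        stop("spectrum already normalized/thresholded")
    if (log && state == "raw") {
        pos <- m[m > 0]
        floorv <- if (length(pos)) min(pos) else 1
        m <- log10(pmax(m, floorv))
        # shift so the table minimum is 0 and magnitudes stay >= 0
        m <- m - min(m)
        state <- "log10"
    }
    ref <- NA_real_
    if (normalizeBy != "none") {
        ref <- if (normalizeBy == "own_max") max(m) else {
            if (is.null(seriesMax)) stop("'seriesMax' required for series_max")
            seriesMax
        }
        if (ref <= 0) stop("normalization maximum must be positive")
        m <- m / ref
        state <- "normalized"
    }
    if (!is.na(thresholdFraction)) {
        cutoff <- thresholdFraction * max(m)
        m[m < cutoff] <- 0
        state <- "thresholded"
    }
    new("Spectrum", magnitude = m, state = state, normRef = ref,
        thresholdFraction = thresholdFraction)
}

#' Shared maximum of a series of spectra
#'
#' Computes the maximum used to normalize a series of spectra jointly (the
#' published analyses normalize a series of pictures by the single largest
#' magnitude among them).  Spectra must be in comparable states.
#'
#' @param specs list of \linkS4class{Spectrum} objects.
#' @param log take the maximum after log10 processing (matching a later
#'   \code{postprocessSpectrum(log = TRUE)} call).
#' @return numeric(1).
#' @export
seriesMaximum <- function(specs, log = TRUE) {
    vals <- vapply(specs, function(sp) {
        m <- sp@magnitude
        if (log && sp@state == "raw") {
            pos <- m[m > 0]
            floorv <- if (length(pos)) min(pos) else 1
            m <- log10(pmax(m, floorv))
            m <- m - min(m)
        }
        max(m)
    }, numeric(1))
    max(vals)
}

#' Occupied radial frequency bands of a thresholded spectrum
#'
#' Partitions frequency space into \code{nBands} concentric annuli between
#' zero and the Nyquist radius and reports which annuli contain at least one
#' surviving (non-zero) bin, excluding the DC bin.  The "richness" score is
#' the fraction of occupied annuli.  Band sets let multi-periodicity claims
#' be tested as set inclusion: a pattern combining two stages' periodicities
#' should occupy (at least) the union of their bands.
#'
#' @param spec a thresholded \linkS4class{Spectrum}.
#' @param nBands number of annuli, >= 2.
#' @return list with integer vector \code{bands} (sorted, 1-based annulus
#'   indices) and numeric \code{richness}.
#' @export
radialBandSet <- function(spec, nBands = 10L) {
    stopifnot(is(spec, "Spectrum"))
    if (nBands < 2L) stop("'nBands' must be >= 2")
    m <- spec@magnitude
    d <- dim(m); ctr <- floor(d / 2) + 1L
    ri <- row(m) - ctr[1]; ci <- col(m) - ctr[2]
    # radius normalized by the Nyquist extent of each axis
    rad <- sqrt((ri / (d[1] / 2))^2 + (ci / (d[2] / 2))^2) / sqrt(2)
    band <- floor(rad * nBands) + 1L
    band[band > nBands] <- nBands
    occupied <- m > 0
    occupied[ctr[1], ctr[2]] <- FALSE  # DC is not a periodicity
    bands <- sort(unique(band[occupied]))
    list(bands = as.integer(bands), richness = length(bands) / nBands)
}

#' Radial symmetry of a spectrum
#'
#' Quantifies how circularly symmetric a spectrum is: bins are grouped into
#' radial annuli, and within each annulus the coefficient of variation of
#' the magnitudes across angles is computed; the summary is the
#' energy-weighted mean CV (0 = perfectly circular).
#'
#' @param spec a \linkS4class{Spectrum}.
#' @param nBands number of annuli.
#' @return numeric(1) mean angular coefficient of variation.
#' @export
radialSymmetryScore <- function(spec, nBands = 10L) {
    m <- spec@magnitude
    d <- dim(m); ctr <- floor(d / 2) + 1L
    ri <- row(m) - ctr[1]; ci <- col(m) - ctr[2]
    rad <- sqrt((ri / (d[1] / 2))^2 + (ci / (d[2] / 2))^2) / sqrt(2)
    band <- floor(rad * nBands) + 1L
    band[band > nBands] <- nBands
    band[ctr[1], ctr[2]] <- NA  # exclude DC
    cvs <- tapply(as.vector(m), as.vector(band), function(v) {
        if (mean(v) == 0) 0 else stats::sd(v) / mean(v)
    })
    ws <- tapply(as.vector(m), as.vector(band), sum)
    if (sum(ws) == 0) return(NA_real_)  # no off-DC energy
    sum(cvs * ws) / sum(ws)
}

setMethod("show", "Spectrum", function(object) {
    d <- dim(object@magnitude)
    cat(sprintf("Spectrum: %dx%d, state '%s'", d[1], d[2], object@state))
    if (!is.na(object@thresholdFraction))
        cat(sprintf(", threshold %.3g x max", object@thresholdFraction))
    cat(sprintf(", max %.4g\n", max(object@magnitude)))
})
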