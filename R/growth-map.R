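#' Per-segment growth factors from two stage tables
#'
#' For each landmark-delimited body segment measured at two developmental
#' stages, the growth factor is the relative increase in length,
#' \code{length_b / length_a}.
#'
#' @param lengthsA,lengthsB data.frames with columns \code{id} and
#'   \code{length} (early and late stage); the same segment ids must appear
#'   in both.
#' @return data.frame with columns \code{id} and \code{factor}.
#' @examples
#' a <- data.frame(id = "trunk", length = 10)
#' b <- data.frame(id = "trunk", length = 25)
#' segmentGrowthFactors(a, b)$factor  # 2.5
#' @export
segmentGrowthFactors <- function(lengthsA, lengthsB) {
    for (nm in c("id", "length"))
        if (!nm %in% names(lengthsA) || !nm %in% names(lengthsB))
            stop("both tables need columns 'id' and 'length'")
    missing <- setdiff(lengthsA$id, lengthsB$id)
    if (length(missing) || nrow(lengthsA) != nrow(lengthsB))
        stop("segment ids differ between stages: ",
             paste(c(missing, setdiff(lengthsB$id, lengthsA$id)), collapse = ", "))
    m <- match(lengthsA$id, lengthsB$id)
    bad <- lengthsA$length <= 0 | lengthsB$length[m] <= 0 |
        !is.finite(lengthsA$length) | !is.finite(lengthsB$length[m])
    if (any(bad))
        stop("non-positive or missing length for segment(s): ",
             paste(lengthsA$id[bad], collapse = ", "))
    data.frame(id = lengthsA$id,
               factor = lengthsB$length[m] / lengthsA$length)
}

# Euclidean distance from each pixel centre to a segment (x1,y1)-(x2,y2).
# Pixel coordinates: x = column index, y = row index (image frame).
.pointSegmentDistance <- function(px, py, x1, y1, x2, y2) {
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx * vx + vy * vy
    if (L2 == 0) stop("segment endpoints coincide")
    t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / L2))
    sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

#' Interpolate a per-pixel growth map from segments
#'
#' Each pixel receives the inverse-squared-distance weighted mean of the
#' segment growth factors:
#' \deqn{gf(p) = \frac{\sum_i gf_i / d(p, seg_i)^2}{\sum_i 1 / d(p, seg_i)^2}}
#' with \eqn{d} the Euclidean point-to-segment distance.  Distances are
#' floored at \code{eps} pixels to keep the weights finite, so pixels on a
#' segment take (approach) that segment's factor.  The result is bounded by
#' the range of the input factors and linear in them.
#'
#' @param segments data.frame with columns \code{x1,y1,x2,y2,factor} (and
#'   optionally \code{id}); coordinates in pixels, image frame.
#' @param gridDim integer(2), output map shape (rows, columns).
#' @param eps minimum distance in pixels, default 0.5.
#' @return a \linkS4class{GrowthMap}.
#' @export
interpolateGrowthMap <- function(segments, gridDim, eps = 0.5) {
    if (NROW(segments) < 1L) stop("need at least one segment")
    for (nm in c("x1", "y1", "x2", "y2", "factor"))
        if (!nm %in% names(segments)) stop("segments need column '", nm, "'")
    if (any(segments$factor <= 0)) stop("growth factors must be positive")
    nr <- as.integer(gridDim[1]); nc <- as.integer(gridDim[2])
    px <- as.vector(col(matrix(0, nr, nc)))
    py <- as.vector(row(matrix(0, nr, nc)))
    num <- den <- numeric(nr * nc)
    for (i in seq_len(nrow(segments))) {
        d <- .pointSegmentDistance(px, py, segments$x1[i], segments$y1[i],
                                   segments$x2[i], segments$y2[i])
        w <- 1 / pmax(d, eps)^2
        num <- num + segments$factor[i] * w
        den <- den + w
    }
    vals <- matrix(num / den, nr, nc)
    new("GrowthMap", values = vals, segments = as.data.frame(segments))
}

#' @describeIn interpolateGrowthMap matrix of interpolated values
#' @param map a \code{GrowthMap}
#' @export
growthValues <- function(map) map@values

setMethod("show", "GrowthMap", function(object) {
    cat(sprintf("GrowthMap: %dx%d from %d segments, values in [%.3g, %.3g]\n",
                nrow(object@values), ncol(object@values),
                nrow(object@segments), min(object@values), max(object@values)))
})

#' Growth contrast between mask regions
#'
#' Compares interpolated growth inside and outside a pattern-occurrence
#' mask: mean growth factor in each region, their ratio, and the
#' point-biserial correlation between per-pixel growth and mask membership.
#' A positive correlation means the pattern sits preferentially on
#' high-growth tissue.
#'
#' @param map a \linkS4class{GrowthMap}.
#' @param mask numeric or logical matrix of the same shape; non-zero marks
#'   pattern presence.
#' @return list with \code{meanInside}, \code{meanOutside}, \code{ratio} and
#'   \code{correlation}.  A constant map gives correlation 0; an empty or
#'   full mask gives NA means/ratio with a warning.
#' @export
regionGrowthContrast <- function(map, mask) {
    v <- map@values
    if (!identical(dim(v), dim(mask)))
        stop("map and mask shapes differ")
    m <- mask != 0
    if (all(m) || !any(m)) {
        warning("degenerate mask (empty or full): ratio undefined")
        return(list(meanInside = if (any(m)) mean(v[m]) else NA_real_,
                    meanOutside = if (!all(m)) mean(v[!m]) else NA_real_,
                    ratio = NA_real_, correlation = NA_real_))
    }
    mi <- mean(v[m]); mo <- mean(v[!m])
    corr <- if (stats::sd(v) == 0) 0 else stats::cor(as.vector(v), as.vector(m))
    list(meanInside = mi, meanOutside = mo, ratio = mi / mo,
         correlation = corr)
}

#' Read a segment table from CSV
#'
#' Expected columns: \code{id, x1, y1, x2, y2} and either \code{factor} or
#' the pair \code{length_stage_a, length_stage_b} from which factors are
#' computed.
#'
#' @param path CSV file.
#' @return data.frame with a \code{factor} column.
#' @export
readSegmentsCSV <- function(path) {
    d <- utils::read.csv(path)
    if (!"factor" %in% names(d)) {
        if (!all(c("length_stage_a", "length_stage_b") %in% names(d)))
            stop("need 'factor' or 'length_stage_a'/'length_stage_b' columns")
        d$factor <- d$length_stage_b / d$length_stage_a
    }
    d
}
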