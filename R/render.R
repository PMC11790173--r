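#' Built-in rendering palettes
#'
#' \code{"leopard"} maps low activator to dark brown and high activator to
#' light yellow; \code{"emu"} to dark grey-brown vs cream; \code{"grey"} to
#' black vs white.  Thresholds sit between the two equilibrium phases of the
#' activator field for the matching parameter set: the spot-forming set
#' (s = 6, r = 30) settles in [2.1, 3.7] (threshold 3, also used by "grey"),
#' the stripe-forming set (s = 10, r = 6) in [3.3, 4.4] (threshold 3.85).
#' Both lie below/around the homogeneous fixed point, which is unstable once
#' a pattern forms.
#'
#' @param name palette name.
#' @return a \linkS4class{PatternPalette}.
#' @export
patternPalette <- function(name = c("leopard", "emu", "grey")) {
    name <- match.arg(name)
    switch(name,
        leopard = new("PatternPalette", dark = c(0.18, 0.09, 0.02),
                      light = c(0.95, 0.82, 0.45), theta = 3),
        emu = new("PatternPalette", dark = c(0.15, 0.12, 0.10),
                  light = c(0.93, 0.89, 0.80), theta = 3.85),
        grey = new("PatternPalette", dark = c(0, 0, 0),
                   light = c(1, 1, 1), theta = 3))
}

#' Render one snapshot instantaneously
#'
#' Colours each pixel from the current activator value only ("real-time"
#' readout).  In threshold mode each pixel is exactly the dark or the light
#' colour depending on whether a exceeds the palette threshold; in continuous
#' mode the colour interpolates linearly between dark and light by
#' \code{(a - minA)/(maxA - minA)}, so a system out of equilibrium shows
#' intermediate colours.
#'
#' @param a numeric matrix, an activator snapshot.
#' @param palette a \linkS4class{PatternPalette}.
#' @param mode "threshold" or "continuous".
#' @param minA,maxA the activator range used for continuous interpolation.
#' @return numeric array height x width x 3, channels in [0,1].
#' @export
renderInstant <- function(a, palette = patternPalette("grey"),
                          mode = c("threshold", "continuous"),
                          minA = 0, maxA = 4.4) {
    mode <- match.arg(mode)
    validObject(palette)
    if (any(!is.finite(a))) stop("'a' contains non-finite values")
    if (mode == "threshold") {
        w <- (a > palette@theta) + 0
    } else {
        w <- pmin(1, pmax(0, (a - minA) / (maxA - minA)))
    }
    out <- array(0, c(dim(a), 3L))
    for (ch in 1:3)
        out[, , ch] <- palette@dark[ch] * (1 - w) + palette@light[ch] * w
    out
}

#' Render a history through the memory mechanism
#'
#' The memory colouration rule: each pixel's final colour is the arithmetic
#' mean over all recorded snapshots of its threshold-mode instantaneous
#' colour.  Pixels dark throughout stay dark, pixels light throughout stay
#' light, and pixels whose state changed during patterning take intermediate
#' colours -- the mechanism behind rosette centres and intermediate bands.
#'
#' Averaging weights are uniform over snapshots, so the snapshot cadence of
#' the history determines the time resolution of the average.
#'
#' @param history a \linkS4class{SimulationHistory} (non-empty).
#' @param palette a \linkS4class{PatternPalette}.
#' @param from "start" averages every snapshot (default); "growth" restricts
#'   the average to snapshots at or after the growth start iteration.
#' @return numeric array height x width x 3, channels in [0,1].
#' @export
renderMemory <- function(history, palette = patternPalette("grey"),
                         from = c("start", "growth")) {
    from <- match.arg(from)
    if (length(history) == 0L) stop("empty history")
    idx <- seq_along(history@iterations)
    if (from == "growth")
        idx <- idx[history@iterations >= history@config@growth@tStart]
    if (length(idx) == 0L) stop("no snapshots in the requested window")
    acc <- matrix(0, nrow(history@aFields[[1]]), ncol(history@aFields[[1]]))
    for (i in idx) acc <- acc + (history@aFields[[i]] > palette@theta)
    w <- acc / length(idx)
    out <- array(0, c(dim(w), 3L))
    for (ch in 1:3)
        out[, , ch] <- palette@dark[ch] * (1 - w) + palette@light[ch] * w
    out
}

#' Write a rendered colour field (or greyscale matrix) as PNG
#'
#' Matrices are linearly mapped to [0,1] over the given range before writing;
#' 3-channel arrays are written as-is.
#'
#' @param x numeric matrix or height x width x 3 array in [0,1].
#' @param path output file.
#' @param range value range mapped to black..white for matrix input; default
#'   the activator clamps [0, 4.4].
#' @return the path, invisibly.
#' @export
writeImagePNG <- function(x, path, range = c(0, 4.4)) {
    if (is.matrix(x)) {
        span <- max(diff(range), .Machine$double.eps)
        x[] <- pmin(1, pmax(0, (x - range[1]) / span))
        attributes(x) <- list(dim = dim(x))
    }
    png::writePNG(x, path)
    invisible(path)
}

#' Read a greyscale image from PNG
#'
#' Multi-channel images are averaged to one grey channel.
#'
#' @param path PNG file.
#' @return numeric matrix in [0,1].
#' @export
readImagePNG <- function(path) {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE],
                                         c(1, 2), mean)
    x
}
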