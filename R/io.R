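#' Read or write a simulation configuration file
#'
#' Configurations serialize to YAML (or JSON) with fields mirroring
#' \linkS4class{SimulationConfig}; either a \code{preset} name plus
#' overrides, or the full field set.
#'
#' @param path YAML or JSON file.
#' @param config a \linkS4class{SimulationConfig}.
#' @return \code{readSimulationConfig}: a \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
    x <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (!is.null(x$preset)) {
        args <- x[names(x) %in% c("gridDim", "totalIters", "maxSurface",
                                  "seed", "snapshotEvery", "dilution")]
        cfg <- do.call(presetConfig, c(list(name = x$preset), args))
        return(cfg)
    }
    rp <- new("ReactionParams")
    for (nm in intersect(names(x), slotNames("ReactionParams")))
        slot(rp, nm) <- as.numeric(x[[nm]])
    gsd <- new("GrowthSchedule")
    if (!is.null(x$g)) gsd@g <- as.numeric(x$g)
    if (!is.null(x$tStart)) gsd@tStart <- as.integer(x$tStart)
    if (!is.null(x$maxSurface)) gsd@maxSurface <- as.numeric(x$maxSurface)
    if (!is.null(x$anisotropy)) gsd@anisotropy <- as.numeric(x$anisotropy)
    cfg <- new("SimulationConfig", reaction = rp, growth = gsd)
    if (!is.null(x$gridDim)) cfg@gridDim <- as.integer(x$gridDim)
    if (!is.null(x$init)) cfg@init <- x$init
    if (!is.null(x$initNoise)) cfg@initNoise <- as.numeric(x$initNoise)
    if (!is.null(x$stripes)) cfg@stripes <- as.integer(x$stripes)
    if (!is.null(x$totalIters)) cfg@totalIters <- as.integer(x$totalIters)
    if (!is.null(x$snapshotEvery)) cfg@snapshotEvery <- as.integer(x$snapshotEvery)
    if (!is.null(x$seed)) cfg@seed <- as.integer(x$seed)
    if (!is.null(x$dilution)) cfg@dilution <- as.logical(x$dilution)
    if (!is.null(x$dGrowthExponent))
        cfg@dGrowthExponent <- as.numeric(x$dGrowthExponent)
    validObject(cfg)
    cfg
}

#' @rdname readSimulationConfig
#' @export
writeSimulationConfig <- function(config, path) {
    rp <- config@reaction; gs <- config@growth
    x <- list(s = rp@s, r = rp@r, d0 = rp@d0, dt = rp@dt,
              minA = rp@minA, maxA = rp@maxA, minB = rp@minB, maxB = rp@maxB,
              g = gs@g, tStart = gs@tStart, maxSurface = gs@maxSurface,
              gridDim = config@gridDim, init = config@init,
              initNoise = config@initNoise, stripes = config@stripes,
              totalIters = config@totalIters,
              snapshotEvery = config@snapshotEvery, seed = config@seed,
              dilution = config@dilution,
              dGrowthExponent = config@dGrowthExponent)
    if (length(gs@anisotropy)) x$anisotropy <- gs@anisotropy
    yaml::write_yaml(x, path)
    invisible(path)
}

#' Export a simulation history to disk
#'
#' Writes each recorded a-field as a greyscale PNG (linearly mapped from the
#' activator clamps) plus a JSON manifest recording, per snapshot, the
#' iteration, surface multiple, diffusion multiplier and file name, together
#' with the configuration used -- enough to reproduce or re-render the run.
#'
#' @param history a \linkS4class{SimulationHistory}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the manifest path, invisibly.
#' @export
exportHistory <- function(history, dir, prefix = "snapshot") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rp <- history@config@reaction
    files <- vapply(seq_along(history@iterations), function(i) {
        f <- sprintf("%s_%06d.png", prefix, history@iterations[i])
        writeImagePNG(history@aFields[[i]], file.path(dir, f),
                      range = c(rp@minA, rp@maxA))
        f
    }, character(1))
    manifest <- list(
        snapshots = data.frame(iteration = history@iterations,
                               surface = history@surface,
                               d = history@d, file = files),
        growthEndIter = history@growthEndIter,
        finalSurface = history@finalSurface,
        config = jsonlite::fromJSON(jsonlite::toJSON(
            list(gridDim = history@config@gridDim,
                 init = history@config@init, seed = history@config@seed,
                 s = rp@s, r = rp@r, dt = rp@dt,
                 g = history@config@growth@g,
                 tStart = history@config@growth@tStart,
                 maxSurface = history@config@growth@maxSurface,
                 snapshotEvery = history@config@snapshotEvery,
                 dilution = history@config@dilution), auto_unbox = TRUE)))
    mp <- file.path(dir, paste0(prefix, "_manifest.json"))
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    invisible(mp)
}

#' Export a spectrum as CSV and/or PNG
#'
#' The CSV is the plain magnitude table (row = image row); the PNG maps the
#' magnitudes linearly to 8-bit grey over their range.
#'
#' @param spec a \linkS4class{Spectrum}.
#' @param csv,png output paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
exportSpectrum <- function(spec, csv = NULL, png = NULL) {
    out <- character()
    if (!is.null(csv)) {
        utils::write.csv(spec@magnitude, csv, row.names = FALSE)
        out <- c(out, csv)
    }
    if (!is.null(png)) {
        writeImagePNG(spec@magnitude, png, range = range(spec@magnitude))
        out <- c(out, png)
    }
    invisible(out)
}

#' Export a growth map as CSV and/or colour-mapped PNG
#'
#' @param map a \linkS4class{GrowthMap}.
#' @param csv,png output paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
exportGrowthMap <- function(map, csv = NULL, png = NULL) {
    out <- character()
    if (!is.null(csv)) {
        utils::write.csv(map@values, csv, row.names = FALSE)
        out <- c(out, csv)
    }
    if (!is.null(png)) {
        v <- map@values
        w <- (v - min(v)) / max(diff(range(v)), .Machine$double.eps)
        img <- array(0, c(dim(v), 3))  # blue (low growth) to red (high)
        img[, , 1] <- w
        img[, , 3] <- 1 - w
        img[, , 2] <- 0.2
        png::writePNG(img, png)
        out <- c(out, png)
    }
    invisible(out)
}
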