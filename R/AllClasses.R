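#' @import methods
NULL

#' Reaction parameters of the growth-coupled Turing system
#'
#' Holds the reaction/diffusion constants of the two-morphogen
#' activator--inhibitor system: the scale parameter \code{s}, the ratio
#' parameter \code{r}, the initial diffusion multiplier \code{d0} (state that
#' decays as the tissue grows), the time step \code{dt}, and the element-wise
#' clamps applied to the two fields after every step.  The homogeneous fixed
#' point of the reaction terms is (a, b) = (4, 4).
#'
#' @slot s numeric(1), scale parameter (dimensionless), > 0.
#' @slot r numeric(1), ratio parameter (dimensionless), > 0.
#' @slot d0 numeric(1), initial diffusion multiplier, > 0.  Any constant can be
#'   absorbed into \code{s*r}; the default 1 is the baseline the presets assume.
#' @slot dt numeric(1), integration time step, default 0.002.
#' @slot minA,maxA numeric(1), clamps on the a-field (defaults 0 and 4.4).
#' @slot minB,maxB numeric(1), clamps on the b-field (defaults 3.5 and 100).
#' @export
setClass("ReactionParams",
    representation(s = "numeric", r = "numeric", d0 = "numeric", dt = "numeric",
                   minA = "numeric", maxA = "numeric",
                   minB = "numeric", maxB = "numeric"),
    prototype(s = 6, r = 30, d0 = 1, dt = 0.002,
              minA = 0, maxA = 4.4, minB = 3.5, maxB = 100))

setValidity("ReactionParams", function(object) {
    msg <- character()
    for (nm in c("s", "r", "d0", "dt"))
        if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)) ||
            slot(object, nm) <= 0)
            msg <- c(msg, sprintf("'%s' must be a single positive number", nm))
    if (length(msg) == 0L) {
        if (object@minA >= object@maxA) msg <- c(msg, "minA must be < maxA")
        if (object@minB >= object@maxB) msg <- c(msg, "minB must be < maxB")
    }
    if (length(msg)) msg else TRUE
})

#' Growth schedule of the simulated tissue
#'
#' Growth is exponential at constant rate: while active, the surface is
#' multiplied by (1 + g*dt) each iteration.  It is inactive before iteration
#' \code{tStart} and stops once the surface has reached \code{maxSurface}
#' times its initial value; remaining iterations let the pattern relax.  An
#' optional anisotropic pair (gx, gy) splits the rate over the two axes; the
#' combined surface rate then satisfies (1+gx*dt)(1+gy*dt) = 1+g*dt.
#'
#' @slot g numeric(1), surface growth rate per unit time, >= 0.
#' @slot tStart integer(1), iteration at which growth begins.
#' @slot maxSurface numeric(1), final surface as a multiple of the initial
#'   surface (>= 1), e.g. 1/0.4 = 2.5.
#' @slot anisotropy numeric(2) axis rates (gx, gy), or numeric(0) for
#'   isotropic growth.
#' @export
setClass("GrowthSchedule",
    representation(g = "numeric", tStart = "integer", maxSurface = "numeric",
                   anisotropy = "numeric"),
    prototype(g = 0.05, tStart = 10000L, maxSurface = 2.5,
              anisotropy = numeric(0)))

setValidity("GrowthSchedule", function(object) {
    msg <- character()
    if (length(object@g) != 1L || object@g < 0)
        msg <- c(msg, "'g' must be a single number >= 0")
    if (length(object@tStart) != 1L || object@tStart < 0L)
        msg <- c(msg, "'tStart' must be a single integer >= 0")
    if (length(object@maxSurface) != 1L || object@maxSurface < 1)
        msg <- c(msg, "'maxSurface' must be >= 1")
    if (!length(object@anisotropy) %in% c(0L, 2L))
        msg <- c(msg, "'anisotropy' must be empty or a pair (gx, gy)")
    if (length(object@anisotropy) == 2L && any(object@anisotropy < 0))
        msg <- c(msg, "anisotropic rates must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Full configuration of a pattern simulation
#'
#' Bundles reaction parameters, growth schedule, grid shape, initial
#' condition, iteration count, snapshot cadence and random seed.  The five
#' named presets (see \code{\link{presetConfig}}) reproduce the published
#' parameter table for the leopard, emu, Pomacanthus, Ictidomys and Tetraodon
#' scenarios.
#'
#' @slot reaction a \linkS4class{ReactionParams}.
#' @slot growth a \linkS4class{GrowthSchedule}.
#' @slot gridDim integer(2), grid rows and columns.
#' @slot init character(1), one of "random_noise", "middle_stripe",
#'   "periodic_stripes".
#' @slot initNoise numeric(1), amplitude of the uniform perturbation applied
#'   to the initial fields.
#' @slot stripes integer(1), number of stripes for "periodic_stripes".
#' @slot totalIters integer(1), number of iterations to run.
#' @slot snapshotEvery integer(1), snapshot cadence in iterations.
#' @slot seed integer(1), RNG seed for the initial condition.
#' @slot dilution logical(1), whether growth dilutes morphogen concentrations
#'   (division by the per-step surface factor).
#' @slot dGrowthExponent numeric(1), exponent of the per-step decay of the
#'   diffusion multiplier: d is divided by the per-step surface factor raised
#'   to this power, so 1 keeps d = 1/S(t) (default), 0 disables the coupling
#'   (dilution-only reading), 2 gives the steeper d = 1/S(t)^2 reading.
#' @export
setClass("SimulationConfig",
    representation(reaction = "ReactionParams", growth = "GrowthSchedule",
                   gridDim = "integer", init = "character",
                   initNoise = "numeric", stripes = "integer",
                   totalIters = "integer", snapshotEvery = "integer",
                   seed = "integer", dilution = "logical",
                   dGrowthExponent = "numeric"),
    prototype(reaction = new("ReactionParams"), growth = new("GrowthSchedule"),
              gridDim = c(200L, 200L), init = "random_noise",
              initNoise = 0.5, stripes = 5L,
              totalIters = 30000L, snapshotEvery = 250L, seed = 1L,
              dilution = TRUE, dGrowthExponent = 1))

.initKinds <- c("random_noise", "middle_stripe", "periodic_stripes")

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (length(object@gridDim) != 2L || any(object@gridDim < 3L))
        msg <- c(msg, "'gridDim' must be two integers >= 3")
    if (!(length(object@init) == 1L && object@init %in% .initKinds))
        msg <- c(msg, paste0("'init' must be one of: ",
                             paste(.initKinds, collapse = ", ")))
    if (object@totalIters < 1L)
        msg <- c(msg, "'totalIters' must be >= 1")
    if (object@snapshotEvery < 1L)
        msg <- c(msg, "'snapshotEvery' must be >= 1")
    if (object@initNoise < 0)
        msg <- c(msg, "'initNoise' must be >= 0")
    if (!object@dGrowthExponent %in% c(0, 1, 2))
        msg <- c(msg, "'dGrowthExponent' must be 0, 1 or 2")
    if (length(msg)) msg else TRUE
})

#' History of a pattern simulation
#'
#' An ordered sequence of snapshots of the two morphogen fields together with
#' the surface multiple and effective diffusion multiplier at each recorded
#' iteration, plus the configuration that produced it.
#'
#' @slot iterations integer vector of recorded iteration indices (strictly
#'   increasing).
#' @slot surface numeric vector, surface multiple S(t) at each snapshot.
#' @slot d numeric vector, effective diffusion multiplier at each snapshot.
#' @slot aFields,bFields lists of numeric matrices, the recorded fields.
#' @slot growthEndIter integer(1), iteration at which the surface first
#'   reached its maximum (NA if growth never completed or never ran).
#' @slot finalSurface numeric(1), surface multiple at the last iteration.
#' @slot config the \linkS4class{SimulationConfig} used.
#' @export
setClass("SimulationHistory",
    representation(iterations = "integer", surface = "numeric", d = "numeric",
                   aFields = "list", bFields = "list",
                   growthEndIter = "integer", finalSurface = "numeric",
                   config = "SimulationConfig"))

setValidity("SimulationHistory", function(object) {
    msg <- character()
    k <- length(object@iterations)
    if (length(object@aFields) != k || length(object@bFields) != k ||
        length(object@surface) != k)
        msg <- c(msg, "snapshot vectors/lists must have equal length")
    if (k > 1L && any(diff(object@iterations) <= 0L))
        msg <- c(msg, "iteration indices must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Two-colour palette for pattern rendering
#'
#' Maps activator values to colours: in threshold mode each pixel is either
#' \code{dark} (a below \code{theta}) or \code{light}; in continuous mode the
#' colour interpolates linearly between the two endpoints over [minA, maxA].
#'
#' @slot dark,light numeric(3) RGB in [0,1].
#' @slot theta numeric(1), activator threshold for binary readout.
#' @export
setClass("PatternPalette",
    representation(dark = "numeric", light = "numeric", theta = "numeric"),
    prototype(dark = c(0.1, 0.05, 0), light = c(0.95, 0.82, 0.45), theta = 3))

setValidity("PatternPalette", function(object) {
    msg <- character()
    if (length(object@dark) != 3L || length(object@light) != 3L ||
        any(c(object@dark, object@light) < 0) ||
        any(c(object@dark, object@light) > 1))
        msg <- c(msg, "'dark' and 'light' must be RGB triples in [0,1]")
    if (length(object@theta) != 1L || !is.finite(object@theta))
        msg <- c(msg, "'theta' must be a single finite number")
    if (length(msg)) msg else TRUE
})

#' Centered 2D DFT magnitude spectrum
#'
#' The magnitude of the two-dimensional discrete Fourier transform of an
#' image, with the zero-frequency (image mean) bin moved to the centre, plus
#' the record of which post-processing steps (log10, normalization,
#' thresholding) have been applied.
#'
#' @slot magnitude numeric matrix of magnitudes (same shape as the source
#'   image), DC centered.
#' @slot state character(1): "raw", "log10", "normalized" or "thresholded".
#' @slot normRef numeric(1), the maximum used for normalization (NA before
#'   normalization); may come from a series of spectra.
#' @slot thresholdFraction numeric(1), fraction of the maximum below which
#'   bins were zeroed (NA if not thresholded).
#' @export
setClass("Spectrum",
    representation(magnitude = "matrix", state = "character",
                   normRef = "numeric", thresholdFraction = "numeric"),
    prototype(state = "raw", normRef = NA_real_,
              thresholdFraction = NA_real_))

setValidity("Spectrum", function(object) {
    msg <- character()
    if (!object@state %in% c("raw", "log10", "normalized", "thresholded"))
        msg <- c(msg, "unknown spectrum state")
    if (object@state == "raw" && any(object@magnitude < 0))
        msg <- c(msg, "raw magnitudes must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Per-pixel tissue growth map
#'
#' Scalar growth factors interpolated over an image grid from segment-level
#' measurements by inverse-squared-distance weighting.
#'
#' @slot values numeric matrix of interpolated growth factors.
#' @slot segments data.frame of source segments (id, x1, y1, x2, y2, factor).
#' @export
setClass("GrowthMap",
    representation(values = "matrix", segments = "data.frame"))

setValidity("GrowthMap", function(object) {
    rng <- range(object@segments$factor)
    v <- object@values
    if (any(v < rng[1] - 1e-9) || any(v > rng[2] + 1e-9))
        "interpolated values must lie within the range of the segment factors"
    else TRUE
})

#' Pattern-formation timing estimate
#'
#' Result of the reverse method: for each measured body distance, the
#' developmental stage at which the observed motif-count ratio matches the
#' relative-size trajectory, plus the wavelength implied by the absolute
#' length at that stage, and consensus summaries across distances.
#'
#' @slot perDistance data.frame with one row per non-reference distance:
#'   distance id, formation ratio, estimated stage, extrapolated flag,
#'   interpolated absolute length, corrected motif count, wavelength.
#' @slot consensusStage numeric(1), median estimated stage.
#' @slot stageIQR numeric(1), interquartile range of the estimated stages.
#' @slot consensusWavelength numeric(1), median per-distance wavelength.
#' @slot reference character(1), id of the reference distance.
#' @export
setClass("TimingEstimate",
    representation(perDistance = "data.frame", consensusStage = "numeric",
                   stageIQR = "numeric", consensusWavelength = "numeric",
                   reference = "character"))

#' Delta calibration report
#'
#' Summary of the motif-count deficit ("delta") between growth simulations and
#' the proportional no-growth expectation, across a grid of growth rates and
#' final sizes.
#'
#' @slot runs data.frame with one row per (rate, final size, seed) simulation.
#' @slot scenarios data.frame aggregated over seeds per (rate, final size).
#' @slot baseline data.frame of the no-growth runs used for the
#'   proportionality fit.
#' @slot slope numeric(1), the through-origin motifs-per-unit-size slope c.
#' @slot correction numeric(1), recommended counting correction (mean final
#'   delta over scenarios that formed growth patterns), in percent.
#' @slot correctionSpread numeric(2), range of per-scenario mean final deltas.
#' @export
setClass("DeltaReport",
    representation(runs = "data.frame", scenarios = "data.frame",
                   baseline = "data.frame", slope = "numeric",
                   correction = "numeric", correctionSpread = "numeric"))
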