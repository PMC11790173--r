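#' Nine-point discrete Laplacian with periodic wrap
#'
#' Applies the standard nine-point stencil over a Moore neighbourhood,
#' weights \code{[[1,4,1],[4,-20,4],[1,4,1]]/6}, with both pairs of opposite
#' borders connected (torus topology).  Because the weights sum to zero and
#' the wrap loses nothing, the grid sum of the result is zero up to roundoff.
#'
#' @param field numeric matrix, at least 3x3.
#' @return numeric matrix of the same shape.
#' @examples
#' x <- matrix(0, 5, 5); x[3, 3] <- 6
#' laplacian9(x)[3, 3]  # -20
#' @export
laplacian9 <- function(field) {
    if (!is.matrix(field) || !is.numeric(field))
        stop("'field' must be a numeric matrix")
    if (any(!is.finite(field)))
        stop("'field' contains non-finite values")
    .laplacian9_cpp(field)
}

#' Build an initial condition for the pattern simulator
#'
#' Three kinds are supported, matching the published scenario table:
#' \describe{
#'   \item{random_noise}{both fields uniformly perturbed around the
#'     homogeneous fixed point (4, 4), amplitude \code{noise}.}
#'   \item{middle_stripe}{one activator stripe (a = maxA) centered on the
#'     middle column over a homogeneous (4, 4) background.}
#'   \item{periodic_stripes}{\code{stripes} evenly spaced parallel activator
#'     stripes.}
#' }
#' Stripe kinds also receive a small perturbation (amplitude \code{noise},
#' default 0.05) so that growth can break the translational symmetry along
#' the stripes, as required for line-and-dots formation; set \code{noise = 0}
#' for a strictly deterministic field.
#'
#' @param kind one of "random_noise", "middle_stripe", "periodic_stripes".
#' @param gridDim integer(2), grid shape (rows, columns), each >= 3.
#' @param seed integer RNG seed; the same (kind, gridDim, seed, ...) always
#'   reproduces the same fields bit for bit.
#' @param noise perturbation amplitude; default 0.5 for random_noise and
#'   0.05 for the stripe kinds.
#' @param stripes number of stripes for "periodic_stripes".
#' @param stripeWidth stripe width in pixels; default max(3, 5\% of width).
#' @param maxA activator clamp used as the stripe level.
#' @return list with numeric matrices \code{a} and \code{b}.
#' @export
makeInitialCondition <- function(kind = .initKinds, gridDim = c(200L, 200L),
                                 seed = 1L, noise = NULL, stripes = 5L,
                                 stripeWidth = NULL, maxA = 4.4) {
    kind <- match.arg(kind)
    gridDim <- as.integer(gridDim)
    if (length(gridDim) != 2L || any(gridDim < 3L))
        stop("'gridDim' must be two integers >= 3")
    nr <- gridDim[1]; nc <- gridDim[2]
    if (is.null(noise)) noise <- if (kind == "random_noise") 0.5 else 0.05
    withr::with_seed(as.integer(seed), {
        a <- matrix(4, nr, nc)
        b <- matrix(4, nr, nc)
        if (kind == "random_noise") {
            a <- a + matrix(stats::runif(nr * nc, -noise, noise), nr, nc)
            b <- b + matrix(stats::runif(nr * nc, -noise, noise), nr, nc)
        } else {
            w <- if (is.null(stripeWidth)) max(3L, round(0.05 * nc)) else
                as.integer(stripeWidth)
            centers <- if (kind == "middle_stripe") (nc + 1) / 2 else
                (seq_len(stripes) - 0.5) * nc / stripes
            for (cc in centers) {
                jj <- (round(cc - w / 2) : (round(cc - w / 2) + w - 1L))
                jj <- ((jj - 1L) %% nc) + 1L
                a[, jj] <- maxA
            }
            if (noise > 0) {
                a <- a + matrix(stats::runif(nr * nc, -noise, noise), nr, nc)
                a <- pmin(a, maxA)
            }
        }
        list(a = a, b = b)
    })
}

#' Named scenario presets
#'
#' Returns the \linkS4class{SimulationConfig} of one of the five published
#' scenarios: \tabular{llllll}{
#'  \tab leopard \tab emu \tab pomacanthus \tab ictidomys \tab tetraodon \cr
#' initial condition \tab noise \tab middle stripe \tab middle stripe \tab
#'   periodic stripes \tab noise \cr
#' s \tab 6 \tab 10 \tab 10 \tab 6 \tab 10 \cr
#' r \tab 30 \tab 6 \tab 6 \tab 30 \tab 8 \cr
#' g \tab 0.05 \tab 0.05 \tab 0.05 \tab 0.01 \tab 0.075 \cr
#' growth start \tab 10000 \tab 10000 \tab 20000 \tab 1000 \tab 10000 \cr
#' }
#' All presets use dt = 0.002 and the standard clamps.  Arguments override
#' the remaining free choices (grid, iteration budget, final size, seed).
#'
#' @param name preset name.
#' @param gridDim grid shape, default 200x200.
#' @param totalIters iteration budget; default runs growth to completion plus
#'   a relaxation tail of 10000 iterations.
#' @param maxSurface final surface multiple, default 2.5 (= 1/0.4).
#' @param seed RNG seed for the initial condition.
#' @param snapshotEvery snapshot cadence, default 250.
#' @param dilution whether growth dilutes the morphogens, default TRUE.
#' @return a \linkS4class{SimulationConfig}.
#' @export
presetConfig <- function(name = c("leopard", "emu", "pomacanthus",
                                  "ictidomys", "tetraodon"),
                         gridDim = c(200L, 200L), totalIters = NULL,
                         maxSurface = 2.5, seed = 1L, snapshotEvery = 250L,
                         dilution = TRUE) {
    name <- match.arg(name)
    tab <- list(
        leopard     = list(init = "random_noise",     s = 6,  r = 30, g = 0.05,  tStart = 10000L),
        emu         = list(init = "middle_stripe",    s = 10, r = 6,  g = 0.05,  tStart = 10000L),
        pomacanthus = list(init = "middle_stripe",    s = 10, r = 6,  g = 0.05,  tStart = 20000L),
        ictidomys   = list(init = "periodic_stripes", s = 6,  r = 30, g = 0.01,  tStart = 1000L),
        tetraodon   = list(init = "random_noise",     s = 10, r = 8,  g = 0.075, tStart = 10000L))[[name]]
    if (is.null(totalIters)) {
        gsteps <- ceiling(log(maxSurface) / log1p(tab$g * 0.002))
        totalIters <- as.integer(tab$tStart + gsteps + 10000L)
    }
    new("SimulationConfig",
        reaction = new("ReactionParams", s = tab$s, r = tab$r),
        growth = new("GrowthSchedule", g = tab$g, tStart = tab$tStart,
                     maxSurface = maxSurface),
        gridDim = as.integer(gridDim), init = tab$init,
        totalIters = as.integer(totalIters),
        snapshotEvery = as.integer(snapshotEvery),
        seed = as.integer(seed), dilution = dilution)
}

#' Run a growth-coupled Turing pattern simulation
#'
#' Iterates the synchronous two-morphogen update
#' \deqn{a' = clamp(a/F + (16 - ab/F^2 + d r s \nabla^2 a) dt)}
#' \deqn{b' = clamp(b/F + (ab/F^2 - b/F - 12 + d s \nabla^2 b) dt)}
#' where \eqn{F} is the per-step surface growth factor (1 while growth is
#' inactive) and \eqn{\nabla^2} the periodic nine-point Laplacian.  Growth is
#' active from iteration \code{tStart} until the surface reaches
#' \code{maxSurface}; while active the surface is multiplied by
#' \eqn{1 + g\,dt} per step and the effective diffusion multiplier decays so
#' that \eqn{d = 1/S(t)} (see \linkS4class{SimulationConfig} for the exponent
#' options), which shortens the pattern wavelength on the fixed grid exactly
#' as mapping a growing tissue onto fixed coordinates does.
#'
#' Snapshots of both fields are recorded every \code{snapshotEvery}
#' iterations, plus always at iteration 0, at \code{tStart}, at the end of
#' growth and at the final iteration.
#'
#' @param config a \linkS4class{SimulationConfig}, e.g. from
#'   \code{\link{presetConfig}}.
#' @param snapshotAt optional integer vector of extra iterations to record.
#' @return a \linkS4class{SimulationHistory}.
#' @examples
#' cfg <- presetConfig("leopard", gridDim = c(64, 64), totalIters = 2000)
#' h <- runSimulation(cfg)
#' range(aField(h))   # within [0, 4.4]
#' @export
runSimulation <- function(config, snapshotAt = integer(0)) {
    validObject(config)
    rp <- config@reaction; gs <- config@growth
    ic <- makeInitialCondition(config@init, config@gridDim, config@seed,
                               noise = config@initNoise,
                               stripes = config@stripes, maxA = rp@maxA)
    # initial fields respect the clamps too, so every snapshot (including
    # iteration 0) satisfies the field invariants
    ic$a[] <- pmin(pmax(ic$a, rp@minA), rp@maxA)
    ic$b[] <- pmin(pmax(ic$b, rp@minB), rp@maxB)
    if (length(gs@anisotropy) == 2L) {
        fx <- 1 + gs@anisotropy[1] * rp@dt
        fy <- 1 + gs@anisotropy[2] * rp@dt
        aniso <- TRUE
    } else {
        # isotropic: split the surface factor evenly over the two axes
        fx <- fy <- sqrt(1 + gs@g * rp@dt)
        aniso <- FALSE
    }
    snaps <- sort(unique(c(
        seq(0L, config@totalIters, by = config@snapshotEvery),
        0L, gs@tStart, config@totalIters, as.integer(snapshotAt))))
    snaps <- snaps[snaps >= 0L & snaps <= config@totalIters]
    res <- .rd_simulate_cpp(ic$a, ic$b, rp@s, rp@r, rp@d0, rp@dt,
                            fx, fy, aniso,
                            gs@tStart, gs@maxSurface,
                            rp@minA, rp@maxA, rp@minB, rp@maxB,
                            config@totalIters, snaps,
                            config@dilution, config@dGrowthExponent)
    new("SimulationHistory",
        iterations = res$iterations, surface = res$surface, d = res$d,
        aFields = res$a, bFields = res$b,
        growthEndIter = as.integer(res$growthEndIter),
        finalSurface = res$finalSurface, config = config)
}

#' One synchronous reaction--diffusion step
#'
#' Exposes a single update of the master equations, mainly for inspection and
#' testing; \code{\link{runSimulation}} performs the same update in compiled
#' code.  Uses only the old field values (Jacobi update) and clamps both
#' fields element-wise afterwards.
#'
#' @param a,b numeric matrices of equal shape.
#' @param params a \linkS4class{ReactionParams}.
#' @param gNow current surface growth rate (0 outside the growth phase).
#' @param d current effective diffusion multiplier.
#' @param dilution whether growth dilutes the concentrations.
#' @param dGrowthExponent decay exponent for \code{d} (see
#'   \linkS4class{SimulationConfig}).
#' @return list with matrices \code{a}, \code{b} and the updated scalar
#'   \code{d}.
#' @export
reactionStep <- function(a, b, params = new("ReactionParams"), gNow = 0,
                         d = params@d0, dilution = TRUE,
                         dGrowthExponent = 1) {
    if (!identical(dim(a), dim(b)))
        stop("'a' and 'b' must have the same shape")
    if (any(!is.finite(a)) || any(!is.finite(b)))
        stop("fields contain non-finite values")
    dt <- params@dt
    f <- 1 + gNow * dt
    dil <- if (dilution && gNow > 0) f else 1
    la <- laplacian9(a); lb <- laplacian9(b)
    an <- a / dil + (16 - a * b / dil^2 + d * params@r * params@s * la) * dt
    bn <- b / dil + (a * b / dil^2 - b / dil - 12 + d * params@s * lb) * dt
    an <- pmin(pmax(an, params@minA), params@maxA)
    bn <- pmin(pmax(bn, params@minB), params@maxB)
    dNew <- if (gNow > 0) d / f^dGrowthExponent else d
    list(a = an, b = bn, d = dNew)
}

#' @describeIn SimulationHistory-class number of snapshots
#' @param x,object a \code{SimulationHistory}
#' @export
setMethod("length", "SimulationHistory", function(x) length(x@iterations))

#' Extract a snapshot field from a history
#'
#' @param history a \linkS4class{SimulationHistory}.
#' @param which snapshot index (default: last), or if \code{iteration} is
#'   given, the snapshot at that iteration.
#' @param iteration optional iteration index; the snapshot recorded at the
#'   nearest iteration is returned.
#' @return numeric matrix.
#' @export
aField <- function(history, which = length(history), iteration = NULL) {
    if (!is.null(iteration))
        which <- which.min(abs(history@iterations - iteration))
    history@aFields[[which]]
}

#' @rdname aField
#' @export
bField <- function(history, which = length(history), iteration = NULL) {
    if (!is.null(iteration))
        which <- which.min(abs(history@iterations - iteration))
    history@bFields[[which]]
}

#' @rdname aField
#' @export
snapshotIterations <- function(history) history@iterations

#' @rdname aField
#' @export
surfaceAt <- function(history, which = length(history)) history@surface[which]

setMethod("show", "SimulationHistory", function(object) {
    cfg <- object@config
    cat(sprintf("SimulationHistory: %d snapshots on a %dx%d grid\n",
                length(object@iterations), cfg@gridDim[1], cfg@gridDim[2]))
    cat(sprintf("  iterations 0..%d, init '%s', s=%g r=%g g=%g\n",
                cfg@totalIters, cfg@init, cfg@reaction@s, cfg@reaction@r,
                cfg@growth@g))
    cat(sprintf("  final surface %.3g (max %.3g), growth ended at %s\n",
                object@finalSurface, cfg@growth@maxSurface,
                ifelse(is.na(object@growthEndIter), "NA",
                       as.character(object@growthEndIter))))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf("SimulationConfig: %dx%d grid, init '%s', %d iterations\n",
                object@gridDim[1], object@gridDim[2], object@init,
                object@totalIters))
    cat(sprintf("  s=%g r=%g dt=%g | g=%g from t=%d to surface %.3g | seed %d\n",
                object@reaction@s, object@reaction@r, object@reaction@dt,
                object@growth@g, object@growth@tStart,
                object@growth@maxSurface, object@seed))
})
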