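# inter-fractional error model: per-axis truncated Gaussian mixtures
# calibrated to the measured port-displacement statistics

.defaultBounds <- function()
    matrix(c(-17, 11, -10.8, 7.0, -8.0, 7.0), nrow = 3, byrow = TRUE,
           dimnames = list(c("lateral", "vertical", "longitudinal"),
                           c("lo", "hi")))

# probability that the 3-D shift magnitude is below `radius`, by midpoint
# quadrature of the product of truncated per-axis mixture densities over
# the cube [-radius, radius]^3 intersected with the ball
.magnitudeProb <- function(p, bounds, ss, sl, radius = 5, nGrid = 80L) {
    h <- 2 * radius / nGrid
    x <- seq(-radius + h / 2, radius - h / 2, by = h)
    f <- vector("list", 3)
    for (k in 1:3) {
        lo <- bounds[k, 1]; hi <- bounds[k, 2]
        Zs <- stats::pnorm(hi, 0, ss) - stats::pnorm(lo, 0, ss)
        Zl <- stats::pnorm(hi, 0, sl) - stats::pnorm(lo, 0, sl)
        num <- p * stats::dnorm(x, 0, sl) + (1 - p) * stats::dnorm(x, 0, ss)
        num[x < lo | x > hi] <- 0
        f[[k]] <- num / (p * Zl + (1 - p) * Zs)
    }
    r2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
    inside <- array(as.numeric(r2 < radius^2), dim(r2))
    n <- length(x)
    m <- f[[1]] %*% matrix(inside, n, n * n)       # 1 x (n*n)
    sum(matrix(m, n, n) * outer(f[[2]], f[[3]])) * h^3
}

.calibCache <- new.env(parent = emptyenv())

.calibrateMixWeight <- function(bounds, ss, sl, target) {
    key <- paste(c(bounds, ss, sl, target), collapse = "|")
    if (!is.null(.calibCache[[key]])) return(.calibCache[[key]])
    fn <- function(p) .magnitudeProb(p, bounds, ss, sl) - target
    lo <- fn(0); hi <- fn(1)
    if (lo * hi > 0)
        stop("distribution error: calibration target ", target,
             " unreachable with the given component SDs")
    p <- stats::uniroot(fn, c(0, 1), tol = 1e-8)$root
    .calibCache[[key]] <- p
    p
}

#' Default calibrated port-error distribution
#'
#' Per-axis zero-mean two-component Gaussian mixture (sigma 1.5 mm small /
#' 6 mm large), truncated to the measured per-axis supports (lateral
#' [-17, 11] mm, vertical [-10.8, 7.0] mm, longitudinal [-8.0, 7.0] mm).
#' The large-component weight is solved by deterministic quadrature so that
#' the fraction of 3-D shift magnitudes below 5 mm equals the measured 87%.
#'
#' @param bounds 3x2 matrix of per-axis supports, mm.
#' @param sigmaSmall,sigmaLarge mixture component SDs, mm.
#' @param target calibration target P(magnitude < 5 mm).
#' @return An [ErrorDistribution-class] with the calibrated mixing weight.
#' @export
defaultErrorDistribution <- function(bounds = .defaultBounds(),
                                     sigmaSmall = 1.5, sigmaLarge = 6,
                                     target = 0.87) {
    p <- .calibrateMixWeight(bounds, sigmaSmall, sigmaLarge, target)
    new("ErrorDistribution", bounds = bounds, sigmaSmall = sigmaSmall,
        sigmaLarge = sigmaLarge, mixWeight = p, target = target)
}

# truncated-mixture sampler for one axis (rejection on the joint mixture)
.sampleAxis <- function(n, p, ss, sl, lo, hi) {
    out <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {
        m <- length(todo)
        sd <- ifelse(stats::runif(m) < p, sl, ss)
        x <- stats::rnorm(m, 0, sd)
        ok <- x >= lo & x <= hi
        out[todo[ok]] <- x[ok]
        todo <- todo[!ok]
    }
    out
}

#' Sample a per-fraction error series
#'
#' Draws one independent 3-D shift per fraction from the truncated per-axis
#' mixture. Reproducible for a fixed seed; every sample lies inside the
#' per-axis supports.
#'
#' @param dist an [ErrorDistribution-class].
#' @param nFractions number of fractions (>= 1).
#' @param seed integer seed.
#' @param errorClass "IPE" or "PRE" tag for the series.
#' @return An [ErrorSeries-class] with scenario "daily".
#' @export
sampleErrorSeries <- function(dist, nFractions, seed,
                              errorClass = c("IPE", "PRE")) {
    errorClass <- match.arg(errorClass)
    validObject(dist)
    if (nFractions < 1)
        stop("distribution error: nFractions must be >= 1")
    shifts <- .withSeed(seed, {
        vapply(1:3, function(k)
            .sampleAxis(nFractions, dist@mixWeight, dist@sigmaSmall,
                        dist@sigmaLarge, dist@bounds[k, 1],
                        dist@bounds[k, 2]),
            numeric(nFractions))
    })
    ErrorSeries(matrix(shifts, ncol = 3), errorClass, "daily", seed)
}

#' The systematic large-error shift
#'
#' Default: the largest-magnitude single-axis support bound, applied along
#' its axis (-17 mm lateral for the default distribution). An explicit
#' `override` vector is passed through unchanged.
#'
#' @param dist an [ErrorDistribution-class].
#' @param override optional numeric(3) shift (mm) to use instead.
#' @return numeric(3) shift in mm.
#' @export
systematicShift <- function(dist, override = NULL) {
    if (!is.null(override)) {
        if (length(override) != 3L || any(!is.finite(override)))
            stop("configuration error: override must be 3 finite mm values")
        return(as.numeric(override))
    }
    b <- dist@bounds
    i <- which.max(abs(b))
    ax <- ((i - 1) %% 3) + 1
    out <- numeric(3)
    out[ax] <- b[i]
    out
}

#' Apply a patient registration error to a plan
#'
#' Shifting the patient by `+shift` relative to the planned fluence is
#' realised as translating every beam isocentre (and with it the source and
#' aperture) by `-shift`, so the accumulated dose lives natively in the
#' planning anatomy without resampling the patient grid.
#'
#' @param plan a [Plan-class].
#' @param shift numeric(3) patient shift, mm.
#' @return The shifted [Plan-class].
#' @export
applyPre <- function(plan, shift) {
    if (length(shift) != 3L || any(!is.finite(shift)))
        stop("displacement error: shift must be 3 finite mm values")
    plan@beams <- lapply(plan@beams, function(b) {
        b@iso <- b@iso - as.numeric(shift)
        b
    })
    plan
}

#' Rigidly translate a volume by a (voxel-rounded) shift
#'
#' Nearest-voxel translation used as the resampling-based alternative
#' realisation of a patient shift, against which [applyPre()] is validated.
#'
#' @param x a [DensityGrid-class] or [DoseGrid-class].
#' @param shift numeric(3) shift, mm (rounded to whole voxels).
#' @param fill value for voxels translated in from outside (default: the
#'   grid minimum, i.e. air for a density grid, 0 for dose).
#' @return An object of the same class as `x`.
#' @export
translateVolume <- function(x, shift, fill = min(x@voxels)) {
    voxShift <- as.integer(round(shift / x@spacing))
    vox <- .translateArray(x@voxels, voxShift, fill)
    if (is(x, "DensityGrid")) DensityGrid(vox, x@spacing, x@origin)
    else DoseGrid(vox, x@spacing, x@origin)
}
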