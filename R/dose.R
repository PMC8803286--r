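# simplified divergent-beam photon dose engine
#
# dose(v) = w * inAperture(v) * (SAD/d)^2 * exp(-muW * radiologicalPath),
# followed by an isotropic Gaussian scatter blur. Attenuation scales with
# mass density only (muW = 0.049 cm^2/g, a 6 MV-like linear attenuation per
# unit density); there is no electron-transport buildup. The engine's
# purpose is relative robustness comparison between perturbed and reference
# runs, not absolute dosimetry.

#' Radiological path length between two points
#'
#' Exact voxel-traversal line integral of density times intersection length
#' (Siddon-style traversal). Symmetric in its endpoints and additive over
#' subsegments; portions of the segment outside the grid contribute zero.
#'
#' @param grid a [DensityGrid-class].
#' @param p0,p1 segment endpoints, mm world coordinates.
#' @return Areal density in g/cm^2.
#' @export
radiologicalPath <- function(grid, p0, p1) {
    if (length(p0) != 3L || length(p1) != 3L)
        stop("geometry error: endpoints must be length-3 mm coordinates")
    if (all(p0 == p1))
        stop("geometry error: p0 and p1 must differ")
    cppRadiologicalPath(as.numeric(grid@voxels),
                        as.integer(dim(grid@voxels)),
                        grid@spacing, grid@origin,
                        as.numeric(p0), as.numeric(p1))
}

# unit vectors of the beam frame for a gantry angle (deg):
# srcDir points from isocentre to source, axis from source into the patient,
# ex the in-plane BEV u axis, ez = +z the BEV w axis
.beamFrame <- function(gantryDeg) {
    g <- gantryDeg * pi / 180
    srcDir <- c(sin(g), cos(g), 0)
    list(srcDir = srcDir,
         axis = -srcDir,
         ex = c(cos(g), -sin(g), 0),
         ez = c(0, 0, 1))
}

.beamSource <- function(beam) {
    fr <- .beamFrame(beam@gantry)
    beam@iso + beam@sad * fr$srcDir
}

#' Compute the dose of a single beam
#'
#' Primary attenuation along exact radiological paths from the source, an
#' inverse-square divergence factor and an aperture test in the beam's-eye
#' view, followed by an isotropic Gaussian scatter blur. Deterministic.
#'
#' @param grid a [DensityGrid-class].
#' @param beam a [Beam-class].
#' @param muW attenuation per unit density, cm^2/g (default 0.049, 6 MV-like).
#' @param scatterSigma Gaussian scatter sigma in mm (0 = no blur, i.e. the
#'   pre-blur primary field).
#' @return A [DoseGrid-class] (per unit beam weight scale).
#' @export
computeBeamDose <- function(grid, beam, muW = 0.049, scatterSigma = 5) {
    validObject(beam)
    if (beam@weight > 0 && !any(beam@aperture$mask))
        stop("plan error: zero-size aperture with positive weight")
    pre <- .beamPrimary(grid, beam, muW)
    dims <- dim(grid@voxels)
    if (scatterSigma > 0)
        pre <- cppGaussBlur(pre, as.integer(dims),
                            scatterSigma / grid@spacing)
    DoseGrid(array(pre, dims), grid@spacing, grid@origin)
}

.beamPrimary <- function(grid, beam, muW) {
    fr <- .beamFrame(beam@gantry)
    src <- beam@iso + beam@sad * fr$srcDir
    ap <- beam@aperture
    cppBeamDose(as.numeric(grid@voxels), as.integer(dim(grid@voxels)),
                grid@spacing, grid@origin, src, fr$axis, fr$ex, fr$ez,
                beam@sad, ap$mask, ap$du, ap$u0, ap$w0, muW, beam@weight)
}

#' Compute the total dose of a plan
#'
#' Superposition of the per-beam primary fields followed by one Gaussian
#' scatter blur (the blur is linear, so this equals blurring each beam).
#'
#' @param grid a [DensityGrid-class].
#' @param plan a [Plan-class].
#' @inheritParams computeBeamDose
#' @return A [DoseGrid-class] in Gy at the plan's current weight scale.
#' @export
computePlanDose <- function(grid, plan, muW = 0.049, scatterSigma = 5) {
    validObject(plan)
    dims <- dim(grid@voxels)
    total <- numeric(prod(dims))
    for (b in plan@beams) {
        if (b@weight == 0) next
        total <- total + .beamPrimary(grid, b, muW)
    }
    if (scatterSigma > 0)
        total <- cppGaussBlur(total, as.integer(dims),
                              scatterSigma / grid@spacing)
    DoseGrid(array(total, dims), grid@spacing, grid@origin)
}

#' Normalize a plan to the prescription
#'
#' Scales all beam weights by one positive factor so that the PTV D90%
#' equals the prescription dose (the engine is linear in beam weight, so the
#' rescaled D90 is exact).
#'
#' @param plan a [Plan-class].
#' @param grid the planning [DensityGrid-class].
#' @param structures the [StructureSet-class] providing the `ptv` mask.
#' @inheritParams computeBeamDose
#' @return The normalized [Plan-class]; `normFactor(plan)` returns the scale
#'   factor applied.
#' @export
normalizePlan <- function(plan, grid, structures, muW = 0.049,
                          scatterSigma = 5) {
    ptv <- getMask(structures, "ptv")
    if (!any(ptv)) stop("plan error: PTV is empty")
    dose <- computePlanDose(grid, plan, muW, scatterSigma)
    d90 <- dvhValue(dose, ptv, kind = "D", threshold = 90)
    if (d90 <= 0)
        stop("normalization error: plan dose in the PTV is zero")
    scale <- plan@prescription@doseGy / d90
    plan@beams <- lapply(plan@beams, function(b) {
        b@weight <- b@weight * scale
        b
    })
    plan@normFactor <- scale
    plan
}
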