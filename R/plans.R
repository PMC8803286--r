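# plan builders for the three delivery techniques

#' Plan-geometry parameters
#'
#' @param sad source-axis distance, mm.
#' @param bevPitch aperture raster pitch in the isocentre plane, mm.
#' @param flashMargin anterior flash beyond the skin for tangents, mm.
#' @param apertureMargin conformal margin around the PTV projection, mm.
#' @param zMargin longitudinal aperture margin for tangents, mm.
#' @param blockMargin posterior clearance of the tangent half-block edge
#'   behind the PTV, mm (the standard 1.5-2 cm of lung inside deep tangent
#'   fields keeps the chest wall out of the penumbra).
#' @param arcBeams number of beams discretising the partial arc.
#' @param arcSpan arc length, degrees.
#' @param helicalAngles gantry angles per rotation for the helical-like plan.
#' @param fanWidth longitudinal fan-beam width at isocentre, mm.
#' @param pitch couch step between rotations as a fraction of `fanWidth`.
#' @return Named list of plan parameters.
#' @export
planParams <- function(sad = 1000, bevPitch = 2.5, flashMargin = 20,
                       apertureMargin = 5, zMargin = 10, blockMargin = 15,
                       arcBeams = 47L, arcSpan = 230, helicalAngles = 32L,
                       fanWidth = 25, pitch = 0.5) {
    list(sad = sad, bevPitch = bevPitch, flashMargin = flashMargin,
         apertureMargin = apertureMargin, zMargin = zMargin,
         blockMargin = blockMargin, arcBeams = as.integer(arcBeams),
         arcSpan = arcSpan, helicalAngles = as.integer(helicalAngles),
         fanWidth = fanWidth, pitch = pitch)
}

# world coordinates of TRUE voxels of a mask
.maskWorld <- function(mask, spacing, origin) {
    idx <- which(mask, arr.ind = TRUE)
    sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}

# project world points into the BEV isocentre plane of a beam frame
.bevProject <- function(pts, src, fr, sad) {
    rel <- sweep(pts, 2, src, `-`)
    d <- rel %*% fr$axis
    list(u = as.vector((rel %*% fr$ex) * sad / d),
         w = as.vector((rel %*% fr$ez) * sad / d),
         d = as.vector(d))
}

# rectangular aperture raster: pixels whose centre lies in the u/w ranges
.rectAperture <- function(uRange, wRange, du) {
    us <- seq(uRange[1] + du / 2, uRange[2], by = du)
    ws <- seq(wRange[1] + du / 2, wRange[2], by = du)
    if (!length(us) || !length(ws))
        stop("plan error: degenerate aperture")
    list(mask = matrix(TRUE, length(us), length(ws)),
         du = du, u0 = us[1], w0 = ws[1])
}

# 2-D disc dilation in pixels
.dilate2d <- function(mask, radiusPx) {
    if (radiusPx <= 0) return(mask)
    r <- ceiling(radiusPx)
    out <- mask
    d <- dim(mask)
    for (ox in -r:r) for (oy in -r:r) {
        if (ox * ox + oy * oy > radiusPx^2 + 1e-9) next
        xs <- seq_len(d[1]) - ox
        ys <- seq_len(d[2]) - oy
        ok <- xs >= 1 & xs <= d[1]
        ok2 <- ys >= 1 & ys <= d[2]
        out[ok, ok2] <- out[ok, ok2] | mask[xs[ok], ys[ok2]]
    }
    out
}

# conformal aperture: BEV projection of mask voxels, dilated by margin (mm)
.conformalAperture <- function(pts, src, fr, sad, du, margin) {
    pr <- .bevProject(pts, src, fr, sad)
    pad <- margin + 2 * du
    u0 <- min(pr$u) - pad; u1 <- max(pr$u) + pad
    w0 <- min(pr$w) - pad; w1 <- max(pr$w) + pad
    nu <- ceiling((u1 - u0) / du) + 1L
    nw <- ceiling((w1 - w0) / du) + 1L
    m <- matrix(FALSE, nu, nw)
    iu <- pmin(pmax(round((pr$u - u0) / du), 0), nu - 1) + 1L
    iw <- pmin(pmax(round((pr$w - w0) / du), 0), nw - 1) + 1L
    m[cbind(iu, iw)] <- TRUE
    m <- .dilate2d(m, margin / du)
    list(mask = m, du = du, u0 = u0, w0 = w0)
}

# radial unit vector (axial plane) from trunk centre towards the implant
.radialDir <- function(structures) {
    bodyC <- .maskCentroid(getMask(structures, "body"),
                           structures@spacing, structures@origin)
    impC <- .maskCentroid(getMask(structures, "implant"),
                          structures@spacing, structures@origin)
    r <- impC - bodyC
    r[3] <- 0
    r / sqrt(sum(r^2))
}

#' Build a tangential parallel-opposed plan
#'
#' Two half-blocked parallel-opposed fields tangent to the chest wall, open
#' anteriorly: the shared posterior field edge is the plane through the
#' isocentre containing the beam axis (half-block), and the anterior edge
#' extends a flash margin beyond the skin. No wedges or bolus.
#'
#' @param structures the phantom [StructureSet-class] (needs `ptv`, `body`,
#'   `implant` masks).
#' @param params a [planParams()] list.
#' @param prescription a [Prescription-class].
#' @return An unnormalized [Plan-class] with two beams 180 degrees apart.
#' @export
makeTangentialPlan <- function(structures, params = planParams(),
                               prescription = Prescription()) {
    ptv <- getMask(structures, "ptv")
    if (!any(ptv)) stop("plan error: PTV is empty")
    body <- getMask(structures, "body")
    sp <- structures@spacing; org <- structures@origin
    r <- .radialDir(structures)
    tang <- c(-r[2], r[1], 0)                 # beam axis direction, in plane

    ptvPts <- .maskWorld(ptv, sp, org)
    ptvC <- colMeans(ptvPts)
    s <- as.vector(sweep(ptvPts, 2, ptvC, `-`) %*% r)
    iso <- ptvC + (min(s) - params$blockMargin) * r
    iso[3] <- ptvC[3]

    bodyPts <- .maskWorld(body, sp, org)
    gantries <- (atan2(-tang[1], -tang[2]) * 180 / pi) %% 360
    gantries <- c(gantries, (gantries + 180) %% 360)

    beams <- lapply(gantries, function(g) {
        fr <- .beamFrame(g)
        src <- iso + params$sad * fr$srcDir
        sgn <- sign(sum(fr$ex * r))
        prB <- .bevProject(bodyPts, src, fr, params$sad)
        prP <- .bevProject(ptvPts, src, fr, params$sad)
        uMax <- max(sgn * prB$u) + params$flashMargin
        wR <- range(prP$w) + c(-1, 1) * params$zMargin
        ap <- if (sgn > 0) .rectAperture(c(0, uMax), wR, params$bevPitch)
              else .rectAperture(c(-uMax, 0), wR, params$bevPitch)
        Beam(g, iso, ap, weight = 1, sad = params$sad)
    })
    new("Plan", technique = "tangential", beams = beams,
        prescription = prescription, normFactor = NA_real_)
}

#' Build a partial-arc plan
#'
#' Equally spaced beams spanning the configured arc (default 230 degrees,
#' 47 beams) over the ipsilateral hemithorax, each with a PTV-conformal
#' aperture; isocentre at the PTV centroid. Weights are uniform; plan
#' quality is set by [normalizePlan()].
#'
#' @inheritParams makeTangentialPlan
#' @return An unnormalized [Plan-class].
#' @export
makeArcPlan <- function(structures, params = planParams(),
                        prescription = Prescription()) {
    ptv <- getMask(structures, "ptv")
    if (!any(ptv)) stop("plan error: PTV is empty")
    sp <- structures@spacing; org <- structures@origin
    ptvPts <- .maskWorld(ptv, sp, org)
    iso <- colMeans(ptvPts)
    r <- .radialDir(structures)
    gc <- (atan2(r[1], r[2]) * 180 / pi)
    gantries <- seq(gc - params$arcSpan / 2, gc + params$arcSpan / 2,
                    length.out = params$arcBeams)
    beams <- lapply(gantries, function(g) {
        fr <- .beamFrame(g)
        src <- iso + params$sad * fr$srcDir
        ap <- .conformalAperture(ptvPts, src, fr, params$sad,
                                 params$bevPitch, params$apertureMargin)
        Beam(g, iso, ap, weight = 1, sad = params$sad)
    })
    new("Plan", technique = "arc", beams = beams,
        prescription = prescription, normFactor = NA_real_)
}

#' Build a helical-like full-rotation plan
#'
#' Emulates a continuously rotating fan beam: gantry angles uniformly cover
#' [0, 360) and are replicated at successive longitudinal isocentre
#' positions stepping by `pitch * fanWidth` across the PTV extent. Each
#' aperture is the PTV-conformal projection restricted to the narrow
#' longitudinal fan window.
#'
#' @inheritParams makeTangentialPlan
#' @return An unnormalized [Plan-class].
#' @export
makeHelicalPlan <- function(structures, params = planParams(),
                            prescription = Prescription()) {
    ptv <- getMask(structures, "ptv")
    if (!any(ptv)) stop("plan error: PTV is empty")
    sp <- structures@spacing; org <- structures@origin
    ptvPts <- .maskWorld(ptv, sp, org)
    ptvC <- colMeans(ptvPts)
    zR <- range(ptvPts[, 3])
    step <- params$pitch * params$fanWidth
    zPos <- seq(zR[1], zR[2], by = step)
    if (max(zPos) < zR[2] - 1e-9) zPos <- c(zPos, zR[2])
    gantries <- seq(0, 360 - 360 / params$helicalAngles,
                    length.out = params$helicalAngles)
    beams <- list()
    for (z in zPos) {
        iso <- c(ptvC[1], ptvC[2], z)
        for (g in gantries) {
            fr <- .beamFrame(g)
            src <- iso + params$sad * fr$srcDir
            ap <- .conformalAperture(ptvPts, src, fr, params$sad,
                                     params$bevPitch, params$apertureMargin)
            # restrict to the fan window in w (BEV longitudinal axis)
            ws <- ap$w0 + (seq_len(ncol(ap$mask)) - 1) * ap$du
            ap$mask[, abs(ws) > params$fanWidth / 2] <- FALSE
            if (!any(ap$mask)) next
            beams[[length(beams) + 1L]] <-
                Beam(g, iso, ap, weight = 1, sad = params$sad)
        }
    }
    if (!length(beams)) stop("plan error: no helical beams constructed")
    new("Plan", technique = "helical", beams = beams,
        prescription = prescription, normFactor = NA_real_)
}
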