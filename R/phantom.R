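# synthetic thorax / tissue-expander phantom generation

# evaluate with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Phantom configuration
#'
#' Geometry of the synthetic thorax: an extruded elliptical body with a
#' hemispherical breast mound containing a saline tissue expander, an
#' ipsilateral lung, a heart, a rib shell around the lung, and the expander's
#' metal injection port (a magnet-core cylinder in a coaxial titanium shell,
#' axis anterior-posterior). All lengths in mm; world coordinates at voxel
#' centres with the grid centred on the origin. Axis convention: x lateral
#' (+x patient left), y anterior-posterior (+y anterior), z longitudinal.
#'
#' Defaults are written for a left-sided case; `laterality = "right"` mirrors
#' the default lateral positions of implant, lung and heart across the
#' midsagittal plane (explicitly supplied centres are taken as given).
#'
#' @param gridShape integer(3) voxels per axis.
#' @param voxelSize numeric(3) mm per axis.
#' @param laterality "left" or "right".
#' @param bodyCenter,bodySemiAxes axial-plane ellipse of the trunk (mm);
#'   the ellipse is extruded along z.
#' @param lungCenter,lungSemiAxes ipsilateral lung ellipsoid (mm).
#' @param heartCenter,heartSemiAxes heart ellipsoid (mm).
#' @param implantCenter,implantRadius spherical expander (mm).
#' @param portCoreRadius,portCoreHalfHeight magnet-core cylinder (mm).
#' @param portShellThickness titanium shell thickness (mm).
#' @param ribThickness rib shell around the lung (mm).
#' @param skinThickness skin rind used to truncate the PTV (mm).
#' @param ptvMargin expansion of the chest wall/implant forming the PTV (mm).
#' @param artefactSlices optional integer z-slices carrying simulated metal
#'   streak artefacts.
#' @param artefactAmplitude multiplicative streak amplitude (fraction).
#' @param seed RNG seed for the (optional) artefact noise.
#' @return A validated list of class `PhantomConfig`.
#' @export
phantomConfig <- function(gridShape = c(128L, 128L, 64L),
                          voxelSize = c(2.5, 2.5, 2.5),
                          laterality = c("left", "right"),
                          bodyCenter = c(0, -40, 0),
                          bodySemiAxes = c(140, 85),
                          lungCenter = NULL,
                          lungSemiAxes = c(55, 55, 70),
                          heartCenter = NULL,
                          heartSemiAxes = c(40, 35, 45),
                          implantCenter = NULL,
                          implantRadius = 35,
                          portCoreRadius = 5,
                          portCoreHalfHeight = 5,
                          portShellThickness = 2,
                          ribThickness = 4,
                          skinThickness = 3,
                          ptvMargin = 5,
                          artefactSlices = NULL,
                          artefactAmplitude = 0.3,
                          seed = 1L) {
    laterality <- match.arg(laterality)
    side <- if (laterality == "left") 1 else -1
    if (is.null(lungCenter)) lungCenter <- c(side * 45, -35, 0)
    if (is.null(heartCenter)) heartCenter <- c(side * 20, -15, -20)
    if (is.null(implantCenter)) implantCenter <- c(side * 60, 55, 0)
    cfg <- list(gridShape = as.integer(gridShape),
                voxelSize = as.numeric(voxelSize), laterality = laterality,
                bodyCenter = bodyCenter, bodySemiAxes = bodySemiAxes,
                lungCenter = lungCenter, lungSemiAxes = lungSemiAxes,
                heartCenter = heartCenter, heartSemiAxes = heartSemiAxes,
                implantCenter = implantCenter, implantRadius = implantRadius,
                portCoreRadius = portCoreRadius,
                portCoreHalfHeight = portCoreHalfHeight,
                portShellThickness = portShellThickness,
                ribThickness = ribThickness, skinThickness = skinThickness,
                ptvMargin = ptvMargin, artefactSlices = artefactSlices,
                artefactAmplitude = artefactAmplitude, seed = seed)
    class(cfg) <- "PhantomConfig"
    validatePhantomConfig(cfg)
    cfg
}

#' Validate a phantom configuration
#'
#' Checks positivity of all lengths and the analytic containment chain
#' port (core + shell) inside implant inside body/grid.
#'
#' @param cfg a `PhantomConfig`.
#' @return `cfg`, invisibly; stops with a configuration error otherwise.
#' @export
validatePhantomConfig <- function(cfg) {
    lens <- c(cfg$voxelSize, cfg$implantRadius, cfg$portCoreRadius,
              cfg$portCoreHalfHeight, cfg$portShellThickness,
              cfg$ribThickness, cfg$skinThickness,
              cfg$bodySemiAxes, cfg$lungSemiAxes, cfg$heartSemiAxes)
    if (any(!is.finite(lens)) || any(lens <= 0))
        stop("configuration error: all radii, thicknesses and voxel sizes ",
             "must be positive")
    if (cfg$ptvMargin < 0)
        stop("configuration error: ptvMargin must be >= 0")
    if (any(cfg$gridShape < 8L))
        stop("configuration error: grid too small")
    # port corner (outer cylinder) must stay inside the implant sphere
    outerR <- cfg$portCoreRadius + cfg$portShellThickness
    outerH <- cfg$portCoreHalfHeight + cfg$portShellThickness
    if (sqrt(outerR^2 + outerH^2) >= cfg$implantRadius)
        stop("configuration error: port (core+shell) protrudes from implant")
    # implant sphere (plus skin) must fit inside the grid
    half <- (cfg$gridShape - 1) * cfg$voxelSize / 2
    if (any(abs(cfg$implantCenter) + cfg$implantRadius + cfg$skinThickness >
            half + cfg$voxelSize / 2))
        stop("configuration error: implant not contained in body grid")
    invisible(cfg)
}

#' Tissue densities (g/cm^3)
#'
#' Nominal physical densities; the metal port components carry the values
#' used clinically for density override of the expander port: titanium shell
#' 4.0 and magnet core 8.0 g/cm^3.
#'
#' @param air,lung,breast,saline,rib,titanium,magnet densities in g/cm^3.
#' @return A validated list of class `TissueModel`.
#' @export
tissueModel <- function(air = 0.001, lung = 0.26, breast = 0.95,
                        saline = 1.0, rib = 1.4, titanium = 4.0,
                        magnet = 8.0) {
    tm <- list(air = air, lung = lung, breast = breast, saline = saline,
               rib = rib, titanium = titanium, magnet = magnet)
    v <- unlist(tm)
    if (any(v <= 0) || any(!is.finite(v)))
        stop("configuration error: densities must be positive")
    ord <- air < lung && lung < breast && breast <= saline &&
        saline < rib && rib < titanium && titanium < magnet
    if (!ord)
        stop("configuration error: densities must satisfy ",
             "air < lung < breast <= saline < rib < titanium < magnet")
    class(tm) <- "TissueModel"
    tm
}

#' @rdname tissueModel
#' @export
defaultTissueModel <- function() tissueModel()

#' Hounsfield-unit to density calibration
#'
#' Ordered anchor pairs (HU, g/cm^3). The default table carries the water
#' point and the extended-scale metal anchors HU 3926 -> 4.0 g/cm^3
#' (titanium shell) and HU 10248 -> 8.0 g/cm^3 (magnet core); the metal
#' anchors are not collinear with the water point, so a piecewise table is
#' required rather than a single slope.
#'
#' @param hu numeric vector of HU anchors, strictly increasing.
#' @param density matching densities (g/cm^3), non-decreasing.
#' @return A data.frame of class `HUCalibration`.
#' @export
huCalibration <- function(hu = c(-1000, 0, 3926, 10248),
                          density = c(0.001, 1.0, 4.0, 8.0)) {
    if (length(hu) != length(density))
        stop("calibration error: hu and density lengths differ")
    if (is.unsorted(hu, strictly = TRUE))
        stop("calibration error: HU anchors must be strictly increasing")
    if (is.unsorted(density))
        stop("calibration error: densities must be non-decreasing")
    cal <- data.frame(hu = hu, density = density)
    class(cal) <- c("HUCalibration", "data.frame")
    cal
}

#' @rdname huCalibration
#' @export
defaultHUCalibration <- function() huCalibration()

#' Convert Hounsfield units to physical density
#'
#' Piecewise-linear interpolation between calibration anchors, clamped to
#' the end anchors outside the table's range.
#'
#' @param hu numeric vector of HU values.
#' @param cal an [huCalibration()] table (>= 2 anchors).
#' @return densities in g/cm^3, same shape as `hu`.
#' @export
huToDensity <- function(hu, cal = defaultHUCalibration()) {
    if (nrow(cal) < 2L)
        stop("calibration error: need at least 2 anchors")
    stats::approx(cal$hu, cal$density, xout = hu, rule = 2,
                  ties = "ordered")$y
}

.ellipsoidMask <- function(cx, cy, cz, center, semi) {
    if (length(semi) == 2L) semi <- c(semi, Inf)
    nx <- length(cx); ny <- length(cy); nz <- length(cz)
    fx <- ((cx - center[1]) / semi[1])^2
    fy <- ((cy - center[2]) / semi[2])^2
    fz <- if (is.finite(semi[3])) ((cz - center[3]) / semi[3])^2 else
        rep(0, nz)
    xy <- outer(fx, fy, `+`)
    arr <- array(rep(xy, nz), c(nx, ny, nz)) +
        array(rep(fz, each = nx * ny), c(nx, ny, nz))
    arr <= 1
}

.ballMask <- function(cx, cy, cz, center, radius)
    .ellipsoidMask(cx, cy, cz, center, rep(radius, 3))

# cylinder with axis along y (anterior-posterior)
.cylinderMaskY <- function(cx, cy, cz, center, radius, halfHeight) {
    nx <- length(cx); ny <- length(cy); nz <- length(cz)
    rx <- (cx - center[1])^2
    rz <- (cz - center[3])^2
    inR <- outer(rx, rz, `+`) <= radius^2    # nx x nz
    inY <- abs(cy - center[2]) <= halfHeight
    arr <- array(FALSE, c(nx, ny, nz))
    arr[, inY, ] <- aperm(array(rep(inR, sum(inY)),
                                c(nx, nz, sum(inY))), c(1, 3, 2))
    arr
}

#' Generate a synthetic thorax/expander phantom
#'
#' Rasterizes the configured geometry onto the voxel grid and assigns one
#' tissue density per voxel (priority: magnet core > titanium shell >
#' saline implant > rib > lung > heart > body soft tissue > air). The PTV is
#' the `ptvMargin` expansion of the implant/chest wall, truncated at the
#' skin anteriorly and at the ribs and lung posteriorly. Deterministic for a
#' fixed configuration and seed.
#'
#' @param cfg a [phantomConfig()].
#' @param tissues a [tissueModel()].
#' @return `list(grid = DensityGrid, structures = StructureSet)` with masks
#'   body, skin, lung, heart, rib, implant, portCore, portShell, ptv.
#' @export
generatePhantom <- function(cfg = phantomConfig(),
                            tissues = defaultTissueModel()) {
    validatePhantomConfig(cfg)
    dims <- cfg$gridShape; sp <- cfg$voxelSize
    org <- -(dims - 1) * sp / 2
    cc <- .gridCoords(dims, sp, org)
    cx <- cc[[1]]; cy <- cc[[2]]; cz <- cc[[3]]

    trunk <- .ellipsoidMask(cx, cy, cz, cfg$bodyCenter, cfg$bodySemiAxes)
    mound <- .ballMask(cx, cy, cz, cfg$implantCenter,
                       cfg$implantRadius + cfg$skinThickness)
    body <- trunk | mound
    implant <- .ballMask(cx, cy, cz, cfg$implantCenter, cfg$implantRadius)

    outerR <- cfg$portCoreRadius + cfg$portShellThickness
    outerH <- cfg$portCoreHalfHeight + cfg$portShellThickness
    core <- .cylinderMaskY(cx, cy, cz, cfg$implantCenter,
                           cfg$portCoreRadius, cfg$portCoreHalfHeight)
    shell <- .cylinderMaskY(cx, cy, cz, cfg$implantCenter, outerR, outerH) &
        !core

    heart <- .ellipsoidMask(cx, cy, cz, cfg$heartCenter, cfg$heartSemiAxes) &
        trunk & !implant
    lung <- .ellipsoidMask(cx, cy, cz, cfg$lungCenter, cfg$lungSemiAxes) &
        trunk & !heart & !implant
    rib <- .dilateMask(lung, cfg$ribThickness, sp) & body & !lung & !heart &
        !implant
    skin <- body & !.erodeMask(body, cfg$skinThickness, sp)
    ptv <- .dilateMask(implant, cfg$ptvMargin, sp) & body & !lung & !rib &
        !heart & !skin

    # mask-level containment checks
    if (any((core | shell) & !implant))
        stop("configuration error: containment violated for pair ",
             "port-implant")
    if (any(implant & !body))
        stop("configuration error: containment violated for pair ",
             "implant-body")

    dens <- array(tissues$air, dims)
    dens[body] <- tissues$breast
    dens[lung] <- tissues$lung
    dens[heart] <- tissues$saline   # water-equivalent soft tissue
    dens[rib] <- tissues$rib
    dens[implant] <- tissues$saline
    dens[shell] <- tissues$titanium
    dens[core] <- tissues$magnet

    if (!is.null(cfg$artefactSlices) && length(cfg$artefactSlices)) {
        breast <- body & !(lung | heart | rib | implant)
        dens <- .withSeed(cfg$seed, {
            for (z in cfg$artefactSlices) {
                sl <- breast[, , z]
                n <- sum(sl)
                if (n) {
                    f <- 1 + cfg$artefactAmplitude *
                        (2 * stats::runif(n) - 1) *
                        sign(sin(seq_len(n) / 2))  # streak-like alternation
                    plane <- dens[, , z]
                    plane[sl] <- plane[sl] * f
                    dens[, , z] <- plane
                }
            }
            dens
        })
    }

    grid <- DensityGrid(dens, sp, org)
    structures <- StructureSet(
        list(body = body, skin = skin, lung = lung, heart = heart, rib = rib,
             implant = implant, portCore = core, portShell = shell,
             ptv = ptv),
        sp, org)
    list(grid = grid, structures = structures)
}

# erosion via complement dilation
.erodeMask <- function(mask, radiusMM, spacing)
    !.dilateMask(!mask, radiusMM, spacing)
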