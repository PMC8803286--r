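#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib expanderRobust, .registration = TRUE
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' VoxelGrid: common geometry for volumetric objects
#'
#' Virtual parent of [DensityGrid-class] and [DoseGrid-class]. A 3-D array on
#' a regular grid. Axis convention: x = lateral (+x patient left),
#' y = vertical/anterior-posterior (+y anterior), z = longitudinal
#' (+z superior). `origin` is the world coordinate (mm) of the centre of
#' voxel `[1, 1, 1]`; world coordinates live at voxel centres.
#'
#' @slot voxels 3-D numeric array.
#' @slot spacing numeric(3), voxel pitch in mm per axis.
#' @slot origin numeric(3), mm.
#' @name VoxelGrid-class
#' @aliases VoxelGrid
#' @exportClass VoxelGrid
setClass("VoxelGrid",
    representation("VIRTUAL",
        voxels = "array", spacing = "numeric", origin = "numeric"))

.validVoxelGrid <- function(object) {
    msg <- NULL
    if (length(dim(object@voxels)) != 3L)
        msg <- c(msg, "voxels must be a 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite values (mm)")
    if (is.null(msg)) TRUE else msg
}
setValidity("VoxelGrid", .validVoxelGrid)

#' DensityGrid: the computational patient
#'
#' 3-D voxel array of physical density in g/cm^3, the quantity the dose
#' engine attenuates against.
#'
#' @name DensityGrid-class
#' @aliases DensityGrid-class
#' @exportClass DensityGrid
setClass("DensityGrid", contains = "VoxelGrid")
setValidity("DensityGrid", function(object) {
    if (any(object@voxels < 0) || any(!is.finite(object@voxels)))
        return("densities must be finite and non-negative")
    TRUE
})

#' DoseGrid: absorbed dose co-registered with a DensityGrid
#'
#' @name DoseGrid-class
#' @aliases DoseGrid-class
#' @exportClass DoseGrid
setClass("DoseGrid", contains = "VoxelGrid")
setValidity("DoseGrid", function(object) {
    if (any(object@voxels < 0) || any(!is.finite(object@voxels)))
        return("dose must be finite and non-negative (Gy)")
    TRUE
})

#' Construct a DensityGrid
#'
#' @param voxels 3-D numeric array of densities (g/cm^3).
#' @param spacing numeric(3) voxel pitch (mm).
#' @param origin numeric(3) world coordinate of voxel `[1,1,1]` centre (mm).
#' @return A [DensityGrid-class].
#' @export
DensityGrid <- function(voxels, spacing, origin) {
    new("DensityGrid", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Construct a DoseGrid
#'
#' @inheritParams DensityGrid
#' @return A [DoseGrid-class].
#' @export
DoseGrid <- function(voxels, spacing, origin) {
    new("DoseGrid", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' StructureSet: named boolean masks on a voxel grid
#'
#' Holds the segmentation of the phantom (body, lung, heart, rib, implant,
#' portCore, portShell, ptv, skin, ...) as logical arrays sharing one
#' geometry.
#'
#' @slot masks named list of logical 3-D arrays with identical dimensions.
#' @slot spacing numeric(3), mm.
#' @slot origin numeric(3), mm.
#' @name StructureSet-class
#' @aliases StructureSet-class
#' @exportClass StructureSet
setClass("StructureSet",
    representation(masks = "list", spacing = "numeric", origin = "numeric"))
setValidity("StructureSet", function(object) {
    msg <- NULL
    if (length(object@masks) == 0L) msg <- c(msg, "no masks")
    if (is.null(names(object@masks)) || anyDuplicated(names(object@masks)))
        msg <- c(msg, "masks must have unique names")
    dims <- lapply(object@masks, dim)
    if (length(unique(lapply(dims, as.integer))) > 1L)
        msg <- c(msg, "all masks must share one dimension")
    for (m in object@masks)
        if (!is.logical(m) || length(dim(m)) != 3L) {
            msg <- c(msg, "masks must be logical 3-D arrays")
            break
        }
    if (is.null(msg)) TRUE else msg
})

#' Construct a StructureSet
#'
#' @param masks named list of logical 3-D arrays.
#' @param spacing numeric(3), mm.
#' @param origin numeric(3), mm.
#' @return A [StructureSet-class].
#' @export
StructureSet <- function(masks, spacing, origin) {
    new("StructureSet", masks = masks, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Beam: one weighted divergent photon field
#'
#' The aperture is a logical raster in the beam's-eye-view isocentre plane:
#' pixel pitch `du` (mm at isocentre), `u0`/`w0` the BEV coordinates of the
#' centre of pixel `[1, 1]`. `u` runs along the in-plane BEV axis
#' `(cos g, -sin g, 0)` for gantry angle `g`, `w` along +z.
#'
#' @slot gantry gantry angle, degrees (0 = source anterior, 90 = source at
#'   patient-left).
#' @slot sad source-axis distance, mm.
#' @slot iso isocentre, numeric(3) mm.
#' @slot weight non-negative beam weight.
#' @slot aperture list(mask, du, u0, w0).
#' @name Beam-class
#' @aliases Beam-class
#' @exportClass Beam
setClass("Beam",
    representation(gantry = "numeric", sad = "numeric", iso = "numeric",
                   weight = "numeric", aperture = "list"))
setValidity("Beam", function(object) {
    msg <- NULL
    if (length(object@sad) != 1L || object@sad <= 0)
        msg <- c(msg, "SAD must be a single positive value (mm)")
    if (length(object@iso) != 3L || any(!is.finite(object@iso)))
        msg <- c(msg, "isocentre must be 3 finite mm values")
    if (length(object@weight) != 1L || object@weight < 0)
        msg <- c(msg, "weight must be a single non-negative value")
    ap <- object@aperture
    need <- c("mask", "du", "u0", "w0")
    if (!all(need %in% names(ap)))
        msg <- c(msg, "aperture needs fields mask, du, u0, w0")
    else {
        if (!is.matrix(ap$mask) || !is.logical(ap$mask))
            msg <- c(msg, "aperture mask must be a logical matrix")
        else if (object@weight > 0 && !any(ap$mask))
            msg <- c(msg, "aperture is empty but the beam has positive weight")
        if (!is.numeric(ap$du) || ap$du <= 0)
            msg <- c(msg, "aperture pixel pitch du must be positive")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a Beam
#'
#' @param gantry gantry angle (deg).
#' @param iso isocentre (mm).
#' @param aperture list(mask, du, u0, w0); see [Beam-class].
#' @param weight beam weight (>= 0).
#' @param sad source-axis distance (mm), default 1000.
#' @return A [Beam-class].
#' @export
Beam <- function(gantry, iso, aperture, weight = 1, sad = 1000) {
    new("Beam", gantry = as.numeric(gantry), sad = as.numeric(sad),
        iso = as.numeric(iso), weight = as.numeric(weight),
        aperture = aperture)
}

#' Prescription: dose, fractionation and planning constraints
#'
#' Defaults reflect a standard postmastectomy course: 50 Gy in 25 fractions,
#' target objectives D90% > 50 Gy and D2% < 55 Gy, ipsilateral lung
#' Dmean < 16 Gy, V5Gy < 50%, V20Gy < 25%, V40Gy < 10%; heart Dmean < 8 Gy,
#' V5Gy < 50%, V25Gy < 5%, V30Gy < 2.5%.
#'
#' @slot doseGy total prescription dose (Gy).
#' @slot fractions number of fractions.
#' @slot constraints named list of planning objectives (informational).
#' @name Prescription-class
#' @aliases Prescription-class
#' @exportClass Prescription
setClass("Prescription",
    representation(doseGy = "numeric", fractions = "numeric",
                   constraints = "list"))
setValidity("Prescription", function(object) {
    msg <- NULL
    if (object@doseGy <= 0) msg <- c(msg, "prescription dose must be > 0")
    if (object@fractions < 1 || object@fractions != round(object@fractions))
        msg <- c(msg, "fractions must be a positive integer")
    if (is.null(msg)) TRUE else msg
})

#' Default prescription (50 Gy in 25 fractions)
#'
#' @param doseGy total dose, Gy.
#' @param fractions number of fractions.
#' @return A [Prescription-class].
#' @export
Prescription <- function(doseGy = 50, fractions = 25) {
    new("Prescription", doseGy = doseGy, fractions = fractions,
        constraints = list(
            target = c(D90_min_Gy = 50, D2_max_Gy = 55),
            lung = c(Dmean_max_Gy = 16, V5Gy_max_pct = 50,
                     V20Gy_max_pct = 25, V40Gy_max_pct = 10),
            heart = c(Dmean_max_Gy = 8, V5Gy_max_pct = 50,
                      V25Gy_max_pct = 5, V30Gy_max_pct = 2.5)))
}

#' Plan: a delivery technique with its weighted beams
#'
#' @slot technique one of "tangential", "arc", "helical".
#' @slot beams list of [Beam-class].
#' @slot prescription a [Prescription-class].
#' @slot normFactor scale applied to the raw beam weights by
#'   [normalizePlan()]; `NA` until the plan is normalized.
#' @name Plan-class
#' @aliases Plan-class
#' @exportClass Plan
setClass("Plan",
    representation(technique = "character", beams = "list",
                   prescription = "Prescription", normFactor = "numeric"))
setValidity("Plan", function(object) {
    msg <- NULL
    if (!object@technique %in% c("tangential", "arc", "helical"))
        msg <- c(msg, "technique must be tangential, arc or helical")
    if (length(object@beams) == 0L)
        msg <- c(msg, "plan has no beams")
    else {
        if (!all(vapply(object@beams, is, TRUE, "Beam")))
            msg <- c(msg, "beams must all be Beam objects")
        else if (sum(vapply(object@beams, function(b) b@weight, 0)) <= 0)
            msg <- c(msg, "total beam weight must be > 0")
    }
    if (is.null(msg)) TRUE else msg
})

#' ErrorDistribution: per-axis truncated Gaussian mixture of port shifts
#'
#' Each axis is a zero-mean two-component Gaussian mixture (small/large
#' standard deviations), truncated to the measured per-axis supports:
#' lateral [-17, 11] mm, vertical [-10.8, 7.0] mm, longitudinal
#' [-8.0, 7.0] mm. The large-component weight is calibrated so the fraction
#' of 3-D shift magnitudes below 5 mm equals the measured 87%.
#'
#' @slot bounds 3x2 matrix (rows lateral/vertical/longitudinal; cols lo, hi),
#'   mm.
#' @slot sigmaSmall small-error component SD (mm).
#' @slot sigmaLarge large-error component SD (mm).
#' @slot mixWeight probability of the large component, per axis draw.
#' @slot target calibration target: P(3-D magnitude < 5 mm).
#' @name ErrorDistribution-class
#' @aliases ErrorDistribution-class
#' @exportClass ErrorDistribution
setClass("ErrorDistribution",
    representation(bounds = "matrix", sigmaSmall = "numeric",
                   sigmaLarge = "numeric", mixWeight = "numeric",
                   target = "numeric"))
setValidity("ErrorDistribution", function(object) {
    msg <- NULL
    b <- object@bounds
    if (!is.numeric(b) || any(dim(b) != c(3L, 2L)) || any(!is.finite(b)))
        msg <- c(msg, "bounds must be a finite 3x2 numeric matrix (mm)")
    else if (any(b[, 1] >= b[, 2]))
        msg <- c(msg, "each lower bound must be below its upper bound")
    if (object@sigmaSmall <= 0 || object@sigmaLarge <= 0)
        msg <- c(msg, "component SDs must be positive")
    if (object@mixWeight < 0 || object@mixWeight > 1)
        msg <- c(msg, "mixing weight must lie in [0, 1]")
    if (object@target <= 0 || object@target >= 1)
        msg <- c(msg, "calibration target must lie in (0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' ErrorSeries: ordered per-fraction 3-D shifts
#'
#' @slot shifts n x 3 matrix of per-fraction shifts (mm), columns
#'   lateral/vertical/longitudinal.
#' @slot errorClass "IPE" (internal port error) or "PRE" (patient
#'   registration error).
#' @slot scenario "daily" or "systematic".
#' @slot seed seed used to draw the series (NA for constructed series).
#' @name ErrorSeries-class
#' @aliases ErrorSeries-class
#' @exportClass ErrorSeries
setClass("ErrorSeries",
    representation(shifts = "matrix", errorClass = "character",
                   scenario = "character", seed = "numeric"))
setValidity("ErrorSeries", function(object) {
    msg <- NULL
    s <- object@shifts
    if (!is.numeric(s) || ncol(s) != 3L || nrow(s) < 1L || any(!is.finite(s)))
        msg <- c(msg, "shifts must be a finite n x 3 numeric matrix (mm)")
    if (!object@errorClass %in% c("IPE", "PRE"))
        msg <- c(msg, "errorClass must be IPE or PRE")
    if (!object@scenario %in% c("daily", "systematic"))
        msg <- c(msg, "scenario must be daily or systematic")
    if (object@scenario == "systematic" && nrow(s) > 1L &&
        any(apply(s, 2, function(x) diff(range(x))) > 0))
        msg <- c(msg, "systematic series must repeat one shift")
    if (is.null(msg)) TRUE else msg
})

#' Construct an ErrorSeries
#'
#' @param shifts n x 3 numeric matrix, mm.
#' @param errorClass "IPE" or "PRE".
#' @param scenario "daily" or "systematic".
#' @param seed seed the series was drawn with (NA if constructed).
#' @return An [ErrorSeries-class].
#' @export
ErrorSeries <- function(shifts, errorClass, scenario, seed = NA_real_) {
    shifts <- as.matrix(shifts)
    colnames(shifts) <- c("lateral", "vertical", "longitudinal")
    new("ErrorSeries", shifts = shifts, errorClass = errorClass,
        scenario = scenario, seed = as.numeric(seed))
}

#' ScenarioResult: cumulative dose of one modelled scenario
#'
#' @slot spec list(technique, errorClass, scenario).
#' @slot dose cumulative [DoseGrid-class] in the planning-anatomy frame.
#' @slot provenance list: per-fraction shifts, per-fraction integral-dose
#'   checksums, port slice extents reached, seeds.
#' @name ScenarioResult-class
#' @aliases ScenarioResult-class
#' @exportClass ScenarioResult
setClass("ScenarioResult",
    representation(spec = "list", dose = "DoseGrid", provenance = "list"))

#' RobustnessReport: technique x scenario robustness summary
#'
#' One row per scenario: change vs reference in V100%Rx of the peri-implant
#' ROI, V20Gy of the restricted ipsilateral lung and V5Gy of the restricted
#' heart, plus point-dose-difference statistics (mean, IQR, P1, P99, as % of
#' prescription) over the ROI.
#'
#' @slot table data.frame of per-scenario metrics.
#' @slot reference data.frame of reference DVH values per technique.
#' @slot manifest list of provenance (seeds, config hash, versions).
#' @name RobustnessReport-class
#' @aliases RobustnessReport-class
#' @exportClass RobustnessReport
setClass("RobustnessReport",
    representation(table = "data.frame", reference = "data.frame",
                   manifest = "list"))
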