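#' Accessors for voxel-grid and plan objects
#'
#' Slot access goes through these accessors rather than `@`.
#'
#' @param x an expanderRobust object.
#' @param name structure name (for `getMask`).
#' @return `voxelData`: the 3-D array; `gridSpacing`/`gridOrigin`:
#'   numeric(3) mm; `structureNames`: character vector; `getMask`: a logical
#'   array; `planBeams`: list of [Beam-class]; `planTechnique`: character;
#'   `normFactor`: numeric; `errorShifts`: the n x 3 shift matrix;
#'   `reportTable`: the per-scenario data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))
#' @rdname accessors
#' @export
setGeneric("getMask", function(x, name) standardGeneric("getMask"))
#' @rdname accessors
#' @export
setGeneric("planBeams", function(x) standardGeneric("planBeams"))
#' @rdname accessors
#' @export
setGeneric("planTechnique", function(x) standardGeneric("planTechnique"))
#' @rdname accessors
#' @export
setGeneric("normFactor", function(x) standardGeneric("normFactor"))
#' @rdname accessors
#' @export
setGeneric("errorShifts", function(x) standardGeneric("errorShifts"))
#' @rdname accessors
#' @export
setGeneric("scenarioDose", function(x) standardGeneric("scenarioDose"))
#' @rdname accessors
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname accessors
setMethod("voxelData", "VoxelGrid", function(x) x@voxels)
#' @rdname accessors
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)
#' @rdname accessors
setMethod("gridSpacing", "StructureSet", function(x) x@spacing)
#' @rdname accessors
setMethod("gridOrigin", "StructureSet", function(x) x@origin)
#' @rdname accessors
setMethod("structureNames", "StructureSet", function(x) names(x@masks))
#' @rdname accessors
setMethod("getMask", "StructureSet", function(x, name) {
    if (!name %in% names(x@masks))
        stop("structure error: no mask named '", name, "'")
    x@masks[[name]]
})
#' @rdname accessors
setMethod("planBeams", "Plan", function(x) x@beams)
#' @rdname accessors
setMethod("planTechnique", "Plan", function(x) x@technique)
#' @rdname accessors
setMethod("normFactor", "Plan", function(x) x@normFactor)
#' @rdname accessors
setMethod("errorShifts", "ErrorSeries", function(x) x@shifts)
#' @rdname accessors
setMethod("scenarioDose", "ScenarioResult", function(x) x@dose)
#' @rdname accessors
setMethod("reportTable", "RobustnessReport", function(x) x@table)

setMethod("show", "DensityGrid", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("DensityGrid %dx%dx%d voxels @ %s mm\n", d[1], d[2], d[3],
                paste(format(object@spacing), collapse = "x")))
    cat(sprintf("  density range %.3f-%.3f g/cm^3\n",
                min(object@voxels), max(object@voxels)))
})

setMethod("show", "DoseGrid", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("DoseGrid %dx%dx%d voxels @ %s mm, max %.2f Gy\n",
                d[1], d[2], d[3],
                paste(format(object@spacing), collapse = "x"),
                max(object@voxels)))
})

setMethod("show", "StructureSet", function(object) {
    d <- dim(object@masks[[1]])
    cat(sprintf("StructureSet on %dx%dx%d grid: %s\n", d[1], d[2], d[3],
                paste(names(object@masks), collapse = ", ")))
})

setMethod("show", "Plan", function(object) {
    cat(sprintf("Plan <%s>: %d beams, %s\n", object@technique,
                length(object@beams),
                if (is.na(object@normFactor)) "unnormalized"
                else sprintf("normalized (factor %.4g)", object@normFactor)))
})

setMethod("show", "ErrorDistribution", function(object) {
    cat("ErrorDistribution (per-axis truncated Gaussian mixture)\n")
    cat(sprintf("  sigma small/large %.2f/%.2f mm, P(large) = %.4f\n",
                object@sigmaSmall, object@sigmaLarge, object@mixWeight))
    ax <- c("lateral", "vertical", "longitudinal")
    for (i in 1:3)
        cat(sprintf("  %-12s [%.1f, %.1f] mm\n", ax[i],
                    object@bounds[i, 1], object@bounds[i, 2]))
})

setMethod("show", "ErrorSeries", function(object) {
    cat(sprintf("ErrorSeries: %d fractions, class %s, scenario %s\n",
                nrow(object@shifts), object@errorClass, object@scenario))
})

setMethod("show", "ScenarioResult", function(object) {
    cat(sprintf("ScenarioResult [%s / %s / %s], max cumulative dose %.2f Gy\n",
                object@spec$technique, object@spec$errorClass,
                object@spec$scenario, max(object@dose@voxels)))
})

setMethod("show", "RobustnessReport", function(object) {
    cat("RobustnessReport\n")
    print(object@table, row.names = FALSE)
})
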