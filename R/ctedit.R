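# density-grid editing: artefact correction, metal overrides, port shifts

.breastMask <- function(structures) {
    m <- structures@masks
    need <- c("body", "lung", "heart", "rib", "implant")
    miss <- setdiff(need, names(m))
    if (length(miss))
        stop("structure error: missing mask(s) ", paste(miss, collapse = ", "))
    m$body & !(m$lung | m$heart | m$rib | m$implant)
}

#' Correct metal-artefact slices
#'
#' Replaces breast-tissue voxels (outside the implant and port) on the
#' listed z-slices with the mean breast density computed over the
#' artefact-free slices; all other voxels are untouched.
#'
#' @param grid a [DensityGrid-class].
#' @param structures the phantom [StructureSet-class].
#' @param artefactSlices integer z indices carrying artefacts (may be empty).
#' @return The corrected [DensityGrid-class].
#' @export
correctArtefacts <- function(grid, structures, artefactSlices) {
    .stopIfGeometryMismatch(grid, structures)
    if (length(artefactSlices) == 0L) return(grid)
    breast <- .breastMask(structures)
    nz <- dim(grid@voxels)[3]
    artefactSlices <- unique(as.integer(artefactSlices))
    if (any(artefactSlices < 1L | artefactSlices > nz))
        stop("configuration error: artefact slice outside grid")
    clean <- setdiff(seq_len(nz), artefactSlices)
    cleanBreast <- breast
    cleanBreast[, , artefactSlices] <- FALSE
    if (!any(cleanBreast))
        stop("correction error: no artefact-free slice containing breast ",
             "tissue")
    meanBreast <- mean(grid@voxels[cleanBreast])
    vox <- grid@voxels
    sel <- array(FALSE, dim(vox))
    sel[, , artefactSlices] <- breast[, , artefactSlices]
    vox[sel] <- meanBreast
    DensityGrid(vox, grid@spacing, grid@origin)
}

#' Override port component densities with their nominal metal values
#'
#' Titanium shell voxels are set to the shell density (default 4.0 g/cm^3)
#' and magnet-core voxels to the core density (default 8.0 g/cm^3); the
#' operation is idempotent and touches no other voxel.
#'
#' @inheritParams correctArtefacts
#' @param tissues a [tissueModel()].
#' @return The overridden [DensityGrid-class].
#' @export
overridePortDensities <- function(grid, structures,
                                  tissues = defaultTissueModel()) {
    .stopIfGeometryMismatch(grid, structures)
    m <- structures@masks
    if (!all(c("portCore", "portShell") %in% names(m)))
        stop("structure error: missing mask(s) portCore/portShell")
    vox <- grid@voxels
    vox[m$portShell] <- tissues$titanium
    vox[m$portCore] <- tissues$magnet
    DensityGrid(vox, grid@spacing, grid@origin)
}

#' Rigidly shift the metal port inside the anatomy (internal port error)
#'
#' Translates the port core/shell masks by the nearest-voxel rounding of a
#' millimetre shift. Vacated voxels are backfilled with the local background
#' (saline density inside the implant, mean breast density elsewhere);
#' destination voxels are overwritten with the metal densities. Port voxel
#' counts are preserved.
#'
#' @inheritParams overridePortDensities
#' @param shift numeric(3) shift in mm (lateral, vertical, longitudinal).
#' @return `list(grid = DensityGrid, structures = StructureSet)` with the
#'   port masks translated.
#' @export
shiftPort <- function(grid, structures, shift,
                      tissues = defaultTissueModel()) {
    .stopIfGeometryMismatch(grid, structures)
    if (length(shift) != 3L || any(!is.finite(shift)))
        stop("displacement error: shift must be 3 finite mm values")
    m <- structures@masks
    if (!all(c("portCore", "portShell", "body", "implant") %in% names(m)))
        stop("structure error: missing mask(s) for port shift")
    voxShift <- as.integer(round(shift / grid@spacing))
    if (all(voxShift == 0L)) return(list(grid = grid, structures = structures))

    oldPort <- m$portCore | m$portShell
    newCore <- .translateMask(m$portCore, voxShift)
    newShell <- .translateMask(m$portShell, voxShift)
    newPort <- newCore | newShell
    if (sum(newPort) != sum(oldPort) || any(newPort & !m$body)) {
        ax <- c("lateral", "vertical", "longitudinal")
        # report the axis along which the translated port leaves the body
        bad <- which.max(abs(voxShift))
        for (k in order(-abs(voxShift))) {
            probe <- rep(0L, 3); probe[k] <- voxShift[k]
            trial <- .translateMask(oldPort, probe)
            if (sum(trial) != sum(oldPort) || any(trial & !m$body)) {
                bad <- k
                break
            }
        }
        stop("displacement error: shifted port leaves the body along the ",
             ax[bad], " axis")
    }

    breast <- .breastMask(structures)
    meanBreast <- if (any(breast)) mean(grid@voxels[breast]) else
        tissues$breast
    vox <- grid@voxels
    vacated <- oldPort & !newPort
    fillSaline <- vacated & m$implant
    vox[fillSaline] <- tissues$saline
    vox[vacated & !m$implant] <- meanBreast
    vox[newShell] <- tissues$titanium
    vox[newCore] <- tissues$magnet

    m$portCore <- newCore
    m$portShell <- newShell
    list(grid = DensityGrid(vox, grid@spacing, grid@origin),
         structures = StructureSet(m, structures@spacing, structures@origin))
}

#' Override the metal port with tissue-equivalent density
#'
#' Models ignoring the port at planning time: all port voxels (core and
#' shell) are set to the breast/soft-tissue density; every other voxel is
#' bit-identical to the input.
#'
#' @inheritParams overridePortDensities
#' @return The overridden [DensityGrid-class].
#' @export
overridePortAsTissue <- function(grid, structures,
                                 tissues = defaultTissueModel()) {
    .stopIfGeometryMismatch(grid, structures)
    m <- structures@masks
    if (!all(c("portCore", "portShell") %in% names(m)))
        stop("structure error: missing mask(s) portCore/portShell")
    vox <- grid@voxels
    vox[m$portCore | m$portShell] <- tissues$breast
    DensityGrid(vox, grid@spacing, grid@origin)
}
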