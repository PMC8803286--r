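# DVH metrics, dose-difference statistics and the robustness report

#' Build the peri-implant region of interest
#'
#' The ROI is the `expansionMM` isotropic Euclidean dilation of the implant,
#' intersected with the PTV, with the implant interior removed, and
#' restricted to the z-slice range where the metal port is present
#' (including the farthest slices it migrated to during simulation).
#'
#' @param structures the phantom [StructureSet-class] (needs `implant`,
#'   `ptv`; port masks used for the default slice range).
#' @param portSliceExtents integer(2) z-slice range; default: the slices
#'   spanned by the unshifted port.
#' @param expansionMM expansion radius, mm (default 5).
#' @return Logical mask with a `provenance` attribute; empty ROIs are
#'   returned with a warning, not an error.
#' @export
buildRoi <- function(structures, portSliceExtents = NULL, expansionMM = 5) {
    implant <- getMask(structures, "implant")
    ptv <- getMask(structures, "ptv")
    if (is.null(portSliceExtents))
        portSliceExtents <- .portZRange(structures)
    if (length(portSliceExtents) != 2L ||
        portSliceExtents[1] > portSliceExtents[2])
        stop("configuration error: empty port slice range")
    roi <- .dilateMask(implant, expansionMM, structures@spacing) & ptv &
        !implant
    nz <- dim(roi)[3]
    lo <- max(1L, as.integer(portSliceExtents[1]))
    hi <- min(nz, as.integer(portSliceExtents[2]))
    keep <- array(FALSE, dim(roi))
    keep[, , lo:hi] <- TRUE
    roi <- roi & keep
    if (!any(roi)) warning("ROI is empty")
    attr(roi, "provenance") <- list(expansionMM = expansionMM,
                                    sliceRange = c(lo, hi),
                                    truncatedToPTV = TRUE)
    roi
}

#' Voxelwise percent dose-difference map
#'
#' `(dose - reference) / rx * 100`, i.e. differences normalized to the
#' prescription dose.
#'
#' @param dose,reference co-registered [DoseGrid-class] objects.
#' @param rx prescription dose, Gy (> 0).
#' @return Numeric array of percent differences.
#' @export
doseDifferenceMap <- function(dose, reference, rx) {
    .stopIfGeometryMismatch(dose, reference, "dose grids")
    if (rx <= 0) stop("configuration error: rx must be > 0")
    (dose@voxels - reference@voxels) / rx * 100
}

#' Point dose-difference statistics over a mask
#'
#' Mean, interquartile range (P75 - P25), and the 1st/99th percentiles of
#' the masked voxel values. Percentiles use linear interpolation between
#' order statistics (type 7).
#'
#' @param diffmap numeric array (e.g. from [doseDifferenceMap()]).
#' @param mask logical mask, non-empty.
#' @return Named numeric: mean, iqr, p1, p99.
#' @export
pointDoseStats <- function(diffmap, mask) {
    if (!any(mask)) stop("statistics error: mask is empty")
    if (!identical(dim(diffmap), dim(mask)))
        stop("geometry error: diffmap and mask shapes differ")
    v <- diffmap[mask]
    q <- stats::quantile(v, c(0.01, 0.25, 0.75, 0.99), names = FALSE,
                         type = 7)
    c(mean = mean(v), iqr = q[3] - q[2], p1 = q[1], p99 = q[4])
}

#' DVH metric of a dose grid over a mask
#'
#' `V`: percent of mask voxels with dose >= `threshold` Gy (the ">="
#' convention at the threshold). `D`: minimum dose received by the hottest
#' `threshold` percent of the mask volume. `mean`: mean mask dose.
#'
#' @param dose a [DoseGrid-class] (or numeric array).
#' @param mask logical mask, non-empty.
#' @param kind "V", "D" or "mean".
#' @param threshold Gy for `V`, percent volume for `D`.
#' @param rx optional prescription dose: for `V`, `threshold = rx` gives
#'   V100%Rx directly.
#' @return The metric value (percent for `V`, Gy for `D`/`mean`).
#' @export
dvhValue <- function(dose, mask, kind = c("V", "D", "mean"),
                     threshold = NULL, rx = NULL) {
    kind <- match.arg(kind)
    arr <- if (is(dose, "DoseGrid")) dose@voxels else dose
    if (!any(mask)) stop("statistics error: mask is empty")
    v <- arr[mask]
    if (kind == "mean") return(mean(v))
    if (is.null(threshold))
        stop("configuration error: threshold required for V/D metrics")
    if (threshold < 0)
        stop("configuration error: threshold must be >= 0")
    if (kind == "V")
        return(100 * sum(v >= threshold) / length(v))
    # D_x: minimum dose of the hottest x% of the volume
    n <- length(v)
    k <- max(1L, ceiling(n * threshold / 100))
    k <- min(k, n)
    sort(v, decreasing = TRUE)[k]
}

#' Restrict an OAR mask to the ROI's slices
#'
#' Zeroes the organ-at-risk mask outside z-slices where the ROI has at
#' least one voxel.
#'
#' @param oarMask logical OAR mask.
#' @param roi logical ROI mask (co-registered).
#' @return The restricted logical mask.
#' @export
restrictOar <- function(oarMask, roi) {
    if (!identical(dim(oarMask), dim(roi)))
        stop("geometry error: masks are not co-registered")
    keepZ <- apply(roi, 3, any)
    out <- oarMask
    out[, , !keepZ] <- FALSE
    out
}

.scenarioLabel <- function(spec)
    if (spec$scenario %in% c("reference", "override")) spec$scenario else
        paste(spec$scenario, spec$errorClass, sep = "-")

#' Build the robustness report
#'
#' For each scenario result, the change vs the reference in V100%Rx of the
#' ROI, V20Gy of the slice-restricted ipsilateral lung and V5Gy of the
#' slice-restricted heart, plus point dose-difference statistics (percent of
#' prescription) over the ROI.
#'
#' @param reference the reference [ScenarioResult-class].
#' @param scenarios list of [ScenarioResult-class] objects, co-registered
#'   with the reference.
#' @param structures the phantom [StructureSet-class].
#' @param roi ROI mask from [buildRoi()].
#' @param rx prescription dose, Gy.
#' @param manifest optional provenance list stored in the report.
#' @return A [RobustnessReport-class].
#' @export
buildReport <- function(reference, scenarios, structures, roi, rx,
                        manifest = list()) {
    refDose <- reference@dose
    lung <- restrictOar(getMask(structures, "lung"), roi)
    heart <- restrictOar(getMask(structures, "heart"), roi)
    if (!any(roi)) stop("statistics error: ROI is empty")

    refRow <- data.frame(
        technique = reference@spec$technique,
        V100Roi_pct = dvhValue(refDose, roi, "V", rx),
        V20Lung_pct = if (any(lung)) dvhValue(refDose, lung, "V", 20) else NA,
        V5Heart_pct = if (any(heart)) dvhValue(refDose, heart, "V", 5) else NA)

    rows <- lapply(scenarios, function(sc) {
        .stopIfGeometryMismatch(sc@dose, refDose, "scenario dose grids")
        dm <- doseDifferenceMap(sc@dose, refDose, rx)
        st <- pointDoseStats(dm, roi)
        data.frame(
            technique = sc@spec$technique,
            errorClass = sc@spec$errorClass,
            scenario = .scenarioLabel(sc@spec),
            dV100Roi_pct = dvhValue(sc@dose, roi, "V", rx) -
                refRow$V100Roi_pct,
            dV20Lung_pct = if (any(lung))
                dvhValue(sc@dose, lung, "V", 20) - refRow$V20Lung_pct else NA,
            dV5Heart_pct = if (any(heart))
                dvhValue(sc@dose, heart, "V", 5) - refRow$V5Heart_pct else NA,
            meanDiff_pct = unname(st["mean"]),
            iqrDiff_pct = unname(st["iqr"]),
            p1Diff_pct = unname(st["p1"]),
            p99Diff_pct = unname(st["p99"]))
    })
    new("RobustnessReport", table = do.call(rbind, rows),
        reference = refRow, manifest = manifest)
}
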