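# scenario execution: cumulative dose in the planning-anatomy frame

.assertNormalized <- function(plan) {
    if (is.na(plan@normFactor))
        stop("scenario error: plan must be normalized first")
    invisible(TRUE)
}

.portZRange <- function(structures) {
    port <- getMask(structures, "portCore") | getMask(structures, "portShell")
    zs <- which(apply(port, 3, any))
    if (!length(zs)) stop("structure error: port masks are empty")
    range(zs)
}

.integralDose <- function(doseArr, spacing)
    sum(doseArr) * prod(spacing) / 1000  # Gy * cm^3

#' Run the reference scenario
#'
#' The full normalized plan dose on the density-corrected grid with neither
#' the port nor the patient displaced.
#'
#' @param grid the density-corrected planning [DensityGrid-class].
#' @param structures the phantom [StructureSet-class].
#' @param plan a normalized [Plan-class].
#' @inheritParams computeBeamDose
#' @return A [ScenarioResult-class].
#' @export
runReference <- function(grid, structures, plan, muW = 0.049,
                         scatterSigma = 5) {
    .assertNormalized(plan)
    dose <- computePlanDose(grid, plan, muW, scatterSigma)
    new("ScenarioResult",
        spec = list(technique = plan@technique, errorClass = "none",
                    scenario = "reference"),
        dose = dose,
        provenance = list(fractions = 1L,
                          checksums = .integralDose(dose@voxels,
                                                    grid@spacing),
                          portZRange = .portZRange(structures)))
}

#' Run a daily-variable error scenario
#'
#' For each fraction the fraction's shift is applied as an internal port
#' error (the port is shifted inside the anatomy) or a patient registration
#' error (the beams are shifted), the plan dose is computed and scaled by
#' 1/fractions, and the per-fraction doses are summed. The cumulative dose
#' is registered to the unperturbed planning anatomy.
#'
#' @inheritParams runReference
#' @param series an [ErrorSeries-class] with scenario "daily" and length
#'   equal to the prescription's fraction count.
#' @param tissues a [tissueModel()] (backfill densities for port shifts).
#' @param keepFractionDoses if TRUE, per-fraction [DoseGrid-class] objects
#'   are kept in the provenance (memory-heavy; default FALSE).
#' @return A [ScenarioResult-class].
#' @export
runDaily <- function(grid, structures, plan, series,
                     tissues = defaultTissueModel(), muW = 0.049,
                     scatterSigma = 5, keepFractionDoses = FALSE) {
    .assertNormalized(plan)
    validObject(series)
    if (series@scenario != "daily")
        stop("scenario error: series scenario tag is '", series@scenario,
             "', expected 'daily'")
    nf <- plan@prescription@fractions
    if (nrow(series@shifts) != nf)
        stop("scenario error: series length ", nrow(series@shifts),
             " does not match ", nf, " fractions")
    dims <- dim(grid@voxels)
    cum <- array(0, dims)
    sums <- numeric(nf)
    zR <- .portZRange(structures)
    kept <- if (keepFractionDoses) vector("list", nf) else NULL
    # fractions with identical effective shifts share one full-weight
    # calculation, scaled by their multiplicity: exact under the linear
    # engine, and an all-equal series reproduces a single plan calculation
    # bit for bit (multiplicity/nf is then exactly 1)
    keys <- apply(series@shifts, 1, function(sh) {
        eff <- if (series@errorClass == "IPE")
            round(sh / grid@spacing) else sh
        paste(sprintf("%.12g", eff), collapse = ",")
    })
    for (grp in split(seq_len(nf), factor(keys, levels = unique(keys)))) {
        sh <- series@shifts[grp[1], ]
        if (series@errorClass == "IPE") {
            moved <- shiftPort(grid, structures, sh, tissues)
            d <- computePlanDose(moved$grid, plan, muW, scatterSigma)
            zR <- range(c(zR, .portZRange(moved$structures)))
        } else {
            d <- computePlanDose(grid, applyPre(plan, sh), muW, scatterSigma)
        }
        cum <- cum + d@voxels * (length(grp) / nf)
        sums[grp] <- .integralDose(d@voxels, grid@spacing) / nf
        if (keepFractionDoses)
            for (i in grp)
                kept[[i]] <- DoseGrid(d@voxels / nf, grid@spacing,
                                      grid@origin)
    }
    new("ScenarioResult",
        spec = list(technique = plan@technique,
                    errorClass = series@errorClass, scenario = "daily"),
        dose = DoseGrid(cum, grid@spacing, grid@origin),
        provenance = list(fractions = nf, shifts = series@shifts,
                          seed = series@seed, checksums = sums,
                          portZRange = zR, fractionDoses = kept))
}

#' Run a systematic error scenario
#'
#' One perturbed full-plan calculation; because the plan carries the
#' total-course weights, the single calculation already equals the
#' fraction-count multiple of a per-fraction perturbed dose.
#'
#' @inheritParams runDaily
#' @param shift numeric(3) persistent shift, mm.
#' @param errorClass "IPE" or "PRE".
#' @return A [ScenarioResult-class].
#' @export
runSystematic <- function(grid, structures, plan, shift,
                          errorClass = c("IPE", "PRE"),
                          tissues = defaultTissueModel(), muW = 0.049,
                          scatterSigma = 5) {
    errorClass <- match.arg(errorClass)
    .assertNormalized(plan)
    zR <- .portZRange(structures)
    if (errorClass == "IPE") {
        moved <- shiftPort(grid, structures, shift, tissues)
        dose <- computePlanDose(moved$grid, plan, muW, scatterSigma)
        zR <- range(c(zR, .portZRange(moved$structures)))
    } else {
        dose <- computePlanDose(grid, applyPre(plan, shift), muW,
                                scatterSigma)
    }
    new("ScenarioResult",
        spec = list(technique = plan@technique, errorClass = errorClass,
                    scenario = "systematic"),
        dose = dose,
        provenance = list(fractions = 1L, shifts = matrix(shift, 1),
                          checksums = .integralDose(dose@voxels,
                                                    grid@spacing),
                          portZRange = zR))
}

#' Run the ignore-the-port scenario
#'
#' The full plan recomputed on a grid where the metal port is overridden
#' with tissue-equivalent density, for comparison against the
#' metal-inclusive reference.
#'
#' @inheritParams runDaily
#' @return A [ScenarioResult-class].
#' @export
runOverride <- function(grid, structures, plan,
                        tissues = defaultTissueModel(), muW = 0.049,
                        scatterSigma = 5) {
    .assertNormalized(plan)
    g2 <- overridePortAsTissue(grid, structures, tissues)
    dose <- computePlanDose(g2, plan, muW, scatterSigma)
    new("ScenarioResult",
        spec = list(technique = plan@technique, errorClass = "none",
                    scenario = "override"),
        dose = dose,
        provenance = list(fractions = 1L,
                          checksums = .integralDose(dose@voxels,
                                                    grid@spacing),
                          portZRange = .portZRange(structures)))
}
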