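# end-to-end orchestration: phantom -> plans -> scenario matrix -> report

#' Default run configuration
#'
#' Bundles the phantom geometry, tissue model, HU calibration, prescription,
#' plan parameters, error distribution, scenario matrix and seeds for
#' [runPipeline()].
#'
#' @param seed master seed; all randomness in a run flows from it.
#' @param techniques subset of c("tangential", "arc", "helical").
#' @param scenarios subset of c("reference", "daily-IPE", "daily-PRE",
#'   "sys-IPE", "sys-PRE", "override").
#' @param phantom a [phantomConfig()].
#' @param outDir optional output directory for report/manifest files.
#' @return A named list of class `RunConfig`.
#' @export
defaultRunConfig <- function(seed = 1L,
                             techniques = c("tangential", "arc", "helical"),
                             scenarios = c("reference", "daily-IPE",
                                           "daily-PRE", "sys-IPE", "sys-PRE",
                                           "override"),
                             phantom = phantomConfig(),
                             outDir = NULL) {
    cfg <- list(
        phantom = phantom,
        tissues = defaultTissueModel(),
        calibration = defaultHUCalibration(),
        prescription = Prescription(),
        plan = planParams(),
        errors = NULL,              # NULL -> defaultErrorDistribution()
        systematicShift = NULL,     # NULL -> largest measured bound
        engine = list(muW = 0.049, scatterSigma = 5),
        techniques = techniques,
        scenarios = scenarios,
        seed = as.integer(seed),
        outDir = outDir)
    class(cfg) <- "RunConfig"
    cfg
}

#' Read a run configuration from YAML
#'
#' Any subset of the [defaultRunConfig()] sections may be given; missing
#' entries keep their defaults. The `phantom` and `plan` sections are passed
#' to [phantomConfig()] and [planParams()].
#'
#' @param path YAML file path.
#' @return A `RunConfig` list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("format error: config file not found")
    y <- yaml::read_yaml(path)
    cfg <- defaultRunConfig()
    if (!is.null(y$phantom)) cfg$phantom <- do.call(phantomConfig, y$phantom)
    if (!is.null(y$plan)) cfg$plan <- do.call(planParams, y$plan)
    if (!is.null(y$tissues)) cfg$tissues <- do.call(tissueModel, y$tissues)
    if (!is.null(y$prescription))
        cfg$prescription <- do.call(Prescription, y$prescription)
    if (!is.null(y$engine)) cfg$engine <- utils::modifyList(cfg$engine,
                                                            y$engine)
    for (f in c("techniques", "scenarios", "seed", "outDir",
                "systematicShift"))
        if (!is.null(y[[f]])) cfg[[f]] <- y[[f]]
    cfg$seed <- as.integer(cfg$seed)
    cfg
}

.buildPlan <- function(technique, structures, params, prescription) {
    switch(technique,
           tangential = makeTangentialPlan(structures, params, prescription),
           arc = makeArcPlan(structures, params, prescription),
           helical = makeHelicalPlan(structures, params, prescription),
           stop("configuration error: unknown technique '", technique, "'"))
}

# z-slice extents reached by the port under the modelled IPE shifts
.portExtentsUnderErrors <- function(structures, series, sysShift, scenarios) {
    zR <- .portZRange(structures)
    dz <- structures@spacing[3]
    zs <- numeric(0)
    if ("daily-IPE" %in% scenarios) zs <- c(zs, series@shifts[, 3])
    if ("sys-IPE" %in% scenarios) zs <- c(zs, sysShift[3])
    if (length(zs))
        zR <- zR + c(min(0, round(min(zs) / dz)), max(0, round(max(zs) / dz)))
    nz <- dim(getMask(structures, "ptv"))[3]
    c(max(1, zR[1]), min(nz, zR[2]))
}

#' Run the full robustness pipeline
#'
#' Executes phantom generation, per-technique plan construction and
#' normalization, the configured scenario matrix (reference, daily and
#' systematic internal-port and patient-registration errors, port
#' tissue-override) and assembles the robustness report. Every stage is
#' logged via `message()`; a run manifest (config hash, seeds, checksums)
#' is attached to the report and written alongside it when `outDir` is set.
#'
#' @param config a `RunConfig` from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @return A [RobustnessReport-class].
#' @export
runPipeline <- function(config = defaultRunConfig()) {
    stage <- function(...) message("[expanderRobust] ", ...)
    stage("generating phantom")
    ph <- generatePhantom(config$phantom, config$tissues)
    grid <- ph$grid
    structures <- ph$structures
    if (!is.null(config$phantom$artefactSlices)) {
        stage("correcting artefact slices")
        grid <- correctArtefacts(grid, structures,
                                 config$phantom$artefactSlices)
    }
    grid <- overridePortDensities(grid, structures, config$tissues)

    dist <- if (is.null(config$errors)) defaultErrorDistribution() else
        config$errors
    nf <- config$prescription@fractions
    seriesIPE <- sampleErrorSeries(dist, nf, config$seed, "IPE")
    seriesPRE <- ErrorSeries(seriesIPE@shifts, "PRE", "daily",
                             config$seed)
    sysShift <- systematicShift(dist, config$systematicShift)
    extents <- .portExtentsUnderErrors(structures, seriesIPE, sysShift,
                                       config$scenarios)
    roi <- buildRoi(structures, extents)
    rx <- config$prescription@doseGy
    muW <- config$engine$muW
    sig <- config$engine$scatterSigma

    tables <- list()
    refs <- list()
    checks <- list()
    for (tech in config$techniques) {
        stage("building and normalizing ", tech, " plan")
        plan <- .buildPlan(tech, structures, config$plan,
                           config$prescription)
        plan <- normalizePlan(plan, grid, structures, muW, sig)
        stage("running reference scenario (", tech, ")")
        ref <- runReference(grid, structures, plan, muW, sig)
        runs <- list()
        for (sc in setdiff(config$scenarios, "reference")) {
            stage("running scenario ", sc, " (", tech, ")")
            runs[[sc]] <- switch(sc,
                "daily-IPE" = runDaily(grid, structures, plan, seriesIPE,
                                       config$tissues, muW, sig),
                "daily-PRE" = runDaily(grid, structures, plan, seriesPRE,
                                       config$tissues, muW, sig),
                "sys-IPE" = runSystematic(grid, structures, plan, sysShift,
                                          "IPE", config$tissues, muW, sig),
                "sys-PRE" = runSystematic(grid, structures, plan, sysShift,
                                          "PRE", config$tissues, muW, sig),
                "override" = runOverride(grid, structures, plan,
                                         config$tissues, muW, sig),
                stop("configuration error: unknown scenario '", sc, "'"))
        }
        scList <- if ("reference" %in% config$scenarios)
            c(list(reference = ref), runs) else runs
        rep <- buildReport(ref, scList, structures, roi, rx)
        tables[[tech]] <- rep@table
        refs[[tech]] <- rep@reference
        checks[[tech]] <- lapply(runs, function(r) r@provenance$checksums)
    }

    manifest <- list(
        package = "expanderRobust",
        version = as.character(utils::packageVersion("expanderRobust")),
        seed = config$seed,
        systematicShift = sysShift,
        mixWeight = dist@mixWeight,
        portSliceExtents = extents,
        configHash = .configHash(list(
            phantom = unclass(config$phantom), plan = config$plan,
            engine = config$engine, techniques = config$techniques,
            scenarios = config$scenarios, seed = config$seed)),
        checksums = checks)
    report <- new("RobustnessReport", table = do.call(rbind, tables),
                  reference = do.call(rbind, refs), manifest = manifest)

    if (!is.null(config$outDir)) {
        stage("writing outputs to ", config$outDir)
        writeReport(report, config$outDir)
        writeErrorSeries(seriesIPE,
                         file.path(config$outDir, "error_series.csv"))
    }
    report
}
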