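# shared fixtures, memoised so expensive phantoms/plans are built once

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
    if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
    .fixtures[[key]]
}

# coarse phantom for module-level tests (fast: 64x64x32 at 5 mm; the port is
# enlarged so its shell is resolved at this pitch)
smallConfig <- function(...) {
    phantomConfig(gridShape = c(64L, 64L, 32L), voxelSize = c(5, 5, 5),
                  portCoreRadius = 7.5, portCoreHalfHeight = 7.5,
                  portShellThickness = 5, ...)
}

smallPhantom <- function() memo("smallPhantom", function() {
    ph <- generatePhantom(smallConfig())
    ph$grid <- overridePortDensities(ph$grid, ph$structures)
    ph
})

# fine (default-geometry) phantom shared by the acceptance-style checks
defaultPhantom <- function() memo("defaultPhantom", function() {
    ph <- generatePhantom()
    ph$grid <- overridePortDensities(ph$grid, ph$structures)
    ph
})

# normalized plan + reference scenario per technique on the default phantom
defaultPlan <- function(technique) memo(paste0("plan.", technique), function() {
    ph <- defaultPhantom()
    plan <- switch(technique,
                   tangential = makeTangentialPlan(ph$structures),
                   arc = makeArcPlan(ph$structures),
                   helical = makeHelicalPlan(ph$structures))
    normalizePlan(plan, ph$grid, ph$structures)
})

defaultReference <- function(technique) memo(paste0("ref.", technique),
    function() {
        ph <- defaultPhantom()
        runReference(ph$grid, ph$structures, defaultPlan(technique))
    })

defaultRoi <- function() memo("roi", function() buildRoi(
    defaultPhantom()$structures))

# uniform water grid centred on the origin
waterGrid <- function(dims = c(60L, 60L, 40L), sp = c(2.5, 2.5, 2.5),
                      density = 1) {
    DensityGrid(array(density, dims), sp, -(dims - 1) * sp / 2)
}

# wide-open rectangular aperture beam
openBeam <- function(gantry = 0, iso = c(0, 0, 0), half = 50, du = 2.5,
                     weight = 1, sad = 1000) {
    n <- floor(2 * half / du)
    u0 <- -half + du / 2
    Beam(gantry, iso,
         list(mask = matrix(TRUE, n, n), du = du, u0 = u0, w0 = u0),
         weight = weight, sad = sad)
}

# dense-sampling quadrature oracle for the radiological path
quadraturePath <- function(grid, p0, p1, n = 10000) {
    t <- (seq_len(n) - 0.5) / n
    pts <- outer(t, p1 - p0) + matrix(p0, n, 3, byrow = TRUE)
    dims <- dim(voxelData(grid))
    sp <- gridSpacing(grid); org <- gridOrigin(grid)
    idx <- sapply(1:3, function(k)
        round((pts[, k] - org[k]) / sp[k]) + 1)
    inb <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
        idx[, 2] >= 1 & idx[, 2] <= dims[2] &
        idx[, 3] >= 1 & idx[, 3] <= dims[3]
    v <- numeric(n)
    v[inb] <- voxelData(grid)[idx[inb, , drop = FALSE]]
    0.1 * mean(v) * sqrt(sum((p1 - p0)^2))
}

# exhaustive-counting DVH oracle
oracleV <- function(doseVals, thr) 100 * sum(doseVals >= thr) /
    length(doseVals)
oracleD <- function(doseVals, pct) {
    n <- length(doseVals)
    k <- min(n, max(1L, ceiling(n * pct / 100)))
    sort(doseVals, decreasing = TRUE)[k]
}
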