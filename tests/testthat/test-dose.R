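test_that("radiological path is exact on analytic segments", {
    wat <- waterGrid()
    # 100 mm through unit density = 10 g/cm^2
    expect_equal(radiologicalPath(wat, c(-50, 0, 0), c(50, 0, 0)), 10)
    # entirely outside the grid
    expect_equal(radiologicalPath(wat, c(500, 500, 0), c(500, 500, 100)), 0)
    # symmetry and additivity over subsegments
    p0 <- c(-61, -40, -33); p1 <- c(55, 70, 41); pm <- (p0 + p1) / 2
    expect_equal(radiologicalPath(wat, p0, p1),
                 radiologicalPath(wat, p1, p0))
    expect_equal(radiologicalPath(wat, p0, p1),
                 radiologicalPath(wat, p0, pm) +
                 radiologicalPath(wat, pm, p1))
    expect_error(radiologicalPath(wat, p0, p0), "must differ")
})

test_that("radiological path agrees with dense-sampling quadrature", {
    set.seed(7)
    dims <- c(60L, 60L, 40L)
    het <- DensityGrid(array(runif(prod(dims), 0.2, 2), dims),
                       c(2.5, 2.5, 2.5), -(dims - 1) * 2.5 / 2)
    for (i in 1:5) {
        p0 <- runif(3, -60, 60); p1 <- runif(3, -60, 60)
        a <- radiologicalPath(het, p0, p1)
        b <- quadraturePath(het, p0, p1)
        expect_lt(abs(a - b) / max(b, 1e-9), 0.005)
    }
})

test_that("central-axis dose falls exponentially with radiological depth", {
    wat <- waterGrid()
    b <- openBeam(gantry = 0)
    d <- voxelData(computeBeamDose(wat, b, scatterSigma = 0))
    # the beam travels -y from a source at y = +1000
    y <- gridOrigin(wat)[2] + (seq_len(60) - 1) * 2.5
    cax <- d[31, , 20]
    i1 <- 55; i2 <- 35
    geo <- ((1000 - y[i1]) / (1000 - y[i2]))^2      # inverse square
    atten <- exp(-0.049 * (y[i1] - y[i2]) / 10)     # mu = 0.049 cm^-1
    expect_equal(cax[i2] / cax[i1], atten * geo, tolerance = 1e-6)
})

test_that("a dense slab attenuates the distal pre-blur dose analytically", {
    wat <- waterGrid()
    slab <- voxelData(wat)
    # 10 mm slab of density 8 at y in (20, 30]
    y <- gridOrigin(wat)[2] + (seq_len(60) - 1) * 2.5
    sel <- y > 20 & y <= 30
    slab[, sel, ] <- 8
    gSlab <- DensityGrid(slab, gridSpacing(wat), gridOrigin(wat))
    b <- openBeam(gantry = 0)
    d0 <- voxelData(computeBeamDose(wat, b, scatterSigma = 0))
    d1 <- voxelData(computeBeamDose(gSlab, b, scatterSigma = 0))
    distal <- which(y < 15)[5]
    expect_equal(d1[31, distal, 20] / d0[31, distal, 20],
                 exp(-0.049 * (8 - 1) * 1.0), tolerance = 1e-6)
    # shadow monotonicity: denser material never raises the distal dose
    expect_true(all(d1[31, y < 20, 20] <= d0[31, y < 20, 20]))
})

test_that("dose outside the aperture edge is penumbral only", {
    wat <- waterGrid(dims = c(80L, 60L, 40L))
    b <- openBeam(gantry = 0, half = 25)
    d <- voxelData(computeBeamDose(wat, b, scatterSigma = 5))
    x <- gridOrigin(wat)[1] + (seq_len(80) - 1) * 2.5
    iy <- 30  # mid depth
    cax <- d[which.min(abs(x)), iy, 20]
    # voxels laterally farther than 3 sigma beyond the field edge get < 1%
    far <- abs(x) > 25 * (1000 - (gridOrigin(wat)[2] + (iy - 1) * 2.5)) /
        1000 + 3 * 5
    expect_true(all(d[far, iy, 20] < 0.01 * cax))
})

test_that("dose is linear in beam weight and superposes over beams", {
    ph <- smallPhantom()
    plan <- makeTangentialPlan(ph$structures)
    beams <- planBeams(plan)
    d1 <- computeBeamDose(ph$grid, beams[[1]])
    b2 <- beams[[1]]; b2@weight <- 2 * b2@weight
    expect_equal(voxelData(computeBeamDose(ph$grid, b2)),
                 2 * voxelData(d1), tolerance = 1e-12)
    total <- computePlanDose(ph$grid, plan)
    sumBeams <- voxelData(computeBeamDose(ph$grid, beams[[1]])) +
        voxelData(computeBeamDose(ph$grid, beams[[2]]))
    expect_equal(voxelData(total), sumBeams, tolerance = 1e-10)
})

test_that("a zero-size aperture with positive weight is a plan error", {
    ph <- smallPhantom()
    expect_error(
        Beam(0, c(0, 0, 0),
             list(mask = matrix(FALSE, 4, 4), du = 2.5, u0 = 0, w0 = 0),
             weight = 1),
        "aperture is empty")
})
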