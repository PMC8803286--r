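test_that("artefact correction restores streaked breast tissue", {
    clean <- generatePhantom(smallConfig())
    noisy <- generatePhantom(smallConfig(artefactSlices = 14:16))
    expect_false(identical(voxelData(noisy$grid), voxelData(clean$grid)))
    fixed <- correctArtefacts(noisy$grid, noisy$structures, 14:16)
    # breast density is uniform off the artefact slices, so correction
    # recovers the clean phantom exactly (well within the 1% requirement)
    expect_equal(voxelData(fixed), voxelData(clean$grid), tolerance = 1e-12)
    # empty artefact list is a no-op
    expect_identical(correctArtefacts(clean$grid, clean$structures,
                                      integer(0)), clean$grid)
})

test_that("artefact correction requires an artefact-free breast slice", {
    ph <- smallPhantom()
    nz <- dim(voxelData(ph$grid))[3]
    expect_error(correctArtefacts(ph$grid, ph$structures, seq_len(nz)),
                 "correction error")
})

test_that("port density override sets nominal metal values and is idempotent", {
    ph <- generatePhantom(smallConfig())
    g1 <- overridePortDensities(ph$grid, ph$structures)
    core <- getMask(ph$structures, "portCore")
    shell <- getMask(ph$structures, "portShell")
    expect_true(all(voxelData(g1)[core] == 8.0))
    expect_true(all(voxelData(g1)[shell] == 4.0))
    expect_identical(voxelData(overridePortDensities(g1, ph$structures)),
                     voxelData(g1))
    # non-port voxels untouched
    other <- !(core | shell)
    expect_identical(voxelData(g1)[other], voxelData(ph$grid)[other])
    expect_error(overridePortDensities(
        ph$grid, StructureSet(list(body = getMask(ph$structures, "body")),
                              gridSpacing(ph$grid), gridOrigin(ph$grid))),
        "structure error")
})

test_that("port shift translates masks by whole voxels and conserves counts", {
    ph <- defaultPhantom()
    res <- shiftPort(ph$grid, ph$structures, c(5, 0, 0))  # 2 voxels lateral
    m0 <- which(getMask(ph$structures, "portCore"), arr.ind = TRUE)
    m1 <- which(getMask(res$structures, "portCore"), arr.ind = TRUE)
    expect_identical(m1[, 1], m0[, 1] + 2L)
    expect_identical(m1[, 2], m0[, 2])
    expect_identical(m1[, 3], m0[, 3])
    # voxel count conserved for random in-bounds shifts
    set.seed(11)
    n0 <- sum(getMask(ph$structures, "portCore")) +
        sum(getMask(ph$structures, "portShell"))
    for (i in 1:8) {
        sh <- runif(3, -10, 10)
        r <- shiftPort(ph$grid, ph$structures, sh)
        expect_identical(sum(getMask(r$structures, "portCore")) +
                         sum(getMask(r$structures, "portShell")), n0)
        expect_identical(gridSpacing(r$grid), gridSpacing(ph$grid))
        expect_identical(gridOrigin(r$grid), gridOrigin(ph$grid))
    }
})

test_that("port shift round-trips and zero shift is the identity", {
    ph <- defaultPhantom()
    expect_identical(shiftPort(ph$grid, ph$structures, c(0, 0, 0))$grid,
                     ph$grid)
    fwd <- shiftPort(ph$grid, ph$structures, c(5, -5, 2.5))
    back <- shiftPort(fwd$grid, fwd$structures, c(-5, 5, -2.5))
    expect_identical(voxelData(back$grid), voxelData(ph$grid))
    expect_identical(back$structures@masks, ph$structures@masks)
})

test_that("port shift out of the body reports the offending axis", {
    ph <- smallPhantom()
    expect_error(shiftPort(ph$grid, ph$structures, c(250, 0, 0)),
                 "displacement error.*lateral")
    expect_error(shiftPort(ph$grid, ph$structures, c(0, 0, 400)),
                 "displacement error.*longitudinal")
})

test_that("tissue override of the port lowers density only inside the port", {
    ph <- defaultPhantom()
    tm <- defaultTissueModel()
    g2 <- overridePortAsTissue(ph$grid, ph$structures, tm)
    port <- getMask(ph$structures, "portCore") |
        getMask(ph$structures, "portShell")
    expect_equal(max(voxelData(g2)[port]), tm$breast)
    expect_identical(voxelData(g2)[!port], voxelData(ph$grid)[!port])
    expect_lt(mean(voxelData(g2)), mean(voxelData(ph$grid)))
})

test_that("artefact correction and port override commute", {
    noisy <- generatePhantom(smallConfig(artefactSlices = 14:16))
    a <- overridePortDensities(correctArtefacts(noisy$grid, noisy$structures,
                                                14:16), noisy$structures)
    b <- correctArtefacts(overridePortDensities(noisy$grid,
                                                noisy$structures),
                          noisy$structures, 14:16)
    expect_equal(voxelData(a), voxelData(b), tolerance = 1e-12)
})
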