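shellStructures <- function(rImplant = 30, dims = c(64L, 64L, 64L),
                            sp = 2.5, ptv = NULL) {
    org <- -(dims - 1) * sp / 2
    cc <- lapply(1:3, function(k) org[k] + (seq_len(dims[k]) - 1) * sp)
    r2 <- outer(outer(cc[[1]]^2, cc[[2]]^2, `+`), cc[[3]]^2, `+`)
    implant <- r2 <= rImplant^2
    if (is.null(ptv)) ptv <- array(TRUE, dims)
    StructureSet(list(implant = implant, ptv = ptv,
                      portCore = implant & r2 <= 5^2,
                      portShell = array(FALSE, dims)),
                 rep(sp, 3), org)
}

test_that("the ROI matches the analytic 5-mm shell around the implant", {
    s <- shellStructures()
    roi <- buildRoi(s, portSliceExtents = c(1, 64))
    analytic <- 4 / 3 * pi * (35^3 - 30^3) / 2.5^3
    expect_lt(abs(sum(roi) - analytic) / analytic, 0.07)
    # implant abutting the PTV boundary truncates the shell
    dims <- c(64L, 64L, 64L)
    half <- array(FALSE, dims); half[1:32, , ] <- TRUE
    sTr <- shellStructures(ptv = half)
    expect_lt(sum(buildRoi(sTr, c(1, 64))), sum(roi))
    # zero expansion gives an empty ROI (warning, not error)
    expect_warning(roi0 <- buildRoi(s, c(1, 64), expansionMM = 0),
                   "empty")
    expect_equal(sum(roi0), 0)
    # slice restriction is recorded and enforced
    roiZ <- buildRoi(s, portSliceExtents = c(30, 35))
    expect_true(all(which(apply(roiZ, 3, any)) %in% 30:35))
    expect_equal(attr(roiZ, "provenance")$sliceRange, c(30, 35))
})

test_that("dose-difference maps are normalized to prescription and antisymmetric", {
    dims <- c(10L, 10L, 5L)
    a <- DoseGrid(array(runif(500, 0, 60), dims), c(2, 2, 2), c(0, 0, 0))
    b <- DoseGrid(array(runif(500, 0, 60), dims), c(2, 2, 2), c(0, 0, 0))
    expect_true(all(doseDifferenceMap(a, a, 50) == 0))
    shifted <- DoseGrid(voxelData(a) + 5, c(2, 2, 2), c(0, 0, 0))
    expect_equal(doseDifferenceMap(shifted, a, 50),
                 array(10, dims))
    expect_equal(doseDifferenceMap(a, b, 50), -doseDifferenceMap(b, a, 50))
    bad <- DoseGrid(array(0, c(9L, 10L, 5L)), c(2, 2, 2), c(0, 0, 0))
    expect_error(doseDifferenceMap(a, bad, 50), "geometry error")
})

test_that("point dose statistics follow the order-statistic conventions", {
    dims <- c(10L, 10L, 1L)
    m <- array(TRUE, dims)
    const <- array(3.5, dims)
    st <- pointDoseStats(const, m)
    expect_equal(unname(st), c(3.5, 0, 3.5, 3.5))
    vals <- array(sample(1:100), dims)
    st <- pointDoseStats(vals, m)
    expect_equal(unname(st["p1"]), 1.99)
    expect_equal(unname(st["p99"]), 99.01)
    expect_equal(unname(st["iqr"]), unname(quantile(1:100, 0.75) -
                                           quantile(1:100, 0.25)))
    # invariant under mask-preserving permutations
    st2 <- pointDoseStats(array(sample(1:100), dims), m)
    expect_equal(st, st2)
    expect_error(pointDoseStats(const, array(FALSE, dims)),
                 "statistics error")
})

test_that("DVH metrics match an exhaustive counting oracle", {
    dims <- c(8L, 8L, 4L)
    half <- array(c(rep(60, 128), rep(40, 128)), dims)
    m <- array(TRUE, dims)
    g <- DoseGrid(half, c(1, 1, 1), c(0, 0, 0))
    expect_equal(dvhValue(g, m, "V", 50), 50)
    expect_equal(dvhValue(g, m, "D", 90), 40)
    uni <- DoseGrid(array(50, dims), c(1, 1, 1), c(0, 0, 0))
    expect_equal(dvhValue(uni, m, "V", 50), 100)
    set.seed(5)
    for (i in 1:25) {
        vals <- array(runif(prod(dims), 0, 70), dims)
        mask <- array(runif(prod(dims)) < 0.6, dims)
        if (!any(mask)) next
        thr <- runif(1, 0, 70)
        pct <- runif(1, 1, 99)
        expect_identical(dvhValue(vals, mask, "V", thr),
                         oracleV(vals[mask], thr))
        expect_identical(dvhValue(vals, mask, "D", pct),
                         oracleD(vals[mask], pct))
        expect_identical(dvhValue(vals, mask, "mean"), mean(vals[mask]))
    }
})

test_that("V and D are monotone and mutually consistent", {
    set.seed(9)
    vals <- array(runif(512, 0, 70), c(8L, 8L, 8L))
    m <- array(TRUE, dim(vals))
    xs <- seq(5, 65, by = 5)
    vs <- vapply(xs, function(x) dvhValue(vals, m, "V", x), 0)
    expect_true(all(diff(vs) <= 0))
    ps <- seq(10, 90, by = 10)
    ds <- vapply(ps, function(p) dvhValue(vals, m, "D", p), 0)
    expect_true(all(diff(ds) <= 0))
    for (p in ps)
        expect_gte(dvhValue(vals, m, "V", dvhValue(vals, m, "D", p)), p)
})

test_that("OAR restriction keeps only slices where the ROI lives", {
    dims <- c(6L, 6L, 10L)
    oar <- array(TRUE, dims)
    roi <- array(FALSE, dims); roi[3, 3, 4:6] <- TRUE
    res <- restrictOar(oar, roi)
    perSlice <- apply(res, 3, sum)
    expect_equal(perSlice, c(0, 0, 0, 36, 36, 36, 0, 0, 0, 0))
    expect_identical(restrictOar(oar, array(TRUE, dims)), oar)
    expect_equal(sum(restrictOar(oar, array(FALSE, dims))), 0)
})

test_that("the robustness report zeroes out for a reference-only run", {
    ph <- smallPhantom()
    plan <- normalizePlan(makeTangentialPlan(
        ph$structures, prescription = Prescription(50, 5)),
        ph$grid, ph$structures)
    ref <- runReference(ph$grid, ph$structures, plan)
    roi <- buildRoi(ph$structures)
    rep <- buildReport(ref, list(ref), ph$structures, roi, 50)
    tab <- reportTable(rep)
    expect_equal(tab$dV100Roi_pct, 0)
    expect_equal(tab$dV20Lung_pct, 0)
    expect_equal(tab$dV5Heart_pct, 0)
    expect_equal(tab$meanDiff_pct, 0)
    expect_equal(tab$iqrDiff_pct, 0)
    expect_equal(tab$p1Diff_pct, 0)
    expect_equal(tab$p99Diff_pct, 0)
})
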