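# scenario runners on a coarse phantom with a short 5-fraction course

accPlan <- function() memo("acc5.plan", function() {
    ph <- smallPhantom()
    normalizePlan(makeTangentialPlan(ph$structures,
                                     prescription = Prescription(50, 5)),
                  ph$grid, ph$structures)
})

test_that("zero-error scenarios reproduce the reference bitwise", {
    ph <- smallPhantom()
    plan <- accPlan()
    ref <- runReference(ph$grid, ph$structures, plan)
    zero <- matrix(0, 5, 3)
    for (cls in c("IPE", "PRE")) {
        daily <- runDaily(ph$grid, ph$structures, plan,
                          ErrorSeries(zero, cls, "daily"))
        expect_identical(voxelData(scenarioDose(daily)),
                         voxelData(scenarioDose(ref)))
        sys <- runSystematic(ph$grid, ph$structures, plan, c(0, 0, 0), cls)
        expect_identical(voxelData(scenarioDose(sys)),
                         voxelData(scenarioDose(ref)))
    }
})

test_that("daily accumulation is the fraction-mean of per-fraction doses", {
    ph <- smallPhantom()
    plan <- accPlan()
    series <- sampleErrorSeries(defaultErrorDistribution(), 5, seed = 21,
                                errorClass = "PRE")
    res <- runDaily(ph$grid, ph$structures, plan, series,
                    keepFractionDoses = TRUE)
    # the stored fraction doses are the full plan doses scaled by 1/5, so
    # the cumulative dose is exactly their sum
    per <- res@provenance$fractionDoses
    expect_equal(voxelData(scenarioDose(res)),
                 Reduce(`+`, lapply(per, voxelData)), tolerance = 1e-13)
})

test_that("a constant daily series equals the systematic scenario", {
    ph <- smallPhantom()
    plan <- accPlan()
    sh <- c(10, -5, 5)
    for (cls in c("IPE", "PRE")) {
        daily <- runDaily(ph$grid, ph$structures, plan,
                          ErrorSeries(matrix(rep(sh, each = 5), 5), cls,
                                      "daily"))
        sys <- runSystematic(ph$grid, ph$structures, plan, sh, cls)
        expect_equal(voxelData(scenarioDose(daily)),
                     voxelData(scenarioDose(sys)), tolerance = 1e-12)
    }
})

test_that("systematic cumulative dose is the fraction multiple of one fraction", {
    ph <- smallPhantom()
    plan <- accPlan()
    sh <- c(10, 0, 0)
    sys <- runSystematic(ph$grid, ph$structures, plan, sh, "IPE")
    frPlan <- plan
    frPlan@beams <- lapply(frPlan@beams, function(b) {
        b@weight <- b@weight / 5; b
    })
    moved <- shiftPort(ph$grid, ph$structures, sh)
    oneFraction <- computePlanDose(moved$grid, frPlan)
    expect_equal(voxelData(scenarioDose(sys)),
                 5 * voxelData(oneFraction), tolerance = 1e-12)
})

test_that("scenario runners validate their inputs", {
    ph <- smallPhantom()
    raw <- makeTangentialPlan(ph$structures,
                              prescription = Prescription(50, 5))
    expect_error(runReference(ph$grid, ph$structures, raw),
                 "must be normalized")
    plan <- accPlan()
    sysSeries <- ErrorSeries(matrix(rep(c(1, 0, 0), each = 5), 5), "IPE",
                             "systematic")
    expect_error(runDaily(ph$grid, ph$structures, plan, sysSeries),
                 "scenario error")
    shortSeries <- ErrorSeries(matrix(0, 3, 3), "IPE", "daily")
    expect_error(runDaily(ph$grid, ph$structures, plan, shortSeries),
                 "does not match")
    # all scenario results share the reference geometry
    res <- runOverride(ph$grid, ph$structures, plan)
    expect_identical(gridSpacing(scenarioDose(res)), gridSpacing(ph$grid))
    expect_identical(gridOrigin(scenarioDose(res)), gridOrigin(ph$grid))
})

test_that("tissue-override of the port raises dose distal to it on a ray", {
    ph <- smallPhantom()
    plan <- accPlan()
    ref <- runReference(ph$grid, ph$structures, plan)
    ov <- runOverride(ph$grid, ph$structures, plan)
    # the port casts a shadow: integral dose can only go up when its metal
    # is replaced by tissue
    expect_gte(sum(voxelData(scenarioDose(ov))),
               sum(voxelData(scenarioDose(ref))))
    expect_gt(max(voxelData(scenarioDose(ov)) -
                  voxelData(scenarioDose(ref))), 0)
})
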