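# independent beam's-eye-view projection oracle used by the plan tests
bevOracle <- function(pts, gantry, iso, sad = 1000) {
    g <- gantry * pi / 180
    src <- iso + sad * c(sin(g), cos(g), 0)
    ex <- c(cos(g), -sin(g), 0); ez <- c(0, 0, 1)
    ax <- -c(sin(g), cos(g), 0)
    rel <- sweep(pts, 2, src, `-`)
    dpar <- rel %*% ax
    list(u = as.vector((rel %*% ex) * sad / dpar),
         w = as.vector((rel %*% ez) * sad / dpar))
}

inAperture <- function(beam, u, w) {
    ap <- beam@aperture
    iu <- round((u - ap$u0) / ap$du) + 1
    iw <- round((w - ap$w0) / ap$du) + 1
    ok <- iu >= 1 & iu <= nrow(ap$mask) & iw >= 1 & iw <= ncol(ap$mask)
    res <- logical(length(u))
    res[ok] <- ap$mask[cbind(iu[ok], iw[ok])]
    res
}

maskWorldPts <- function(mask, s) {
    idx <- which(mask, arr.ind = TRUE)
    sweep(sweep(idx - 1, 2, gridSpacing(s), `*`), 2, gridOrigin(s), `+`)
}

test_that("tangential plan is half-blocked parallel-opposed covering the PTV", {
    ph <- smallPhantom()
    plan <- makeTangentialPlan(ph$structures)
    beams <- planBeams(plan)
    expect_length(beams, 2L)
    g <- vapply(beams, function(b) b@gantry, 0)
    expect_equal(abs(((g[1] - g[2]) %% 360)), 180)
    # every PTV voxel projects inside both apertures
    pts <- maskWorldPts(getMask(ph$structures, "ptv"), ph$grid)
    for (b in beams) {
        pr <- bevOracle(pts, b@gantry, b@iso, b@sad)
        expect_true(all(inAperture(b, pr$u, pr$w)))
    }
})

test_that("tangential posterior field edges coincide within one voxel", {
    ph <- smallPhantom()
    plan <- makeTangentialPlan(ph$structures)
    beams <- planBeams(plan)
    iso <- beams[[1]]@iso
    # probe along the radial (block-normal) direction through the isocentre;
    # the pre-blur dose boundary must sit at the same probe index for both
    sp <- gridSpacing(ph$grid)
    bodyC <- c(0, -40, 0)
    impC <- c(60, 55, 0)
    r <- impC - bodyC; r[3] <- 0; r <- r / sqrt(sum(r^2))
    probes <- t(vapply(-12:12, function(k) iso + k * sp[1] * r,
                       numeric(3)))
    edges <- vapply(beams, function(b) {
        pr <- bevOracle(probes, b@gantry, b@iso, b@sad)
        which(inAperture(b, pr$u, pr$w))[1]
    }, 0L)
    expect_lte(abs(edges[1] - edges[2]), 1L)
})

test_that("arc plan spans the configured arc about the PTV centroid", {
    ph <- smallPhantom()
    plan <- makeArcPlan(ph$structures)
    g <- vapply(planBeams(plan), function(b) b@gantry, 0)
    expect_length(g, 47L)
    expect_equal(max(g) - min(g), 230)
    expect_equal(length(unique(round(diff(sort(g)), 9))), 1L)
    ptvC <- colMeans(maskWorldPts(getMask(ph$structures, "ptv"), ph$grid))
    expect_true(all(abs(planBeams(plan)[[1]]@iso - ptvC) <=
                    gridSpacing(ph$grid)))
    # mirrored laterality mirrors the gantry angles
    phR <- generatePhantom(smallConfig(laterality = "right"))
    gR <- vapply(planBeams(makeArcPlan(phR$structures)),
                 function(b) b@gantry, 0)
    expect_equal(sort((-gR) %% 360), sort(g %% 360), tolerance = 1e-9)
})

test_that("helical plan covers all angles and the PTV longitudinal extent", {
    ph <- smallPhantom()
    prm <- planParams()
    plan <- makeHelicalPlan(ph$structures, prm)
    g <- vapply(planBeams(plan), function(b) b@gantry, 0)
    expect_equal(sort(unique(g)),
                 seq(0, 360 - 360 / prm$helicalAngles,
                     by = 360 / prm$helicalAngles))
    # union of fan windows covers the PTV z-range
    zIso <- vapply(planBeams(plan), function(b) b@iso[3], 0)
    pts <- maskWorldPts(getMask(ph$structures, "ptv"), ph$grid)
    zR <- range(pts[, 3])
    expect_lte(min(zIso) - prm$fanWidth / 2, zR[1])
    expect_gte(max(zIso) + prm$fanWidth / 2, zR[2])
    # conformality: no aperture opening beyond PTV projection + margin
    for (b in planBeams(plan)[c(1, 50, 150)]) {
        ap <- b@aperture
        open <- which(ap$mask, arr.ind = TRUE)
        uo <- ap$u0 + (open[, 1] - 1) * ap$du
        wo <- ap$w0 + (open[, 2] - 1) * ap$du
        pr <- bevOracle(pts, b@gantry, b@iso, b@sad)
        tol <- prm$apertureMargin + 2 * ap$du
        for (i in seq_len(nrow(open))) {
            dmin <- min(sqrt((pr$u - uo[i])^2 + (pr$w - wo[i])^2))
            expect_lte(dmin, tol)
        }
        expect_true(all(abs(wo) <= prm$fanWidth / 2))
    }
})

test_that("normalization pins PTV D90 at the prescription and is linear", {
    ph <- smallPhantom()
    ptv <- getMask(ph$structures, "ptv")
    for (builder in list(makeTangentialPlan, makeArcPlan)) {
        plan <- builder(ph$structures)
        norm <- normalizePlan(plan, ph$grid, ph$structures)
        d <- computePlanDose(ph$grid, norm)
        expect_equal(dvhValue(d, ptv, "D", 90), 50, tolerance = 1e-3)
        # doubling input weights halves the scale factor
        plan2 <- plan
        plan2@beams <- lapply(plan2@beams, function(b) {
            b@weight <- 2 * b@weight; b
        })
        norm2 <- normalizePlan(plan2, ph$grid, ph$structures)
        expect_equal(normFactor(norm2), normFactor(norm) / 2,
                     tolerance = 1e-9)
        # relative DVH shape invariant under normalization
        dRaw <- computePlanDose(ph$grid, plan)
        q <- seq(0.05, 0.95, by = 0.1)
        expect_equal(
            unname(quantile(voxelData(d)[ptv], q)) / 50,
            unname(quantile(voxelData(dRaw)[ptv], q)) /
                dvhValue(dRaw, ptv, "D", 90),
            tolerance = 1e-9)
    }
})

test_that("plan builders reject an empty PTV", {
    ph <- smallPhantom()
    m <- ph$structures@masks
    m$ptv <- array(FALSE, dim(m$ptv))
    s2 <- StructureSet(m, gridSpacing(ph$grid), gridOrigin(ph$grid))
    expect_error(makeTangentialPlan(s2), "PTV is empty")
    expect_error(makeArcPlan(s2), "PTV is empty")
    expect_error(makeHelicalPlan(s2), "PTV is empty")
})
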