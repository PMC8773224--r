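# The analysis mask: top-hat correction, thresholding/cleanup, area
# filtering and two-channel object classification.

test_that("component labelling uses 8-connectivity for foreground", {
    m <- matrix(0L, 6, 6)
    m[2, 2] <- 1L; m[3, 3] <- 1L            # diagonal touch
    expect_equal(max(labelComponents(m, 8)), 1L)
    expect_equal(max(labelComponents(m, 4)), 2L)
    m[5, 5] <- 1L                            # separate object
    expect_equal(max(labelComponents(m, 8)), 2L)
})

test_that("top-hat removes flat and slowly varying background", {
    prm <- SegmentationParams()
    flat <- matrix(5, 120, 120)
    out <- tophatBackground(flat, prm, pixelSize = 1)
    expect_lt(max(abs(out)), 1e-9)
    expect_gte(min(out), 0)

    # a disk smaller than the cell radius survives within 1% amplitude
    img <- matrix(2, 150, 150)
    cx <- 75; cy <- 75; r <- 15; amp <- 10
    for (i in 1:150) for (j in 1:150)
        if ((i - cx)^2 + (j - cy)^2 <= r^2) img[i, j] <- 2 + amp
    out <- tophatBackground(img, prm, 1)
    expect_lt(abs(out[cx, cy] - amp) / amp, 0.01)
    expect_lt(max(out[img == 2]), 1e-9)

    # a slow linear ramp leaves residual below the GCU threshold
    ramp <- outer(seq(0, 3, length.out = 200), rep(1, 200))
    out <- tophatBackground(ramp, prm, 1)
    expect_lt(max(out), SegmentationParams()@gcuThreshold)

    expect_error(tophatBackground(matrix(0, 20, 20), prm, 1), "larger")
})

test_that("segmentation fills nuclear holes and filters by area", {
    prm <- SegmentationParams()
    # rendered single cell with a 150 um2 nuclear hole
    sp <- tinyScene(noiseGreen = 0.05, bgGreen = 0,
                    holeAreaMin = 150, holeAreaMax = 150,
                    cellAreaMeanlog = log(1500), cellAreaSdlog = 1e-6)
    sc <- generateScene(1, 0, sp, seed = 4)
    pair <- renderScene(sc, sp)
    corr <- tophatBackground(greenChannel(pair), prm, 1)
    lab <- segmentChannel(corr, prm@gcuThreshold, prm, 1)
    expect_equal(max(lab), 1L)
    # the filled object area includes the hole
    expect_gt(sum(lab == 1L), 0.95 * sceneCells(sc)$area)

    # object below 150 um2 is removed, above 5500 um2 is removed
    img <- matrix(0, 200, 200)
    img[10:19, 10:19] <- 10                 # 100 px^2
    img[50:130, 50:130] <- 10               # 6561 px^2
    img[150:170, 150:170] <- 10             # 441 px^2 -> survives
    lab <- segmentChannel(img, 4, prm, 1)
    expect_equal(max(lab), 1L)
    expect_equal(sum(lab > 0), 441L)
})

test_that("area filter agrees with the brute-force oracle exactly", {
    set.seed(42)
    for (rep in 1:5) {
        m <- matrix(runif(80 * 80) < 0.35, 80, 80)
        lab <- labelComponents(m, 8)
        filtered <- CaMPARIquant:::.areaFilter(lab, 5L, 60L)
        surv <- oracleAreaFilter(lab, 5L, 60L)
        # surviving pixel sets are identical
        expect_identical(matrix(lab %in% surv, nrow(lab)), filtered > 0L)
        # every surviving component keeps its pixel count
        sizesB <- table(lab[lab %in% surv])
        sizesA <- table(filtered[filtered > 0L])
        expect_identical(sort(as.integer(sizesB)), sort(as.integer(sizesA)))
    }
})

test_that("hole fill never decreases object areas and precedes filtering", {
    set.seed(9)
    for (rep in 1:4) {
        m <- matrix(runif(70 * 70) < 0.45, 70, 70)
        lab <- labelComponents(m, 8)
        filled <- CaMPARIquant:::.fillHoles(lab, 50L)
        before <- tabulate(lab, nbins = max(lab))
        after <- tabulate(filled, nbins = max(lab))
        expect_true(all(after >= before))
    }
    # fill-then-filter keeps an object whose filled area crosses areaMin
    img <- matrix(0, 100, 100)
    img[40:59, 40:59] <- 10                 # 400 px ring + hole below
    img[45:54, 45:54] <- 0                  # 100 px hole -> 300 px annulus
    prm <- SegmentationParams(areaMin = 350, areaMax = 5500,
                              holeFillMax = 150)
    lab <- segmentChannel(img, 4, prm, 1)
    expect_equal(max(lab), 1L)              # 400 px after fill
    expect_equal(sum(lab > 0), 400L)
    # with filtering conceptually first the annulus (300 px) would die
    expect_lt(300, 350)
})

test_that("edge sensitivity and segmentation adjustment shift the threshold", {
    img <- matrix(0, 60, 60)
    img[20:39, 20:39] <- 5
    prm0 <- SegmentationParams(tophatEdgeSensitivity = 0,
                               areaMin = 100, areaMax = 5500)
    expect_equal(max(segmentChannel(img, 4, prm0, 1)), 1L)
    # -30 per-mille of range 5 -> effective threshold 4 + 0.15: survives
    prm1 <- SegmentationParams(tophatEdgeSensitivity = -30,
                               areaMin = 100, areaMax = 5500)
    expect_equal(max(segmentChannel(img, 4, prm1, 1)), 1L)
    # offset large enough to push the object under threshold
    prm2 <- SegmentationParams(tophatEdgeSensitivity = -300,
                               areaMin = 100, areaMax = 5500)
    expect_equal(max(segmentChannel(img, 4, prm2, 1)), 0L)
    # adjustment is multiplicative on the channel threshold
    prm3 <- SegmentationParams(segmentationAdjustment = 1.5,
                               tophatEdgeSensitivity = 0,
                               areaMin = 100, areaMax = 5500)
    expect_equal(max(segmentChannel(img, 4, prm3, 1)), 0L)
})

test_that("object classification follows the overlap rule", {
    prm <- SegmentationParams(areaMin = 50, areaMax = 5500)
    gimg <- matrix(0, 80, 80); rimg <- matrix(0, 80, 80)
    gimg[10:29, 10:29] <- 10
    rimg[10:29, 10:29] <- 1
    gM <- segmentChannel(gimg, 4, prm, 1)
    rM <- segmentChannel(rimg, 0.3, prm, 1)
    # identical masks -> merged
    ot <- classifyObjects(gM, rM, gimg, rimg, prm, 1)
    expect_equal(ot$class, "merged")
    # disjoint masks -> green-only and red-only
    rimg2 <- matrix(0, 80, 80); rimg2[50:69, 50:69] <- 1
    rM2 <- segmentChannel(rimg2, 0.3, prm, 1)
    ot2 <- classifyObjects(gM, rM2, gimg, rimg2, prm, 1)
    expect_setequal(ot2$class, c("green-only", "red-only"))
    # 60% area overlap of equal squares -> merged at the 50% default
    rimg3 <- matrix(0, 80, 80); rimg3[10:29, 18:37] <- 1
    rM3 <- segmentChannel(rimg3, 0.3, prm, 1)
    ov <- sum(gM > 0 & rM3 > 0) / min(sum(gM > 0), sum(rM3 > 0))
    expect_gte(ov, 0.5)
    ot3 <- classifyObjects(gM, rM3, gimg, rimg3, prm, 1)
    expect_true("merged" %in% ot3$class)
    # 40% overlap -> not merged
    rimg4 <- matrix(0, 80, 80); rimg4[10:29, 22:41] <- 1
    rM4 <- segmentChannel(rimg4, 0.3, prm, 1)
    ot4 <- classifyObjects(gM, rM4, gimg, rimg4, prm, 1)
    expect_false("merged" %in% ot4$class)
    expect_error(classifyObjects(gM, rM4[1:40, ], gimg, rimg4, prm, 1),
                 "geometry")
})

test_that("mask recovers ground truth on debris-free default scenes", {
    prm <- SegmentationParams()
    totTrue <- 0; totDet <- 0; matched <- 0
    for (s in 1:3) {
        sp <- SceneParams()       # default density, 600 um field
        sc <- generateScene(40, 0.5, sp, seed = 200 + s)
        pair <- renderScene(sc, sp)
        ot <- segmentField(pair, prm)
        cells <- sceneCells(sc)
        det <- ot[ot$class != "red-only", ]
        d <- outer(cells$x, det$x, "-")^2 + outer(cells$y, det$y, "-")^2
        hit <- apply(d, 1, function(z) any(z < 15^2))
        totTrue <- totTrue + nrow(cells)
        totDet <- totDet + nrow(det)
        matched <- matched + sum(hit)
    }
    expect_gte(matched / totTrue, 0.95)     # recall
    expect_gte(matched / totDet, 0.95)      # precision
})

test_that("out-of-range red debris never enters the merged class", {
    sp <- SceneParams(debrisFrac = 0.3, debrisAreaMeanlog = log(8000),
                      debrisAreaSdlog = 0.1)
    sc <- generateScene(15, 0.5, sp, seed = 31)
    pair <- renderScene(sc, sp)
    ot <- segmentField(pair, SegmentationParams())
    # oversized debris is filtered from the red mask entirely: every
    # merged object must match a true converted cell position
    cells <- sceneCells(sc)
    mg <- ot[ot$class == "merged", ]
    if (nrow(mg)) {
        d <- outer(mg$x, cells$x[cells$converted], "-")^2 +
             outer(mg$y, cells$y[cells$converted], "-")^2
        expect_true(all(apply(d, 1, min) < 15^2))
    }
    expect_true(all(ot$area <= 5500 + 1))
})
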