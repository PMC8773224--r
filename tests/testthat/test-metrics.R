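# Per-well photoconversion metrics and the baseline subtraction.

mkObjects <- function(classes, meanRed = NULL, integratedRed = NULL) {
    n <- length(classes)
    data.frame(objectId = sprintf("O%d", seq_len(n)),
               class = as.character(classes),
               area = rep(900, n), x = seq_len(n) * 40, y = rep(50, n),
               meanGreen = rep(15, n),
               meanRed = if (is.null(meanRed)) rep(1, n) else meanRed,
               integratedRed = if (is.null(integratedRed))
                   rep(900, n) else integratedRed,
               greenLabel = seq_len(n), redLabel = seq_len(n),
               stringsAsFactors = FALSE)
}

test_that("conversion rate is merged over green cells, in percent", {
    expect_equal(conversionRate(mkObjects(rep("green-only", 50))), 0)
    ot <- mkObjects(rep(c("merged", "green-only"), c(13, 87)))
    expect_equal(conversionRate(ot), 13)
    expect_equal(conversionRate(mkObjects(rep("merged", 7))), 100)
    # red-only objects are excluded from the denominator
    ot2 <- rbind(ot, mkObjects(rep("red-only", 40)))
    expect_equal(conversionRate(ot2), 13)
    # no green cells -> flagged missing, not zero
    expect_true(is.na(conversionRate(mkObjects(rep("red-only", 5)))))
    expect_true(is.na(conversionRate(mkObjects(character(0)))))
})

test_that("intensity metrics aggregate object-weighted red statistics", {
    # single merged object: all three metrics finite and consistent
    one <- mkObjects("merged", meanRed = 1.7, integratedRed = 1530)
    im <- intensityMetrics(one)
    expect_equal(im[["redMeanAll"]], 1.7)
    expect_equal(im[["mergedRedMean"]], 1.7)
    expect_equal(im[["redIntegratedPerWell"]], 1530)
    # two merged (1, 2) plus one red-only (3)
    ot <- mkObjects(c("merged", "merged", "red-only"),
                    meanRed = c(1, 2, 3), integratedRed = c(10, 20, 30))
    im <- intensityMetrics(ot)
    expect_equal(im[["redMeanAll"]], 2.0)
    expect_equal(im[["mergedRedMean"]], 1.5)
    expect_equal(im[["redIntegratedPerWell"]], 60 / 2)
    # missing denominators are flagged
    im0 <- intensityMetrics(mkObjects(rep("green-only", 3)))
    expect_true(all(is.na(im0)))
})

test_that("red debris inflates intensity metrics but not the conversion rate", {
    prm <- SegmentationParams()
    base <- SceneParams()
    withDebris <- SceneParams(debrisFrac = 0.15)
    clean <- measureWell(0.4, 25, 2, base, prm, seed = 77)
    dirty <- measureWell(0.4, 25, 2, withDebris, prm, seed = 77)
    # same seed: identical cells, debris added on top
    expect_equal(clean$metrics$conversionRate, dirty$metrics$conversionRate,
                 tolerance = 0.05)
    expect_gt(dirty$metrics$redMeanAll, clean$metrics$redMeanAll)
    expect_gt(dirty$metrics$nRedOnly, 0)
})

test_that("well metrics pool fields as ratios of sums", {
    f1 <- mkObjects(rep(c("merged", "green-only"), c(2, 8)))
    f2 <- mkObjects(rep(c("merged", "green-only"), c(6, 4)))
    m <- computeWellMetrics(list(f1, f2), well = "B3")
    expect_equal(m$nGreen, 20)
    expect_equal(m$nMerged, 8)
    expect_equal(m$conversionRate, 40)   # 8/20, not mean(20%, 60%)
    expect_equal(m$well, "B3")
})

test_that("baseline subtraction preserves sign and structure", {
    expect_equal(baselineSubtract(12, 10), 2)
    expect_equal(baselineSubtract(60, 13), 47)
    expect_equal(baselineSubtract(10, 10), 0)
    expect_equal(baselineSubtract(c(5, 20), 10), c(-5, 10))  # not clipped
    expect_error(baselineSubtract(10, NA_real_), "reference")

    df <- data.frame(
        condition = rep(c("A", "B"), each = 3),
        role = rep(c("Pre-Parabola", "Zero-G", "Histamine"), 2),
        conversionRate = c(10, 12, 60, 2, 3, 40))
    out <- baselineSubtract(df, groupCols = "condition")
    expect_equal(out$adjustedRate, c(0, 2, 50, 0, 1, 38))
    bad <- df[df$role != "Pre-Parabola", ]
    expect_error(baselineSubtract(bad, groupCols = "condition"),
                 "no Pre-Parabola")
})

test_that("pipeline conversion estimate is binomially consistent", {
    nWells <- 6; cells <- 30; fields <- 2; p <- 0.3
    est <- numeric(nWells); tru <- numeric(nWells)
    for (wl in seq_len(nWells)) {
        r <- measureWell(p, cells, fields, SceneParams(),
                         SegmentationParams(), seed = 500 + wl)
        est[wl] <- r$metrics$conversionRate
        tru[wl] <- r$metrics$trueRate
    }
    N <- nWells * cells * fields
    expect_lt(abs(mean(est) / 100 - p), 3 * sqrt(p * (1 - p) / N))
    # the mask-based estimate tracks the realised ground truth closely
    expect_lt(mean(abs(est - tru)), 2)
})
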