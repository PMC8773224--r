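# Forward model: Hill occupancy, saturating conversion probability and
# the empirical / two-point hazard calibrations.

f391w <- VariantSpec("CaMPARI2-F391W", kd = 109.7, hillN = 1,
                     kFree = 0.02, kBound = 0.13)

test_that("Hill occupancy matches direct arithmetic and its fixed points", {
    expect_equal(hillOccupancy(109.7, f391w), 0.5)
    expect_equal(hillOccupancy(0, f391w), 0)
    wt <- VariantSpec("CaMPARI2", kd = 199.2)
    expect_equal(hillOccupancy(150, wt), 150 / 349.2, tolerance = 1e-12)
    # half-occupancy at kd holds for any cooperativity
    for (n in c(0.5, 1, 2, 4)) {
        v <- VariantSpec("x", kd = 80, hillN = n)
        expect_equal(hillOccupancy(80, v), 0.5)
    }
    # monotone nondecreasing in concentration
    cc <- seq(0, 2000, by = 25)
    expect_true(all(diff(hillOccupancy(cc, f391w)) >= 0))
    expect_error(hillOccupancy(-1, f391w), "nonnegative")
})

test_that("conversion probability saturates with the expected kinetics", {
    expect_equal(conversionProbability(150, f391w,
                                       ConversionParams(illuminationS = 0)), 0)
    # hazard ln 2 per s: half of plateau at 1 s, 7/8 at 3 s
    v <- VariantSpec("x", kd = 100, kFree = log(2), kBound = log(2))
    p1 <- conversionProbability(150, v, ConversionParams(illuminationS = 1))
    p3 <- conversionProbability(150, v, ConversionParams(illuminationS = 3))
    expect_equal(p1, 0.5)
    expect_equal(p3, 1 - 2^-3)
    # monotone in t, C and hazards; bounded in [0, 1)
    ts <- c(0, 1, 2, 4, 8, 16, 64)
    ps <- vapply(ts, function(t) conversionProbability(
        500, f391w, ConversionParams(illuminationS = t)), numeric(1))
    expect_true(all(diff(ps) > 0) && all(ps >= 0 & ps < 1))
    pc <- vapply(c(0, 50, 150, 1e3, 1e6), function(C)
        conversionProbability(C, f391w), numeric(1))
    expect_true(all(diff(pc) > 0))
})

test_that("empirical calibration inverts the saturation law", {
    expect_equal(calibrateEmpirical(0, 5), 0)
    expect_equal(calibrateEmpirical(0.13, 8), -log(0.87) / 8)
    expect_equal(calibrateEmpirical(0.65, 8), -log(0.35) / 8)
    # round-trip identity on hazards to 1e-10 relative
    for (k in c(1e-4, 0.01741, 0.1312, 1.2)) {
        v <- VariantSpec("x", kd = 100, kFree = k, kBound = k)
        p <- conversionProbability(150, v)
        expect_equal(calibrateEmpirical(p, 8), k, tolerance = 1e-10)
    }
    expect_error(calibrateEmpirical(1, 8), "infeasible")
    expect_error(calibrateEmpirical(0.5, 0), "positive")
})

test_that("two-point calibration solves the hazard system or reports infeasibility", {
    # degenerate consistency: equal probabilities -> shared hazard
    res <- calibrateTwoPoint(0.3, 0.3, 100, 1e6, kd = 109.7)
    expect_true(res$feasible)
    expect_equal(res$kFree, res$kBound, tolerance = 1e-9)
    expect_equal(res$kFree, -log(0.7) / 8, tolerance = 1e-9)

    # published-contrast case: hazard contrast 7.5x cannot arise from the
    # occupancy contrast at K_D = 109.7 nM and basal 150 nM
    res <- calibrateTwoPoint(0.13, 0.65, 150, 1e6, kd = 109.7)
    o <- oracleTwoPoint(0.13, 0.65, 150, 1e6, kd = 109.7)
    expect_false(res$feasible)
    expect_lt(res$kFree, 0)
    expect_equal(res$kFree, o[["kFree"]], tolerance = 1e-9)
    expect_equal(res$kBound, o[["kBound"]], tolerance = 1e-9)
    expect_match(res$reason, "k_free")

    # low-basal case agrees with the Cramer-rule oracle as well
    res <- calibrateTwoPoint(0.02, 0.40, 20, 1e6, kd = 199.2)
    o <- oracleTwoPoint(0.02, 0.40, 20, 1e6, kd = 199.2)
    expect_equal(res$kFree, o[["kFree"]], tolerance = 1e-9)
    expect_equal(res$kBound, o[["kBound"]], tolerance = 1e-9)
    expect_identical(res$feasible, o[["kFree"]] >= 0)

    # feasible round-trip: forward-simulate from solved hazards
    res <- calibrateTwoPoint(0.10, 0.60, 50, 1e6, kd = 199.2)
    if (res$feasible) {
        v <- VariantSpec("x", kd = 199.2, kFree = res$kFree,
                         kBound = res$kBound)
        expect_equal(conversionProbability(50, v), 0.10, tolerance = 1e-9)
        expect_equal(conversionProbability(1e6, v), 0.60, tolerance = 1e-9)
    }
    expect_error(calibrateTwoPoint(0.1, 0.2, 100, 100, kd = 199.2),
                 "singular")
})

test_that("bundled variant table carries the published affinities", {
    vars <- campariVariants()
    expect_setequal(names(vars),
        c("CaMPARI2", "CaMPARI2-F391W", "CaMPARI2-H396K",
          "CaMPARI2-F391W-G395D", "CaMPARI2-L398T"))
    expect_equal(vars[["CaMPARI2"]]@kd, 199.2)
    expect_equal(vars[["CaMPARI2-F391W"]]@kd, 109.7)
    expect_true(is.na(vars[["CaMPARI2-L398T"]]@kd))
})

test_that("variant invariants are enforced", {
    expect_error(VariantSpec("x", kd = -1), "positive")
    expect_error(VariantSpec("x", kd = 100, kFree = 0.5, kBound = 0.1),
                 "exceed")
    expect_error(CalciumCondition("x", -5), "nonnegative")
})
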