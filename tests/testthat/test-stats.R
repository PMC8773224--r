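# Assay statistics: ANOVA/Tukey, Z'-factor, saturation fit, deposited
# per-well loader.

test_that("ANOVA F and Tukey p agree with the sums-of-squares oracle", {
    # textbook two-group instance
    res <- anovaTukey(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
    expect_equal(res$F, 13.5, tolerance = 1e-12)

    set.seed(13)
    for (rep in 1:4) {
        g <- rep(c("Pre-Parabola", "Pull-Up", "Zero-G", "Histamine"),
                 times = c(4, 5, 3, 6))
        y <- rnorm(length(g), mean = ifelse(g == "Histamine", 3, 0))
        res <- anovaTukey(y, g, reference = "Pre-Parabola")
        o <- oracleAnovaTukey(y, g)
        expect_equal(res$F, o$F, tolerance = 1e-8)
        expect_equal(res$p, o$p, tolerance = 1e-8)
        got <- setNames(res$comparisons$pAdj, res$comparisons$contrast)
        expect_equal(got[names(o$pAdj)], o$pAdj, tolerance = 1e-8)
        # reference comparisons are the ones involving Pre-Parabola
        expect_equal(nrow(res$vsReference), 3L)
    }

    # identical constants: no significant pairs
    res <- anovaTukey(rep(5, 9), rep(c("a", "b", "c"), each = 3))
    expect_false(any(res$comparisons$significant))
    expect_error(anovaTukey(1:5, c("a", "a", "a", "a", "b")),
                 "at least two replicates")
    expect_error(anovaTukey(1:4, rep("a", 4)), "two groups")
})

test_that("Z'-factor matches its definition and invariances", {
    expect_equal(zprimeValue(zPrime(c(52, 52), c(2, 2))), 1)
    # means 52 and 2, sds 3 and 1 -> 1 - 12/50
    z <- zPrime(c(49, 52, 55), c(1, 2, 3))
    expect_equal(zprimeValue(z), 0.76)
    expect_equal(z@meanPos, 52); expect_equal(z@sdPos, 3)
    # affine invariance under shared positive scale and shift
    for (s in 1:5) {
        set.seed(s)
        pos <- rnorm(8, 60, 4); neg <- rnorm(8, 10, 2)
        a <- runif(1, -50, 50); b <- runif(1, 0.1, 20)
        expect_equal(zprimeValue(zPrime(a + b * pos, a + b * neg)),
                     zprimeValue(zPrime(pos, neg)), tolerance = 1e-12)
    }
    expect_error(zPrime(c(1, 1), c(1, 1)), "undefined")
    expect_error(zPrime(1, c(1, 2)), "two replicates")
})

test_that("overlapping controls give a non-positive Z' with high probability", {
    set.seed(99)
    bad <- replicate(200, {
        zprimeValue(zPrime(rnorm(12), rnorm(12)))
    })
    expect_gt(mean(bad <= 0), 0.9)
    expect_true(all(bad <= 1))
})

test_that("saturation fit recovers exact and half-time kinetics", {
    t <- c(0, 0.5, 1, 2, 4, 8, 16, 32)
    y <- 1 * (1 - exp(-log(2) * t))
    fit <- fitSaturation(t, y, nBoot = 50)
    expect_equal(fit@rMax, 1, tolerance = 1e-6)
    expect_equal(fit@k, log(2), tolerance = 1e-6)
    # half of the plateau at 1 s
    at1 <- fit@rMax * (1 - exp(-fit@k * 1))
    expect_equal(at1 / fit@rMax, 0.5, tolerance = 1e-6)
    # scale equivariance: ratios x c -> rMax x c, k unchanged
    fit3 <- fitSaturation(t, 3.7 * y, nBoot = 50)
    expect_equal(fit3@rMax, 3.7, tolerance = 1e-5)
    expect_equal(fit3@k, fit@k, tolerance = 1e-5)
    expect_error(fitSaturation(c(0, 1), c(0, 0.5)), "three distinct")
})

test_that("bootstrap interval covers the true rate constant", {
    # time-course design samples the rising phase densely, as a
    # photoconversion series over 0-32 s would
    t <- c(0, 1, 2, 4, 8, 16, 24, 32)
    rmax <- 1; k <- log(2)
    hits <- 0; reps <- 200
    for (r in seq_len(reps)) {
        set.seed(3000 + r)
        y <- rmax * (1 - exp(-k * t)) + rnorm(length(t), 0, 0.05 * rmax)
        fit <- fitSaturation(t, y, nBoot = 200, seed = r)
        ci <- fit@paramCI["k", ]
        if (ci[1] <= k && k <= ci[2]) hits <- hits + 1
    }
    expect_gte(hits / reps, 0.85)
})

test_that("per-flight Z' from a deposited-format table delegates correctly", {
    # synthetic stand-in for the deposited per-well quantitative table
    tab <- data.frame(
        flight = rep(c(1, 2), each = 8),
        treatment = rep(rep(c("Histamine", "Histamine+BAPTA"), each = 4), 2),
        conversion_rate = c(52, 55, 49, 54, 2, 3, 1, 2,
                            48, 41, 50, 45, 4, 6, 5, 7))
    z1 <- zPrimeFromDeposited(tab, flight = 1)
    direct <- zPrime(c(52, 55, 49, 54), c(2, 3, 1, 2))
    expect_equal(zprimeValue(z1), zprimeValue(direct))
    # column mapping for differently headed CSVs
    tab2 <- data.frame(day = 1, drug = rep(c("H", "HB"), each = 3),
                       rate = c(60, 62, 58, 5, 6, 4))
    z2 <- zPrimeFromDeposited(tab2, 1,
        mapping = list(flight = "day", treatment = "drug", value = "rate",
                       positive = "H", negative = "HB"))
    expect_equal(zprimeValue(z2), zprimeValue(zPrime(c(60, 62, 58),
                                                     c(5, 6, 4))))
    expect_error(zPrimeFromDeposited(tab, flight = 9), "lacks replicates")
    expect_error(zPrimeFromDeposited(tab[, -1], 1), "lacks mapped")
})
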