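# Independent oracles used across tests; deliberately brute-force and
# separate from the package's code paths.

# one-way ANOVA + Tukey-Kramer from explicit sums of squares and the
# studentized range distribution
oracleAnovaTukey <- function(values, groups) {
    groups <- factor(groups)
    m <- tapply(values, groups, mean)
    n <- tapply(values, groups, length)
    grand <- mean(values)
    ssb <- sum(n * (m - grand)^2)
    dfb <- nlevels(groups) - 1L
    ssw <- sum((values - m[groups])^2)
    dfw <- length(values) - nlevels(groups)
    msw <- ssw / dfw
    Fv <- (ssb / dfb) / msw
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2)
    pAdj <- apply(pairs, 2, function(pr) {
        d <- abs(m[pr[2]] - m[pr[1]])
        se <- sqrt(msw / 2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
        stats::ptukey(d / se, nlevels(groups), dfw, lower.tail = FALSE)
    })
    names(pAdj) <- paste(pairs[2, ], pairs[1, ], sep = "-")
    list(F = Fv, p = stats::pf(Fv, dfb, dfw, lower.tail = FALSE),
         pAdj = pAdj)
}

# brute-force area filter on a labelled mask: survivors by pixel count
oracleAreaFilter <- function(lab, minPx, maxPx) {
    labels <- setdiff(sort(unique(as.vector(lab))), 0L)
    keep <- labels[vapply(labels, function(l) {
        a <- sum(lab == l)
        a >= minPx && a <= maxPx
    }, logical(1))]
    keep
}

# Cramer-rule solution of the two-point hazard system
oracleTwoPoint <- function(pBasal, pStim, cBasal, cStim, kd, hillN = 1,
                           t = 8) {
    f <- function(C) if (C == 0) 0 else 1 / (1 + (kd / C)^hillN)
    h <- -log(1 - c(pBasal, pStim)) / t
    f1 <- f(cBasal); f2 <- f(cStim)
    det <- (1 - f1) * f2 - (1 - f2) * f1
    kFree <- (h[1] * f2 - h[2] * f1) / det
    kBound <- ((1 - f1) * h[2] - (1 - f2) * h[1]) / det
    c(kFree = kFree, kBound = kBound)
}

# small scene parameters for fast unit tests (fits ~25 default cells)
tinyScene <- function(...) {
    SceneParams(fieldWidth = 400, fieldHeight = 400, ...)
}
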