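# Assay statistics: one-way ANOVA with Tukey-Kramer post-test against a
# designated reference, the Z'-factor, and the saturation-curve fit of
# the photoconversion time course.

#' One-way ANOVA with Tukey post-test
#'
#' Fits a one-way ANOVA across groups and computes Tukey-Kramer
#' adjusted pairwise comparisons (valid for unequal group sizes). When a
#' reference group is named, its comparisons are flagged at
#' \code{alpha}.
#'
#' @param values numeric response (e.g. well-level conversion rates).
#' @param groups group labels (phase or treatment).
#' @param reference optional reference group, e.g. "Pre-Parabola" or
#'   "Untreated".
#' @param alpha significance level.
#' @return list: \code{F}, \code{p}, \code{df}, \code{comparisons}
#'   (data.frame with contrast, diff, lwr, upr, pAdj, significant), and
#'   \code{vsReference} (subset of comparisons involving the reference).
#' @examples
#' anovaTukey(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$F  # 13.5
#' @export
anovaTukey <- function(values, groups, reference = NULL, alpha = 0.05) {
    groups <- factor(groups)
    if (nlevels(groups) < 2L)
        stop("ANOVA needs at least two groups")
    n <- table(groups)
    if (any(n < 2L))
        stop("every group needs at least two replicates")
    fit <- stats::aov(values ~ groups)
    at <- summary(fit)[[1]]
    tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
    # TukeyHSD rows follow combn() pair order as "later-earlier"; carry
    # the pair explicitly since level names may themselves contain "-"
    pairs <- utils::combn(levels(groups), 2)
    stopifnot(identical(rownames(tuk),
                        paste(pairs[2, ], pairs[1, ], sep = "-")))
    comparisons <- data.frame(
        contrast = rownames(tuk),
        group1 = pairs[2, ], group2 = pairs[1, ],
        diff = tuk[, "diff"],
        lwr = tuk[, "lwr"], upr = tuk[, "upr"], pAdj = tuk[, "p adj"],
        stringsAsFactors = FALSE)
    comparisons$significant <- !is.na(comparisons$pAdj) &
        comparisons$pAdj < alpha
    rownames(comparisons) <- NULL
    vsRef <- if (!is.null(reference)) {
        hit <- comparisons$group1 == reference |
               comparisons$group2 == reference
        comparisons[hit, , drop = FALSE]
    } else comparisons[0, , drop = FALSE]
    list(F = at[1, "F value"], p = at[1, "Pr(>F)"],
         df = c(at[1, "Df"], at[2, "Df"]),
         comparisons = comparisons, vsReference = vsRef)
}

#' Z'-factor of a positive/negative control pair
#'
#' \code{1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|} with sample
#' (n-1) standard deviations. Values above ~0.5 indicate an excellent
#' assay window; the statistic never exceeds 1 and is invariant under a
#' common affine rescaling of both groups.
#'
#' @param pos,neg replicate values of the positive and negative
#'   controls (each n >= 2, distinct means).
#' @return a \code{\link{ZPrimeResult}}.
#' @examples
#' zprimeValue(zPrime(c(49, 52, 55), c(1, 2, 3)))
#' @export
zPrime <- function(pos, neg) {
    if (length(pos) < 2L || length(neg) < 2L)
        stop("both control groups need at least two replicates")
    mp <- mean(pos); mn <- mean(neg)
    if (mp == mn)
        stop("Z'-factor undefined: control means coincide")
    new("ZPrimeResult", meanPos = mp, sdPos = stats::sd(pos),
        meanNeg = mn, sdNeg = stats::sd(neg),
        zprime = 1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mp - mn))
}

#' Fit a saturation curve to a photoconversion time course
#'
#' Least-squares fit of \code{R(t) = rMax (1 - exp(-k t))} to red/green
#' intensity ratios over illumination time, with a parametric-bootstrap
#' confidence band (refitting on Gaussian resamples of the fitted
#' curve) evaluated at the observed time points.
#'
#' @param times illumination durations in s (>= 3 distinct values,
#'   spanning down to early times).
#' @param ratios red/green intensity ratios.
#' @param nBoot bootstrap resamples for the band.
#' @param level band level (default 0.90).
#' @param seed seed for the bootstrap.
#' @return a \code{\link{SaturationFit}}.
#' @examples
#' t <- c(0, 1, 2, 4, 8, 16, 32)
#' fitSaturation(t, 1 - exp(-log(2) * t), nBoot = 50)
#' @export
fitSaturation <- function(times, ratios, nBoot = 1000, level = 0.90,
                          seed = 1L) {
    stopifnot(length(times) == length(ratios))
    if (length(unique(times)) < 3L)
        stop("need at least three distinct time points")
    startR <- max(ratios)
    if (startR <= 0) stop("ratios must contain positive values")
    # crude half-time start plus a fallback grid of rate starts;
    # Levenberg-Marquardt on the residuals directly, so weakly
    # identified rate constants still return a least-squares solution
    tPos <- times[times > 0 & ratios > 0]
    startK <- if (length(tPos)) log(2) / stats::median(tPos) else 0.5
    .fit1 <- function(y, k0, r0) tryCatch(
        minpack.lm::nls.lm(
            par = list(rmax = r0, k = k0),
            lower = c(1e-12, 1e-12),
            fn = function(p) y - p$rmax * (1 - exp(-p$k * times)),
            control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) e)
    fit <- NULL
    for (k0 in unique(c(startK, 0.05, 0.2, 1, 5))) {
        cand <- .fit1(ratios, k0, startR)
        if (!inherits(cand, "error")) {
            if (is.null(fit) ||
                sum(cand$fvec^2) < sum(fit$fvec^2))
                fit <- cand
        }
    }
    if (is.null(fit))
        stop("saturation fit did not converge: ",
             conditionMessage(.fit1(ratios, startK, startR)))
    co <- unlist(fit$par)
    pred <- co[["rmax"]] * (1 - exp(-co[["k"]] * times))
    sigma <- sqrt(sum((ratios - pred)^2) /
                  max(1L, length(ratios) - 2L))
    set.seed(as.integer(seed))
    curves <- matrix(NA_real_, nBoot, length(times))
    pars <- matrix(NA_real_, nBoot, 2L)
    dfres <- max(1L, length(ratios) - 2L)
    for (b in seq_len(nBoot)) {
        # propagate the uncertainty of the residual SD (few time
        # points) by drawing it from its scaled inverse-chi-square
        # sampling distribution for each resample
        sigmaB <- sigma * sqrt(dfres / stats::rchisq(1, dfres))
        yb <- pred + stats::rnorm(length(times), 0, sigmaB)
        fb <- .fit1(yb, co[["k"]], co[["rmax"]])
        if (inherits(fb, "error")) next
        cb <- unlist(fb$par)
        pars[b, ] <- cb
        curves[b, ] <- cb[["rmax"]] * (1 - exp(-cb[["k"]] * times))
    }
    a <- (1 - level) / 2
    qs <- apply(curves, 2, stats::quantile, probs = c(a, 1 - a),
                na.rm = TRUE)
    ord <- order(times)
    band <- data.frame(time = times, fit = pred,
                       lower = qs[1, ], upper = qs[2, ])[ord, ]
    rownames(band) <- NULL
    ci <- rbind(rMax = stats::quantile(pars[, 1], c(a, 1 - a), na.rm = TRUE),
                k = stats::quantile(pars[, 2], c(a, 1 - a), na.rm = TRUE))
    new("SaturationFit", rMax = co[["rmax"]], k = co[["k"]],
        sigma = sigma, level = level, band = band, paramCI = ci)
}

#' Per-flight Z'-factor from a deposited per-well table
#'
#' Computes the Z'-factor for one flight from a quantitative per-well
#' results table: histamine-only wells are the positive control,
#' BAPTA-pretreated histamine wells the negative control. Column names
#' and treatment labels are supplied through a mapping so deposited
#' CSVs with differing headers can be consumed directly.
#'
#' @param table data.frame of per-well results.
#' @param flight flight identifier to subset on.
#' @param mapping list with entries \code{flight}, \code{treatment},
#'   \code{value} (column names) and \code{positive}, \code{negative}
#'   (treatment labels).
#' @return a \code{\link{ZPrimeResult}}.
#' @export
zPrimeFromDeposited <- function(table, flight,
        mapping = list(flight = "flight", treatment = "treatment",
                       value = "conversion_rate",
                       positive = "Histamine",
                       negative = "Histamine+BAPTA")) {
    need <- c(mapping$flight, mapping$treatment, mapping$value)
    if (!all(need %in% names(table)))
        stop("table lacks mapped columns: ",
             paste(setdiff(need, names(table)), collapse = ", "))
    sub <- table[table[[mapping$flight]] == flight, , drop = FALSE]
    pos <- sub[[mapping$value]][sub[[mapping$treatment]] == mapping$positive]
    neg <- sub[[mapping$value]][sub[[mapping$treatment]] == mapping$negative]
    if (length(pos) < 2L || length(neg) < 2L)
        stop("flight '", flight,
             "' lacks replicates for a mapped condition")
    zPrime(pos, neg)
}
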