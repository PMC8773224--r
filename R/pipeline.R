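# End-to-end orchestration: schedule -> simulate -> segment -> metrics
# -> baseline subtraction -> assay statistics -> report bundle.
#
# The pipeline streams well by well: at no point is more than one
# rendered field held in memory.

#' Default conversion-probability map
#'
#' Ground-truth conversion probabilities per construct and role for
#' simulated campaigns, built from the bundled reference rates:
#' CaMPARI2-F391W converts at 13% basally (all flight phases) and 65%
#' under histamine; CaMPARI2 at 2% and 55%; GFP never converts.
#'
#' @return data.frame with columns construct, role, p.
#' @export
defaultConversionRates <- function() {
    ref <- utils::read.csv(system.file("extdata",
        "reference_conversion_rates.csv", package = "CaMPARIquant"),
        stringsAsFactors = FALSE)
    base <- function(con)
        ref$conversion_rate_pct[ref$construct == con &
                                ref$condition == "Pre-Parabola"] / 100
    hist <- function(con)
        ref$conversion_rate_pct[ref$construct == con &
                                ref$condition == "Histamine"] / 100
    rows <- list(data.frame(construct = "GFP", role = "Any", p = 0))
    for (con in c("CaMPARI2", "CaMPARI2-F391W")) {
        rows[[length(rows) + 1L]] <- data.frame(
            construct = con, role = c(.FLIGHT_PHASES, "Histamine"),
            p = c(rep(base(con), 5L), hist(con)))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Default run configuration
#'
#' A small, deterministic demonstration campaign: one untreated plate,
#' all four illuminated parabolas, modest cell counts and field sizes
#' (the acceptance-scale simulations use larger wells). All entries can
#' be overridden by name.
#'
#' @param ... named overrides of config entries.
#' @return a run-config list.
#' @export
defaultRunConfig <- function(...) {
    cfg <- list(
        seed = 1L,
        outDir = file.path(tempdir(), "campariquant-run"),
        layout = defaultPlateLayout(),
        profile = defaultFlightProfile(),
        parabolas = c(0, 10, 20, 30),
        simulateParabolas = c(0, 10, 20, 30),
        rates = defaultConversionRates(),
        nCellsPerField = 15,
        fieldsPerWell = 2,
        sceneParams = SceneParams(fieldWidth = 400, fieldHeight = 400),
        segParams = SegmentationParams(),
        anovaReference = "Pre-Parabola",
        zprimePositive = "Histamine",
        zprimeNegative = "Pre-Parabola",
        zprimeCondition = "CaMPARI2-F391W",
        alpha = 0.05)
    override <- list(...)
    cfg[names(override)] <- override
    cfg
}

#' Read a run configuration from YAML
#'
#' Scalar entries (seed, counts, statistical options) and flat
#' parameter blocks \code{sceneParams} / \code{segParams} are read from
#' YAML and merged over \code{\link{defaultRunConfig}}.
#'
#' @param file YAML path.
#' @return a run-config list.
#' @export
readRunConfig <- function(file) {
    raw <- yaml::read_yaml(file)
    cfg <- defaultRunConfig()
    for (nm in setdiff(names(raw), c("sceneParams", "segParams", "rates")))
        cfg[[nm]] <- raw[[nm]]
    if (!is.null(raw$sceneParams))
        cfg$sceneParams <- do.call(SceneParams, raw$sceneParams)
    if (!is.null(raw$segParams))
        cfg$segParams <- do.call(SegmentationParams, raw$segParams)
    if (!is.null(raw$rates))
        cfg$rates <- do.call(rbind, lapply(raw$rates, as.data.frame))
    cfg
}

#' Run the full quantification pipeline
#'
#' Builds the illumination schedule and its heat budget, simulates and
#' measures every selected well (scene -> render -> mask -> metrics),
#' applies the Pre-Parabola baseline subtraction, and computes the
#' assay statistics (ANOVA/Tukey across phases per construct; Z'-factor
#' between the configured positive and negative roles). All tables are
#' written as CSV under \code{outDir} together with a plain-text run
#' log; two runs with the same seed produce byte-identical CSVs.
#'
#' @param config a run-config list from \code{\link{defaultRunConfig}}
#'   or \code{\link{readRunConfig}}.
#' @return (invisibly) the report bundle: schedule, energyJ,
#'   wellMetrics, adjusted, anova (per construct), zprime, outDir.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
    cfg <- config
    if (!dir.exists(cfg$outDir)) dir.create(cfg$outDir, recursive = TRUE)
    layout <- cfg$layout

    sched <- buildSchedule(layout, parabolas = cfg$parabolas,
                           profile = cfg$profile)
    writeSchedule(sched, file.path(cfg$outDir, "schedule.csv"))
    energy <- heatEnergy(sched)

    # phase/GFP wells are only measurable if their parabola was flown and
    # illuminated; post-flight histamine controls are measured regardless
    w <- layout@wells
    sel <- w[w$parabola %in% cfg$simulateParabolas &
             (w$role == "Histamine" | w$parabola %in% cfg$parabolas), ,
             drop = FALSE]
    if (nrow(sel) == 0L) stop("no wells selected for simulation")
    metrics <- vector("list", nrow(sel))
    for (i in seq_len(nrow(sel))) {
        p <- .resolveP(sel$construct[i], sel$role[i], cfg$rates)
        wseed <- (as.integer(cfg$seed) * 1009L +
                  match(sel$well[i], w$well) * 7919L) %% 2147483647L
        res <- measureWell(p, cfg$nCellsPerField, cfg$fieldsPerWell,
                           cfg$sceneParams, cfg$segParams,
                           seed = wseed, well = sel$well[i])
        m <- res$metrics
        m$plate <- layout@plate; m$drug <- layout@drug
        m$condition <- sel$condition[i]; m$construct <- sel$construct[i]
        m$role <- sel$role[i]; m$parabola <- sel$parabola[i]
        m$pTrue <- p; m$seed <- wseed
        metrics[[i]] <- m
    }
    wm <- do.call(rbind, metrics)
    utils::write.csv(wm, file.path(cfg$outDir, "well_metrics.csv"),
                     row.names = FALSE)

    camp <- wm[wm$construct != "GFP", , drop = FALSE]
    # baseline subtraction needs Pre-Parabola wells; a histamine-only
    # run (e.g. no illuminated parabolas) skips it
    adjusted <- if (any(camp$role == "Pre-Parabola"))
        baselineSubtract(camp, groupCols = "condition") else NULL
    if (!is.null(adjusted))
        utils::write.csv(adjusted,
                         file.path(cfg$outDir, "well_metrics_adjusted.csv"),
                         row.names = FALSE)

    anovas <- list()
    for (con in unique(camp$condition)) {
        sub <- camp[camp$condition == con & camp$role != "Histamine", ]
        cnt <- table(sub$role)
        if (length(cnt) >= 2L && all(cnt >= 2L))
            anovas[[con]] <- anovaTukey(sub$conversionRate, sub$role,
                                        reference = cfg$anovaReference,
                                        alpha = cfg$alpha)
    }

    zp <- NULL
    pos <- camp$conversionRate[camp$condition == cfg$zprimeCondition &
                               camp$role == cfg$zprimePositive]
    neg <- camp$conversionRate[camp$condition == cfg$zprimeCondition &
                               camp$role == cfg$zprimeNegative]
    if (length(pos) >= 2L && length(neg) >= 2L)
        zp <- zPrime(pos, neg)

    log <- c(
        "CaMPARIquant pipeline run",
        paste("seed:", cfg$seed),
        paste("plate:", layout@plate, "drug:", layout@drug),
        paste("scheduled events:", nrow(sched)),
        paste("heat energy (J):", energy),
        paste("simulated wells:", nrow(wm)),
        paste("fields per well:", cfg$fieldsPerWell),
        paste("cells per field:", cfg$nCellsPerField),
        if (!is.null(zp)) paste("Z'-factor:", signif(zp@zprime, 4)))
    writeLines(log, file.path(cfg$outDir, "run_log.txt"))

    invisible(list(schedule = sched, energyJ = energy, wellMetrics = wm,
                   adjusted = adjusted, anova = anovas, zprime = zp,
                   outDir = cfg$outDir, config = cfg))
}
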