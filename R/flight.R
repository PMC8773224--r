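# Parabolic-flight model: gravity profile, plate layout, per-parabola
# illumination schedule and the LED thermal budget.

#' Default parabolic-flight gravity profile
#'
#' 31 consecutive parabolas; each cycles through Pre-Parabola (1 g),
#' Pull-Up (20 s, 1.8 g), Zero-G (22 s, 1e-5 g), Pull-Out (20 s, 1.8 g)
#' and Post-Parabola (1 g). The flanking 1 g phases default to 30 s and
#' 28 s so consecutive parabola starts are 120 s apart.
#'
#' @param nParabolas number of parabolas.
#' @param preS,postS durations of the flanking 1 g phases, s.
#' @return a \code{\link{FlightProfile}}.
#' @examples
#' defaultFlightProfile()
#' @export
defaultFlightProfile <- function(nParabolas = 31, preS = 30, postS = 28) {
    phases <- data.frame(
        phase = .FLIGHT_PHASES,
        gLevel = c(1, 1.8, 1e-5, 1.8, 1),
        duration = c(preS, 20, 22, 20, postS))
    new("FlightProfile", phases = phases,
        nParabolas = as.integer(nParabolas))
}

#' Default 96-well plate layout
#'
#' CaMPARI2 wells fill the left plate half (columns 1-6) and
#' CaMPARI2-F391W the right half (columns 7-12). Within each half, each
#' of the four illuminated parabolas (0, 10, 20, 30) is assigned a block
#' of 12 wells: one turbo-GFP control, two wells per flight phase
#' (Pre-Parabola, Pull-Up, Zero-G, Pull-Out, Post-Parabola), and one
#' post-flight histamine-control well, giving 11 illuminated wells per
#' condition per parabola and 8 histamine wells per plate.
#'
#' @param plate plate identifier.
#' @param drug plate-level drug treatment (one of Untreated, DMSO, Gd3+,
#'   Thapsigargin, Flunarizine, Ruthenium red, GSK2193874, BAPTA-AM).
#' @param parabolas the four illuminated parabola numbers.
#' @return a \code{\link{PlateLayout}}.
#' @export
defaultPlateLayout <- function(plate = "P1", drug = "Untreated",
                               parabolas = c(0, 10, 20, 30)) {
    stopifnot(length(parabolas) == 4L)
    rows <- LETTERS[1:8]
    halves <- list(
        list(condition = "CaMPARI2", cols = 1:6),
        list(condition = "CaMPARI2-F391W", cols = 7:12))
    roleBlock <- c("GFP",
                   rep(.FLIGHT_PHASES, each = 2L),
                   "Histamine")
    out <- lapply(halves, function(h) {
        grid <- expand.grid(row = rows, col = h$cols,
                            stringsAsFactors = FALSE)
        grid <- grid[order(grid$col, grid$row), ]
        data.frame(
            well = paste0(grid$row, grid$col),
            row = grid$row, col = grid$col,
            condition = h$condition,
            role = rep(roleBlock, times = 4L),
            parabola = rep(parabolas, each = 12L),
            stringsAsFactors = FALSE)
    })
    w <- do.call(rbind, out)
    w$construct <- ifelse(w$role == "GFP", "GFP", w$condition)
    w <- w[, c("well", "row", "col", "condition", "construct",
               "parabola", "role")]
    new("PlateLayout", plate = plate, drug = drug, wells = w)
}

#' Per-parabola illumination schedule
#'
#' For each requested parabola and each condition (plate half), the GFP
#' control well is illuminated first at the start of the Pre-Parabola
#' phase, followed by two wells per flight phase. Within a phase, events
#' from all plates are packed sequentially in well order into waves of
#' at most \code{maxConcurrent} simultaneous 8 s illuminations (the
#' hardware drives four LEDs in parallel per unit). Histamine-control
#' wells are illuminated after the flight and are not scheduled here.
#'
#' @param layout a \code{\link{PlateLayout}} or a list of them (a unit
#'   holds two plates).
#' @param parabolas parabola numbers to schedule; must be present in the
#'   layout and within the profile.
#' @param profile a \code{\link{FlightProfile}}.
#' @param durationS illumination duration per well, s.
#' @param ledPowerW electrical power dissipated per LED, W.
#' @param radiantFluxW optical output per LED, W.
#' @param maxConcurrent concurrency limit per unit.
#' @return data.frame of illumination events: plate, well, condition,
#'   construct, parabola, phase, gLevel, start (s from flight-profile
#'   origin), duration, ledPowerW, radiantFluxW.
#' @examples
#' sched <- buildSchedule(defaultPlateLayout(), parabolas = 0)
#' nrow(sched)      # 22 events per plate per parabola
#' heatEnergy(sched)
#' @export
buildSchedule <- function(layout, parabolas = c(0, 10, 20, 30),
                          profile = defaultFlightProfile(),
                          durationS = 8, ledPowerW = 2.8,
                          radiantFluxW = 1.1, maxConcurrent = 4) {
    if (is(layout, "PlateLayout")) layout <- list(layout)
    stopifnot(all(vapply(layout, is, logical(1), "PlateLayout")))
    parabolas <- as.integer(parabolas)
    if (length(parabolas) == 0L) return(.emptySchedule())
    if (any(parabolas < 0L | parabolas >= profile@nParabolas))
        stop("parabola index outside the flight profile")
    period <- sum(profile@phases$duration)
    phaseStart <- cumsum(c(0, profile@phases$duration))[1:5]
    names(phaseStart) <- .FLIGHT_PHASES

    ev <- list()
    for (p in parabolas) {
        for (ph in .FLIGHT_PHASES) {
            block <- do.call(rbind, lapply(layout, function(L) {
                w <- L@wells
                sel <- w$parabola == p &
                    (w$role == ph | (ph == "Pre-Parabola" & w$role == "GFP"))
                if (!any(sel)) return(NULL)
                b <- w[sel, , drop = FALSE]
                # GFP first, then phase wells in well order
                b <- b[order(b$role != "GFP", b$condition, b$col, b$row), ]
                b$plate <- L@plate
                b
            }))
            if (is.null(block) || nrow(block) == 0L) {
                if (ph != "Pre-Parabola") next
                stop("layout provides no wells for parabola ", p)
            }
            # GFP events across plates lead the Pre-Parabola packing
            block <- block[order(block$role != "GFP"), , drop = FALSE]
            wave <- (seq_len(nrow(block)) - 1L) %/% maxConcurrent
            g <- profile@phases$gLevel[match(ph, .FLIGHT_PHASES)]
            ev[[length(ev) + 1L]] <- data.frame(
                plate = block$plate, well = block$well,
                condition = block$condition, construct = block$construct,
                parabola = p, phase = ph, gLevel = g,
                start = p * period + phaseStart[[ph]] + wave * durationS,
                duration = durationS, ledPowerW = ledPowerW,
                radiantFluxW = radiantFluxW,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, ev)
    out[order(out$start, out$plate, out$well), ]
}

.emptySchedule <- function() {
    data.frame(plate = character(), well = character(),
               condition = character(), construct = character(),
               parabola = integer(), phase = character(),
               gLevel = numeric(), start = numeric(),
               duration = numeric(), ledPowerW = numeric(),
               radiantFluxW = numeric(), stringsAsFactors = FALSE)
}

#' LED heat budget of an illumination schedule
#'
#' Total electrical energy dissipated as heat: the sum over events of
#' LED power times duration. The full per-unit schedule of 44 events at
#' 2.8 W for 8 s yields 985.6 J.
#'
#' @param events schedule data.frame from \code{\link{buildSchedule}}.
#' @return energy in J.
#' @export
heatEnergy <- function(events) {
    if (nrow(events) == 0L) return(0)
    sum(events$ledPowerW * events$duration)
}

#' Flight phase at a time point
#'
#' Locates a time (seconds from the profile origin) within the repeating
#' parabola cycle and returns the parabola index, phase name and g-level
#' (piecewise constant).
#'
#' @param profile a \code{\link{FlightProfile}}.
#' @param t time in s; must satisfy 0 <= t < total profile duration.
#' @return list with \code{parabola}, \code{phase}, \code{gLevel}.
#' @export
phaseAt <- function(profile, t) {
    period <- sum(profile@phases$duration)
    total <- period * profile@nParabolas
    if (length(t) != 1L || is.na(t) || t < 0 || t >= total)
        stop("'t' must lie in [0, ", total, ")")
    parab <- floor(t / period)
    within <- t - parab * period
    idx <- findInterval(within, cumsum(c(0, profile@phases$duration)),
                        rightmost.closed = FALSE)
    list(parabola = as.integer(parab),
         phase = profile@phases$phase[idx],
         gLevel = profile@phases$gLevel[idx])
}

#' Write a schedule as CSV
#'
#' @param events schedule data.frame.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeSchedule <- function(events, file) {
    utils::write.csv(events, file, row.names = FALSE)
    invisible(file)
}
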